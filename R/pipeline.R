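#' Pipeline configuration
#'
#' End-to-end orchestration: either a synthetic [cohort_spec()] or real
#' inputs (a directory of SWC files plus a metadata CSV with columns
#' `cell_id`, `layer`, `label`), exactly one of the two.
#'
#' @param synthetic_spec A [cohort_spec()], or `NULL`.
#' @param swc_dir Directory of `.swc` files, or `NULL`.
#' @param metadata_csv Metadata CSV path (required with `swc_dir`).
#' @param laminar A [laminar_model()] or path to a laminar CSV/YAML.
#' @param thresholds [qc_thresholds()].
#' @param excluded_types Types dropped before classification.
#' @param classifiers Character vector of [classifier_spec()] names.
#' @param selections Subset of `c("none", "KW", "RF_BVI")`.
#' @param sampling Logical vector of sampling settings to run.
#' @param n_folds Target fold count (reduced to the positive count when a
#'   type has fewer positives).
#' @param n_draws Monte-Carlo draws for laminar features.
#' @param bvi_trees In-fold RF BVI forest size.
#' @param seed Master seed, recorded in every artifact.
#' @param output_dir Output directory.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(synthetic_spec = NULL, swc_dir = NULL,
                            metadata_csv = NULL, laminar = laminar_model(),
                            thresholds = qc_thresholds(),
                            excluded_types = c("BP", "NGC"),
                            classifiers = "RF", selections = "KW",
                            sampling = TRUE, n_folds = 10, n_draws = 200,
                            bvi_trees = 2000, seed = 1,
                            output_dir = "morphotype_results") {
  if (is.null(synthetic_spec) == is.null(swc_dir)) {
    stop("provide exactly one of synthetic_spec or swc_dir")
  }
  if (!is.null(swc_dir) && is.null(metadata_csv)) {
    stop("metadata_csv is required with swc_dir")
  }
  if (is.character(laminar)) laminar <- read_laminar_model(laminar)
  structure(list(synthetic_spec = synthetic_spec, swc_dir = swc_dir,
                 metadata_csv = metadata_csv, laminar = laminar,
                 thresholds = thresholds, excluded_types = excluded_types,
                 classifiers = classifiers, selections = selections,
                 sampling = sampling, n_folds = n_folds, n_draws = n_draws,
                 bvi_trees = bvi_trees, seed = seed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

load_real_cohort <- function(config) {
  meta <- utils::read.csv(config$metadata_csv)
  stopifnot(all(c("cell_id", "layer", "label") %in% names(meta)))
  neurons <- lapply(seq_len(nrow(meta)), function(i) {
    path <- file.path(config$swc_dir, paste0(meta$cell_id[i], ".swc"))
    center_at_soma(read_swc(path, cell_id = meta$cell_id[i],
                            home_layer = meta$layer[i],
                            label = meta$label[i]))
  })
  cohort_roster(neurons, thresholds = config$thresholds)
}

#' Run the full classification pipeline
#'
#' Read or generate the cohort, QC and exclude, extract the 103
#' morphometrics, then cross-validate every requested (classifier,
#' selection, sampling) combination in each one-versus-all setting (the
#' seven base types plus the compound basket class). Writes the feature
#' table, a per-setting results table (classifier, selection, sampling,
#' F, TPR, TNR, morphometric count), the exclusion and QC logs, per-type
#' atypicality reports, and a reproducibility manifest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `features`, `results` (data frame),
#'   `cv` (list of `cv_result`s), `roster`, `exclusions`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  roster <- if (!is.null(config$synthetic_spec)) {
    generate_cohort(config$synthetic_spec, thresholds = config$thresholds)
  } else {
    load_real_cohort(config)
  }
  roster2 <- apply_exclusions(roster, config$excluded_types)
  excl <- attr(roster2, "exclusion_log")
  utils::write.csv(roster$table, file.path(config$output_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(excl, file.path(config$output_dir, "exclusions.csv"),
                   row.names = FALSE)

  features <- extract_feature_table(roster2, model = config$laminar,
                                    n_draws = config$n_draws,
                                    seed = derive_seed(config$seed, 1L))
  utils::write.csv(features, file.path(config$output_dir, "features.csv"),
                   row.names = FALSE)

  fx <- features[feature_columns(features)]
  base_labels <- features$label
  settings <- c(sort(unique(base_labels)), "BA")
  results <- list()
  cvs <- list()
  for (tp in settings) {
    y <- if (tp == "BA") merge_basket(base_labels) else base_labels == tp
    for (cl in config$classifiers) {
      for (sel in config$selections) {
        for (sm in config$sampling) {
          cfg <- cv_config(n_folds = min(config$n_folds, sum(y)),
                           selection = sel, sampling = sm,
                           seed = derive_seed(config$seed, 7L),
                           bvi_trees = config$bvi_trees)
          cv <- cross_validate(fx, y, classifier_spec(cl), cfg)
          key <- paste(tp, cl, sel, sm, sep = "/")
          cvs[[key]] <- cv
          results[[key]] <- data.frame(
            type = tp, classifier = cl, selection = sel, sampling = sm,
            f_measure = cv$mean_f,
            tp = cv$counts[["tp"]], n_pos = cv$n_positives,
            tn = cv$counts[["tn"]], n_neg = cv$n_negatives,
            tpr = cv$tpr, tnr = cv$tnr,
            n_morphometrics = cv$n_features_used)
        }
      }
    }
    # atypicality over all models run for this setting
    keys <- grep(paste0("^", gsub("([/])", "\\\\\\1", tp), "/"),
                 names(cvs), value = TRUE)
    atyp <- atypicality_report(cvs[keys], cell_ids = features$cell_id)
    utils::write.csv(atyp, file.path(config$output_dir,
                                     paste0("atypicality_",
                                            gsub("/", "", tp), ".csv")),
                     row.names = FALSE)
  }
  results <- do.call(rbind, c(results, make.row.names = FALSE))
  utils::write.csv(results, file.path(config$output_dir, "results.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = config$seed,
    n_cells = nrow(features),
    excluded = nrow(excl),
    classifiers = config$classifiers, selections = config$selections,
    sampling = config$sampling, n_folds = config$n_folds,
    n_draws = config$n_draws,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("morphotype")))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, results = results, cv = cvs,
                 roster = roster2, exclusions = excl))
}
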