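#' Train a one-versus-all ensemble over the base types
#'
#' One binary model per base type (the compound basket class is handled by
#' its own separate setting, not by the ensemble), each trained on the
#' full table with the configured selection and sampling.
#'
#' @param table Feature data frame.
#' @param labels Character vector of base type labels.
#' @param spec A [classifier_spec()].
#' @param selection `"none"`, `"KW"` or `"RF_BVI"`.
#' @param sampling Apply [hybrid_sample()] before fitting?
#' @param seed Integer seed.
#' @param alpha,bvi_trees,bvi_cutoff,sampler As in [cv_config()].
#' @return An `ova_ensemble`: named list of fitted models with their
#'   feature subsets, in alphabetical type order.
#' @export
train_ova <- function(table, labels, spec, selection = "KW",
                      sampling = TRUE, seed = 1, alpha = 0.05,
                      bvi_trees = 2000, bvi_cutoff = 0.01,
                      sampler = sampling_config()) {
  x <- as.data.frame(table)
  types <- sort(unique(labels))
  models <- lapply(seq_along(types), function(i) {
    tp <- types[i]
    y <- labels == tp
    med <- vapply(x, stats::median, 1, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    xi <- x
    for (j in seq_along(xi)) xi[[j]][is.na(xi[[j]])] <- med[[j]]
    cols <- colnames(xi)
    if (selection == "KW") {
      sel <- kw_select(xi, y, alpha = alpha)
      if (length(sel$selected) > 0) cols <- sel$selected
    } else if (selection == "RF_BVI") {
      sel <- rf_bvi(xi, y, n_trees = bvi_trees, cutoff = bvi_cutoff,
                    seed = derive_seed(seed, 500L + i))
      if (length(sel$selected) > 0) cols <- sel$selected
    }
    xi <- xi[cols]
    if (sampling) {
      sc <- sampler
      sc$seed <- derive_seed(seed, 600L + i)
      samp <- hybrid_sample(xi, y, sc)
      xi <- samp$table; y <- samp$labels
    }
    list(model = fit_classifier(spec, xi, y, seed = derive_seed(seed, 700L + i)),
         medians = med)
  })
  names(models) <- types
  structure(models, class = "ova_ensemble")
}

#' Multi-class combination of one-versus-all models
#'
#' Assigns each cell to the type whose model is most confident (highest
#' positive-class probability). Exact ties are broken by alphabetical
#' type order; an all-zero probability row falls back to the first type
#' with a warning.
#'
#' @param ensemble An [train_ova()] result.
#' @param newdata Feature data frame containing the training columns.
#' @return List: `type` (character vector) and `probabilities` (cells x
#'   types matrix).
#' @export
combine_multiclass <- function(ensemble, newdata) {
  stopifnot(inherits(ensemble, "ova_ensemble"))
  types <- names(ensemble)   # alphabetical by construction
  probs <- vapply(types, function(tp) {
    m <- ensemble[[tp]]
    xi <- as.data.frame(newdata)
    for (j in seq_along(xi)) {
      if (is.numeric(xi[[j]]) && anyNA(xi[[j]])) {
        xi[[j]][is.na(xi[[j]])] <- m$medians[[colnames(xi)[j]]]
      }
    }
    predict_classifier(m$model, xi)
  }, numeric(nrow(as.data.frame(newdata))))
  probs <- matrix(probs, ncol = length(types),
                  dimnames = list(NULL, types))
  if (any(rowSums(probs) == 0)) {
    warning("cell(s) with all-zero probabilities assigned to first type")
  }
  assigned <- types[apply(probs, 1, which.max)]  # first max = alphabetical
  list(type = assigned, probabilities = probs)
}

#' Atypical-cell report from cross-validation results
#'
#' Cells that different models commonly misclassify are candidate
#' atypical morphologies. Aggregates the per-cell predictions of several
#' [cross_validate()] results (for example, the two or three most
#' accurate models of one type) over all repetitions.
#'
#' @param cv_results List of `cv_result` objects over the same cells with
#'   the same truth vector.
#' @param cell_ids Optional character vector of cell identifiers.
#' @return Data frame: `cell_id`, `truth`, `times_positive`, `total_runs`,
#'   `misclass_frac`, sorted by misclassification fraction (descending).
#' @export
atypicality_report <- function(cv_results, cell_ids = NULL) {
  stopifnot(length(cv_results) >= 1,
            all(vapply(cv_results, inherits, TRUE, "cv_result")))
  truth <- cv_results[[1]]$truth
  for (cv in cv_results) stopifnot(identical(cv$truth, truth))
  preds <- do.call(rbind, lapply(cv_results, `[[`, "predictions"))
  n_runs <- nrow(preds)
  times_pos <- colSums(preds)
  misclass <- colMeans(preds != matrix(truth, n_runs, length(truth),
                                       byrow = TRUE))
  out <- data.frame(
    cell_id = cell_ids %||% sprintf("cell_%03d", seq_along(truth)),
    truth = truth, times_positive = times_pos, total_runs = n_runs,
    misclass_frac = misclass)
  out[order(-out$misclass_frac, out$cell_id), ]
}
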