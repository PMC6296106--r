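#' Quality-control thresholds
#'
#' Defaults target the reconstruction defects seen in curated interneuron
#' sets: isolated extremely long segments (tracing jumps), axons too short
#' to be informative, and arbors implausibly flat in the slice-depth (Z)
#' dimension.
#'
#' @param max_segment_length Flag any segment longer than this (micrometers).
#' @param min_axon_length Minimum total axonal cable length (micrometers).
#' @param min_depth_to_length_ratio Minimum ratio of axonal Z-range to total
#'   axonal length; flat arbors fall below 1/100 while typical ratios are
#'   near 1/60.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_segment_length = 100,
                          min_axon_length = 3000,
                          min_depth_to_length_ratio = 1 / 100) {
  stopifnot(max_segment_length > 0, min_axon_length > 0,
            min_depth_to_length_ratio > 0)
  structure(list(max_segment_length = max_segment_length,
                 min_axon_length = min_axon_length,
                 min_depth_to_length_ratio = min_depth_to_length_ratio),
            class = "qc_thresholds")
}

#' Quality-control report for a neuron
#'
#' Deterministic screen for reconstruction defects. Degenerate neurons
#' yield flags, never failures.
#'
#' @param x A centered [neuron()].
#' @param thresholds A [qc_thresholds()].
#' @return A `qc_report` list: `cell_id`, logical flags `long_segment`,
#'   `short_axon`, `flat_arbor`, `interrupted_axon`, and
#'   `multifurcation_count` (nodes with three or more children, all
#'   processes).
#' @export
qc_report <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "neuron"), inherits(thresholds, "qc_thresholds"))
  nd <- x$nodes
  seg_ax <- process_segments(x, "axon")
  seg_de <- process_segments(x, "dendrite")
  axon_len <- sum(seg_ax$length)
  axon_nodes <- nd$type == "axon"
  z_range <- if (any(axon_nodes)) diff(range(nd$z[axon_nodes])) else 0
  # multifurcations: branching points with >= 3 same-process children
  # (the soma legitimately bears several stems and is not counted)
  n_multi <- sum(vapply(c("axon", "dendrite"), function(p) {
    b <- process_bifurcations(x, p)
    sum(b$n_children >= 3L)
  }, 1L))
  structure(list(
    cell_id = x$cell_id,
    long_segment = any(c(seg_ax$length, seg_de$length) >
                       thresholds$max_segment_length),
    short_axon = axon_len < thresholds$min_axon_length,
    flat_arbor = axon_len > 0 &&
      (z_range / axon_len) < thresholds$min_depth_to_length_ratio,
    interrupted_axon = length(process_roots(x, "axon")) > 1L,
    multifurcation_count = n_multi
  ), class = "qc_report")
}

qc_flags <- function(report) {
  f <- c("long_segment", "short_axon", "flat_arbor", "interrupted_axon")
  f[vapply(report[f], isTRUE, TRUE)]
}

#' Build a cohort roster
#'
#' @param neurons List of [neuron()] objects (labels and home layers carried
#'   on the neurons).
#' @param thresholds [qc_thresholds()] used for per-cell QC reports.
#' @return A `cohort_roster`: list with `neurons`, `qc` (per-cell reports)
#'   and a `table` data frame (cell_id, label, home_layer, QC flags).
#' @export
cohort_roster <- function(neurons, thresholds = qc_thresholds()) {
  stopifnot(all(vapply(neurons, inherits, TRUE, "neuron")))
  qc <- lapply(neurons, qc_report, thresholds = thresholds)
  tab <- data.frame(
    cell_id = vapply(neurons, function(n) n$cell_id, ""),
    label = vapply(neurons, function(n) n$label, ""),
    home_layer = vapply(neurons, function(n) n$home_layer, ""),
    long_segment = vapply(qc, function(q) q$long_segment, TRUE),
    short_axon = vapply(qc, function(q) q$short_axon, TRUE),
    flat_arbor = vapply(qc, function(q) q$flat_arbor, TRUE),
    interrupted_axon = vapply(qc, function(q) q$interrupted_axon, TRUE),
    multifurcation_count = vapply(qc, function(q) q$multifurcation_count, 1L))
  structure(list(neurons = neurons, qc = qc, table = tab),
            class = "cohort_roster")
}

#' @exportS3Method base::print
print.cohort_roster <- function(x, ...) {
  cat(sprintf("<cohort_roster> %d cells; labels: %s\n", nrow(x$table),
              paste(names(table(x$table$label)), collapse = ", ")))
  invisible(x)
}

#' Apply cohort exclusion rules
#'
#' Removes first the cells of excluded (too scarce) types, then cells whose
#' QC reports flag an interrupted or short axon. Other QC flags (long
#' segments, flat arbors) are reported but do not exclude.
#'
#' @param roster A [cohort_roster()].
#' @param excluded_types Character vector of type labels to drop entirely.
#' @return The filtered `cohort_roster`, with an `exclusion_log` attribute
#'   (data frame cell_id, reason).
#' @export
apply_exclusions <- function(roster, excluded_types = c("BP", "NGC")) {
  stopifnot(inherits(roster, "cohort_roster"))
  tab <- roster$table
  reason <- rep(NA_character_, nrow(tab))
  reason[tab$label %in% excluded_types] <- "excluded_type"
  flagged <- is.na(reason) & (tab$interrupted_axon | tab$short_axon)
  reason[flagged] <- ifelse(tab$interrupted_axon[flagged],
                            "interrupted_axon", "short_axon")
  keep <- is.na(reason)
  out <- structure(list(neurons = roster$neurons[keep],
                        qc = roster$qc[keep],
                        table = tab[keep, , drop = FALSE]),
                   class = "cohort_roster")
  attr(out, "exclusion_log") <- data.frame(
    cell_id = tab$cell_id[!keep], reason = reason[!keep])
  out
}

#' Compound basket-class membership
#'
#' The nest, large and small basket types form a compound basket (BA)
#' class; base labels are preserved.
#'
#' @param labels Character vector of base type labels.
#' @param vocabulary Permitted base labels.
#' @return Logical vector: `TRUE` where the label is a basket subtype.
#' @export
merge_basket <- function(labels,
                         vocabulary = c("ChC", "BTC", "DBC", "SBC", "NBC",
                                        "MC", "LBC", "BP", "NGC")) {
  bad <- setdiff(unique(labels), vocabulary)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  labels %in% c("NBC", "LBC", "SBC")
}

#' Cortical laminar model
#'
#' Ordered layers from the pia to the white matter with thickness mean and
#' standard deviation, used by the Monte-Carlo laminar-distribution
#' morphometrics. The default values are a synthetic configuration modeled
#' on juvenile rat somatosensory cortex magnitudes; real analyses should
#' supply measured thicknesses.
#'
#' @param layers Character vector of layer names, pia first (`"L1"`).
#' @param thickness_mean,thickness_sd Numeric vectors (micrometers).
#' @return A `laminar_model` data frame.
#' @export
laminar_model <- function(layers = c("L1", "L2/3", "L4", "L5", "L6"),
                          thickness_mean = c(165, 502, 190, 525, 700),
                          thickness_sd = 0.1 * thickness_mean) {
  stopifnot(length(layers) == length(thickness_mean),
            length(layers) == length(thickness_sd),
            all(thickness_mean > 0), all(thickness_sd >= 0),
            !anyDuplicated(layers), layers[1] == "L1")
  structure(data.frame(layer = layers, thickness_mean = thickness_mean,
                       thickness_sd = thickness_sd),
            class = c("laminar_model", "data.frame"))
}

#' Read a laminar model from a CSV or YAML file
#'
#' CSV columns (or YAML keys): `layer`, `thickness_mean`, `thickness_sd`.
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @return A [laminar_model()].
#' @export
read_laminar_model <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    d <- do.call(rbind, lapply(y$layers, as.data.frame))
  } else {
    d <- utils::read.csv(path)
  }
  laminar_model(d$layer, d$thickness_mean, d$thickness_sd)
}
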