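#' Extract the full 103-morphometric feature vector for one neuron
#'
#' Assembles every standard and custom operation into a single named
#' vector in catalog order. Deterministic given the seed (which drives
#' only the Monte-Carlo laminar features). Features of an absent dendrite
#' are missing-coded; a missing axon is an error, since the axon carries
#' the discriminative signal.
#'
#' @param x A centered [neuron()].
#' @param model A [laminar_model()] (for the laminar features).
#' @param catalog The [feature_catalog()].
#' @param n_draws Monte-Carlo draws for the laminar features.
#' @param seed Integer seed.
#' @param cell_size Grid cell size (micrometers).
#' @param step Arc-length resampling step (micrometers).
#' @return Named numeric vector of length 103.
#' @export
extract_features <- function(x, model = laminar_model(),
                             catalog = feature_catalog(), n_draws = 1000,
                             seed = 1, cell_size = 20, step = 1) {
  stopifnot(inherits(x, "neuron"))
  if (!any(x$nodes$type == "axon")) {
    stop("neuron ", x$cell_id, " has no axonal arbor")
  }
  ax_br <- decompose_branches(x, "axon")
  de_br <- decompose_branches(x, "dendrite")

  std_ax <- c(branch_metrics(x, "axon", ax_br),
              distance_metrics(x, "axon"),
              angle_metrics(x, "axon", ax_br),
              topology_metrics(x, "axon", ax_br))
  std_de <- c(branch_metrics(x, "dendrite", de_br),
              distance_metrics(x, "dendrite"),
              angle_metrics(x, "dendrite", de_br),
              topology_metrics(x, "dendrite", de_br))
  names(std_de) <- paste0("d.", names(std_de))
  term <- terminal_branch_metrics(x, "axon", ax_br)

  or_ax <- orientation_metrics(x, "axon", step)
  or_de <- orientation_metrics(x, "dendrite", step)
  names(or_de) <- paste0("d.", names(or_de))
  gr_ax <- grid_metrics(x, "axon", cell_size, step)
  gr_de <- grid_metrics(x, "dendrite", cell_size, step)
  names(gr_de) <- paste0("d.", names(gr_de))
  lam_ax <- laminar_metrics(x, model, "axon", n_draws,
                            seed = derive_seed(seed, 1L), step = step)
  lam_de <- laminar_metrics(x, model, "dendrite", n_draws,
                            seed = derive_seed(seed, 2L), step = step)
  pol <- dendrite_polarity_metrics(x, step = step)
  pat <- pattern_metrics(x, ax_br)

  vals <- c(std_ax, std_de, term, or_ax, or_de, gr_ax, gr_de, lam_ax,
            "d.translaminar" = unname(lam_de["translaminar"]), pol, pat)
  out <- vals[catalog$name]
  names(out) <- catalog$name
  out
}

#' Extract the feature table for a cohort
#'
#' @param roster A [cohort_roster()] (or plain list of neurons).
#' @param model,n_draws,seed,cell_size,step As in [extract_features()];
#'   per-cell seeds are derived from `seed`.
#' @return Data frame: `cell_id`, `label`, `home_layer`, then the 103
#'   morphometrics as columns.
#' @export
extract_feature_table <- function(roster, model = laminar_model(),
                                  n_draws = 1000, seed = 1, cell_size = 20,
                                  step = 1) {
  neurons <- if (inherits(roster, "cohort_roster")) roster$neurons else roster
  catalog <- feature_catalog()
  rows <- lapply(seq_along(neurons), function(i)
    extract_features(neurons[[i]], model, catalog, n_draws,
                     seed = derive_seed(seed, 100L + i),
                     cell_size = cell_size, step = step))
  feat <- as.data.frame(do.call(rbind, rows))
  data.frame(cell_id = vapply(neurons, function(n) n$cell_id, ""),
             label = vapply(neurons, function(n) n$label, ""),
             home_layer = vapply(neurons, function(n) n$home_layer, ""),
             feat, check.names = FALSE)
}

#' Columns of a feature table that hold morphometrics
#' @param table A feature table from [extract_feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(colnames(table), c("cell_id", "label", "home_layer"))
}
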