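#' The 103-morphometric feature catalog
#'
#' 55 standard metric/topological morphometrics (per-arbor summaries of
#' branch, bifurcation and node measures for the axon and, with a `d.`
#' prefix, the dendrites, plus `t.`-prefixed axonal terminal-branch
#' features) and 48 custom quantifications of Petilla features (arbor
#' orientation and extent, grid density, Monte-Carlo laminar distribution,
#' dendritic polarity and displacement, and MC/ChC-typical pattern scores).
#' Measures sensitive to reconstruction granularity (diameters, local
#' bifurcation angles, segment counts) are deliberately absent.
#'
#' @return Data frame with columns `name`, `process` (`axon`, `dendrite`),
#'   `family`, `custom` (logical).
#' @export
feature_catalog <- function() {
  std_per_process <- c(
    "length.avg", "length.sd", "length.med", "length.max", "total_length",
    "N_stems", "N_bifurcations", "terminal_degree",
    "branch_order.avg", "branch_order.max",
    "height", "width", "depth",
    "euclidean_dist.avg", "euclidean_dist.sd", "euclidean_dist.max",
    "path_dist.avg", "path_dist.sd", "path_dist.max",
    "remote_bifurcation_angle.avg", "remote_bifurcation_angle.sd",
    "remote_tilt_angle.avg", "torque_angle.avg",
    "partition_asymmetry.avg", "partition_asymmetry.sd")
  std_family <- c(rep("branch", 5), rep("topology", 5), rep("extent", 3),
                  rep("distance", 6), rep("angle", 4), rep("topology", 2))
  terminal <- c("t.length.avg", "t.length.sd", "t.length.med",
                "t.tortuosity.avg", "t.remote_bifurcation_angle.avg")
  orient_per_process <- c(
    "eccentricity", "radial", "x_mean", "x_mean_abs", "x_sd",
    "y_mean", "y_mean_abs", "y_sd", "y_std_mean", "y_max", "y_min",
    "ratio_x", "ratio_y")
  grid_per_process <- c("grid_area", "grid_mean", "density", "density_bifs")
  laminar_axon <- c("translaminar", "l1_prob", "l1_width", "l1_bifs", "l1_gxa")
  polarity <- c("d.insert.eccentricity", "d.insert.radial", "d.insert.y_mean",
                "d.multipolar", "d.displaced")
  pattern <- c("short_vertical_terminals", "short_vertical_frac",
               "axon_origin")

  cat_ <- rbind(
    data.frame(name = std_per_process, process = "axon", family = std_family,
               custom = FALSE),
    data.frame(name = paste0("d.", std_per_process), process = "dendrite",
               family = std_family, custom = FALSE),
    data.frame(name = terminal, process = "axon", family = "terminal_branch",
               custom = FALSE),
    data.frame(name = orient_per_process, process = "axon",
               family = "orientation", custom = TRUE),
    data.frame(name = paste0("d.", orient_per_process), process = "dendrite",
               family = "orientation", custom = TRUE),
    data.frame(name = grid_per_process, process = "axon", family = "grid",
               custom = TRUE),
    data.frame(name = paste0("d.", grid_per_process), process = "dendrite",
               family = "grid", custom = TRUE),
    data.frame(name = laminar_axon, process = "axon", family = "laminar",
               custom = TRUE),
    data.frame(name = "d.translaminar", process = "dendrite",
               family = "laminar", custom = TRUE),
    data.frame(name = polarity, process = "dendrite", family = "polarity",
               custom = TRUE),
    data.frame(name = pattern, process = "axon", family = "pattern",
               custom = TRUE))
  stopifnot(!anyDuplicated(cat_$name), nrow(cat_) == 103,
            sum(!cat_$custom) == 55, sum(cat_$custom) == 48)
  cat_
}
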