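#' Resample an arbor at fixed arc-length steps
#'
#' Returns a length-weighted point cloud: each segment of the process is
#' replaced by points at midpoints of equal arc-length subdivisions, so
#' node spacing (reconstruction granularity) does not bias centroids or
#' covariances.
#'
#' @param x A centered [neuron()].
#' @param process `"axon"` or `"dendrite"`.
#' @param step Arc-length step in micrometers (default 1).
#' @return Matrix with columns `x`, `y`, `z` (0 rows if the process is
#'   absent or has zero cable length).
#' @export
resample_points <- function(x, process, step = 1) {
  seg <- process_segments(x, process)
  seg <- seg[seg$length > 0, , drop = FALSE]
  if (nrow(seg) == 0) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  npts <- pmax(1L, as.integer(ceiling(seg$length / step - 1e-9)))
  idx <- rep(seq_len(nrow(seg)), npts)
  t_ <- unlist(lapply(npts, function(k) (seq_len(k) - 0.5) / k))
  cbind(x = seg$x0[idx] + t_ * (seg$x1[idx] - seg$x0[idx]),
        y = seg$y0[idx] + t_ * (seg$y1[idx] - seg$y0[idx]),
        z = seg$z0[idx] + t_ * (seg$z1[idx] - seg$z0[idx]))
}

# Eccentricity and radial alignment of a 2D point cloud: 1 - lambda2/lambda1
# over the X-Y covariance eigenvalues, and |cos| of the principal axis
# against +Y.
xy_orientation <- function(px, py) {
  if (length(px) < 2) return(c(eccentricity = NA_real_, radial = NA_real_))
  cv <- stats::cov(cbind(px, py))
  e <- eigen(cv, symmetric = TRUE)
  l1 <- e$values[1]; l2 <- max(e$values[2], 0)
  if (l1 <= 1e-12) return(c(eccentricity = NA_real_, radial = NA_real_))
  c(eccentricity = 1 - l2 / l1, radial = abs(e$vectors[2, 1]))
}

#' Arbor orientation and extent morphometrics
#'
#' PCA-based orientation of the X-Y projection of the length-weighted
#' arbor point cloud, plus coordinate moments: signed and absolute means,
#' standard deviations, extremes, and the tangential/radial spread ratios.
#'
#' @inheritParams resample_points
#' @return Named numeric vector (all `NA` for a zero-length arbor).
#' @export
orientation_metrics <- function(x, process, step = 1) {
  nm <- c("eccentricity", "radial", "x_mean", "x_mean_abs", "x_sd", "y_mean",
          "y_mean_abs", "y_sd", "y_std_mean", "y_max", "y_min",
          "ratio_x", "ratio_y")
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  p <- resample_points(x, process, step)
  if (nrow(p) < 2) return(out)
  orient <- xy_orientation(p[, "x"], p[, "y"])
  out["eccentricity"] <- orient["eccentricity"]
  out["radial"] <- orient["radial"]
  out["x_mean"] <- mean(p[, "x"])
  out["x_mean_abs"] <- mean(abs(p[, "x"]))
  out["x_sd"] <- stats::sd(p[, "x"])
  out["y_mean"] <- mean(p[, "y"])
  out["y_mean_abs"] <- mean(abs(p[, "y"]))
  out["y_sd"] <- stats::sd(p[, "y"])
  out["y_std_mean"] <- out["y_mean"] / out["y_sd"]
  out["y_max"] <- max(p[, "y"])
  out["y_min"] <- min(p[, "y"])
  out["ratio_x"] <- out["x_sd"] / (out["x_sd"] + out["y_sd"])
  out["ratio_y"] <- out["y_sd"] / (out["x_sd"] + out["y_sd"])
  out
}

#' Grid-density morphometrics
#'
#' Overlay a square grid on the X-Y projection of the resampled arbor:
#' `grid_area` is the occupied surface, `grid_mean` the mean point count
#' per occupied cell (branch clustering), `density` the cable length per
#' occupied surface, and `density_bifs` the mean pairwise Euclidean
#' distance among bifurcation nodes (low values mean dense clustering).
#'
#' @inheritParams resample_points
#' @param cell_size Grid cell edge in micrometers (default 20).
#' @return Named numeric vector.
#' @export
grid_metrics <- function(x, process, cell_size = 20, step = 1) {
  out <- stats::setNames(rep(NA_real_, 4),
                         c("grid_area", "grid_mean", "density", "density_bifs"))
  p <- resample_points(x, process, step)
  if (nrow(p) == 0) return(out)
  cells <- paste(floor(p[, "x"] / cell_size), floor(p[, "y"] / cell_size))
  n_occ <- length(unique(cells))
  out["grid_area"] <- n_occ * cell_size^2
  out["grid_mean"] <- nrow(p) / n_occ
  out["density"] <- process_length(x, process) / out["grid_area"]
  bif <- process_bifurcations(x, process)
  if (nrow(bif) >= 2) {
    i <- match(bif$id, x$nodes$id)
    out["density_bifs"] <- mean(stats::dist(cbind(x$nodes$x[i], x$nodes$y[i],
                                                  x$nodes$z[i])))
  }
  out
}

#' Monte-Carlo laminar-distribution morphometrics
#'
#' The soma's vertical position within its home layer is unknown and layer
#' thicknesses are random; laminar reach is therefore estimated over
#' `n_draws` draws in which each thickness is sampled from a truncated
#' normal and the soma offset uniformly within the home layer.
#' `translaminar` is the probability that the arbor crosses a home-layer
#' boundary; `l1_prob` the probability of reaching layer L1; `l1_width`,
#' `l1_bifs` and `l1_gxa` are unconditional expectations (zero when L1 is
#' not reached) of the arbor's X-range, bifurcation count, and horizontal
#' fan (sum of segment |dX|) above the L1 lower boundary.
#'
#' @param x A centered [neuron()] with a known home layer.
#' @param model A [laminar_model()].
#' @param process Process whose reach is tested (default `"axon"`).
#' @param n_draws Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param step Resampling step for the point cloud.
#' @return Named numeric vector. For a dendritic arbor only
#'   `translaminar` is meaningful; the `l1_*` components are still
#'   computed from the same geometry.
#' @export
laminar_metrics <- function(x, model, process = "axon", n_draws = 1000,
                            seed = 1, step = 1) {
  out <- stats::setNames(rep(NA_real_, 5),
                         c("translaminar", "l1_prob", "l1_width", "l1_bifs",
                           "l1_gxa"))
  stopifnot(inherits(model, "laminar_model"))
  home <- x$home_layer
  if (is.na(home) || !(home %in% model$layer)) {
    stop("home layer '", home, "' not in laminar model for ", x$cell_id)
  }
  nd <- x$nodes
  sel <- nd$type == process
  if (!any(sel)) return(out)
  p <- resample_points(x, process, step)
  y_top <- max(nd$y[sel]); y_bot <- min(nd$y[sel])

  # sorted-by-Y prefix structures for O(draws + n log n) expectations
  ord <- order(p[, "y"], decreasing = TRUE)
  py <- p[ord, "y"]; px <- p[ord, "x"]
  cmax <- cummax(px); cmin <- cummin(px)
  bif <- process_bifurcations(x, process)
  bif_y <- sort(nd$y[match(bif$id, nd$id)], decreasing = TRUE)
  seg <- process_segments(x, process)
  seg_my <- (seg$y0 + seg$y1) / 2
  seg_ord <- order(seg_my, decreasing = TRUE)
  seg_dx <- cumsum(abs(seg$x1 - seg$x0)[seg_ord])
  seg_my <- seg_my[seg_ord]

  hi <- match(home, model$layer)
  between <- if (hi > 1) model$layer[seq_len(hi - 1)][-1] else character(0)
  # `between`: layers strictly between L1 and the home layer

  with_seed(seed, {
    draw_thick <- function(layer) {
      i <- match(layer, model$layer)
      t_ <- stats::rnorm(n_draws, model$thickness_mean[i], model$thickness_sd[i])
      while (any(t_ <= 0)) {
        bad <- t_ <= 0
        t_[bad] <- stats::rnorm(sum(bad), model$thickness_mean[i],
                                model$thickness_sd[i])
      }
      t_
    }
    t_home <- draw_thick(home)
    offset <- stats::runif(n_draws, 0, t_home)   # soma depth below layer top
    upper <- offset                              # home-layer top in Y frame
    lower <- offset - t_home                     # home-layer bottom
    cross <- (y_top > upper) | (y_bot < lower)
    if (home == model$layer[1]) {
      reach_l1 <- rep(TRUE, n_draws)
      b_l1 <- lower                              # inside L1: whole arbor counts
    } else {
      b_l1 <- upper
      for (l in between) b_l1 <- b_l1 + draw_thick(l)
      reach_l1 <- y_top > b_l1
    }
    k_pts <- findInterval(-b_l1, -py)            # points with y > boundary
    width_d <- ifelse(k_pts > 0, cmax[pmax(k_pts, 1)] - cmin[pmax(k_pts, 1)], 0)
    k_bif <- findInterval(-b_l1, -bif_y)
    gxa_d <- ifelse(findInterval(-b_l1, -seg_my) > 0,
                    seg_dx[pmax(findInterval(-b_l1, -seg_my), 1)], 0)
    out["translaminar"] <- mean(cross)
    out["l1_prob"] <- mean(reach_l1)
    out["l1_width"] <- mean(width_d * reach_l1)
    out["l1_bifs"] <- mean(k_bif * reach_l1)
    out["l1_gxa"] <- mean(gxa_d * reach_l1)
  })
  out
}

#' Dendritic polarity and displacement morphometrics
#'
#' Bipolar/bitufted versus multipolar dendrites are distinguished by
#' whether the dendrite roots lie along a single axis: the PCA eccentricity
#' of the unit insertion vectors (soma centroid to each dendritic root, X-Y
#' projection). `d.displaced` is the X-Y distance between the
#' length-weighted centroids of the dendritic and axonal arbors.
#'
#' @param x A centered [neuron()] with at least one dendritic root and one
#'   axonal node.
#' @param bipolarity_threshold Insertion-eccentricity cutoff below which
#'   the dendrites count as multipolar (default 0.85).
#' @param step Resampling step.
#' @return Named numeric vector.
#' @export
dendrite_polarity_metrics <- function(x, bipolarity_threshold = 0.85,
                                      step = 1) {
  out <- stats::setNames(rep(NA_real_, 5),
                         c("d.insert.eccentricity", "d.insert.radial",
                           "d.insert.y_mean", "d.multipolar", "d.displaced"))
  nd <- x$nodes
  roots <- process_roots(x, "dendrite")
  if (length(roots) == 0) return(out)
  v <- cbind(nd$x[roots], nd$y[roots])
  n <- sqrt(rowSums(v^2))
  v <- v[n > 0, , drop = FALSE] / n[n > 0]
  if (nrow(v) == 1) {
    out["d.insert.eccentricity"] <- 1
    out["d.insert.radial"] <- abs(v[1, 2])
    out["d.insert.y_mean"] <- v[1, 2]
  } else {
    orient <- xy_orientation(v[, 1], v[, 2])
    out["d.insert.eccentricity"] <- orient["eccentricity"]
    out["d.insert.radial"] <- orient["radial"]
    out["d.insert.y_mean"] <- mean(v[, 2])
  }
  out["d.multipolar"] <-
    as.numeric(out["d.insert.eccentricity"] < bipolarity_threshold)
  pa <- resample_points(x, "axon", step)
  pd <- resample_points(x, "dendrite", step)
  if (nrow(pa) > 0 && nrow(pd) > 0) {
    out["d.displaced"] <- sqrt((mean(pd[, "x"]) - mean(pa[, "x"]))^2 +
                               (mean(pd[, "y"]) - mean(pa[, "y"]))^2)
  }
  out
}

#' Type-specific arborization-pattern morphometrics
#'
#' `short_vertical_terminals` counts axonal terminal branches whose
#' endpoint displacement is predominantly vertical (`|dY| >= |dX|`) and no
#' longer than 50 micrometers vertically — the chandelier 'short vertical
#' terminal' pattern. `axon_origin` is the Y component of the unit vector
#' from the soma centroid to the axonal root (+1: the axon emerges from
#' the top of the soma).
#'
#' @inheritParams branch_metrics
#' @param max_vertical Vertical extent bound for a 'short' terminal
#'   (micrometers, default 50).
#' @return Named numeric vector.
#' @export
pattern_metrics <- function(x, branches = decompose_branches(x, "axon"),
                            max_vertical = 50) {
  out <- stats::setNames(rep(NA_real_, 3),
                         c("short_vertical_terminals", "short_vertical_frac",
                           "axon_origin"))
  nd <- x$nodes
  term <- Filter(function(b) b$is_terminal, branches)
  if (length(term) > 0) {
    disp <- vapply(term, function(b) {
      i0 <- match(b$start_id, nd$id); i1 <- match(b$end_id, nd$id)
      c(abs(nd$x[i1] - nd$x[i0]), abs(nd$y[i1] - nd$y[i0]))
    }, numeric(2))
    short_vert <- disp[2, ] <= max_vertical & disp[2, ] >= disp[1, ]
    out["short_vertical_terminals"] <- sum(short_vert)
    out["short_vertical_frac"] <- mean(short_vert)
  } else {
    out["short_vertical_terminals"] <- 0
    out["short_vertical_frac"] <- 0
  }
  roots <- process_roots(x, "axon")
  if (length(roots) > 0) {
    r <- roots[1]
    v <- c(nd$x[r], nd$y[r], nd$z[r])
    nv <- sqrt(sum(v^2))
    if (nv > 0) out["axon_origin"] <- v[2] / nv
  }
  out
}
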