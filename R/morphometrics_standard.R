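#' Branch-level summary morphometrics
#'
#' Branch path-length summaries, stem/terminal/bifurcation counts,
#' centrifugal-order summaries, and arbor extent (coordinate ranges).
#'
#' @param x A centered [neuron()].
#' @param process `"axon"` or `"dendrite"`.
#' @param branches Optional precomputed [decompose_branches()] result.
#' @return Named numeric vector (`NA` when the process is absent).
#' @export
branch_metrics <- function(x, process, branches = decompose_branches(x, process)) {
  out <- stats::setNames(rep(NA_real_, 13),
                         c("length.avg", "length.sd", "length.med",
                           "length.max", "total_length", "N_stems",
                           "N_bifurcations", "terminal_degree",
                           "branch_order.avg", "branch_order.max",
                           "height", "width", "depth"))
  if (length(branches) == 0) return(out)
  len <- vapply(branches, `[[`, 1, "length")
  ord <- vapply(branches, `[[`, 1L, "order")
  term <- vapply(branches, `[[`, TRUE, "is_terminal")
  bif <- process_bifurcations(x, process)
  nd <- x$nodes
  sel <- nd$type == process
  out["length.avg"] <- mean(len)
  out["length.sd"] <- stats::sd(len)
  out["length.med"] <- stats::median(len)
  out["length.max"] <- max(len)
  out["total_length"] <- process_length(x, process)
  out["N_stems"] <- length(process_roots(x, process))
  out["N_bifurcations"] <- nrow(bif)
  out["terminal_degree"] <- sum(term)
  out["branch_order.avg"] <- mean(ord)
  out["branch_order.max"] <- max(ord)
  out["height"] <- diff(range(nd$y[sel]))
  out["width"] <- diff(range(nd$x[sel]))
  out["depth"] <- diff(range(nd$z[sel]))
  out
}

# Path distance from every node of a process to the soma centroid: cable
# length to the arbor root plus the root's Euclidean offset from the
# (centered) soma. Returns a vector indexed by node row (NA outside the
# process).
node_path_distances <- function(x, process) {
  nd <- x$nodes
  sel <- which(nd$type == process)
  if (length(sel) == 0) return(rep(NA_real_, nrow(nd)))
  pd <- rep(NA_real_, nrow(nd))
  roots <- process_roots(x, process)
  kids <- process_children(x, process)
  for (r in roots) {
    pd[r] <- sqrt(nd$x[r]^2 + nd$y[r]^2 + nd$z[r]^2)
    stack <- r
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ch <- kids[[cur]]
      if (length(ch) > 0) {
        pd[ch] <- pd[cur] + sqrt((nd$x[ch] - nd$x[cur])^2 +
                                 (nd$y[ch] - nd$y[cur])^2 +
                                 (nd$z[ch] - nd$z[cur])^2)
        stack <- c(stack, ch)
      }
    }
  }
  pd
}

# Exact line integral of |p0 + t v| over t in [0, 1] (the mean Euclidean
# distance from the origin along a straight segment, before length
# weighting).
segment_dist_integral <- function(p0, v) {
  a <- sum(v^2); b <- 2 * sum(p0 * v); c_ <- sum(p0^2)
  if (a < 1e-24) return(sqrt(c_))
  disc <- 4 * a * c_ - b^2
  if (disc <= 1e-12 * a * max(c_, 1)) {
    # segment lies on a line through the origin
    t0 <- -b / (2 * a)
    int_abs <- if (t0 <= 0) 0.5 - t0 else if (t0 >= 1) t0 - 0.5
               else (t0^2 + (1 - t0)^2) / 2
    return(sqrt(a) * int_abs)
  }
  f <- function(t) {
    q <- sqrt(a * t^2 + b * t + c_)
    (2 * a * t + b) * q / (4 * a) +
      disc / (8 * a^1.5) * log(2 * a * t + b + 2 * sqrt(a) * q)
  }
  f(1) - f(0)
}

#' Arborization-distance morphometrics
#'
#' Euclidean and along-tree path distance from the arbor to the soma
#' centroid. Averages and standard deviations are length-weighted exact
#' line integrals over the arbor cable, so reconstruction granularity
#' (node spacing, collinear subdivision) cannot bias them; maxima are
#' exact over nodes.
#'
#' @inheritParams branch_metrics
#' @return Named numeric vector.
#' @export
distance_metrics <- function(x, process) {
  out <- stats::setNames(rep(NA_real_, 6),
                         c("euclidean_dist.avg", "euclidean_dist.sd",
                           "euclidean_dist.max", "path_dist.avg",
                           "path_dist.sd", "path_dist.max"))
  nd <- x$nodes
  sel <- nd$type == process
  if (!any(sel)) return(out)
  pd_node <- node_path_distances(x, process)
  seg <- process_segments(x, process)
  seg <- seg[seg$length > 0, , drop = FALSE]
  if (nrow(seg) > 0) {
    L <- seg$length
    # Euclidean distance: first moment by quadrature-free closed form,
    # second moment polynomial
    e1 <- e2 <- numeric(nrow(seg))
    for (i in seq_len(nrow(seg))) {
      p0 <- c(seg$x0[i], seg$y0[i], seg$z0[i])
      v <- c(seg$x1[i] - seg$x0[i], seg$y1[i] - seg$y0[i],
             seg$z1[i] - seg$z0[i])
      e1[i] <- segment_dist_integral(p0, v)
      e2[i] <- sum(p0^2) + sum(p0 * v) + sum(v^2) / 3
    }
    # path distance grows linearly along a segment from the parent's value
    prow <- match(seg$parent, nd$id)
    pd0 <- ifelse(is.na(pd_node[prow]),
                  sqrt(seg$x0^2 + seg$y0^2 + seg$z0^2), pd_node[prow])
    p1 <- pd0 + L / 2
    p2 <- pd0^2 + pd0 * L + L^2 / 3
    w <- L / sum(L)
    em <- sum(w * e1); ev <- max(sum(w * e2) - em^2, 0)
    pm <- sum(w * p1); pv <- max(sum(w * p2) - pm^2, 0)
    out["euclidean_dist.avg"] <- em
    out["euclidean_dist.sd"] <- sqrt(ev)
    out["path_dist.avg"] <- pm
    out["path_dist.sd"] <- sqrt(pv)
  }
  out["euclidean_dist.max"] <- max(sqrt(nd$x[sel]^2 + nd$y[sel]^2 +
                                        nd$z[sel]^2))
  out["path_dist.max"] <- max(pd_node, na.rm = TRUE)
  out
}

# Geometry of every strict bifurcation of a process: the bifurcation point,
# the two child-branch endpoints, the parent-branch start (NA rows when the
# bifurcation is a root), and subtree tip counts through each child.
bifurcation_geometry <- function(x, process,
                                 branches = decompose_branches(x, process)) {
  nd <- x$nodes
  pos <- function(id) {
    i <- match(id, nd$id)
    c(nd$x[i], nd$y[i], nd$z[i])
  }
  if (length(branches) == 0) return(list())
  starts <- vapply(branches, `[[`, 1L, "start_id")
  ends <- vapply(branches, `[[`, 1L, "end_id")
  is_root_branch <- vapply(branches, `[[`, TRUE, "is_root")
  by_start <- split(seq_along(branches), starts)
  out <- list()
  for (s in names(by_start)) {
    idx <- by_start[[s]]
    idx <- idx[!is_root_branch[idx]]
    if (length(idx) != 2L) next        # multifurcations and roots skipped
    b_id <- as.integer(s)
    parent_branch <- which(ends == b_id & !(seq_along(branches) %in% idx))
    out[[length(out) + 1L]] <- list(
      bif_id = b_id, bif = pos(b_id),
      child_ends = lapply(idx, function(i) pos(branches[[i]]$end_id)),
      child_first = vapply(idx, function(i) branches[[i]]$nodes[2], 1L),
      child_terminal = vapply(idx, function(i) branches[[i]]$is_terminal, TRUE),
      parent_start = if (length(parent_branch) == 1)
        pos(branches[[parent_branch[1]]]$start_id) else NULL,
      parent_bif_id = if (length(parent_branch) == 1)
        branches[[parent_branch[1]]]$start_id else NA_integer_)
  }
  out
}

#' Bifurcation-angle morphometrics
#'
#' Remote bifurcation angle (between the vectors from a bifurcation to its
#' two child-branch endpoints), remote tilt angle (between the vector back
#' to the parent-branch start and each child endpoint vector, averaged),
#' and torque (dihedral angle between consecutive bifurcation planes,
#' folded to `[0, 90]`). Multifurcations are ignored throughout.
#'
#' @inheritParams branch_metrics
#' @return Named numeric vector (`NA` when no strict bifurcation exists).
#' @export
angle_metrics <- function(x, process, branches = decompose_branches(x, process)) {
  out <- stats::setNames(rep(NA_real_, 4),
                         c("remote_bifurcation_angle.avg",
                           "remote_bifurcation_angle.sd",
                           "remote_tilt_angle.avg", "torque_angle.avg"))
  geo <- bifurcation_geometry(x, process, branches)
  if (length(geo) == 0) return(out)
  rem <- vapply(geo, function(g)
    vec_angle(g$child_ends[[1]] - g$bif, g$child_ends[[2]] - g$bif), 1)
  tilt <- vapply(geo, function(g) {
    if (is.null(g$parent_start)) return(NA_real_)
    back <- g$parent_start - g$bif
    mean(c(vec_angle(back, g$child_ends[[1]] - g$bif),
           vec_angle(back, g$child_ends[[2]] - g$bif)))
  }, 1)
  normals <- lapply(geo, function(g) {
    a <- g$child_ends[[1]] - g$bif; b <- g$child_ends[[2]] - g$bif
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    if (sqrt(sum(n^2)) < 1e-12) NULL else n / sqrt(sum(n^2))
  })
  bif_ids <- vapply(geo, `[[`, 1L, "bif_id")
  torq <- vapply(geo, function(g) {
    j <- match(g$parent_bif_id, bif_ids)
    if (is.na(j) || is.null(normals[[j]])) return(NA_real_)
    i <- match(g$bif_id, bif_ids)
    if (is.null(normals[[i]])) return(NA_real_)
    a <- vec_angle(normals[[i]], normals[[j]])
    min(a, 180 - a)
  }, 1)
  out["remote_bifurcation_angle.avg"] <- mean(rem, na.rm = TRUE)
  out["remote_bifurcation_angle.sd"] <- stats::sd(rem[!is.na(rem)])
  if (any(!is.na(tilt))) out["remote_tilt_angle.avg"] <- mean(tilt, na.rm = TRUE)
  if (any(!is.na(torq))) out["torque_angle.avg"] <- mean(torq, na.rm = TRUE)
  out
}

#' Topological morphometrics
#'
#' Partition asymmetry `|l - r| / (l + r - 2)` over the subtree tip counts
#' `l`, `r` of each strict bifurcation (0 when `l = r = 1`).
#'
#' @inheritParams branch_metrics
#' @return Named numeric vector.
#' @export
topology_metrics <- function(x, process,
                             branches = decompose_branches(x, process)) {
  out <- stats::setNames(rep(NA_real_, 2),
                         c("partition_asymmetry.avg", "partition_asymmetry.sd"))
  geo <- bifurcation_geometry(x, process, branches)
  if (length(geo) == 0) return(out)
  counts <- tip_counts(x, process)
  pa <- vapply(geo, function(g) {
    lr <- subtree_tips(x, process, g$child_first, counts)
    if (sum(lr) <= 2) 0 else abs(lr[1] - lr[2]) / (sum(lr) - 2)
  }, 1)
  out["partition_asymmetry.avg"] <- mean(pa)
  out["partition_asymmetry.sd"] <- stats::sd(pa)
  out
}

#' Axonal terminal-branch morphometrics
#'
#' Length and tortuosity (path length over straight endpoint distance,
#' always at least 1) of terminal branches, plus the remote bifurcation
#' angle restricted to bifurcations with at least one terminal child.
#' Terminal branches with coincident endpoints have undefined tortuosity
#' and are excluded from the average with a warning.
#'
#' @inheritParams branch_metrics
#' @return Named numeric vector.
#' @export
terminal_branch_metrics <- function(x, process = "axon",
                                    branches = decompose_branches(x, process)) {
  out <- stats::setNames(rep(NA_real_, 5),
                         c("t.length.avg", "t.length.sd", "t.length.med",
                           "t.tortuosity.avg",
                           "t.remote_bifurcation_angle.avg"))
  term <- Filter(function(b) b$is_terminal, branches)
  if (length(term) == 0) return(out)
  len <- vapply(term, `[[`, 1, "length")
  nd <- x$nodes
  tort <- vapply(term, function(b) {
    i0 <- match(b$start_id, nd$id); i1 <- match(b$end_id, nd$id)
    chord <- sqrt((nd$x[i1] - nd$x[i0])^2 + (nd$y[i1] - nd$y[i0])^2 +
                  (nd$z[i1] - nd$z[i0])^2)
    if (chord < 1e-9) NA_real_ else b$length / chord
  }, 1)
  if (anyNA(tort)) {
    warning(sum(is.na(tort)), " terminal branch(es) with coincident ",
            "endpoints excluded from tortuosity in ", x$cell_id)
  }
  geo <- bifurcation_geometry(x, process, branches)
  with_term <- Filter(function(g) any(g$child_terminal), geo)
  out["t.length.avg"] <- mean(len)
  out["t.length.sd"] <- stats::sd(len)
  out["t.length.med"] <- stats::median(len)
  if (any(!is.na(tort))) out["t.tortuosity.avg"] <- mean(tort, na.rm = TRUE)
  if (length(with_term) > 0) {
    out["t.remote_bifurcation_angle.avg"] <- mean(vapply(with_term, function(g)
      vec_angle(g$child_ends[[1]] - g$bif, g$child_ends[[2]] - g$bif), 1))
  }
  out
}
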