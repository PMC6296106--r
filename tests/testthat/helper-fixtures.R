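# Toy neurons and independent oracles used across the suite.

# Build a neuron from compact node rows: list(id, type, x, y, z, parent).
toy_neuron <- function(rows, cell_id = "toy", home_layer = "L4",
                       label = NA_character_) {
  df <- as.data.frame(do.call(rbind, lapply(rows, function(r)
    c(r[[1]], NA, r[[3]], r[[4]], r[[5]], 0.5, r[[6]]))))
  names(df) <- c("id", "type", "x", "y", "z", "radius", "parent")
  df$type <- vapply(rows, `[[`, "", 2)
  neuron(df, cell_id = cell_id, home_layer = home_layer, label = label)
}

# soma at origin; axon root -> A -> bifurcation B -> two terminals
toy_bifurcating <- function() {
  toy_neuron(list(
    list(1, "soma", 0, 0, 0, -1),
    list(2, "axon", 0, 10, 0, 1),
    list(3, "axon", 0, 20, 0, 2),
    list(4, "axon", 0, 30, 0, 3),      # bifurcation B
    list(5, "axon", 10, 40, 0, 4),
    list(6, "axon", -10, 40, 0, 4),
    list(7, "dendrite", 0, -10, 0, 1),
    list(8, "dendrite", 0, -20, 0, 7)))
}

# Random small axonal tree (parents always precede children).
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  rows <- list(list(1, "soma", 0, 0, 0, -1),
               list(2, "axon", stats::rnorm(1), stats::rnorm(1),
                    stats::rnorm(1), 1))
  for (i in 3:n_nodes) {
    parent <- sample(2:(i - 1), 1)
    rows[[i]] <- list(i, "axon", stats::rnorm(1, 0, 5), stats::rnorm(1, 0, 5),
                      stats::rnorm(1, 0, 5), parent)
  }
  toy_neuron(rows, cell_id = paste0("rand", seed))
}

# Insert a collinear midpoint into every in-arbor segment of a neuron
# (soma-attached stems are left alone: subdividing them would move the
# arbor root, which is a structural change, not a granularity change).
subdivide_segments <- function(x) {
  nd <- x$nodes
  next_id <- max(nd$id) + 1L
  new_rows <- list()
  for (i in seq_len(nrow(nd))) {
    if (nd$parent[i] == -1L) next
    p <- match(nd$parent[i], nd$id)
    if (nd$type[p] != nd$type[i]) next
    mid <- list(id = next_id, type = nd$type[i],
                x = (nd$x[i] + nd$x[p]) / 2, y = (nd$y[i] + nd$y[p]) / 2,
                z = (nd$z[i] + nd$z[p]) / 2, radius = nd$radius[i],
                parent = nd$parent[i])
    nd$parent[i] <- next_id
    next_id <- next_id + 1L
    new_rows[[length(new_rows) + 1L]] <- mid
  }
  nd2 <- rbind(nd, do.call(rbind, lapply(new_rows, as.data.frame)))
  neuron(nd2, cell_id = x$cell_id, home_layer = x$home_layer,
         label = x$label)
}

# Rigid rotation of all coordinates about the origin.
rotate_neuron <- function(x, axis, deg) {
  th <- deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  m <- as.matrix(x$nodes[, c("x", "y", "z")])
  rot <- function(v) {
    v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                    k[3] * v[1] - k[1] * v[3],
                    k[1] * v[2] - k[2] * v[1]) * sin(th) +
      k * sum(k * v) * (1 - cos(th))
  }
  m2 <- t(apply(m, 1, rot))
  x$nodes$x <- m2[, 1]; x$nodes$y <- m2[, 2]; x$nodes$z <- m2[, 3]
  x
}

# ---- independent oracles -------------------------------------------------

# First-principles recomputation of selected arbor summaries, enumerating
# chains and subtrees directly on the node table.
oracle_arbor_stats <- function(x, process) {
  nd <- x$nodes
  in_proc <- nd$type == process
  pidx <- match(nd$parent, nd$id)
  child_of <- function(i) which(in_proc & !is.na(pidx) & pidx == i & in_proc[pmax(pidx, 1)])
  nkids <- vapply(seq_len(nrow(nd)), function(i)
    if (in_proc[i]) length(child_of(i)) else NA_integer_, 1L)
  roots <- which(in_proc & (is.na(pidx) | !in_proc[pmax(pidx, 1)] |
                            nd$parent == -1L))
  dist3 <- function(i, j) sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2 +
                               (nd$z[i] - nd$z[j])^2)
  # chains: heads are roots and children of branching nodes
  heads <- c(roots, which(in_proc & !is.na(pidx) & in_proc[pmax(pidx, 1)] &
                          vapply(pidx, function(p)
                            !is.na(p) && in_proc[p] && nkids[p] >= 2, TRUE)))
  heads <- unique(heads)
  branch_lengths <- c()
  endpoints <- list()
  for (h in heads) {
    len <- if (h %in% roots) 0 else dist3(h, pidx[h])
    cur <- h
    while (nkids[cur] == 1L) {
      nxt <- child_of(cur)
      len <- len + dist3(cur, nxt)
      cur <- nxt
    }
    branch_lengths <- c(branch_lengths, len)
    endpoints[[length(endpoints) + 1L]] <- list(head = h, end = cur)
  }
  # tips below each node
  tips_below <- function(i) {
    ch <- child_of(i)
    if (length(ch) == 0) 1L else sum(vapply(ch, tips_below, 1L))
  }
  pa <- c()
  ang <- c()
  for (i in which(in_proc & nkids == 2L)) {
    ch <- child_of(i)
    lr <- vapply(ch, tips_below, 1L)
    pa <- c(pa, if (sum(lr) <= 2) 0 else abs(lr[1] - lr[2]) / (sum(lr) - 2))
    ends <- vapply(ch, function(cc) {
      cur <- cc
      while (nkids[cur] == 1L) cur <- child_of(cur)
      cur
    }, 1L)
    v1 <- c(nd$x[ends[1]] - nd$x[i], nd$y[ends[1]] - nd$y[i],
            nd$z[ends[1]] - nd$z[i])
    v2 <- c(nd$x[ends[2]] - nd$x[i], nd$y[ends[2]] - nd$y[i],
            nd$z[ends[2]] - nd$z[i])
    ang <- c(ang, acos(min(1, max(-1, sum(v1 * v2) /
                                  sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi)
  }
  seg_child <- which(in_proc & !is.na(pidx))
  list(
    total_length = sum(vapply(seg_child, function(i) dist3(i, pidx[i]), 1)),
    n_stems = length(roots),
    terminal_degree = sum(nkids == 0L, na.rm = TRUE),
    branch_lengths = sort(branch_lengths),
    partition_asymmetry = pa,
    remote_angles = sort(ang),
    euclid_max = max(sqrt(nd$x[in_proc]^2 + nd$y[in_proc]^2 +
                          nd$z[in_proc]^2)))
}

# Brute-force Benjamini-Hochberg adjustment.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  adj
}

# Tie-corrected Kruskal-Wallis statistic for two groups, from first
# principles.
oracle_kw_stat <- function(v, g) {
  r <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}
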