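#' Construct a neuron from a node table
#'
#' A neuron is a forest of reconstruction points (soma, axon, dendrite)
#' with parent links, as stored in SWC files, plus the metadata used by the
#' classification pipeline: the cortical layer containing the soma and an
#' optional type label.
#'
#' @param nodes Data frame with columns `id`, `type` (SWC integer code or one
#'   of `"soma"`, `"axon"`, `"dendrite"`, `"other"`), `x`, `y`, `z`, `radius`,
#'   `parent` (`-1` or `NA` for roots). Coordinates and radii in micrometers.
#' @param cell_id Character cell identifier.
#' @param home_layer Name of the cortical layer containing the soma, or `NA`.
#' @param label Morphological type label, or `NA`.
#' @return An object of class `neuron`.
#' @export
neuron <- function(nodes, cell_id = "cell", home_layer = NA_character_,
                   label = NA_character_) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(required %in% names(nodes))) {
    stop("nodes must have columns: ", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  if (is.numeric(nodes$type)) {
    nodes$type <- c("soma", "axon", "dendrite", "dendrite")[
      ifelse(nodes$type %in% 1:4, nodes$type, NA_integer_)]
    nodes$type[is.na(nodes$type)] <- "other"
  }
  nodes$type <- as.character(nodes$type)
  nodes$id <- as.integer(nodes$id)
  nodes$parent[is.na(nodes$parent)] <- -1L
  nodes$parent <- as.integer(nodes$parent)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (any(nodes$radius < 0)) stop("negative radius")
  miss <- setdiff(nodes$parent[nodes$parent != -1L], nodes$id)
  if (length(miss) > 0) {
    stop("parent id(s) absent from node table: ", paste(miss, collapse = ", "))
  }
  check_acyclic(nodes)
  structure(list(cell_id = cell_id, nodes = nodes,
                 home_layer = home_layer, label = label),
            class = "neuron")
}

# Parent links must form a forest: every node reaches a root without revisits.
check_acyclic <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)   # NA for roots
  n <- nrow(nodes)
  state <- integer(n)                    # 0 unseen, 1 in progress, 2 done
  for (i in seq_len(n)) {
    j <- i
    path <- integer(0)
    while (!is.na(j) && state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- idx[j]
    }
    if (!is.na(j) && state[j] == 1L) stop("cyclic parent links in node table")
    state[path] <- 2L
  }
  invisible(TRUE)
}

#' @exportS3Method base::print
print.neuron <- function(x, ...) {
  cat(sprintf("<neuron %s> %d nodes (%d soma, %d axon, %d dendrite)",
              x$cell_id, nrow(x$nodes), sum(x$nodes$type == "soma"),
              sum(x$nodes$type == "axon"), sum(x$nodes$type == "dendrite")))
  if (!is.na(x$label)) cat(" label:", x$label)
  if (!is.na(x$home_layer)) cat(" layer:", x$home_layer)
  cat("\n")
  invisible(x)
}

#' Read a neuron from an SWC file
#'
#' Standard whitespace-delimited seven-column SWC with `#` comment lines:
#' `id type x y z radius parent`. SWC structure type 1 maps to soma, 2 to
#' axon, 3 and 4 both to dendrite (interneurons have no apical dendrite),
#' any other code to `other`. The neuron is returned un-centered.
#'
#' @param path Path to an SWC file.
#' @param cell_id Cell identifier; defaults to the file name without extension.
#' @param home_layer,label Optional metadata, as in [neuron()].
#' @return A [neuron()].
#' @export
read_swc <- function(path, cell_id = NULL, home_layer = NA_character_,
                     label = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty SWC file: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad) > 0) {
    stop("malformed SWC line ", which(keep)[bad[1]], " in ", path)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    stop("non-numeric SWC field at line ", which(keep)[which(rowSums(is.na(m)) > 0)[1]])
  }
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                      parent = as.integer(m[, 7]))
  miss <- setdiff(nodes$parent[nodes$parent != -1L], nodes$id)
  if (length(miss) > 0) {
    at <- which(nodes$parent %in% miss)[1]
    stop("SWC line ", which(keep)[at], ": parent id ", nodes$parent[at],
         " absent from file ", path)
  }
  neuron(nodes, cell_id = cell_id %||% sub("\\.[^.]*$", "", basename(path)),
         home_layer = home_layer, label = label)
}

#' Write a neuron to an SWC file
#'
#' @param x A [neuron()].
#' @param path Output file path.
#' @param digits Number of significant digits for coordinates and radii.
#' @return `path`, invisibly.
#' @export
write_swc <- function(x, path, digits = 6) {
  stopifnot(inherits(x, "neuron"))
  code <- c(soma = 1L, axon = 2L, dendrite = 3L, other = 5L)[x$nodes$type]
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  lines <- paste(x$nodes$id, code, fmt(x$nodes$x), fmt(x$nodes$y),
                 fmt(x$nodes$z), fmt(x$nodes$radius), x$nodes$parent)
  writeLines(c(paste("#", x$cell_id), lines), path)
  invisible(path)
}

#' Center a neuron at its soma centroid
#'
#' Translates all coordinates so the arithmetic mean of the soma-node
#' coordinates is the origin. Morphometrics assume this frame (Y is the
#' radial axis, pia in +Y). Idempotent.
#'
#' @param x A [neuron()] with at least one soma node.
#' @return The centered neuron.
#' @export
center_at_soma <- function(x) {
  stopifnot(inherits(x, "neuron"))
  s <- x$nodes$type == "soma"
  if (!any(s)) stop("neuron ", x$cell_id, " has no soma nodes")
  ctr <- c(mean(x$nodes$x[s]), mean(x$nodes$y[s]), mean(x$nodes$z[s]))
  x$nodes$x <- x$nodes$x - ctr[1]
  x$nodes$y <- x$nodes$y - ctr[2]
  x$nodes$z <- x$nodes$z - ctr[3]
  x
}

# Segment table of one process: child/parent node coordinates and lengths.
# A segment belongs to a process when its child node does; segments that cross
# from the soma are measured from the recorded soma surface point.
process_segments <- function(x, process) {
  nd <- x$nodes
  sel <- which(nd$type == process & nd$parent != -1L)
  if (length(sel) == 0) {
    return(data.frame(child = integer(0), parent = integer(0),
                      x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      length = numeric(0)))
  }
  pi_ <- match(nd$parent[sel], nd$id)
  d <- sqrt((nd$x[sel] - nd$x[pi_])^2 + (nd$y[sel] - nd$y[pi_])^2 +
            (nd$z[sel] - nd$z[pi_])^2)
  data.frame(child = nd$id[sel], parent = nd$id[pi_],
             x0 = nd$x[pi_], y0 = nd$y[pi_], z0 = nd$z[pi_],
             x1 = nd$x[sel], y1 = nd$y[sel], z1 = nd$z[sel], length = d)
}

# Total cable length of a process, in micrometers.
process_length <- function(x, process) {
  sum(process_segments(x, process)$length)
}

# Root nodes of a process: process nodes whose parent is absent or of a
# different process (usually the soma).
process_roots <- function(x, process) {
  nd <- x$nodes
  sel <- nd$type == process
  pt <- nd$type[match(nd$parent, nd$id)]
  which(sel & (nd$parent == -1L | is.na(pt) | pt != process))
}
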