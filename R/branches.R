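# Index-based adjacency of one process: for every node row, the integer
# rows of its same-process children. Built once per traversal.
process_children <- function(x, process) {
  nd <- x$nodes
  n <- nrow(nd)
  in_proc <- nd$type == process
  pidx <- match(nd$parent, nd$id)
  kid <- which(in_proc)
  kid <- kid[!is.na(pidx[kid])]
  kid <- kid[in_proc[pidx[kid]]]
  split(kid, factor(pidx[kid], levels = seq_len(n)))
}

#' Decompose an arbor into branches
#'
#' A branch is the maximal node path between a root or branching point and
#' the next branching point or terminal tip. Nodes with three or more
#' children (multifurcations) terminate branches exactly as bifurcations do;
#' they are, however, skipped by all angle and partition-asymmetry
#' statistics downstream.
#'
#' @param x A centered [neuron()].
#' @param process `"axon"` or `"dendrite"`.
#' @return A list of branches, each a list with elements `nodes` (node ids;
#'   the first node is shared with the parent branch), `order` (centrifugal
#'   order, root branch = 0), `is_terminal`, `is_root`, `length` (path
#'   length, micrometers), `start_id`, `end_id`. Empty list when the
#'   process is absent.
#' @export
decompose_branches <- function(x, process) {
  stopifnot(inherits(x, "neuron"))
  nd <- x$nodes
  if (!any(nd$type == process)) return(list())
  kids <- process_children(x, process)
  roots <- process_roots(x, process)
  branches <- list()
  stack <- lapply(roots, function(r) list(attach = NA_integer_, start = r,
                                          order = 0L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    path <- c(if (!is.na(top$attach)) top$attach, top$start)
    cur <- top$start
    repeat {
      ch <- kids[[cur]]
      if (length(ch) == 1L) {
        cur <- ch
        path <- c(path, cur)
      } else break
    }
    ch <- kids[[cur]]
    seg_len <- if (length(path) > 1) {
      i0 <- path[-length(path)]; i1 <- path[-1]
      sum(sqrt((nd$x[i1] - nd$x[i0])^2 + (nd$y[i1] - nd$y[i0])^2 +
               (nd$z[i1] - nd$z[i0])^2))
    } else 0
    branches[[length(branches) + 1L]] <- list(
      nodes = nd$id[path], order = top$order, is_terminal = length(ch) == 0L,
      is_root = is.na(top$attach), length = seg_len,
      start_id = nd$id[path[1]], end_id = nd$id[cur])
    for (k in rev(ch)) {
      stack[[length(stack) + 1L]] <- list(attach = cur, start = k,
                                          order = top$order + 1L)
    }
  }
  branches
}

# Bifurcation table of a process: one row per branching node with the
# number of same-process children; `strict` marks true bifurcations.
process_bifurcations <- function(x, process) {
  nd <- x$nodes
  in_proc <- nd$type == process
  pidx <- match(nd$parent, nd$id)
  kid <- which(in_proc & !is.na(pidx))
  kid <- kid[in_proc[pidx[kid]]]
  tab <- tabulate(pidx[kid], nbins = nrow(nd))
  sel <- which(tab >= 2L)
  data.frame(id = nd$id[sel], n_children = tab[sel], strict = tab[sel] == 2L)
}

# Terminal-tip count of the subtree under every node, computed in one
# bottom-up pass over a depth-first ordering. Returns a vector indexed by
# node row (NA outside the process).
tip_counts <- function(x, process) {
  nd <- x$nodes
  n <- nrow(nd)
  kids <- process_children(x, process)
  tips <- rep(NA_real_, n)
  roots <- process_roots(x, process)
  order_ <- integer(n)
  oi <- 0L
  stack <- roots
  while (length(stack) > 0) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    oi <- oi + 1L
    order_[oi] <- cur
    stack <- c(stack, kids[[cur]])
  }
  order_ <- order_[seq_len(oi)]
  for (i in rev(order_)) {
    ch <- kids[[i]]
    tips[i] <- if (length(ch) == 0L) 1 else sum(tips[ch])
  }
  tips
}

# Tip counts for specific node ids (thin wrapper over tip_counts).
subtree_tips <- function(x, process, ids, counts = tip_counts(x, process)) {
  counts[match(ids, x$nodes$id)]
}
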