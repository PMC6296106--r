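#' Kruskal-Wallis feature relevance with FDR control
#'
#' Per-feature rank test of the positive against the negative class (the
#' two-group Kruskal-Wallis test, tie-corrected), with Benjamini-Hochberg
#' adjustment across features. A feature is selected when its adjusted
#' p-value is below `alpha`. Being rank-based, the ranking is invariant
#' under strictly monotone transforms of any feature.
#'
#' @param table Data frame or matrix of numeric features (rows = cells).
#' @param labels Logical vector (`TRUE` = positive class) or two-level
#'   factor whose second level is taken as positive.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return A `selection_result`: list with `method`, `ranking` (data frame
#'   `feature`, `statistic`, `p`, `p_adj`, `selected`, ordered by adjusted
#'   then raw p, ties broken by feature name) and `selected` (character).
#' @export
kw_select <- function(table, labels, alpha = 0.05) {
  x <- as.data.frame(table)
  g <- as_binary_labels(labels)
  if (length(unique(g)) < 2) stop("both classes required")
  res <- vapply(x, function(v) {
    ok <- !is.na(v)
    if (sum(ok) < 2 || length(unique(v[ok])) == 1 ||
        length(unique(g[ok])) < 2) {
      return(c(stat = NA_real_, p = 1))   # constant/degenerate: p = 1
    }
    kt <- stats::kruskal.test(v[ok], factor(g[ok]))
    c(stat = unname(kt$statistic), p = kt$p.value)
  }, numeric(2))
  if (anyNA(x)) warning("missing feature values excluded pairwise")
  p <- res["p", ]
  p[is.na(p)] <- 1
  p_adj <- stats::p.adjust(p, method = "BH")
  ranking <- data.frame(feature = colnames(x), statistic = res["stat", ],
                        p = p, p_adj = p_adj, selected = p_adj < alpha,
                        row.names = NULL)
  ranking <- ranking[order(ranking$p_adj, ranking$p, ranking$feature), ]
  structure(list(method = "KW", ranking = ranking,
                 selected = ranking$feature[ranking$selected]),
            class = "selection_result")
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must be binary")
  f == levels(f)[2]
}

#' Balanced random-forest variable importance
#'
#' Fits a random forest and scores each feature by the arithmetic mean of
#' its per-class permutation importances (the mean decrease in class-wise
#' out-of-bag accuracy), so the scarce positive class weighs as much as
#' the majority. Features with balanced importance above `cutoff` are
#' selected.
#'
#' @inheritParams kw_select
#' @param n_trees Number of trees (default 20000 for stable rankings).
#' @param mtry Variables per split; default `floor(sqrt(ncol(table)))`.
#' @param cutoff Selection threshold on the balanced importance
#'   (default 0.01).
#' @param seed Integer seed.
#' @return A `selection_result` with per-class importances alongside the
#'   balanced score.
#' @export
rf_bvi <- function(table, labels, n_trees = 20000, mtry = NULL, cutoff = 0.01,
                   seed = 1) {
  x <- as.data.frame(table)
  g <- as_binary_labels(labels)
  if (length(unique(g)) < 2) stop("both classes required")
  y <- factor(ifelse(g, "pos", "neg"), levels = c("neg", "pos"))
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  fit <- with_seed(seed,
    randomForest::randomForest(x = randomForest::na.roughfix(x), y = y,
                               ntree = n_trees, mtry = mtry,
                               importance = TRUE))
  imp <- fit$importance   # unscaled per-class mean decrease in accuracy
  bvi <- (imp[, "neg"] + imp[, "pos"]) / 2
  ranking <- data.frame(feature = colnames(x), vi_neg = imp[, "neg"],
                        vi_pos = imp[, "pos"], bvi = bvi,
                        selected = bvi > cutoff, row.names = NULL)
  ranking <- ranking[order(-ranking$bvi, ranking$feature), ]
  structure(list(method = "RF_BVI", ranking = ranking,
                 selected = ranking$feature[ranking$selected]),
            class = "selection_result")
}

#' @exportS3Method base::print
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result %s> %d/%d features selected\n", x$method,
              length(x$selected), nrow(x$ranking)))
  invisible(x)
}

#' Prune correlated features in rank order
#'
#' Greedy pass keeping a feature only if its absolute Pearson correlation
#' with every better-ranked kept feature is at most `threshold`.
#'
#' @param ranked_features Character vector, best first.
#' @param table Feature table containing those columns.
#' @param threshold Absolute-correlation bound (default 0.90).
#' @return Character vector of kept features, in rank order.
#' @export
correlation_prune <- function(ranked_features, table, threshold = 0.90) {
  kept <- character(0)
  for (f in ranked_features) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(stats::cor(table[[f]], table[[k]],
                                       use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, f)
  }
  kept
}
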