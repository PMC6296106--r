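#' F-measure of the positive class
#'
#' Harmonic mean of precision `tp / (tp + fp)` and recall
#' `tp / (tp + fn)`. Counts may be fractional (averages over
#' cross-validation repetitions). Defined as 0 when `tp = 0` and some
#' error exists; an all-zero confusion is an error.
#'
#' @param tp,fp,fn Non-negative (possibly fractional) confusion counts.
#' @return F-measure in `[0, 1]`.
#' @export
f_measure <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  if (tp + fp + fn == 0) stop("undefined F-measure: no counts")
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Cross-validation configuration
#'
#' Repeated stratified k-fold cross-validation with feature selection and
#' sampling executed inside the loop (on training folds only, never on
#' held-out rows). Ten repetitions are used whenever sampling is enabled
#' (sampling is stochastic), one otherwise.
#'
#' @param n_folds Folds (default 10; use 7 when only seven positives
#'   exist).
#' @param n_repeats Repetitions; default 10 with sampling, 1 without.
#' @param selection `"none"`, `"KW"` or `"RF_BVI"`.
#' @param sampling Apply [hybrid_sample()] to training folds?
#' @param seed Master seed (drives folds, sampling and learners).
#' @param alpha KW selection threshold.
#' @param bvi_trees,bvi_cutoff RF BVI forest size and threshold; the
#'   default forest is reduced from the 20000-tree standalone setting to
#'   keep in-fold selection affordable.
#' @param sampler A [sampling_config()].
#' @return A `cv_config`.
#' @export
cv_config <- function(n_folds = 10, n_repeats = NULL,
                      selection = c("none", "KW", "RF_BVI"),
                      sampling = FALSE, seed = 1, alpha = 0.05,
                      bvi_trees = 2000, bvi_cutoff = 0.01,
                      sampler = sampling_config()) {
  selection <- match.arg(selection)
  n_repeats <- n_repeats %||% if (sampling) 10L else 1L
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), selection = selection,
                 sampling = sampling, seed = seed, alpha = alpha,
                 bvi_trees = bvi_trees, bvi_cutoff = bvi_cutoff,
                 sampler = sampler),
            class = "cv_config")
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin, so per-fold class proportions are within one cell of
# the global proportions.
stratified_folds <- function(y, n_folds, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

#' One-versus-all repeated cross-validation
#'
#' For each repetition and fold: fit the configured feature selection on
#' the training rows, reduce columns, optionally rebalance the training
#' rows, fit the classifier, and predict held-out rows with positive-class
#' probabilities. Missing feature values are imputed with train-fold
#' medians. Fold predictions are pooled per repetition into confusion
#' counts and an F-measure; counts are then averaged over repetitions
#' (hence possibly fractional).
#'
#' @param table Feature data frame (numeric columns only).
#' @param labels Logical vector, `TRUE` = positive class.
#' @param spec A [classifier_spec()].
#' @param config A [cv_config()].
#' @return A `cv_result`: per-repetition counts and F, averaged counts,
#'   `mean_f`, TPR/TNR, per-cell prediction and probability matrices
#'   (repetitions x cells), selected features per fold, and the median
#'   number of features used.
#' @export
cross_validate <- function(table, labels, spec, config = cv_config()) {
  x <- as.data.frame(table)
  y <- as_binary_labels(labels)
  stopifnot(nrow(x) == length(y))
  n_pos <- sum(y)
  if (n_pos < config$n_folds) {
    stop("positive count (", n_pos, ") is below n_folds (", config$n_folds,
         "); use a smaller k, e.g. cv_config(n_folds = ", n_pos, ")")
  }
  n <- nrow(x)
  preds <- matrix(NA, config$n_repeats, n)
  probs <- matrix(NA_real_, config$n_repeats, n)
  rep_counts <- matrix(0, config$n_repeats, 4,
                       dimnames = list(NULL, c("tp", "fp", "tn", "fn")))
  sel_log <- list()
  n_feat <- integer(0)

  for (r in seq_len(config$n_repeats)) {
    fold <- stratified_folds(y, config$n_folds,
                             derive_seed(config$seed, r))
    for (k in seq_len(config$n_folds)) {
      tr <- which(fold != k); te <- which(fold == k)
      if (length(unique(y[tr])) < 2) {
        stop("a class is absent from training fold ", k, " (repetition ",
             r, ")")
      }
      xtr <- x[tr, , drop = FALSE]
      med <- vapply(xtr, stats::median, 1, na.rm = TRUE)
      med[!is.finite(med)] <- 0
      impute <- function(d) {
        for (j in seq_along(d)) d[[j]][is.na(d[[j]])] <- med[[j]]
        d
      }
      xtr <- impute(xtr)
      xte <- impute(x[te, , drop = FALSE])

      cols <- colnames(x)
      if (config$selection == "KW") {
        sel <- kw_select(xtr, y[tr], alpha = config$alpha)
        if (length(sel$selected) > 0) cols <- sel$selected
      } else if (config$selection == "RF_BVI") {
        sel <- rf_bvi(xtr, y[tr], n_trees = config$bvi_trees,
                      cutoff = config$bvi_cutoff,
                      seed = derive_seed(config$seed, 1000L * r + k))
        if (length(sel$selected) > 0) cols <- sel$selected
      }
      sel_log[[length(sel_log) + 1L]] <- cols
      n_feat <- c(n_feat, length(cols))
      xtr <- xtr[cols]
      xte <- xte[cols]

      ytr <- y[tr]
      if (config$sampling) {
        sc <- config$sampler
        sc$seed <- derive_seed(config$seed, 2000L * r + k)
        samp <- hybrid_sample(xtr, ytr, sc)
        xtr <- samp$table; ytr <- samp$labels
      }
      model <- fit_classifier(spec, xtr, ytr,
                              seed = derive_seed(config$seed, 3000L * r + k))
      p <- predict_classifier(model, xte)
      probs[r, te] <- p
      preds[r, te] <- p >= 0.5
    }
    rep_counts[r, ] <- c(tp = sum(preds[r, ] & y),
                         fp = sum(preds[r, ] & !y),
                         tn = sum(!preds[r, ] & !y),
                         fn = sum(!preds[r, ] & y))
  }
  f_rep <- apply(rep_counts, 1, function(cc)
    f_measure(cc["tp"], cc["fp"], cc["fn"]))
  avg <- colMeans(rep_counts)
  structure(list(
    counts_per_rep = as.data.frame(rep_counts), f_per_rep = f_rep,
    counts = avg, mean_f = mean(f_rep),
    tpr = avg["tp"] / n_pos, tnr = avg["tn"] / (n - n_pos),
    n_positives = n_pos, n_negatives = n - n_pos,
    predictions = preds, probabilities = probs, truth = y,
    selected_features = sel_log,
    n_features_used = stats::median(n_feat),
    spec = spec, config = config), class = "cv_result")
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result %s/%s%s> F = %.2f  TP %.1f / %d  TN %.1f / %d  (%d features)\n",
    x$spec$name, x$config$selection,
    if (x$config$sampling) "/sampling" else "", x$mean_f,
    x$counts["tp"], x$n_positives, x$counts["tn"], x$n_negatives,
    x$n_features_used))
  invisible(x)
}
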