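#' Hybrid sampling configuration
#'
#' Class rebalancing for one-versus-all training sets: random
#' undersampling of the majority negatives combined with SMOTE
#' oversampling of the minority positives. Defaults keep half of the
#' negatives and add two synthetic positives per real positive — on a
#' 7-positive / 210-negative task this retains 105 negatives and adds 14
#' synthetic positives, a 126-row training set. When the positive class is
#' already the majority, nothing is removed or added.
#'
#' @param undersample_fraction Fraction of negatives retained (default 0.5).
#' @param smote_multiplier Synthetic positives per real positive
#'   (default 2).
#' @param k_neighbors SMOTE neighbor count (default 5; reduced with a
#'   warning when fewer positives exist).
#' @param seed Integer seed.
#' @return A `sampling_config`.
#' @export
sampling_config <- function(undersample_fraction = 0.5, smote_multiplier = 2,
                            k_neighbors = 5, seed = 1) {
  stopifnot(undersample_fraction > 0, undersample_fraction <= 1,
            smote_multiplier >= 0, k_neighbors >= 1)
  structure(list(undersample_fraction = undersample_fraction,
                 smote_multiplier = smote_multiplier,
                 k_neighbors = k_neighbors, seed = seed),
            class = "sampling_config")
}

#' Hybrid undersampling + SMOTE oversampling
#'
#' Each synthetic positive is `x + u (x_nn - x)` for a real positive `x`,
#' one of its `k` nearest positive neighbors `x_nn` (Euclidean, in feature
#' space) and `u ~ Uniform(0, 1)`, so synthetic points lie on segments
#' between real positives.
#'
#' @param table Data frame of numeric features.
#' @param labels Logical vector (`TRUE` = positive) or two-level factor.
#' @param config A [sampling_config()].
#' @return List: `table` (resampled features), `labels` (logical),
#'   `synthetic` (logical marker of SMOTE rows), `log` (counts before and
#'   after).
#' @export
hybrid_sample <- function(table, labels, config = sampling_config()) {
  x <- as.data.frame(table)
  g <- as_binary_labels(labels)
  n_pos <- sum(g); n_neg <- sum(!g)
  if (n_pos >= n_neg) {
    # positive class is the majority: leave the data untouched by default
    return(list(table = x, labels = g, synthetic = rep(FALSE, nrow(x)),
                log = list(n_pos = n_pos, n_neg = n_neg,
                           n_neg_kept = n_neg, n_synthetic = 0L,
                           positive_majority = TRUE)))
  }
  if (n_pos < 2) stop("SMOTE requires at least 2 positive instances")
  k <- config$k_neighbors
  if (k > n_pos - 1) {
    warning("k_neighbors reduced from ", k, " to ", n_pos - 1)
    k <- n_pos - 1
  }
  n_keep <- as.integer(ceiling(config$undersample_fraction * n_neg))
  n_syn <- as.integer(floor(config$smote_multiplier * n_pos))
  with_seed(config$seed, {
    keep_neg <- sort(sample(which(!g), n_keep))
    pos_idx <- which(g)
    pm <- as.matrix(x[pos_idx, , drop = FALSE])
    pm[is.na(pm)] <- 0
    dm <- as.matrix(stats::dist(pm))
    diag(dm) <- Inf
    nn <- do.call(rbind, lapply(seq_len(n_pos), function(i)
      order(dm[i, ])[seq_len(k)]))
    syn <- matrix(NA_real_, n_syn, ncol(x), dimnames = list(NULL, colnames(x)))
    if (n_syn > 0) {
      seeds <- rep(seq_len(n_pos), length.out = n_syn)
      for (s in seq_len(n_syn)) {
        i <- seeds[s]
        j <- nn[i, sample.int(k, 1)]
        u <- stats::runif(1)
        syn[s, ] <- pm[i, ] + u * (pm[j, ] - pm[i, ])
      }
    }
  })
  out_x <- rbind(x[pos_idx, , drop = FALSE],
                 x[keep_neg, , drop = FALSE],
                 as.data.frame(syn))
  rownames(out_x) <- NULL
  list(table = out_x,
       labels = c(rep(TRUE, n_pos), rep(FALSE, n_keep), rep(TRUE, n_syn)),
       synthetic = c(rep(FALSE, n_pos + n_keep), rep(TRUE, n_syn)),
       log = list(n_pos = n_pos, n_neg = n_neg, n_neg_kept = n_keep,
                  n_synthetic = n_syn, positive_majority = FALSE))
}
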