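# Separable two-class feature table used across classifier tests.
make_separable <- function(n_pos, n_neg, gap = 3, p_noise = 4, seed = 1) {
  set.seed(seed)
  n <- n_pos + n_neg
  y <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  x <- as.data.frame(matrix(stats::rnorm(n * p_noise), n))
  colnames(x) <- paste0("noise", seq_len(p_noise))
  x$sig1 <- ifelse(y, gap, 0) + stats::rnorm(n)
  x$sig2 <- ifelse(y, -gap, 0) + stats::rnorm(n)
  list(x = x, y = y)
}

test_that("F-measure reproduces printed confusion arithmetic", {
  expect_equal(round(f_measure(105, 94 - 84, 123 - 105), 2), 0.88)
  expect_equal(round(f_measure(3, 210 - 208, 7 - 3), 2), 0.50)
  expect_equal(round(f_measure(106, 94 - 76, 123 - 106), 2), 0.86)
  expect_equal(round(f_measure(38, 167 - 160, 50 - 38), 2), 0.80)
  expect_equal(f_measure(50, 0, 0), 1)
  expect_equal(f_measure(0, 5, 5), 0)
  expect_error(f_measure(0, 0, 0), "undefined")
  # fractional averaged counts are accepted
  expect_equal(round(f_measure(104.2, 94 - 84.2, 123 - 104.2), 2), 0.88)
})

test_that("every classifier emits calibrated probabilities in [0, 1]", {
  d <- make_separable(25, 35, seed = 5)
  for (nm in c("CART", "kNN", "LDA", "NB", "RF", "RMLR", "SVM", "NNET",
               "ADA")) {
    m <- fit_classifier(classifier_spec(nm), d$x, d$y, seed = 3)
    p <- predict_classifier(m, d$x)
    expect_length(p, nrow(d$x))
    expect_true(all(p >= 0 & p <= 1), label = nm)
    # separable training data: resubstitution accuracy is high
    expect_gte(mean((p >= 0.5) == d$y), 0.9)
  }
  expect_error(fit_classifier(classifier_spec("LDA"), d$x,
                              rep(TRUE, nrow(d$x))), "both classes")
})

test_that("cross-validation recovers separable classes and is seeded", {
  d <- make_separable(30, 50, seed = 11)
  cfg <- cv_config(n_folds = 5, selection = "KW", sampling = FALSE, seed = 21)
  cv1 <- cross_validate(d$x, d$y, classifier_spec("RF"), cfg)
  expect_gte(cv1$mean_f, 0.95)
  cv2 <- cross_validate(d$x, d$y, classifier_spec("RF"), cfg)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_identical(cv1$mean_f, cv2$mean_f)
  # confusion count conservation per repetition
  cc <- cv1$counts_per_rep
  expect_true(all(cc$tp + cc$fn == 30))
  expect_true(all(cc$tn + cc$fp == 50))
})

test_that("stratified folds keep class proportions within one cell", {
  y <- c(rep(TRUE, 23), rep(FALSE, 77))
  fold <- morphotype:::stratified_folds(y, 10, seed = 13)
  for (k in 1:10) {
    expect_lte(abs(sum(y[fold == k]) - 2.3), 1)
    expect_true(sum(fold == k) %in% 9:11)
  }
  d <- make_separable(6, 40)
  expect_error(cross_validate(d$x, d$y, classifier_spec("RF"),
                              cv_config(n_folds = 10)), "smaller k")
})

test_that("in-fold selection does not leak held-out information", {
  # pure-noise features: an honest pipeline stays near chance while a
  # leaky one (selection on all rows before CV) inflates performance
  set.seed(31)
  n <- 60
  x <- as.data.frame(matrix(stats::rnorm(n * 40), n))
  y <- rep(c(TRUE, FALSE), each = n / 2)
  cfg <- cv_config(n_folds = 5, selection = "KW", sampling = FALSE, seed = 3)
  cv <- cross_validate(x, y, classifier_spec("LDA"), cfg)
  acc <- (cv$counts[["tp"]] + cv$counts[["tn"]]) / n
  expect_lt(acc, 0.75)

  # leaky reference: select the apparently-best noise features using all
  # rows, then cross-validate only those columns
  sel_all <- kw_select(x, y, alpha = 0.5)
  leak_cols <- utils::head(sel_all$ranking$feature, 5)
  cv_leak <- cross_validate(x[leak_cols], y, classifier_spec("LDA"), cfg)
  acc_leak <- (cv_leak$counts[["tp"]] + cv_leak$counts[["tn"]]) / n
  expect_gt(acc_leak, acc)
})

test_that("sampling inside CV handles scarce positives", {
  d <- make_separable(8, 60, gap = 2.5, seed = 41)
  cfg <- cv_config(n_folds = 7, n_repeats = 2, selection = "KW",
                   sampling = TRUE, seed = 17)
  cv <- suppressWarnings(
    cross_validate(d$x, d$y, classifier_spec("RF"), cfg))
  expect_gte(cv$mean_f, 0.6)
  expect_equal(nrow(cv$counts_per_rep), 2)
  expect_true(all(cv$counts_per_rep$tp + cv$counts_per_rep$fn == 8))
})

test_that("multi-class combination picks the most confident model", {
  set.seed(51)
  types <- c("AA", "BB", "CC")
  n_per <- 25
  y <- rep(types, each = n_per)
  x <- data.frame(f1 = stats::rnorm(75) + 5 * (y == "AA"),
                  f2 = stats::rnorm(75) + 5 * (y == "BB"),
                  f3 = stats::rnorm(75) + 5 * (y == "CC"))
  ens <- train_ova(x, y, classifier_spec("RMLR"), selection = "none",
                   sampling = FALSE, seed = 2)
  out <- combine_multiclass(ens, x)
  expect_gte(mean(out$type == y), 0.9)
  expect_identical(colnames(out$probabilities), sort(types))

  # tie-break contract: equal probabilities resolve alphabetically
  fake <- structure(list(), class = "ova_ensemble")
  probs <- matrix(0.5, 1, 3, dimnames = list(NULL, c("BTC", "MC", "NBC")))
  expect_equal(c("BTC", "MC", "NBC")[apply(probs, 1, which.max)], "BTC")
})

test_that("atypicality counts conserve runs and rank stubborn errors first", {
  d <- make_separable(15, 25, gap = 2, seed = 61)
  cfg <- cv_config(n_folds = 5, n_repeats = 3, selection = "none",
                   sampling = FALSE, seed = 7)
  cvs <- list(cross_validate(d$x, d$y, classifier_spec("RF"), cfg),
              cross_validate(d$x, d$y, classifier_spec("RMLR"), cfg))
  rep_ <- atypicality_report(cvs)
  expect_equal(nrow(rep_), 40)
  expect_equal(unique(rep_$total_runs), 6)
  # positive + negative assignments sum to total runs per cell
  neg_assign <- rep_$total_runs - rep_$times_positive
  expect_true(all(rep_$times_positive + neg_assign == rep_$total_runs))
  expect_true(!is.unsorted(rev(rep_$misclass_frac)))
  # a true positive never predicted positive would rank first
  worst <- rep_[1, ]
  expect_gte(worst$misclass_frac, max(rep_$misclass_frac) - 1e-12)
})
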