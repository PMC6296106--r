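#' Classifier specification
#'
#' The nine supervised classifiers, each with fixed, pre-specified
#' parameters (no tuning): CART (min split 10, min leaf 5), kNN (k = 5,
#' Euclidean, unweighted), LDA (shared covariance), Gaussian NB, RF (2000
#' trees, mtry = sqrt(p)), RMLR (lasso logistic, lambda = 0.01,
#' standardized inputs), SVM (RBF, gamma = 1/p, C = 1), NNET (one hidden
#' layer of 5 units), and ADA (3000 depth-1 boosted trees, shrinkage
#' 0.001). Distance- and gradient-based learners (kNN, RMLR, SVM, NNET)
#' see train-fold-standardized inputs; tree, Bayes and LDA models see raw
#' values.
#'
#' @param name One of `"CART"`, `"kNN"`, `"LDA"`, `"NB"`, `"RF"`,
#'   `"RMLR"`, `"SVM"`, `"NNET"`, `"ADA"`.
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(name) {
  name <- match.arg(name, c("CART", "kNN", "LDA", "NB", "RF", "RMLR", "SVM",
                            "NNET", "ADA"))
  params <- switch(name,
    CART = list(minsplit = 10, minbucket = 5),
    kNN = list(k = 5),
    LDA = list(),
    NB = list(),
    RF = list(n_trees = 2000),
    RMLR = list(lambda = 0.01),
    SVM = list(cost = 1),
    NNET = list(size = 5),
    ADA = list(n_trees = 3000, depth = 1, shrinkage = 0.001))
  structure(list(name = name, params = params,
                 standardize = name %in% c("kNN", "RMLR", "SVM", "NNET")),
            class = "classifier_spec")
}

# Standardization constants from a training table; zero-variance columns
# get unit scale.
std_params <- function(x) {
  mu <- vapply(x, mean, 1, na.rm = TRUE)
  sg <- vapply(x, stats::sd, 1, na.rm = TRUE)
  sg[!is.finite(sg) | sg < 1e-12] <- 1
  list(mu = mu, sg = sg)
}

apply_std <- function(x, sp) {
  as.data.frame(Map(function(v, m, s) (v - m) / s, x, sp$mu[colnames(x)],
                    sp$sg[colnames(x)]), check.names = FALSE)
}

#' Fit a classifier on a binary training set
#'
#' @param spec A [classifier_spec()].
#' @param x Data frame of numeric features (no missing values).
#' @param y Logical vector, `TRUE` = positive class.
#' @param seed Integer seed for stochastic learners.
#' @return A `fitted_classifier`; pass to [predict_classifier()].
#' @export
fit_classifier <- function(spec, x, y, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"), nrow(x) == length(y))
  if (length(unique(y)) < 2) stop("both classes required to fit ", spec$name)
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  sp <- if (spec$standardize) std_params(x) else NULL
  xs <- if (spec$standardize) apply_std(x, sp) else x
  p <- ncol(x)
  fit <- with_seed(seed, switch(spec$name,
    CART = rpart::rpart(y ~ ., data = cbind(xs, y = yf), method = "class",
                        control = rpart::rpart.control(
                          minsplit = spec$params$minsplit,
                          minbucket = spec$params$minbucket)),
    kNN = list(train = as.matrix(xs), cl = yf, k = spec$params$k),
    LDA = MASS::lda(xs, grouping = yf),
    NB = e1071::naiveBayes(xs, yf),
    RF = ranger::ranger(x = xs, y = yf, num.trees = spec$params$n_trees,
                        mtry = max(1L, floor(sqrt(p))), probability = TRUE,
                        num.threads = 1, seed = seed),
    RMLR = glmnet::glmnet(glmnet_x(xs), yf, family = "binomial", alpha = 1,
                          lambda = spec$params$lambda, standardize = TRUE),
    SVM = fit_svm(xs, yf, spec$params$cost),
    NNET = nnet::nnet(x = as.matrix(xs), y = as.numeric(y),
                      size = spec$params$size, maxit = 200, trace = FALSE,
                      decay = 1e-4),
    ADA = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = spec$params$depth,
                    eta = spec$params$shrinkage, nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(xs), label = as.numeric(y)),
      nrounds = spec$params$n_trees, verbose = 0)))
  structure(list(spec = spec, fit = fit, std = sp, features = colnames(x)),
            class = "fitted_classifier")
}

# glmnet needs >= 2 columns; pad single-feature designs with a zero column.
glmnet_x <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2) m <- cbind(m, `.const` = 0)
  m
}

# RBF SVM with a calibrated positive-class probability. libsvm's built-in
# Platt scaling needs enough instances per class; when it is unavailable a
# sigmoid is fit on the training decision values instead.
fit_svm <- function(xs, yf, cost) {
  m <- as.matrix(xs)
  fit <- try(e1071::svm(m, yf, kernel = "radial", gamma = 1 / ncol(m),
                        cost = cost, probability = TRUE, scale = FALSE),
             silent = TRUE)
  if (!inherits(fit, "try-error") && !is.null(fit$probA)) {
    return(list(svm = fit, platt = NULL))
  }
  fit <- e1071::svm(m, yf, kernel = "radial", gamma = 1 / ncol(m),
                    cost = cost, probability = FALSE, scale = FALSE)
  dvm <- attr(stats::predict(fit, m, decision.values = TRUE),
              "decision.values")
  sgn <- if (startsWith(colnames(dvm)[1], "pos")) 1 else -1
  df <- data.frame(y = as.numeric(yf == "pos"), d = sgn * dvm[, 1])
  platt <- suppressWarnings(stats::glm(y ~ d, data = df,
                                       family = stats::binomial()))
  list(svm = fit, platt = platt, sgn = sgn)
}

#' Positive-class probability predictions
#'
#' @param model A [fit_classifier()] result.
#' @param newx Data frame with at least the training feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_classifier <- function(model, newx) {
  stopifnot(inherits(model, "fitted_classifier"))
  miss <- setdiff(model$features, colnames(newx))
  if (length(miss) > 0) {
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  }
  x <- as.data.frame(newx)[model$features]
  if (!is.null(model$std)) x <- apply_std(x, model$std)
  spec <- model$spec
  fit <- model$fit
  pr <- switch(spec$name,
    CART = stats::predict(fit, x, type = "prob")[, "pos"],
    kNN = {
      pred <- class::knn(fit$train, as.matrix(x), fit$cl, k = fit$k,
                         prob = TRUE)
      pw <- attr(pred, "prob")
      ifelse(pred == "pos", pw, 1 - pw)
    },
    LDA = stats::predict(fit, x)$posterior[, "pos"],
    NB = stats::predict(fit, x, type = "raw")[, "pos"],
    RF = stats::predict(fit, data = x, num.threads = 1)$predictions[, "pos"],
    RMLR = as.numeric(stats::predict(fit, glmnet_x(x), type = "response")),
    SVM = {
      m <- as.matrix(x)
      if (is.null(fit$platt)) {
        attr(stats::predict(fit$svm, m, probability = TRUE),
             "probabilities")[, "pos"]
      } else {
        dv <- attr(stats::predict(fit$svm, m, decision.values = TRUE),
                   "decision.values")[, 1]
        as.numeric(stats::predict(fit$platt,
                                  data.frame(d = dv * fit$sgn),
                                  type = "response"))
      }
    },
    NNET = as.numeric(stats::predict(fit, as.matrix(x))),
    ADA = as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(as.matrix(x)))))
  pmin(1, pmax(0, as.numeric(pr)))
}
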