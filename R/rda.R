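# Weighted regularized discriminant analysis (RDA).
#
# A linear-Gaussian classifier with per-observation weights w_n > 0:
#   class means      mu_k   = sum_n M_nk w_n x_n / sum_n M_nk w_n
#   pooled covariance Sigma = sum_{n,k} M_nk w_n (x_n - mu_k)(x_n - mu_k)^T
#                             / (1 - sum_k W2_k / W_k)
#   regularization   Sigma_gamma = (1 - gamma) Sigma + gamma I,  gamma in [0,1]
# where M is the N x K class membership matrix, W_k the per-class weight
# sum and W2_k the per-class sum of squared weights (weights normalized to
# total 1, which makes the denominator (N-K)/N at equal weights and
# recovers the unbiased pooled estimator).  delta >= 0 zeroes linear
# coefficients of magnitude below it, eliminating predictors.  Prediction
# minimizes expected classification cost over the posterior.

#' Weighted class means
#'
#' The weighted estimate of each class mean,
#' `mu_k = sum_n M_nk w_n x_n / sum_n M_nk w_n`.
#'
#' @param x Numeric matrix, one row per observation.
#' @param y Class labels, one per row of `x`.
#' @param w Positive observation weights (any scale; only ratios matter).
#' @return A K x d matrix of class means with labels as row names.
#' @export
estimate_weighted_means <- function(x, y, w = rep(1, nrow(x))) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(w) == length(y))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("observation weights must be strictly positive and finite", call. = FALSE)
  }
  yf <- factor(y)
  wk <- as.vector(rowsum(w, yf))
  if (any(wk <= 0)) {
    stop("class ", levels(yf)[which(wk <= 0)[1]], " has zero total weight",
         call. = FALSE)
  }
  means <- rowsum(x * w, yf) / wk
  rownames(means) <- levels(yf)
  means
}

#' Weighted pooled within-class covariance
#'
#' The weighted pooled covariance estimate
#' `Sigma = sum_{n,k} M_nk w_n (x_n - mu_k)(x_n - mu_k)^T / (1 - sum_k W2_k/W_k)`
#' with weights normalized to sum to one.  At equal weights this is the
#' classical pooled estimator with divisor `N - K`.
#'
#' @inheritParams estimate_weighted_means
#' @param class_means Optional K x d matrix of class means (rows named by
#'   class); computed from the data when omitted.
#' @return A d x d symmetric positive semidefinite matrix.
#' @export
estimate_weighted_covariance <- function(x, y, w = rep(1, nrow(x)),
                                         class_means = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), length(w) == length(y))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("observation weights must be strictly positive and finite", call. = FALSE)
  }
  w <- w / sum(w)
  yf <- factor(y)
  if (is.null(class_means)) {
    class_means <- estimate_weighted_means(x, y, w)
  }
  wk <- as.vector(rowsum(w, yf))
  w2k <- as.vector(rowsum(w^2, yf))
  denom <- 1 - sum(w2k / wk)
  if (denom <= 0) {
    stop("weighted covariance undefined: 1 - sum_k W2_k/W_k = ",
         format(denom), " <= 0 (weights too concentrated per class)",
         call. = FALSE)
  }
  dev <- x - class_means[match(as.character(y), rownames(class_means)), , drop = FALSE]
  s <- crossprod(dev * sqrt(w)) / denom
  (s + t(s)) / 2
}

#' Shrink a covariance matrix toward the identity
#'
#' `Sigma_gamma = (1 - gamma) * Sigma + gamma * I` with `gamma` in `[0, 1]`:
#' `gamma = 0` leaves the matrix unchanged, `gamma = 1` yields the identity.
#'
#' @param cov Symmetric covariance matrix.
#' @param gamma Amount of regularization in `[0, 1]`.
#' @return A matrix of the same dimension.
#' @export
regularize_covariance <- function(cov, gamma) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stop("`cov` must be square", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  (1 - gamma) * cov + gamma * diag(nrow(cov))
}

#' Zero small linear coefficients and flag eliminated predictors
#'
#' Sets every coefficient with magnitude below `delta` to zero.  A predictor
#' (row) is flagged eliminated when its coefficient is zero for every class
#' after thresholding.
#'
#' @param coefficients d x K matrix of per-class linear coefficients (or a
#'   vector, treated as one class).
#' @param delta Threshold, `>= 0`.
#' @return A list with `coefficients` (thresholded matrix) and `eliminated`
#'   (integer indices of all-zero predictors).
#' @export
apply_delta_threshold <- function(coefficients, delta) {
  if (!is.finite(delta) || delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  m <- as.matrix(coefficients)
  m[abs(m) < delta] <- 0
  list(coefficients = m, eliminated = which(rowSums(m != 0) == 0))
}

default_cost_matrix <- function(k) {
  matrix(1, k, k) - diag(k)
}

# Matrix-level fit used by both the tibble surface and the hot optimizer
# loop (avoids per-call data-frame overhead).
fit_rda_impl <- function(x, y, w, gamma, delta, cost_matrix = NULL,
                         prior = "weighted") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(y) != n) stop("labels and rows disagree", call. = FALSE)
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n) stop("need one weight per observation", call. = FALSE)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("observation weights must be strictly positive and finite", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma < 0 || gamma > 1) {
    stop("`gamma` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(delta) || delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  yf <- factor(y)
  classes <- levels(yf)
  k <- length(classes)
  if (k < 2L) stop("need at least 2 classes", call. = FALSE)
  if (is.null(cost_matrix)) cost_matrix <- default_cost_matrix(k)
  cost_matrix <- as.matrix(cost_matrix)
  if (!identical(dim(cost_matrix), c(k, k)) || any(cost_matrix < 0) ||
      any(diag(cost_matrix) != 0)) {
    stop("`cost_matrix` must be K x K, nonnegative, zero on the diagonal",
         call. = FALSE)
  }

  w <- w / sum(w)
  wk <- as.vector(rowsum(w, yf))
  w2k <- as.vector(rowsum(w^2, yf))
  means <- rowsum(x * w, yf) / wk
  rownames(means) <- classes

  denom <- 1 - sum(w2k / wk)
  if (denom <= 0) {
    stop("weighted covariance undefined: 1 - sum_k W2_k/W_k <= 0", call. = FALSE)
  }
  dev <- x - means[as.integer(yf), , drop = FALSE]
  sigma <- crossprod(dev * sqrt(w)) / denom
  sigma <- (sigma + t(sigma)) / 2
  sigma_gamma <- regularize_covariance(sigma, gamma)

  ev <- eigen(sigma_gamma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10) {
    if (gamma == 0) {
      stop("regularized covariance is singular at gamma = 0; ",
           "increase gamma above 0 to obtain an invertible model", call. = FALSE)
    }
    stop("regularized covariance is numerically singular", call. = FALSE)
  }
  sigma_inv <- chol2inv(chol(sigma_gamma))

  mu_bar <- colSums(w * x)                       # weighted pooled mean
  mc <- t(means) - mu_bar                        # d x K centered means
  thr <- apply_delta_threshold(sigma_inv %*% mc, delta)
  coef <- thr$coefficients
  dimnames(coef) <- list(colnames(x), classes)
  qk <- colSums(mc * coef)                       # (mu_k - mu_bar)' L_k

  priors <- switch(prior,
    weighted = wk,
    uniform = rep(1 / k, k),
    stop("`prior` must be \"weighted\" or \"uniform\"", call. = FALSE)
  )
  priors <- priors / sum(priors)

  structure(
    list(
      classes = classes,
      class_means = means,
      covariance = sigma,
      reg_covariance = sigma_gamma,
      gamma = gamma,
      delta = delta,
      priors = priors,
      cost_matrix = cost_matrix,
      coefficients = coef,
      eliminated = thr$eliminated,
      mu_bar = mu_bar,
      qk = qk,
      class_weight_sums = wk,
      class_sq_weight_sums = w2k,
      weights = w,
      n = n,
      feature_names = colnames(x)
    ),
    class = "rda_model"
  )
}

#' Fit a weighted regularized discriminant classifier
#'
#' Fits the weighted RDA model: normalizes the observation weights to sum
#' to one, estimates weighted class means and the weighted pooled
#' covariance, shrinks the covariance toward the identity by `gamma`,
#' computes per-class linear coefficients
#' `Sigma_gamma^-1 (mu_k - mu_bar)` (centered by the weighted pooled mean),
#' and zeroes coefficients of magnitude below `delta`.
#'
#' @param data Data frame with one row per observation: a label column plus
#'   numeric feature columns (bookkeeping columns `cycle_id`, `covariate`,
#'   `cycle_index` are ignored).
#' @param weights Positive observation weights, one per row; default equal.
#' @param gamma Covariance regularization in `[0, 1]`.
#' @param delta Coefficient threshold, `>= 0`.
#' @param label_col Name of the label column (default `"subject_id"`).
#' @param cost_matrix K x K misclassification costs `C[y, k]` (cost of
#'   predicting `y` when truth is `k`); nonnegative, zero diagonal.
#'   Defaults to 0--1 cost, under which prediction is the posterior argmax.
#' @param prior `"weighted"` (class priors proportional to class weight
#'   sums, the default) or `"uniform"`.
#' @return An `rda_model` object; see [predict.rda_model()],
#'   [rda_posterior()], [tidy.rda_model()].
#' @examples
#' d <- tibble::tibble(
#'   subject_id = rep(1:2, each = 4),
#'   f1 = c(rnorm(4), rnorm(4, 3)), f2 = c(rnorm(4), rnorm(4, -2))
#' )
#' m <- fit_rda(d, gamma = 0.1)
#' predict(m, d)
#' @export
fit_rda <- function(data, weights = NULL, gamma = 0, delta = 0,
                    label_col = "subject_id", cost_matrix = NULL,
                    prior = c("weighted", "uniform")) {
  prior <- match.arg(prior)
  fm <- feature_matrix(data, label_col)
  model <- fit_rda_impl(fm$x, fm$y, weights, gamma, delta, cost_matrix, prior)
  model$label_col <- label_col
  model
}

#' @export
print.rda_model <- function(x, ...) {
  cat("<rda_model>\n")
  cat("  classes:    ", length(x$classes), "\n")
  cat("  features:   ", ncol(x$class_means),
      " (", length(x$eliminated), " eliminated by delta)\n", sep = "")
  cat("  gamma:      ", format(x$gamma, digits = 4), "\n")
  cat("  delta:      ", format(x$delta, digits = 4), "\n")
  cat("  fitted on:  ", x$n, "weighted observations\n")
  invisible(x)
}

# Log-scores (up to a shared constant) for each class; `rule` controls
# whether the prior enters.
rda_scores <- function(model, x, rule = "posterior") {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$class_means)) {
    stop("feature dimension does not match the fitted model", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  s <- sweep(x, 2, model$mu_bar) %*% model$coefficients
  s <- sweep(s, 2, model$qk / 2)
  if (rule == "posterior") s <- sweep(s, 2, log(model$priors), `+`)
  s
}

# Fast path: stabilized posterior + minimum expected cost, on a matrix.
rda_predict_impl <- function(model, x, rule = "posterior") {
  s <- rda_scores(model, x, rule)
  p <- exp(s - apply(s, 1, max))
  p <- p / rowSums(p)
  costs <- p %*% t(model$cost_matrix)
  model$classes[max.col(-costs, ties.method = "first")]
}

new_data_matrix <- function(model, new_data) {
  if (is.matrix(new_data)) return(new_data)
  cols <- model$feature_names
  if (!is.null(cols) && all(cols %in% names(new_data))) {
    return(as.matrix(new_data[cols]))
  }
  feature_matrix_cols <- feature_cols(new_data, model$label_col %||% "subject_id")
  as.matrix(new_data[feature_matrix_cols])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class membership probabilities under a fitted RDA model
#'
#' Gaussian class probabilities `prior_k * N(x; mu_k, Sigma_gamma)`
#' normalized to sum to one over classes, computed with log-density
#' stabilization.  With `rule = "likelihood"` the prior is dropped and the
#' normalized class-conditional density is returned instead.
#'
#' @param model A fitted [fit_rda()] model.
#' @param new_data Data frame with the model's feature columns, or a
#'   numeric matrix.
#' @param rule `"posterior"` (default) or `"likelihood"`.
#' @return A tibble with one probability column per class.
#' @export
rda_posterior <- function(model, new_data, rule = c("posterior", "likelihood")) {
  rule <- match.arg(rule)
  s <- rda_scores(model, new_data_matrix(model, new_data), rule)
  m <- apply(s, 1, max)
  p <- exp(s - m)
  p <- p / rowSums(p)
  colnames(p) <- model$classes
  tibble::as_tibble(p, .name_repair = "minimal")
}

#' Predict classes by minimum expected cost
#'
#' Predicts the class minimizing the expected classification cost
#' `sum_k P(x|k) C(y|k)`; with the default 0--1 cost this is the posterior
#' argmax.  Exact ties resolve to the lowest class index.
#'
#' @param object A fitted [fit_rda()] model.
#' @param new_data Data frame or numeric matrix of features.
#' @param type `"class"` for labels, `"prob"` for class probabilities,
#'   `"cost"` for per-class expected costs.
#' @param rule Probability used inside the expected cost: `"posterior"`
#'   (default) or `"likelihood"`.
#' @param ... Unused.
#' @return A tibble: `.pred_class`, or one column per class.
#' @export
predict.rda_model <- function(object, new_data,
                              type = c("class", "prob", "cost"),
                              rule = c("posterior", "likelihood"), ...) {
  type <- match.arg(type)
  rule <- match.arg(rule)
  p <- as.matrix(rda_posterior(object, new_data, rule))
  if (type == "prob") {
    return(tibble::as_tibble(p, .name_repair = "minimal"))
  }
  costs <- p %*% t(object$cost_matrix)   # costs[, y] = sum_k C[y, k] p_k
  colnames(costs) <- object$classes
  if (type == "cost") {
    return(tibble::as_tibble(costs, .name_repair = "minimal"))
  }
  idx <- max.col(-costs, ties.method = "first")
  labels <- object$classes[idx]
  # restore the original label type where possible
  if (!anyNA(suppressWarnings(as.integer(object$classes)))) {
    labels <- as.integer(labels)
  }
  tibble::tibble(.pred_class = labels)
}

#' @export
tidy.rda_model <- function(x, ...) {
  coef <- x$coefficients
  terms <- x$feature_names %||% sprintf("x%d", seq_len(nrow(coef)))
  tibble::tibble(
    class = rep(x$classes, each = nrow(coef)),
    term = rep(terms, times = ncol(coef)),
    estimate = as.vector(coef),
    eliminated = rep(seq_len(nrow(coef)) %in% x$eliminated, times = ncol(coef))
  )
}

#' @export
glance.rda_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_classes = length(x$classes),
    n_features = ncol(x$class_means),
    n_eliminated = length(x$eliminated),
    gamma = x$gamma,
    delta = x$delta
  )
}
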