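test_that("weighted class means follow the weighted-sum formula", {
  x <- rbind(c(0, 0), c(2, 2))
  expect_equal(unname(estimate_weighted_means(x, c(1, 1), c(1, 1))),
               rbind(c(1, 1)))

  m <- estimate_weighted_means(matrix(c(0, 4), ncol = 1), c(1, 1),
                               w = c(0.25, 0.75))
  expect_equal(unname(m), rbind(3))

  # single observation per class: the weight cancels
  x <- rbind(c(1, 2), c(5, -1))
  for (w in list(c(1, 1), c(0.2, 0.9), c(1e-8, 1))) {
    expect_equal(unname(estimate_weighted_means(x, c(1, 2), w)), unname(x))
  }

  expect_error(estimate_weighted_means(x, c(1, 2), c(0, 1)), "positive")
})

test_that("weighted covariance matches the pooled (N-K) estimator at equal weights", {
  # zero deviations give the zero matrix
  x <- rbind(c(1, 1), c(1, 1), c(3, 0), c(3, 0))
  expect_equal(estimate_weighted_covariance(x, c(1, 1, 2, 2)),
               matrix(0, 2, 2))

  # two classes, 1-D points at +-1 around each class mean: 4 / (N - K) = 2
  x <- matrix(c(-1, 1, 9, 11), ncol = 1)
  expect_equal(estimate_weighted_covariance(x, c(1, 1, 2, 2)),
               matrix(2, 1, 1))

  # random data: equal weights recover the textbook pooled estimator
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(20:40, 1)
    d <- sample(2:5, 1)
    k <- sample(2:4, 1)
    y <- sample(seq_len(k), n, replace = TRUE)
    y[seq_len(k)] <- seq_len(k)  # every class non-empty
    x <- matrix(rnorm(n * d), n, d)
    expect_equal(estimate_weighted_covariance(x, y),
                 pooled_covariance_oracle(x, y), tolerance = 1e-10)
  }

  # one observation per class: sum_k W2_k/W_k = 1, the denominator vanishes
  x <- matrix(c(0, 5), ncol = 1)
  expect_error(estimate_weighted_covariance(x, c(1, 2), c(0.5, 0.5)), "W2_k")
})

test_that("identity shrinkage interpolates between the covariance and I", {
  s <- diag(c(2, 4))
  expect_equal(regularize_covariance(s, 0), s)
  expect_equal(regularize_covariance(s, 1), diag(2))
  expect_equal(regularize_covariance(s, 0.5), diag(c(1.5, 2.5)))
  expect_error(regularize_covariance(s, 1.2), "\\[0, 1\\]")
  expect_error(regularize_covariance(s, -0.1), "\\[0, 1\\]")

  # strict positive definiteness for gamma in (0, 1] over random PSD inputs
  set.seed(8)
  for (rep in 1:10) {
    a <- matrix(rnorm(16), 4)
    s <- crossprod(a)
    s[4, ] <- s[, 4] <- 0  # singular direction
    for (g in c(0.01, 0.5, 1)) {
      ev <- eigen(regularize_covariance(s, g), symmetric = TRUE,
                  only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("unit weights, gamma = 0, delta = 0 reproduce classical LDA decisions", {
  skip_if_not_installed("MASS")
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    d <- sample(2:5, 1)
    n_per <- sample(5:15, 1)
    data <- random_feature_data(n_per, d, k, sep = 3, seed = 1000 + rep)
    x <- as.matrix(data[, -1])
    model <- fit_rda(data, gamma = 0, delta = 0)
    query <- x + matrix(rnorm(length(x), sd = 0.5), nrow(x))
    ours <- predict(model, query)$.pred_class
    lda_fit <- MASS::lda(x, grouping = data$subject_id)
    oracle <- as.integer(as.character(predict(lda_fit, query)$class))
    expect_equal(ours, oracle)
  }
})

test_that("gamma = 1 with equal priors predicts the nearest class mean", {
  set.seed(13)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    data <- random_feature_data(sample(4:8, 1), sample(2:4, 1), k,
                                sep = 2, seed = 2000 + rep)
    x <- as.matrix(data[, -1])
    model <- fit_rda(data, gamma = 1, prior = "uniform")
    query <- x + matrix(rnorm(length(x)), nrow(x))
    ours <- predict(model, query)$.pred_class
    oracle <- nearest_mean_predict(x, data$subject_id, query)
    expect_equal(ours, oracle)
  }
})

test_that("posteriors are symmetric, normalized, and match the two-Gaussian closed form", {
  # class means 0 and 2, Sigma_gamma = I at gamma = 1, equal priors
  d <- tibble::tibble(subject_id = c(1, 1, 2, 2), f1 = c(-1, 1, 1, 3))
  model <- fit_rda(d, gamma = 1, prior = "uniform")
  expect_equal(unname(as.matrix(model$class_means)), rbind(0, 2))

  p0 <- as.matrix(rda_posterior(model, matrix(0)))
  expect_equal(unname(p0[1, 1]), 1 / (1 + exp(-2)), tolerance = 1e-12)

  # equidistant point: exact (0.5, 0.5)
  p1 <- as.matrix(rda_posterior(model, matrix(1)))
  expect_equal(unname(p1[1, ]), c(0.5, 0.5))

  # normalization over random inputs
  set.seed(3)
  pr <- as.matrix(rda_posterior(model, matrix(rnorm(20, sd = 50))))
  expect_equal(unname(rowSums(pr)), rep(1, 20))

  expect_error(rda_posterior(model, matrix(NaN)), "finite")
})

test_that("prediction minimizes expected cost and breaks ties toward the lower class", {
  d <- tibble::tibble(subject_id = c(1, 1, 2, 2), f1 = c(-1, 1, 1, 3))
  base <- fit_rda(d, gamma = 1, prior = "uniform")

  # 0-1 cost: argmax posterior
  expect_equal(predict(base, matrix(0))$.pred_class, 1L)
  # exact tie resolves to the lower class index
  expect_equal(predict(base, matrix(1))$.pred_class, 1L)

  # posteriors (0.6, 0.4) with C(1|2) = 10, C(2|1) = 1: expected costs (4, 0.6)
  cost <- rbind(c(0, 10), c(1, 0))
  model <- fit_rda(d, gamma = 1, prior = "uniform", cost_matrix = cost)
  x_star <- 1 + 0.5 * log(2 / 3)  # posterior of class 1 is exactly 0.6 here
  p <- as.matrix(rda_posterior(model, matrix(x_star)))
  expect_equal(unname(p[1, ]), c(0.6, 0.4), tolerance = 1e-12)
  costs <- as.matrix(predict(model, matrix(x_star), type = "cost"))
  expect_equal(unname(costs[1, ]), c(4.0, 0.6), tolerance = 1e-10)
  expect_equal(predict(model, matrix(x_star))$.pred_class, 2L)
})

test_that("delta thresholding zeroes small coefficients monotonically", {
  co <- cbind(c(0.5, 0.01), c(-0.3, 0.005))
  out <- apply_delta_threshold(co, 0)
  expect_equal(out$coefficients, co)
  expect_length(out$eliminated, 0)

  out <- apply_delta_threshold(co, 0.1)
  expect_equal(out$coefficients, cbind(c(0.5, 0), c(-0.3, 0)))
  expect_equal(out$eliminated, 2L)

  out <- apply_delta_threshold(co, 10)
  expect_true(all(out$coefficients == 0))
  expect_equal(out$eliminated, c(1L, 2L))

  # zeroed set grows with delta; surviving coefficients are >= delta
  set.seed(9)
  co <- matrix(rnorm(30), 10, 3)
  prev <- rep(FALSE, 30)
  for (delta in c(0, 0.2, 0.5, 1, 3)) {
    z <- as.vector(apply_delta_threshold(co, delta)$coefficients == 0)
    expect_true(all(z[prev]))
    kept <- apply_delta_threshold(co, delta)$coefficients
    expect_true(all(abs(kept[kept != 0]) >= delta))
    prev <- z
  }
})

test_that("the fitted model is invariant to rescaling all weights", {
  data <- random_feature_data(6, 3, 3, seed = 77)
  set.seed(78)
  w <- runif(nrow(data), 0.2, 1)
  m1 <- fit_rda(data, weights = w, gamma = 0.3, delta = 0.05)
  m2 <- fit_rda(data, weights = 7 * w, gamma = 0.3, delta = 0.05)
  expect_equal(m1$class_means, m2$class_means)
  expect_equal(m1$covariance, m2$covariance)
  expect_equal(m1$coefficients, m2$coefficients)
  expect_equal(m1$priors, m2$priors)
})

test_that("splitting a duplicated observation's weight preserves the class means", {
  data <- random_feature_data(5, 3, 2, seed = 99)
  w <- rep(1, nrow(data))
  dup <- dplyr::bind_rows(data, data[1, ])
  w_dup <- c(w, w[1])
  w_dup[1] <- w[1] / 2
  w_dup[length(w_dup)] <- w[1] / 2
  m1 <- fit_rda(data, weights = w, gamma = 0.2)
  m2 <- fit_rda(dup, weights = w_dup, gamma = 0.2)
  expect_equal(m1$class_means, m2$class_means, tolerance = 1e-12)
})

test_that("a singular model at gamma = 0 raises the advisory error", {
  # more features than observations: pooled covariance is rank-deficient
  data <- random_feature_data(3, 10, 2, seed = 55)
  expect_error(fit_rda(data, gamma = 0), "gamma")
  expect_silent(fit_rda(data, gamma = 0.1))
})

test_that("tidiers summarize the fit", {
  data <- random_feature_data(6, 3, 3, seed = 31)
  model <- fit_rda(data, gamma = 0.2, delta = 0.01)
  td <- tidy(model)
  expect_equal(nrow(td), 3 * 3)
  expect_named(td, c("class", "term", "estimate", "eliminated"))
  gl <- glance(model)
  expect_equal(gl$n_classes, 3L)
  expect_equal(gl$gamma, 0.2)
})
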