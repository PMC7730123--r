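# Shared fixtures and independent oracles, all built in code.

# Gaussian class clouds as a feature tibble: k classes, n_per_class rows,
# d dimensions, class means drawn with spread `sep`.
random_feature_data <- function(n_per_class, d, k, sep = 4, seed = 1,
                                within_sd = 1) {
  set.seed(seed)
  means <- matrix(rnorm(k * d, sd = sep), k, d)
  x <- do.call(rbind, lapply(seq_len(k), function(cl) {
    sweep(matrix(rnorm(n_per_class * d, sd = within_sd), n_per_class, d),
          2, means[cl, ], `+`)
  }))
  colnames(x) <- sprintf("f%02d", seq_len(d))
  dplyr::bind_cols(
    tibble::tibble(subject_id = rep(seq_len(k), each = n_per_class)),
    tibble::as_tibble(x)
  )
}

# Independent nearest-class-mean classifier on a plain matrix: unweighted
# class means, Euclidean distance, lowest-index tie-break.
nearest_mean_predict <- function(train_x, train_y, test_x) {
  classes <- sort(unique(train_y))
  means <- t(vapply(classes, function(cl) {
    colMeans(train_x[train_y == cl, , drop = FALSE])
  }, numeric(ncol(train_x))))
  d2 <- outer(rowSums(test_x^2), rowSums(means^2), `+`) -
    2 * test_x %*% t(means)
  classes[max.col(-d2, ties.method = "first")]
}

# Textbook pooled within-class covariance with divisor N - K, computed by
# a direct per-class loop.
pooled_covariance_oracle <- function(x, y) {
  classes <- unique(y)
  s <- matrix(0, ncol(x), ncol(x))
  for (cl in classes) {
    xc <- x[y == cl, , drop = FALSE]
    xc <- sweep(xc, 2, colMeans(xc))
    s <- s + crossprod(xc)
  }
  s / (nrow(x) - length(classes))
}

# Gait tibble built from an explicit list of 32 x 11 x 3 tensors.
gait_tibble_from_tensors <- function(tensors, subject_id,
                                     covariate = "clothes1") {
  rows <- t(vapply(tensors, flatten_gait_tensor, numeric(32 * 11 * 3)))
  colnames(rows) <- gait_feature_names()
  dplyr::bind_cols(
    tibble::tibble(
      cycle_id = seq_along(tensors),
      subject_id = subject_id,
      covariate = rep_len(covariate, length(tensors)),
      cycle_index = stats::ave(subject_id, subject_id, FUN = seq_along)
    ),
    tibble::as_tibble(rows)
  )
}

# Feature tibble with n_k samples per class laid out so that "last per
# class" rules are easy to reason about.
labeled_points <- function(n_per_class, k, d = 2, seed = 1) {
  random_feature_data(n_per_class, d, k, sep = 8, seed = seed)
}
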