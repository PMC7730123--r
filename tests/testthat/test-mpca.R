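small_gaits <- function(seed = 21, n_subjects = 3, cycles = 3) {
  generate_gait_data(gait_config(n_subjects = n_subjects,
                                 cycles_per_subject = cycles,
                                 class_separation = 4, noise_sd = 1,
                                 seed = seed))
}

test_that("full retention keeps all mode dimensions and reconstructs exactly", {
  d <- small_gaits()
  proj <- fit_mpca(d, variation_kept = 1)
  expect_equal(proj$ranks, c(32L, 11L, 3L))
  for (u in proj$mode_matrices) {
    expect_equal(crossprod(u), diag(ncol(u)), tolerance = 1e-8)
  }
  rec <- reconstruct_mpca(d, proj)
  expect_equal(as.matrix(rec[gait_feature_names()]),
               as.matrix(d[gait_feature_names()]),
               tolerance = 1e-8)
})

# expand a core through fixed factors (independent of the package internals)
mode_multiply_for_test <- function(core, u1, u2, u3) {
  d <- dim(core)
  m1 <- u1 %*% matrix(core, nrow = d[1])                      # mode-1
  x <- array(m1, dim = c(nrow(u1), d[2], d[3]))
  m2 <- u2 %*% matrix(aperm(x, c(2, 1, 3)), nrow = d[2])      # mode-2
  x <- aperm(array(m2, dim = c(nrow(u2), nrow(u1), d[3])), c(2, 1, 3))
  m3 <- u3 %*% matrix(aperm(x, c(3, 1, 2)), nrow = d[3])      # mode-3
  aperm(array(m3, dim = c(nrow(u3), nrow(u1), nrow(u2))), c(2, 3, 1))
}

test_that("data of known multilinear rank (2,2,1) is captured at those ranks", {
  set.seed(7)
  u1 <- qr.Q(qr(matrix(rnorm(32 * 2), 32)))
  u2 <- qr.Q(qr(matrix(rnorm(11 * 2), 11)))
  u3 <- qr.Q(qr(matrix(rnorm(3 * 1), 3)))
  tensors <- lapply(1:12, function(i) {
    core <- array(rnorm(2 * 2 * 1, sd = 5), dim = c(2, 2, 1))
    x <- mode_multiply_for_test(core, u1, u2, u3)
    x
  })
  d <- gait_tibble_from_tensors(tensors, subject_id = rep(1:3, each = 4))
  proj <- fit_mpca(d, variation_kept = 0.999)
  expect_equal(proj$ranks, c(2L, 2L, 1L))
  expect_gte(proj$captured_fraction, 0.999)
})

test_that("initialization equals the eigenvectors of the raw mode-1 unfolding scatter", {
  d <- small_gaits(seed = 31)
  proj <- fit_mpca(d, variation_kept = 0.9, max_iterations = 0)

  arr <- array(0, dim = c(32, 11, 3, nrow(d)))
  x <- as.matrix(d[gait_feature_names()])
  for (i in seq_len(nrow(d))) {
    arr[, , , i] <- unflatten_gait_tensor(x[i, ])
  }
  centered <- arr - as.vector(rowMeans(arr, dims = 3))
  s1 <- matrix(0, 32, 32)
  for (i in seq_len(dim(centered)[4])) {
    unf <- matrix(centered[, , , i], nrow = 32)
    s1 <- s1 + unf %*% t(unf)
  }
  oracle <- eigen(s1, symmetric = TRUE)$vectors[, seq_len(proj$ranks[1])]
  # same subspace: |U' V| = identity up to sign
  expect_equal(abs(crossprod(proj$mode_matrices[[1]], oracle)),
               diag(proj$ranks[1]), tolerance = 1e-6)
})

test_that("projection centers, is linear, and preserves distances at full retention", {
  d <- small_gaits(seed = 41)
  proj <- fit_mpca(d, variation_kept = 1)

  # the training mean projects to the zero vector
  mean_row <- colMeans(as.matrix(d[gait_feature_names()]))
  mean_tbl <- d[1, ]
  mean_tbl[gait_feature_names()] <- as.list(mean_row)
  f_mean <- as.matrix(project_mpca(mean_tbl, proj)[, -(1:4)])
  expect_equal(max(abs(f_mean)), 0, tolerance = 1e-10)

  # multilinearity: project(a + b) = project(a) + project(b) - project(0)
  a <- d[1, ]; b <- d[2, ]
  ab <- a
  ab[gait_feature_names()] <- as.list(
    as.numeric(a[1, gait_feature_names()]) + as.numeric(b[1, gait_feature_names()])
  )
  zero <- a
  zero[gait_feature_names()] <- as.list(rep(0, length(gait_feature_names())))
  pa <- as.matrix(project_mpca(a, proj)[, -(1:4)])
  pb <- as.matrix(project_mpca(b, proj)[, -(1:4)])
  pab <- as.matrix(project_mpca(ab, proj)[, -(1:4)])
  p0 <- as.matrix(project_mpca(zero, proj)[, -(1:4)])
  expect_equal(pab, pa + pb - p0, tolerance = 1e-8)

  # isometry under full orthonormal bases
  f <- as.matrix(project_mpca(d, proj)[, -(1:4)])
  x <- as.matrix(d[gait_feature_names()])
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(as.matrix(dist(f)), as.matrix(dist(xc)), tolerance = 1e-8)
})

test_that("identity mode matrices return the flattened centered tensor", {
  d <- small_gaits(seed = 51)
  proj <- structure(
    list(mode_matrices = list(diag(32), diag(11), diag(3)),
         mean_tensor = array(0, dim = c(32, 11, 3)),
         ranks = c(32L, 11L, 3L)),
    class = "mpca_projection"
  )
  f <- as.matrix(project_mpca(d, proj)[, -(1:4)])
  expect_equal(unname(f), unname(as.matrix(d[gait_feature_names()])),
               tolerance = 1e-12)
})

test_that("captured scatter is non-decreasing in retained dimensions", {
  d <- small_gaits(seed = 61, n_subjects = 4, cycles = 3)
  caps <- vapply(c(0.7, 0.9, 0.99), function(vk) {
    fit_mpca(d, variation_kept = vk)$captured_fraction
  }, numeric(1))
  expect_true(all(diff(caps) >= -1e-12))
})

test_that("degenerate inputs are rejected", {
  d <- small_gaits()
  expect_error(fit_mpca(d[1, ]), "at least 2")
  expect_error(fit_mpca(d, variation_kept = 0), "in \\(0, 1\\]")
  proj <- fit_mpca(d, variation_kept = 0.9)
  expect_error(project_mpca(d[, -5], proj), "missing")
})
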