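# Multilinear principal component analysis (MPCA) for gait-signature
# tensors.  Operates mode-wise on the 32 x 11 x 3 arrays rather than on
# flattened vectors: each mode gets an orthonormal projection matrix, chosen
# to capture a target fraction of the mode-wise scatter and refined by
# alternating partial projections.

#' Fit a multilinear PCA projection to gait-signature tensors
#'
#' Centers the training tensors by their mean and fits one orthonormal
#' matrix per tensor mode.  Retained dimensions per mode are the smallest
#' capturing at least `variation_kept` of that mode's scatter eigenvalue
#' sum (full-projection initialization); the matrices are then refined by
#' alternating partial-projection iterations until the captured scatter
#' improves by less than `1e-6` of the total or `max_iterations` sweeps are
#' done.  `max_iterations = 0` returns the initialization.
#'
#' @param data A gait tibble as produced by [generate_gait_data()] (one row
#'   per cycle, tensor columns per [gait_feature_names()]); at least 2 rows.
#' @param variation_kept Fraction of per-mode scatter to retain, in (0, 1].
#' @param max_iterations Maximum alternating refinement sweeps (default 5).
#' @return An `mpca_projection`: mode matrices, mean tensor, retained ranks,
#'   per-mode eigenvalues, and the captured scatter fraction.
#' @export
fit_mpca <- function(data, variation_kept = 0.97, max_iterations = 5L) {
  if (nrow(data) < 2L) {
    stop("MPCA needs at least 2 samples (scatter is zero otherwise)", call. = FALSE)
  }
  if (!(variation_kept > 0 && variation_kept <= 1)) {
    stop("`variation_kept` must be in (0, 1]", call. = FALSE)
  }
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 0L) stop("`max_iterations` must be >= 0", call. = FALSE)

  arr <- gait_to_array(data)           # (32, 11, 3, N)
  dims <- dim(arr)[1:3]
  n <- dim(arr)[4]
  mean_tensor <- rowMeans(arr, dims = 3L)
  centered <- arr - as.vector(mean_tensor)
  total_scatter <- sum(centered^2)
  if (total_scatter == 0) {
    stop("all samples identical: MPCA scatter is zero", call. = FALSE)
  }

  # Mode-m scatter of a (d1, d2, d3, N) array: sum_s X_s(m) X_s(m)^T.
  mode_scatter <- function(a, m) {
    u <- unfold_tensor(a, m)           # sample index folded into columns
    tcrossprod(u)
  }

  # Full-projection initialization + per-mode rank selection.
  u <- vector("list", 3L)
  eigenvalues <- vector("list", 3L)
  ranks <- integer(3L)
  for (m in 1:3) {
    e <- eigen(mode_scatter(centered, m), symmetric = TRUE)
    vals <- pmax(e$values, 0)
    eigenvalues[[m]] <- vals
    ranks[m] <- if (variation_kept >= 1) {
      dims[m]
    } else {
      frac <- cumsum(vals) / sum(vals)
      which(frac >= variation_kept)[1]
    }
    u[[m]] <- e$vectors[, seq_len(ranks[m]), drop = FALSE]
  }

  project_all <- function(a, mats) {
    for (m in 1:3) a <- mode_multiply(a, t(mats[[m]]), m)
    a
  }
  captured <- sum(project_all(centered, u)^2)

  iterations_run <- 0L
  if (max_iterations > 0L) {
    for (it in seq_len(max_iterations)) {
      for (m in 1:3) {
        partial <- centered
        for (j in setdiff(1:3, m)) {
          partial <- mode_multiply(partial, t(u[[j]]), j)
        }
        e <- eigen(mode_scatter(partial, m), symmetric = TRUE)
        eigenvalues[[m]] <- pmax(e$values, 0)
        u[[m]] <- e$vectors[, seq_len(ranks[m]), drop = FALSE]
      }
      iterations_run <- it
      new_captured <- sum(project_all(centered, u)^2)
      improved <- new_captured - captured
      captured <- new_captured
      if (improved < 1e-6 * total_scatter) break
    }
  }

  structure(
    list(
      mode_matrices = u,
      mean_tensor = mean_tensor,
      variation_kept = variation_kept,
      ranks = ranks,
      eigenvalues = eigenvalues,
      captured_fraction = captured / total_scatter,
      total_scatter = total_scatter,
      iterations = iterations_run,
      n_train = n
    ),
    class = "mpca_projection"
  )
}

#' @export
print.mpca_projection <- function(x, ...) {
  cat("<mpca_projection>\n")
  cat("  retained ranks:   ", paste(x$ranks, collapse = " x "),
      " (", prod(x$ranks), " features)\n", sep = "")
  cat("  captured scatter: ", format(x$captured_fraction, digits = 5), "\n")
  cat("  fitted on:        ", x$n_train, "samples,", x$iterations,
      "refinement sweeps\n")
  invisible(x)
}

#' Project gait cycles through a fitted MPCA
#'
#' Centers each tensor by the training mean, multiplies every mode by the
#' transposed mode matrix, and flattens the core tensor mode-1-major,
#' mode-3-minor into feature columns `pc_001, pc_002, ...`.
#'
#' @param data A gait tibble; tensor columns must match the fitted shape.
#' @param projection A fitted [fit_mpca()] object.
#' @return A tibble with the metadata columns of `data` (cycle_id,
#'   subject_id, covariate, cycle_index where present) plus the feature
#'   columns.
#' @export
project_mpca <- function(data, projection) {
  stopifnot(inherits(projection, "mpca_projection"))
  arr <- gait_to_array(data)
  if (!identical(dim(arr)[1:3], dim(projection$mean_tensor))) {
    stop("sample shape does not match the fitted mean tensor", call. = FALSE)
  }
  centered <- arr - as.vector(projection$mean_tensor)
  core <- centered
  for (m in 1:3) core <- mode_multiply(core, t(projection$mode_matrices[[m]]), m)
  n <- dim(core)[4]
  # mode-1 major, mode-3 minor flattening of each core
  feats <- t(matrix(aperm(core, c(3L, 2L, 1L, 4L)), ncol = n))
  colnames(feats) <- sprintf("pc_%03d", seq_len(ncol(feats)))
  meta <- intersect(META_COLS, names(data))
  dplyr::bind_cols(data[meta], tibble::as_tibble(feats))
}

#' Reconstruct gait cycles from their MPCA cores
#'
#' Back-projects each core tensor through the mode matrices and adds the
#' training mean.  With full retention (`variation_kept = 1`) this
#' reconstructs the input exactly (up to numerical tolerance).
#'
#' @inheritParams project_mpca
#' @return A gait tibble of the same layout as the generator output.
#' @export
reconstruct_mpca <- function(data, projection) {
  stopifnot(inherits(projection, "mpca_projection"))
  arr <- gait_to_array(data)
  centered <- arr - as.vector(projection$mean_tensor)
  core <- centered
  for (m in 1:3) core <- mode_multiply(core, t(projection$mode_matrices[[m]]), m)
  recon <- core
  for (m in 1:3) recon <- mode_multiply(recon, projection$mode_matrices[[m]], m)
  recon <- recon + as.vector(projection$mean_tensor)
  meta <- intersect(META_COLS, names(data))
  dplyr::bind_cols(data[meta], tibble::as_tibble(array_to_rows(recon)))
}

#' @export
tidy.mpca_projection <- function(x, ...) {
  purrr::map_dfr(1:3, function(m) {
    vals <- x$eigenvalues[[m]]
    tibble::tibble(
      mode = m,
      dimension = seq_along(vals),
      eigenvalue = vals,
      cumulative_fraction = cumsum(vals) / sum(vals),
      retained = seq_along(vals) <= x$ranks[m]
    )
  })
}

#' @export
glance.mpca_projection <- function(x, ...) {
  tibble::tibble(
    rank_frames = x$ranks[1],
    rank_channels = x$ranks[2],
    rank_angles = x$ranks[3],
    n_features = prod(x$ranks),
    variation_kept = x$variation_kept,
    captured_fraction = x$captured_fraction,
    iterations = x$iterations,
    n_train = x$n_train
  )
}

#' @export
autoplot.mpca_projection <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dimension,
                                  y = .data$cumulative_fraction,
                                  colour = factor(.data$mode))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$retained)) +
    ggplot2::geom_hline(yintercept = object$variation_kept, linetype = 2) +
    ggplot2::labs(x = "mode dimension", y = "cumulative scatter fraction",
                  colour = "mode", shape = "retained") +
    ggplot2::theme_minimal()
}
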