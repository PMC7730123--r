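# Synthetic gait-signature generator.  Emulates the statistical structure of
# a marker-less motion-capture gait dataset: K subjects with smooth periodic
# per-class mean trajectories, additive sensor noise smoothed by a moving
# average, anthropometric constants per subject (height, ankle distance),
# and systematic covariate shifts (clothing change, backpack).

COVARIATE_LEVELS <- c("clothes1", "clothes2", "backpack")

#' Configuration of the synthetic gait-signature generator
#'
#' Defines the study conditions under which labeled gait cycles are
#' generated.  Each subject (class) has a fixed smooth mean trajectory
#' tensor; a cycle is that mean plus smoothed Gaussian motion-capture noise,
#' plus a per-(subject, covariate) offset tensor for cycles recorded under a
#' covariate condition (second set of clothes, backpack).
#'
#' @param n_subjects Number of subjects (classes), at least 2.
#' @param cycles_per_subject Gait cycles per subject in the baseline
#'   (`clothes1`) condition; a scalar or a length-`n_subjects` vector.
#' @param class_separation Frobenius norm of each class's mean-trajectory
#'   offset from the shared base gait pattern, in units of `noise_sd`.
#'   Typical pairwise distance between class means is `sqrt(2)` times this.
#' @param noise_sd Standard deviation (degrees) of the i.i.d. motion-capture
#'   noise added to the 10 bone channels before smoothing.
#' @param covariate_shift_sd Root-mean-square amplitude (degrees) of the
#'   smooth additive offset applied to `clothes2`/`backpack` cycles; drawn
#'   once per (subject, covariate).
#' @param smoothing_window Moving-average window (frames) applied to the
#'   noise along the gait cycle; default 9.
#' @param clothes2_subjects,clothes2_cycles Subjects recorded in a second
#'   set of clothes and their cycle counts (scalar or per-subject vector).
#' @param backpack_subjects,backpack_cycles Subjects recorded with a
#'   backpack and their cycle counts.
#' @param seed Integer seed; equal seeds give bit-identical datasets.
#' @return A `gait_config` list.
#' @seealso [gpjatk_config()] for a preset emulating the 414-cycle,
#'   32-subject benchmark layout; [generate_gait_data()].
#' @export
gait_config <- function(n_subjects = 32L,
                        cycles_per_subject = 10L,
                        class_separation = 3,
                        noise_sd = 2,
                        covariate_shift_sd = 2,
                        smoothing_window = 9L,
                        clothes2_subjects = integer(0),
                        clothes2_cycles = integer(0),
                        backpack_subjects = integer(0),
                        backpack_cycles = integer(0),
                        seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) {
    stop("`n_subjects` must be an integer >= 2", call. = FALSE)
  }
  cycles_per_subject <- as.integer(cycles_per_subject)
  if (length(cycles_per_subject) == 1L) {
    cycles_per_subject <- rep(cycles_per_subject, n_subjects)
  }
  if (length(cycles_per_subject) != n_subjects || any(cycles_per_subject < 1L)) {
    stop("`cycles_per_subject` must be positive, scalar or length `n_subjects`",
         call. = FALSE)
  }
  if (class_separation < 0 || noise_sd <= 0 || covariate_shift_sd < 0) {
    stop("`class_separation`/`covariate_shift_sd` must be >= 0 and `noise_sd` > 0",
         call. = FALSE)
  }
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 1L || smoothing_window > GAIT_DIMS[["frames"]]) {
    stop("`smoothing_window` must be in [1, ", GAIT_DIMS[["frames"]], "]",
         call. = FALSE)
  }
  norm_cov <- function(subjects, cycles, what) {
    subjects <- as.integer(subjects)
    cycles <- as.integer(cycles)
    if (length(subjects) == 0L) return(list(subjects = integer(0), cycles = integer(0)))
    if (length(cycles) == 1L) cycles <- rep(cycles, length(subjects))
    if (length(cycles) != length(subjects) || any(cycles < 1L) ||
        any(subjects < 1L | subjects > n_subjects)) {
      stop("invalid `", what, "` covariate specification", call. = FALSE)
    }
    list(subjects = subjects, cycles = cycles)
  }
  c2 <- norm_cov(clothes2_subjects, clothes2_cycles, "clothes2")
  bp <- norm_cov(backpack_subjects, backpack_cycles, "backpack")
  structure(
    list(
      n_subjects = n_subjects,
      cycles_per_subject = cycles_per_subject,
      class_separation = class_separation,
      noise_sd = noise_sd,
      covariate_shift_sd = covariate_shift_sd,
      smoothing_window = smoothing_window,
      clothes2_subjects = c2$subjects,
      clothes2_cycles = c2$cycles,
      backpack_subjects = bp$subjects,
      backpack_cycles = bp$cycles,
      seed = as.integer(seed)
    ),
    class = "gait_config"
  )
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  cat("  subjects:          ", x$n_subjects, "\n")
  cat("  clothes1 cycles:   ", sum(x$cycles_per_subject), "\n")
  cat("  clothes2 cycles:   ", sum(x$clothes2_cycles), "\n")
  cat("  backpack cycles:   ", sum(x$backpack_cycles), "\n")
  cat("  class separation:  ", x$class_separation, "(x noise_sd)\n")
  cat("  noise sd:          ", x$noise_sd, "deg\n")
  cat("  covariate shift:   ", x$covariate_shift_sd, "deg RMS\n")
  cat("  smoothing window:  ", x$smoothing_window, "frames\n")
  cat("  seed:              ", x$seed, "\n")
  invisible(x)
}

#' Preset emulating the 414-cycle benchmark layout
#'
#' Reproduces the class/covariate structure of the 32-subject gait
#' benchmark: 325 baseline (`clothes1`) cycles over 32 subjects, 58
#' clothing-change cycles over subjects 26--31, and 31 backpack cycles over
#' subjects 26--32 (414 cycles total).  Per-subject counts within the
#' published totals are an allocation choice of this generator.
#'
#' @inheritParams gait_config
#' @return A `gait_config`.
#' @export
gpjatk_config <- function(class_separation = 3, noise_sd = 2,
                          covariate_shift_sd = 2, seed = 1L) {
  gait_config(
    n_subjects = 32L,
    cycles_per_subject = c(rep(11L, 5L), rep(10L, 27L)),      # 325
    class_separation = class_separation,
    noise_sd = noise_sd,
    covariate_shift_sd = covariate_shift_sd,
    clothes2_subjects = 26:31,
    clothes2_cycles = c(10L, 10L, 10L, 10L, 9L, 9L),          # 58
    backpack_subjects = 26:32,
    backpack_cycles = c(5L, 5L, 5L, 4L, 4L, 4L, 4L),          # 31
    seed = seed
  )
}

#' Centered moving-average filter
#'
#' Smooths a series with a centered moving average of the given window
#' length, the filter applied to motion-capture trajectories.  At the
#' boundaries the window shrinks symmetrically so that it covers only valid
#' indices and the output keeps the input length; even windows therefore act
#' as the next-smaller odd window.
#'
#' @param x Numeric vector.
#' @param window Window length in samples (default 9); must be between 1 and
#'   `length(x)`.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' moving_average_filter(c(0, 1, 2, 3, 4), window = 1)
#' @export
moving_average_filter <- function(x, window = 9L) {
  n <- length(x)
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("`window` must be >= 1", call. = FALSE)
  if (window > n) stop("`window` (", window, ") exceeds series length (", n, ")",
                       call. = FALSE)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    r <- min(h, i - 1L, n - i)
    mean(x[(i - r):(i + r)])
  }, numeric(1))
}

# 32 x 32 linear operator equivalent to moving_average_filter(), built by
# filtering the identity (the filter is linear), so array smoothing stays
# consistent with the exported function.
smoothing_operator <- function(window) {
  n <- GAIT_DIMS[["frames"]]
  vapply(seq_len(n), function(j) {
    e <- numeric(n)
    e[j] <- 1
    moving_average_filter(e, window)
  }, numeric(n))
}

# Smooth periodic curves: a (frames x 10 x 3) array of low-order Fourier
# series, one per (bone channel, angle).  `amp` scales harmonics 1..H,
# `mean_sd` the constant term.
random_fourier_tensor <- function(amp, mean_sd) {
  n_f <- GAIT_DIMS[["frames"]]
  n_b <- GAIT_DIMS[["channels"]] - 1L
  n_a <- GAIT_DIMS[["angles"]]
  h <- length(amp)
  tau <- 2 * pi * (seq_len(n_f) - 1L) / n_f
  basis_cos <- outer(tau, seq_len(h), function(t, k) cos(k * t))
  basis_sin <- outer(tau, seq_len(h), function(t, k) sin(k * t))
  out <- array(0, dim = c(n_f, n_b, n_a))
  for (b in seq_len(n_b)) {
    for (a in seq_len(n_a)) {
      ca <- rnorm(h) * amp
      sa <- rnorm(h) * amp
      out[, b, a] <- rnorm(1) * mean_sd + basis_cos %*% ca + basis_sin %*% sa
    }
  }
  out
}

#' Generate a labeled synthetic gait dataset
#'
#' Draws gait cycles under the conditions of a [gait_config()]: every class
#' has a fixed smooth mean trajectory (shared base gait pattern plus a
#' class-specific low-order Fourier offset of Frobenius norm
#' `class_separation * noise_sd`); each cycle adds i.i.d. Gaussian noise
#' smoothed along the cycle with the configured moving-average window;
#' `clothes2`/`backpack` cycles additionally receive a per-(subject,
#' covariate) smooth offset.  Channel 11 holds the subject's height,
#' distance between ankles, and an exact zero in every frame.
#'
#' @param config A [gait_config()].
#' @param seed Seed overriding `config$seed`.
#' @return A tibble with one row per gait cycle: `cycle_id`, `subject_id`,
#'   `covariate`, `cycle_index` (acquisition order within subject), and the
#'   1056 tensor columns named by [gait_feature_names()].
#' @examples
#' gaits <- generate_gait_data(gait_config(n_subjects = 3, cycles_per_subject = 4))
#' dplyr::count(gaits, subject_id)
#' @export
generate_gait_data <- function(config = gait_config(), seed = config$seed) {
  stopifnot(inherits(config, "gait_config"))
  with_seed(seed, {
    n_f <- GAIT_DIMS[["frames"]]
    n_b <- GAIT_DIMS[["channels"]] - 1L
    n_a <- GAIT_DIMS[["angles"]]
    k <- config$n_subjects

    # Shared base gait pattern: dominant fundamental with decaying harmonics,
    # amplitudes on the scale of tens of degrees.
    base <- random_fourier_tensor(amp = c(20, 8, 3), mean_sd = 15)

    # Per-class smooth offsets, normalized to the configured separation.
    devs <- lapply(seq_len(k), function(i) {
      d <- random_fourier_tensor(amp = c(1, 0.6, 0.3), mean_sd = 0.5)
      nrm <- sqrt(sum(d^2))
      if (nrm > 0) d * (config$class_separation * config$noise_sd / nrm) else d
    })

    # Anthropometric constants, fixed across a subject's cycles.
    heights <- runif(k, 1.50, 1.95)
    ankles <- runif(k, 0.10, 0.40)

    # Covariate offsets drawn once per (subject, covariate).
    cov_offset <- list(clothes2 = vector("list", k), backpack = vector("list", k))
    for (cov in c("clothes2", "backpack")) {
      subs <- config[[paste0(cov, "_subjects")]]
      for (s in subs) {
        d <- random_fourier_tensor(amp = c(1, 0.6, 0.3), mean_sd = 0.5)
        rms <- sqrt(mean(d^2))
        cov_offset[[cov]][[s]] <- if (rms > 0) d * (config$covariate_shift_sd / rms) else d
      }
    }

    # Acquisition plan: per subject, clothes1 cycles then clothes2 then
    # backpack; cycle_index counts within subject across covariates.
    plan <- dplyr::bind_rows(
      tibble::tibble(
        subject_id = rep(seq_len(k), config$cycles_per_subject),
        covariate = "clothes1"
      ),
      tibble::tibble(
        subject_id = rep(config$clothes2_subjects, config$clothes2_cycles),
        covariate = "clothes2"
      ),
      tibble::tibble(
        subject_id = rep(config$backpack_subjects, config$backpack_cycles),
        covariate = "backpack"
      )
    )
    plan <- dplyr::arrange(plan, .data$subject_id,
                           match(.data$covariate, COVARIATE_LEVELS))
    plan <- dplyr::mutate(
      dplyr::group_by(plan, .data$subject_id),
      cycle_index = dplyr::row_number()
    )
    plan <- dplyr::ungroup(plan)
    n <- nrow(plan)

    smooth <- smoothing_operator(config$smoothing_window)

    rows <- matrix(0, nrow = n, ncol = prod(GAIT_DIMS))
    for (i in seq_len(n)) {
      s <- plan$subject_id[i]
      mu <- base + devs[[s]]
      off <- cov_offset[[plan$covariate[i]]]
      if (!is.null(off) && !is.null(off[[s]])) mu <- mu + off[[s]]
      noise <- array(rnorm(n_f * n_b * n_a, sd = config$noise_sd),
                     dim = c(n_f, n_b, n_a))
      noise <- fold_tensor(smooth %*% unfold_tensor(noise, 1L), 1L,
                           c(n_f, n_b, n_a))
      tens <- array(0, dim = unname(GAIT_DIMS))
      tens[, seq_len(n_b), ] <- mu + noise
      tens[, GAIT_DIMS[["channels"]], 1L] <- heights[s]
      tens[, GAIT_DIMS[["channels"]], 2L] <- ankles[s]
      # third slot of channel 11 stays exactly 0
      rows[i, ] <- flatten_gait_tensor(tens)
    }
    colnames(rows) <- gait_feature_names()

    dplyr::bind_cols(
      tibble::tibble(
        cycle_id = seq_len(n),
        subject_id = plan$subject_id,
        covariate = plan$covariate,
        cycle_index = plan$cycle_index
      ),
      tibble::as_tibble(rows)
    )
  })
}
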