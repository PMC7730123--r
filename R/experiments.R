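# Evaluation protocols: hold-out splits with per-class "last sample"
# validation extraction, repeated optimizer runs, and stratified 10-fold
# cross-validation, reporting CCR and confusion matrices.

#' Correct classified ratio
#'
#' Fraction of samples whose predicted class equals the true class.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return A number in `[0, 1]`.
#' @export
ccr <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  mean(as.character(y_true) == as.character(y_pred))
}

#' Confusion matrix of counts
#'
#' Entry `(k, y)` counts samples of true class `k` predicted as `y` (rows =
#' truth, columns = prediction).
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param classes Class labels fixing the matrix dimension and order;
#'   defaults to the sorted union of observed labels.
#' @return A K x K integer matrix with dimnames `true`/`predicted`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  classes <- as.character(classes)
  m <- table(
    factor(y_true, levels = classes),
    factor(y_pred, levels = classes)
  )
  m <- unclass(m)
  dimnames(m) <- list(true = classes, predicted = classes)
  storage.mode(m) <- "integer"
  m
}

#' Experiment split protocols
#'
#' Defines how a gait dataset is divided into training, validation, and
#' test sets.  The presets mirror the four benchmark experiments:
#'
#' * `set1` — train/validation/test all from the baseline (`clothes1`)
#'   cycles; per class, the last `test_fraction` of cycles form the test
#'   set and the last remaining cycle the validation set.
#' * `set2` — test on the clothing-change (`clothes2`) cycles; the
#'   baseline cycles form the training portion, with the last 2 cycles per
#'   class held out for validation.
#' * `set3` — as `set2` but testing on the `backpack` cycles.
#' * `set4` — stratified 10-fold cross-validation over the baseline
#'   cycles, with roughly 10% of the data (at least one cycle per class)
#'   extracted from each fold's training portion for validation
#'   (80%/10%/10%).
#'
#' "Last" refers to the dataset's per-class acquisition order (row order
#' within each class).
#'
#' @param name Preset name or `"custom"`.
#' @param validation_per_class Validation cycles extracted per class from
#'   the training portion (preset: 1 for `set1`, 2 for `set2`/`set3`).
#' @param test_covariate Covariate tag selecting the test set (`set2`/`set3`),
#'   or `NULL`.
#' @param test_fraction Per-class fraction of pool cycles moved to the test
#'   set when no covariate rule applies (`set1`); 0 gives an empty test set.
#' @param n_folds Number of cross-validation folds (`set4`: 10; 1 = hold-out).
#' @param repetitions Number of repeated optimizer runs (default 10).
#' @param pool_covariate Covariate tag(s) forming the training pool when a
#'   `covariate` column is present (default `"clothes1"`); `NULL` uses all
#'   rows.
#' @return A `gait_protocol` list.
#' @export
gait_protocol <- function(name = c("set1", "set2", "set3", "set4", "custom"),
                          validation_per_class = NULL, test_covariate = NULL,
                          test_fraction = NULL, n_folds = NULL,
                          repetitions = 10L, pool_covariate = "clothes1") {
  name <- match.arg(name)
  defaults <- switch(name,
    set1 = list(validation_per_class = 1L, test_covariate = NULL,
                test_fraction = 0.48, n_folds = 1L),
    set2 = list(validation_per_class = 2L, test_covariate = "clothes2",
                test_fraction = 0, n_folds = 1L),
    set3 = list(validation_per_class = 2L, test_covariate = "backpack",
                test_fraction = 0, n_folds = 1L),
    set4 = list(validation_per_class = NULL, test_covariate = NULL,
                test_fraction = 0, n_folds = 10L),
    custom = list(validation_per_class = 1L, test_covariate = NULL,
                  test_fraction = 0, n_folds = 1L)
  )
  p <- list(
    name = name,
    validation_per_class = validation_per_class %||% defaults$validation_per_class,
    test_covariate = test_covariate %||% defaults$test_covariate,
    test_fraction = test_fraction %||% defaults$test_fraction,
    n_folds = as.integer(n_folds %||% defaults$n_folds),
    repetitions = as.integer(repetitions),
    pool_covariate = pool_covariate
  )
  if (!is.null(p$validation_per_class) && p$validation_per_class < 1L) {
    stop("`validation_per_class` must be >= 1", call. = FALSE)
  }
  if (p$n_folds > 1L && p$n_folds < 2L) {
    stop("`n_folds` must be >= 2 for cross-validation", call. = FALSE)
  }
  structure(p, class = "gait_protocol")
}

#' @export
print.gait_protocol <- function(x, ...) {
  cat("<gait_protocol> ", x$name, "\n", sep = "")
  if (x$n_folds > 1L) {
    cat("  ", x$n_folds, "-fold cross-validation\n", sep = "")
  } else {
    if (!is.null(x$test_covariate)) {
      cat("  test: covariate ", x$test_covariate, "\n", sep = "")
    } else {
      cat("  test: last ", format(x$test_fraction), " of each class\n", sep = "")
    }
    cat("  validation per class: ", x$validation_per_class, "\n", sep = "")
  }
  cat("  repetitions: ", x$repetitions, "\n", sep = "")
  invisible(x)
}

# Rows forming the training pool under a protocol.
pool_rows <- function(data, protocol) {
  if (!is.null(protocol$pool_covariate) && "covariate" %in% names(data)) {
    which(data$covariate %in% protocol$pool_covariate)
  } else {
    seq_len(nrow(data))
  }
}

#' Hold-out split of a gait dataset
#'
#' Selects the test set by the protocol's rule (a covariate tag or the last
#' `test_fraction` of each class's pool cycles), then removes the last
#' `validation_per_class` cycles of each class from the remaining training
#' portion as the validation set.  The three subsets are disjoint; "last"
#' follows the per-class row order of `data`.
#'
#' @param data A gait or feature tibble with a label column (and optionally
#'   a `covariate` column).
#' @param protocol A [gait_protocol()].
#' @param label_col Label column name.
#' @return A list of tibbles: `train`, `validation`, `test`.
#' @export
split_holdout <- function(data, protocol, label_col = "subject_id") {
  stopifnot(inherits(protocol, "gait_protocol"))
  if (!label_col %in% names(data)) {
    stop("column `", label_col, "` not found", call. = FALSE)
  }
  y <- data[[label_col]]
  pool <- pool_rows(data, protocol)

  if (!is.null(protocol$test_covariate)) {
    if (!"covariate" %in% names(data)) {
      stop("protocol selects test by covariate but the data has no ",
           "`covariate` column", call. = FALSE)
    }
    test_idx <- which(data$covariate %in% protocol$test_covariate)
  } else if (protocol$test_fraction > 0) {
    test_idx <- unlist(lapply(split(pool, y[pool]), function(rows) {
      n_test <- floor(protocol$test_fraction * length(rows))
      if (n_test > 0) tail(rows, n_test) else integer(0)
    }), use.names = FALSE)
    pool <- setdiff(pool, test_idx)
  } else {
    test_idx <- integer(0)
  }

  v <- protocol$validation_per_class
  by_class <- split(pool, y[pool])
  too_small <- vapply(by_class, length, integer(1)) <= v
  if (any(too_small)) {
    stop("class ", names(by_class)[which(too_small)[1]], " has only ",
         length(by_class[[which(too_small)[1]]]),
         " training cycles; needs more than validation_per_class = ", v,
         call. = FALSE)
  }
  val_idx <- unlist(lapply(by_class, tail, v), use.names = FALSE)
  train_idx <- setdiff(pool, val_idx)

  list(
    train = data[sort(train_idx), , drop = FALSE],
    validation = data[sort(val_idx), , drop = FALSE],
    test = data[sort(test_idx), , drop = FALSE]
  )
}

# Stratified fold assignment: within-class shuffle, then a global
# round-robin counter so overall fold sizes differ by at most one.
assign_folds <- function(y, n_folds, seed = NULL) {
  with_seed(seed, {
    folds <- integer(length(y))
    counter <- 0L
    for (cls in unique(y)) {
      rows <- which(y == cls)
      rows <- rows[sample.int(length(rows))]
      folds[rows] <- (counter + seq_along(rows) - 1L) %% n_folds + 1L
      counter <- counter + length(rows)
    }
    folds
  })
}

new_eval_report <- function(runs, confusions, protocol, classes, seeds) {
  agg <- Reduce(`+`, confusions)
  structure(
    list(
      runs = runs,
      mean_ccr = mean(runs$ccr),
      confusion_matrices = confusions,
      aggregate_confusion = agg,
      protocol = protocol,
      classes = classes,
      seeds = seeds
    ),
    class = "gait_eval_report"
  )
}

#' Stratified k-fold cross-validation of the hybrid classifier
#'
#' Partitions the training pool into `protocol$n_folds` disjoint folds of
#' near-equal size (stratified by class).  Each fold in turn is the test
#' set; from the remaining training portion, roughly 10% of the data — at
#' least one cycle per class, taken last-per-class — is extracted for
#' validation, and [train_hybrid()] is run with a fold-specific sub-seed.
#'
#' @param data A gait-feature tibble (reduced features + labels).
#' @param protocol A [gait_protocol()] with `n_folds >= 2`.
#' @param algorithm,n_agents,n_iterations,label_col,... Passed to
#'   [train_hybrid()].
#' @param seed Master seed; fold assignment and per-fold optimizer seeds
#'   derive from it.
#' @return A `gait_eval_report`.
#' @export
kfold_cv <- function(data, protocol, algorithm = c("pso", "gwo", "woa"),
                     n_agents = 30L, n_iterations = 25L, seed = 1L,
                     label_col = "subject_id", ...) {
  stopifnot(inherits(protocol, "gait_protocol"), protocol$n_folds >= 2L)
  algorithm <- match.arg(algorithm)
  pool <- pool_rows(data, protocol)
  data <- data[pool, , drop = FALSE]
  y <- data[[label_col]]
  n <- nrow(data)
  k_classes <- length(unique(y))
  if (n < protocol$n_folds) {
    stop("fewer samples (", n, ") than folds (", protocol$n_folds, ")",
         call. = FALSE)
  }
  seeds <- derive_seeds(seed, protocol$n_folds + 1L)
  folds <- assign_folds(y, protocol$n_folds, seed = seeds[1])
  v_per_class <- protocol$validation_per_class %||%
    max(1L, round(0.1 * n / k_classes))

  classes <- sort(unique(as.character(y)))
  runs <- vector("list", protocol$n_folds)
  confusions <- vector("list", protocol$n_folds)
  for (f in seq_len(protocol$n_folds)) {
    test <- data[folds == f, , drop = FALSE]
    rest_idx <- which(folds != f)
    by_class <- split(rest_idx, y[rest_idx])
    val_idx <- unlist(lapply(by_class, function(rows) {
      tail(rows, min(v_per_class, length(rows) - 1L))
    }), use.names = FALSE)
    train <- data[setdiff(rest_idx, val_idx), , drop = FALSE]
    validation <- data[sort(val_idx), , drop = FALSE]
    fit <- train_hybrid(train, validation, test, algorithm = algorithm,
                        n_agents = n_agents, n_iterations = n_iterations,
                        seed = seeds[f + 1L], label_col = label_col, ...)
    runs[[f]] <- tibble::tibble(
      run = f, seed = seeds[f + 1L],
      validation_confusion = fit$validation_confusion,
      ccr = fit$test_ccr
    )
    confusions[[f]] <- fit$test_confusion_matrix
  }
  new_eval_report(dplyr::bind_rows(runs), confusions, protocol, classes,
                  seeds[-1])
}

#' Run a full evaluation experiment
#'
#' Dispatches on the protocol: hold-out protocols split once and repeat
#' [train_hybrid()] `repetitions` times with distinct optimizer sub-seeds
#' (the split itself is deterministic); cross-validation protocols run
#' [kfold_cv()].  CCRs and confusion matrices are aggregated across runs.
#'
#' @param data A gait-feature tibble (reduced features + labels).
#' @param protocol A [gait_protocol()].
#' @param algorithm,n_agents,n_iterations,label_col,... Passed to
#'   [train_hybrid()].
#' @param seed Master seed for the repetition sub-seeds.
#' @param repetitions Overrides `protocol$repetitions`.
#' @return A `gait_eval_report`: per-run CCRs, mean CCR, per-run and
#'   aggregate confusion matrices, seeds used.
#' @export
run_experiment <- function(data, protocol, algorithm = c("pso", "gwo", "woa"),
                           n_agents = 30L, n_iterations = 25L, seed = 1L,
                           repetitions = NULL, label_col = "subject_id", ...) {
  stopifnot(inherits(protocol, "gait_protocol"))
  algorithm <- match.arg(algorithm)
  if (protocol$n_folds > 1L) {
    return(kfold_cv(data, protocol, algorithm = algorithm,
                    n_agents = n_agents, n_iterations = n_iterations,
                    seed = seed, label_col = label_col, ...))
  }
  repetitions <- as.integer(repetitions %||% protocol$repetitions)
  split <- split_holdout(data, protocol, label_col)
  if (nrow(split$test) == 0L) {
    stop("protocol produced an empty test set", call. = FALSE)
  }
  classes <- sort(unique(as.character(split$train[[label_col]])))
  seeds <- derive_seeds(seed, repetitions)
  runs <- vector("list", repetitions)
  confusions <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    fit <- train_hybrid(split$train, split$validation, split$test,
                        algorithm = algorithm, n_agents = n_agents,
                        n_iterations = n_iterations, seed = seeds[r],
                        label_col = label_col, ...)
    runs[[r]] <- tibble::tibble(
      run = r, seed = seeds[r],
      validation_confusion = fit$validation_confusion,
      ccr = fit$test_ccr
    )
    confusions[[r]] <- fit$test_confusion_matrix
  }
  new_eval_report(dplyr::bind_rows(runs), confusions, protocol, classes, seeds)
}

#' @export
print.gait_eval_report <- function(x, ...) {
  cat("<gait_eval_report> protocol ", x$protocol$name, ", ",
      nrow(x$runs), " runs\n", sep = "")
  cat("  mean CCR: ", format(x$mean_ccr, digits = 4), "\n")
  cat("  per-run CCR: ", paste(format(x$runs$ccr, digits = 3), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
tidy.gait_eval_report <- function(x, ...) {
  x$runs
}

#' @export
glance.gait_eval_report <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol$name,
    n_runs = nrow(x$runs),
    mean_ccr = x$mean_ccr,
    sd_ccr = stats::sd(x$runs$ccr),
    mean_validation_confusion = mean(x$runs$validation_confusion)
  )
}

#' @export
autoplot.gait_eval_report <- function(object, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = factor(.data$run), y = .data$ccr)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$mean_ccr, linetype = 2) +
    ggplot2::labs(x = "run", y = "test CCR",
                  title = paste("Protocol", object$protocol$name)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a confusion matrix
#'
#' Row-normalized heatmap (rows = true class) of a counts matrix as
#' produced by [confusion_matrix()] or stored in a `gait_eval_report`.
#'
#' @param m A K x K counts matrix.
#' @return A ggplot object.
#' @export
plot_confusion_matrix <- function(m) {
  d <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(d) <- c("true", "predicted", "count")
  d <- dplyr::group_by(d, .data$true)
  d <- dplyr::mutate(d, fraction = .data$count / sum(.data$count))
  d <- dplyr::ungroup(d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "fraction") +
    ggplot2::theme_minimal()
}
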