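# File-format plumbing: delimited text for gait cycles and feature tables,
# JSON for configurations, fitted models, projections, and reports.  CSV
# dialect: comma-separated, header row, UTF-8, '.' decimal.  Outputs are
# written atomically (temp file + rename) and contain no timestamps, so
# identical inputs give byte-identical files.

atomic_write <- function(write_fn, path) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fn(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read and write gait datasets as CSV
#'
#' One row per gait cycle: `cycle_id`, `subject_id`, `covariate`,
#' `cycle_index`, then the 1056 tensor columns named by
#' [gait_feature_names()] (frame-major, channel-middle, angle-minor — the
#' name `t07_b03_a2` is frame 7, channel 3, angle 2).  Values round-trip to
#' better than 1e-12 relative precision and labels exactly.
#'
#' @param data A gait tibble.
#' @param path File path.
#' @return `read_gait_csv()` returns a gait tibble; `write_gait_csv()`
#'   returns `path` invisibly.
#' @export
write_gait_csv <- function(data, path) {
  stopifnot(all(c("subject_id", "covariate") %in% names(data)))
  atomic_write(function(p) readr::write_csv(data, p, progress = FALSE), path)
}

#' @rdname write_gait_csv
#' @export
read_gait_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("subject_id", "covariate", gait_feature_names()),
                     names(data))
  if (length(missing) > 0L) {
    stop("not a gait table: missing column ", missing[1], call. = FALSE)
  }
  bad <- setdiff(unique(data$covariate), COVARIATE_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown covariate value \"", bad[1], "\" (expected ",
         paste(COVARIATE_LEVELS, collapse = ", "), ")", call. = FALSE)
  }
  data$subject_id <- as.integer(data$subject_id)
  data
}

#' Read and write feature tables as CSV
#'
#' Feature tables carry the metadata columns present (`cycle_id`,
#' `subject_id`, `covariate`, `cycle_index`) plus numeric feature columns
#' (e.g. `pc_001`... from [project_mpca()]).
#'
#' @param data A feature tibble.
#' @param path File path.
#' @export
write_feature_csv <- function(data, path) {
  atomic_write(function(p) readr::write_csv(data, p, progress = FALSE), path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("subject_id" %in% names(data)) {
    data$subject_id <- as.integer(data$subject_id)
  }
  data
}

write_json_file <- function(x, path) {
  atomic_write(function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

#' JSON serialization of generator configurations
#'
#' @param config A [gait_config()].
#' @param path File path.
#' @export
write_gait_config <- function(config, path) {
  stopifnot(inherits(config, "gait_config"))
  write_json_file(unclass(config), path)
}

#' @rdname write_gait_config
#' @export
read_gait_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(gait_config, x[setdiff(names(x), character(0))])
}

#' JSON serialization of fitted RDA models
#'
#' Matrices are stored as nested row-major JSON arrays; the bundle carries
#' class means, the pooled and regularized covariances, priors, the cost
#' matrix, thresholded coefficients, and the hyperparameters.
#'
#' @param model An [fit_rda()] model.
#' @param path File path.
#' @export
write_rda_model <- function(model, path) {
  stopifnot(inherits(model, "rda_model"))
  write_json_file(unclass(model), path)
}

#' @rdname write_rda_model
#' @export
read_rda_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("class_means", "covariance", "reg_covariance", "cost_matrix",
              "coefficients")) {
    x[[f]] <- as.matrix(x[[f]])
  }
  x$classes <- as.character(x$classes)
  x$feature_names <- as.character(x$feature_names)
  dimnames(x$class_means) <- list(x$classes, x$feature_names)
  dimnames(x$covariance) <- list(x$feature_names, x$feature_names)
  dimnames(x$reg_covariance) <- list(x$feature_names, x$feature_names)
  dimnames(x$coefficients) <- list(x$feature_names, x$classes)
  dimnames(x$cost_matrix) <- NULL
  names(x$qk) <- x$classes
  names(x$mu_bar) <- x$feature_names
  x$eliminated <- as.integer(x$eliminated)
  structure(x, class = "rda_model")
}

#' JSON serialization of MPCA projections
#'
#' @param projection An [fit_mpca()] projection.
#' @param path File path.
#' @export
write_mpca <- function(projection, path) {
  stopifnot(inherits(projection, "mpca_projection"))
  x <- unclass(projection)
  x$mean_tensor_flat <- as.vector(flatten_gait_tensor(x$mean_tensor))
  x$mean_tensor <- NULL
  write_json_file(x, path)
}

#' @rdname write_mpca
#' @export
read_mpca <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$mode_matrices <- lapply(x$mode_matrices, as.matrix)
  x$mean_tensor <- unflatten_gait_tensor(x$mean_tensor_flat)
  x$mean_tensor_flat <- NULL
  x$ranks <- as.integer(x$ranks)
  structure(x, class = "mpca_projection")
}

#' Write a training result or evaluation report as JSON
#'
#' @param x A `gait_train_result` or `gait_eval_report`.
#' @param path File path.
#' @export
write_result_json <- function(x, path) {
  if (inherits(x, "gait_train_result")) {
    out <- list(
      algorithm = x$algorithm,
      n_agents = x$n_agents,
      n_iterations = x$n_iterations,
      seed = x$seed,
      delta = x$delta,
      gamma = x$gamma,
      weights = x$weights,
      objective_history = x$objective_history,
      validation_confusion = x$validation_confusion,
      test_ccr = x$test_ccr,
      test_confusion_matrix = x$test_confusion_matrix
    )
  } else if (inherits(x, "gait_eval_report")) {
    out <- list(
      protocol = x$protocol$name,
      seeds = x$seeds,
      runs = x$runs,
      mean_ccr = x$mean_ccr,
      aggregate_confusion = x$aggregate_confusion
    )
  } else {
    stop("unsupported result type", call. = FALSE)
  }
  write_json_file(out, path)
}
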