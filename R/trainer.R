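# Integration of the swarm optimizers with the weighted RDA classifier.
# One candidate solution ("agent") is the vector [w_1 ... w_n, delta, gamma]
# where n is the training-set size: the observation weights in
# [1e-8, 1] and the two hyperparameters in [0, 1].  The objective is the
# confusion value — the fraction of validation samples misclassified by the
# RDA fitted on the training set with the decoded parameters.

WEIGHT_RANGE <- c(1e-8, 1)

#' Encode and decode RDA agent vectors
#'
#' An agent lays out the candidate solution as
#' `[w_1, ..., w_n, delta, gamma]`: one weight per training observation
#' (each in `[1e-8, 1]`) followed by the coefficient threshold and the
#' regularization amount (each in `[0, 1]`).  `decode_agent()` inverts
#' `encode_agent()` and checks the length.
#'
#' @param weights Observation weights within `[1e-8, 1]`.
#' @param delta,gamma Hyperparameters within `[0, 1]`.
#' @param agent Numeric vector of length `n_train + 2`.
#' @param n_train Number of training observations encoded in the agent.
#' @return `encode_agent()`: a numeric vector; `decode_agent()`: a list
#'   with `weights`, `delta`, `gamma`.
#' @export
encode_agent <- function(weights, delta, gamma) {
  if (any(weights < WEIGHT_RANGE[1]) || any(weights > WEIGHT_RANGE[2])) {
    stop("weights must lie in [1e-8, 1]", call. = FALSE)
  }
  if (delta < 0 || delta > 1 || gamma < 0 || gamma > 1) {
    stop("`delta` and `gamma` must lie in [0, 1]", call. = FALSE)
  }
  c(weights, delta, gamma)
}

#' @rdname encode_agent
#' @export
decode_agent <- function(agent, n_train) {
  if (length(agent) != n_train + 2L) {
    stop("agent has length ", length(agent), ", expected n_train + 2 = ",
         n_train + 2L, call. = FALSE)
  }
  list(
    weights = agent[seq_len(n_train)],
    delta = agent[n_train + 1L],
    gamma = agent[n_train + 2L]
  )
}

#' Box bounds of the agent search space
#'
#' @param n_train Training-set size.
#' @return List with `lower` and `upper` vectors of length `n_train + 2`.
#' @export
agent_bounds <- function(n_train) {
  list(
    lower = c(rep(WEIGHT_RANGE[1], n_train), 0, 0),
    upper = c(rep(WEIGHT_RANGE[2], n_train), 1, 1)
  )
}

# Matrix-level objective used in the optimizer hot loop.
confusion_objective_impl <- function(train_x, train_y, val_x, val_y,
                                     cost_matrix = NULL, prior = "weighted") {
  force(train_x); force(train_y); force(val_x); force(val_y)
  function(agent) {
    par <- decode_agent(agent, nrow(train_x))
    model <- tryCatch(
      fit_rda_impl(train_x, train_y, par$weights, par$gamma, par$delta,
                   cost_matrix, prior),
      error = function(e) NULL
    )
    if (is.null(model)) return(1)  # failed fits score worst, never crash
    pred <- rda_predict_impl(model, val_x)
    mean(pred != as.character(val_y))
  }
}

#' Validation confusion value of an agent
#'
#' Fits the weighted RDA on the training set with the weights and
#' hyperparameters decoded from `agent`, and returns the fraction of
#' validation samples misclassified.  A failed fit (e.g. a singular model
#' at `gamma = 0`) scores the worst value 1 rather than erroring, so the
#' optimizer can move through infeasible regions.
#'
#' @param agent Numeric agent vector of length `nrow(train) + 2`.
#' @param train,validation Feature tibbles sharing feature columns and
#'   label space.
#' @param label_col Label column name.
#' @param cost_matrix Optional misclassification cost matrix.
#' @return The confusion value in `[0, 1]`.
#' @export
confusion_objective <- function(agent, train, validation,
                                label_col = "subject_id", cost_matrix = NULL) {
  if (nrow(validation) == 0L) stop("validation set is empty", call. = FALSE)
  tr <- feature_matrix(train, label_col)
  va <- feature_matrix(validation, label_col)
  obj <- confusion_objective_impl(tr$x, tr$y, va$x, va$y, cost_matrix)
  obj(agent)
}

#' Train a swarm-tuned weighted RDA classifier
#'
#' Runs the selected metaheuristic over the `(n_train + 2)`-dimensional
#' agent box, minimizing the validation confusion value; refits the RDA
#' with the best agent and evaluates it on the test set.
#'
#' @param train,validation,test Disjoint feature tibbles (e.g. from
#'   [project_mpca()]); `test` may be `NULL`.  Every class appearing in
#'   `validation`/`test` must be present in `train`.
#' @param algorithm `"pso"`, `"gwo"`, or `"woa"`.
#' @param n_agents,n_iterations Swarm budget (defaults 30 and 25).
#' @param seed Integer seed making the run deterministic.
#' @param label_col Label column name.
#' @param cost_matrix Optional misclassification cost matrix.
#' @param inject_baseline Inject a unit-weight, `delta = 0`, `gamma = 0.5`
#'   baseline agent into the initial population (off by default).
#' @param swarm_params Passed to [swarm_optimize()] `params`.
#' @return A `gait_train_result`: `best_agent`, decoded `weights`, `delta`,
#'   `gamma`, the refitted `model`, `objective_history`,
#'   `validation_confusion`, and (with a test set) `test_ccr` and
#'   `test_confusion_matrix`.
#' @export
train_hybrid <- function(train, validation, test = NULL,
                         algorithm = c("pso", "gwo", "woa"),
                         n_agents = 30L, n_iterations = 25L, seed = NULL,
                         label_col = "subject_id", cost_matrix = NULL,
                         inject_baseline = FALSE, swarm_params = list()) {
  algorithm <- match.arg(algorithm)
  if (nrow(validation) == 0L) stop("validation set is empty", call. = FALSE)
  tr <- feature_matrix(train, label_col)
  va <- feature_matrix(validation, label_col)
  train_classes <- sort(unique(as.character(tr$y)))
  check_classes <- function(y, what) {
    extra <- setdiff(unique(as.character(y)), train_classes)
    if (length(extra) > 0L) {
      stop("class ", extra[1], " appears in the ", what,
           " set but not in the training set", call. = FALSE)
    }
  }
  check_classes(va$y, "validation")
  if (!is.null(test)) {
    te <- feature_matrix(test, label_col)
    check_classes(te$y, "test")
  }

  n <- nrow(tr$x)
  bounds <- agent_bounds(n)
  objective <- confusion_objective_impl(tr$x, tr$y, va$x, va$y, cost_matrix)
  init <- if (inject_baseline) {
    matrix(encode_agent(rep(1, n), 0, 0.5), nrow = 1)
  } else {
    NULL
  }

  opt <- swarm_optimize(objective, bounds$lower, bounds$upper,
                        algorithm = algorithm, n_agents = n_agents,
                        n_iterations = n_iterations, seed = seed,
                        params = swarm_params, init = init)

  par <- decode_agent(opt$best_position, n)
  model <- fit_rda_impl(tr$x, tr$y, par$weights, par$gamma, par$delta,
                        cost_matrix)
  model$label_col <- label_col

  result <- list(
    best_agent = opt$best_position,
    weights = par$weights,
    delta = par$delta,
    gamma = par$gamma,
    model = model,
    algorithm = algorithm,
    n_agents = n_agents,
    n_iterations = n_iterations,
    seed = seed,
    objective_history = opt$history,
    validation_confusion = opt$best_value,
    test_ccr = NA_real_,
    test_confusion_matrix = NULL
  )
  if (!is.null(test)) {
    pred <- rda_predict_impl(model, te$x)
    result$test_ccr <- ccr(as.character(te$y), pred)
    result$test_confusion_matrix <-
      confusion_matrix(as.character(te$y), pred, classes = train_classes)
  }
  structure(result, class = "gait_train_result")
}

#' @export
print.gait_train_result <- function(x, ...) {
  cat("<gait_train_result> RDA-", toupper(x$algorithm), "\n", sep = "")
  cat("  agents x iterations:  ", x$n_agents, "x", x$n_iterations, "\n")
  cat("  best (delta, gamma):  ",
      format(x$delta, digits = 4), ", ", format(x$gamma, digits = 4), "\n",
      sep = "")
  cat("  validation confusion: ", format(x$validation_confusion, digits = 4), "\n")
  if (!is.na(x$test_ccr)) {
    cat("  test CCR:             ", format(x$test_ccr, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
tidy.gait_train_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$objective_history) - 1L,
    best_confusion = x$objective_history
  )
}

#' @export
glance.gait_train_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_agents = x$n_agents,
    n_iterations = x$n_iterations,
    delta = x$delta,
    gamma = x$gamma,
    validation_confusion = x$validation_confusion,
    test_ccr = x$test_ccr
  )
}

#' @export
autoplot.gait_train_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$best_confusion)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "iteration",
      y = "best validation confusion",
      title = paste0("RDA-", toupper(object$algorithm), " objective history")
    ) +
    ggplot2::theme_minimal()
}
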