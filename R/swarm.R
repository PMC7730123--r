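# Bound-constrained population metaheuristics: particle swarm optimization
# (PSO), grey wolf optimization (GWO), and the whale optimization algorithm
# (WOA), all minimizing a scalar objective over a box.  Positions are hard-
# clamped to the box after every update; the objective is evaluated once
# per agent per iteration.

clamp <- function(x, lower, upper) {
  pmin(pmax(x, matrix(lower, nrow(x), ncol(x), byrow = TRUE)),
       matrix(upper, nrow(x), ncol(x), byrow = TRUE))
}

eval_population <- function(objective, x) {
  v <- apply(x, 1, objective)
  if (any(!is.finite(v))) {
    stop("objective returned a non-finite value", call. = FALSE)
  }
  as.numeric(v)
}

#' Linearly decaying exploration schedule
#'
#' The coefficient schedule `a = 2 - 2 t / t_max` shared by the grey wolf
#' and whale optimizers: it decreases linearly from 2 at `t = 0` to 0 at
#' `t = t_max`, trading exploration for exploitation.
#'
#' @param t Current iteration, `0 <= t <= t_max`.
#' @param t_max Total number of iterations.
#' @return The scalar `a`.
#' @export
a_schedule <- function(t, t_max) {
  if (t < 0 || t > t_max) stop("`t` must lie in [0, t_max]", call. = FALSE)
  2 - 2 * t / t_max
}

# ---------------------------------------------------------------------------
# PSO

#' One particle swarm iteration
#'
#' Updates every particle's velocity as
#' `v <- omega v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh uniform
#' draws `r1, r2` per particle and dimension, clamps the velocity to
#' `params$vmax`, moves `x <- x + v`, clamps to the box, and refreshes the
#' personal/global bests by objective comparison.
#'
#' @param state List with matrices `x`, `v`, `pbest` (n_agents x d),
#'   vectors `pbest_val`, `gbest` (length d), scalar `gbest_val`, bounds
#'   `lower`/`upper`, and iteration counter `t`.
#' @param params List with `omega`, `c1`, `c2`, optional `vmax` (per-
#'   dimension velocity clamp), and optional fixed draws `r1`, `r2`
#'   (scalars or matrices) replacing the random ones.
#' @param objective Function of a position vector returning a finite scalar.
#' @return The updated state.
#' @export
pso_step <- function(state, params, objective) {
  n <- nrow(state$x)
  d <- ncol(state$x)
  r1 <- params$r1 %||% matrix(runif(n * d), n, d)
  r2 <- params$r2 %||% matrix(runif(n * d), n, d)
  if (length(r1) == 1L) r1 <- matrix(r1, n, d)
  if (length(r2) == 1L) r2 <- matrix(r2, n, d)

  gb <- matrix(state$gbest, n, d, byrow = TRUE)
  v <- params$omega * state$v +
    params$c1 * r1 * (state$pbest - state$x) +
    params$c2 * r2 * (gb - state$x)
  if (!is.null(params$vmax)) {
    vmax <- matrix(params$vmax, n, d, byrow = TRUE)
    v <- pmin(pmax(v, -vmax), vmax)
  }
  x <- clamp(state$x + v, state$lower, state$upper)

  val <- eval_population(objective, x)
  improved <- val < state$pbest_val
  state$pbest[improved, ] <- x[improved, , drop = FALSE]
  state$pbest_val[improved] <- val[improved]
  best <- which.min(state$pbest_val)
  if (state$pbest_val[best] < state$gbest_val) {
    state$gbest <- state$pbest[best, ]
    state$gbest_val <- state$pbest_val[best]
  }
  state$x <- x
  state$v <- v
  state$t <- state$t + 1L
  state
}

# ---------------------------------------------------------------------------
# GWO

#' One grey wolf iteration
#'
#' With `a = a_schedule(t, t_max)`, every wolf draws per-dimension `r1, r2`
#' for each of the three leaders (alpha, beta, delta), forms
#' `A = 2 a r1 - a`, `C = 2 r2`, distances `D = |C * leader - x|`, candidate
#' positions `X_i = leader - A * D`, and moves to their average, clamped to
#' the box.  Leaders are then refreshed against the new evaluations, so
#' alpha always carries the best solution seen.
#'
#' @param state List with matrix `x`, leader positions/values `alpha`,
#'   `alpha_val`, `beta`, `beta_val`, `delta`, `delta_val`, bounds, and
#'   `t`, `t_max`.
#' @param objective Objective function (finite scalar).
#' @param draws Optional fixed draws: list with `r1`, `r2`, each a scalar
#'   or an `n x d x 3` array (third index = leader), replacing the random
#'   ones.
#' @return The updated state.
#' @export
gwo_step <- function(state, objective, draws = NULL) {
  n <- nrow(state$x)
  d <- ncol(state$x)
  a <- a_schedule(state$t, state$t_max)

  get_draw <- function(r, lead) {
    if (is.null(r)) return(matrix(runif(n * d), n, d))
    if (length(r) == 1L) return(matrix(r, n, d))
    matrix(r[, , lead], n, d)
  }
  leaders <- list(state$alpha, state$beta, state$delta)
  xnew <- matrix(0, n, d)
  for (i in 1:3) {
    r1 <- get_draw(draws$r1, i)
    r2 <- get_draw(draws$r2, i)
    av <- 2 * a * r1 - a
    cv <- 2 * r2
    lead <- matrix(leaders[[i]], n, d, byrow = TRUE)
    dist <- abs(cv * lead - state$x)
    xnew <- xnew + (lead - av * dist)
  }
  x <- clamp(xnew / 3, state$lower, state$upper)

  val <- eval_population(objective, x)
  for (i in seq_len(n)) {
    if (val[i] < state$alpha_val) {
      state$delta <- state$beta; state$delta_val <- state$beta_val
      state$beta <- state$alpha; state$beta_val <- state$alpha_val
      state$alpha <- x[i, ]; state$alpha_val <- val[i]
    } else if (val[i] < state$beta_val) {
      state$delta <- state$beta; state$delta_val <- state$beta_val
      state$beta <- x[i, ]; state$beta_val <- val[i]
    } else if (val[i] < state$delta_val) {
      state$delta <- x[i, ]; state$delta_val <- val[i]
    }
  }
  state$x <- x
  state$t <- state$t + 1L
  state
}

# ---------------------------------------------------------------------------
# WOA

#' One whale optimization iteration
#'
#' With `a = a_schedule(t, t_max)`, every whale draws scalars `r1, r2`
#' (`A = 2 a r1 - a`, `C = 2 r2`), a branch variable `p` and a spiral
#' parameter `k` in `[-1, 1]`.  If `p < 0.5` and `|A| < 1` it encircles the
#' best solution (`x <- xbest - A |C xbest - x|`); if `p < 0.5` and
#' `|A| >= 1` it moves relative to a random whale; if `p >= 0.5` it spirals:
#' `x <- |xbest - x| exp(b k) cos(2 pi k) + xbest`.  Positions are clamped
#' and the best-so-far refreshed.
#'
#' @param state List with matrix `x`, vectors `best`/scalar `best_val`,
#'   bounds, spiral shape `b`, and `t`, `t_max`.
#' @param objective Objective function (finite scalar).
#' @param draws Optional fixed draws: list with per-whale vectors (or
#'   scalars) `r1`, `r2`, `p`, `k`, and optional `rand_idx` (index of the
#'   random whale used in the exploration branch).
#' @return The updated state.
#' @export
woa_step <- function(state, objective, draws = NULL) {
  n <- nrow(state$x)
  d <- ncol(state$x)
  a <- a_schedule(state$t, state$t_max)

  take <- function(r, default) {
    if (is.null(r)) return(default)
    if (length(r) == 1L) rep(r, n) else r
  }
  r1 <- take(draws$r1, runif(n))
  r2 <- take(draws$r2, runif(n))
  p <- take(draws$p, runif(n))
  kk <- take(draws$k, runif(n, -1, 1))
  rand_idx <- take(draws$rand_idx, sample.int(n, n, replace = TRUE))

  av <- 2 * a * r1 - a
  cv <- 2 * r2
  x <- state$x
  for (i in seq_len(n)) {
    if (p[i] < 0.5) {
      if (abs(av[i]) < 1) {
        dist <- abs(cv[i] * state$best - state$x[i, ])
        x[i, ] <- state$best - av[i] * dist
      } else {
        xr <- state$x[rand_idx[i], ]
        dist <- abs(cv[i] * xr - state$x[i, ])
        x[i, ] <- xr - av[i] * dist
      }
    } else {
      dstar <- abs(state$best - state$x[i, ])
      x[i, ] <- dstar * exp(state$b * kk[i]) * cos(2 * pi * kk[i]) + state$best
    }
  }
  x <- clamp(x, state$lower, state$upper)

  val <- eval_population(objective, x)
  best <- which.min(val)
  if (val[best] < state$best_val) {
    state$best <- x[best, ]
    state$best_val <- val[best]
  }
  state$x <- x
  state$t <- state$t + 1L
  state
}

# ---------------------------------------------------------------------------
# Driver

#' Minimize an objective over a box with a swarm metaheuristic
#'
#' Runs PSO, GWO, or WOA for `n_iterations` iterations with `n_agents`
#' agents initialized uniformly over the box.  Deterministic given `seed`.
#'
#' Default algorithm parameters: PSO uses inertia decaying linearly from
#' 0.9 to 0.4 across iterations, `c1 = c2 = 1.49`, and velocities clamped
#' to 20% of the box width per dimension; WOA uses spiral shape `b = 1`;
#' GWO and WOA share the [a_schedule()] decay.  Override via `params`
#' (`omega` fixes the PSO inertia instead of the decay; `c1`, `c2`,
#' `vmax_frac`, `b`).
#'
#' @param objective Function of a position vector returning a finite scalar.
#' @param lower,upper Finite bound vectors, `lower < upper` elementwise.
#' @param algorithm `"pso"`, `"gwo"`, or `"woa"`.
#' @param n_agents Population size (default 30).
#' @param n_iterations Iteration budget (default 25).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param params Named list of algorithm-specific overrides.
#' @param init Optional matrix of starting positions replacing the first
#'   rows of the uniform initialization (e.g. to inject a baseline agent).
#' @return A `swarm_result`: `best_position`, `best_value`, `history`
#'   (running best value, length `n_iterations + 1` including
#'   initialization), `algorithm`, `n_evaluations`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- swarm_optimize(sphere, rep(-5, 3), rep(5, 3),
#'                       algorithm = "gwo", n_iterations = 50, seed = 1)
#' res$best_value
#' @export
swarm_optimize <- function(objective, lower, upper,
                           algorithm = c("pso", "gwo", "woa"),
                           n_agents = 30L, n_iterations = 25L,
                           seed = NULL, params = list(), init = NULL) {
  algorithm <- match.arg(algorithm)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper elementwise", call. = FALSE)
  }
  n_agents <- as.integer(n_agents)
  n_iterations <- as.integer(n_iterations)
  if (n_agents < 2L || n_iterations < 1L) {
    stop("need `n_agents` >= 2 and `n_iterations` >= 1", call. = FALSE)
  }

  with_seed(seed, {
    x <- matrix(runif(n_agents * d), n_agents, d)
    x <- sweep(sweep(x, 2, upper - lower, `*`), 2, lower, `+`)
    if (!is.null(init)) {
      init <- matrix(init, ncol = d)
      rows <- seq_len(min(nrow(init), n_agents))
      x[rows, ] <- clamp(init[rows, , drop = FALSE], lower, upper)
    }
    val <- eval_population(objective, x)
    history <- numeric(n_iterations + 1L)
    history[1] <- min(val)
    n_eval <- n_agents

    if (algorithm == "pso") {
      omega_from <- params$omega_from %||% 0.9
      omega_to <- params$omega_to %||% 0.4
      pso_params <- list(
        c1 = params$c1 %||% 1.49,
        c2 = params$c2 %||% 1.49,
        vmax = (params$vmax_frac %||% 0.2) * (upper - lower)
      )
      best <- which.min(val)
      state <- list(
        x = x, v = matrix(0, n_agents, d),
        pbest = x, pbest_val = val,
        gbest = x[best, ], gbest_val = val[best],
        lower = lower, upper = upper, t = 0L
      )
      for (t in seq_len(n_iterations)) {
        pso_params$omega <- params$omega %||%
          (omega_from - (omega_from - omega_to) * (t - 1) / max(1, n_iterations - 1))
        state <- pso_step(state, pso_params, objective)
        n_eval <- n_eval + n_agents
        history[t + 1L] <- state$gbest_val
      }
      best_position <- state$gbest
      best_value <- state$gbest_val
    } else if (algorithm == "gwo") {
      ord <- order(val)
      state <- list(
        x = x,
        alpha = x[ord[1], ], alpha_val = val[ord[1]],
        beta = x[ord[2], ], beta_val = val[ord[2]],
        delta = x[ord[min(3L, n_agents)], ],
        delta_val = val[ord[min(3L, n_agents)]],
        lower = lower, upper = upper, t = 0L, t_max = n_iterations
      )
      for (t in seq_len(n_iterations)) {
        state <- gwo_step(state, objective)
        n_eval <- n_eval + n_agents
        history[t + 1L] <- state$alpha_val
      }
      best_position <- state$alpha
      best_value <- state$alpha_val
    } else {
      best <- which.min(val)
      state <- list(
        x = x, best = x[best, ], best_val = val[best],
        lower = lower, upper = upper,
        b = params$b %||% 1, t = 0L, t_max = n_iterations
      )
      for (t in seq_len(n_iterations)) {
        state <- woa_step(state, objective)
        n_eval <- n_eval + n_agents
        history[t + 1L] <- state$best_val
      }
      best_position <- state$best
      best_value <- state$best_val
    }

    structure(
      list(
        best_position = best_position,
        best_value = best_value,
        history = history,
        algorithm = algorithm,
        n_agents = n_agents,
        n_iterations = n_iterations,
        n_evaluations = n_eval
      ),
      class = "swarm_result"
    )
  })
}

#' @export
print.swarm_result <- function(x, ...) {
  cat("<swarm_result> ", x$algorithm, ": best value ",
      format(x$best_value, digits = 6), " after ", x$n_iterations,
      " iterations (", x$n_evaluations, " evaluations)\n", sep = "")
  invisible(x)
}

#' @export
tidy.swarm_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$history) - 1L,
    best_value = x$history
  )
}
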