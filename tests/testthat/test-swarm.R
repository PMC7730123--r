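sphere <- function(x) sum(x^2)

test_that("the exploration schedule decays linearly from 2 to 0", {
  expect_equal(a_schedule(0, 25), 2)
  expect_equal(a_schedule(25, 25), 0)
  expect_equal(a_schedule(12.5, 25), 1)
  expect_error(a_schedule(26, 25), "t_max")
})

test_that("pso_step reproduces the velocity/position update by hand", {
  mk_state <- function(x, v, pbest, gbest, pbest_val = 10, gbest_val = 5) {
    list(x = matrix(x), v = matrix(v), pbest = matrix(pbest),
         pbest_val = pbest_val, gbest = gbest, gbest_val = gbest_val,
         lower = -100, upper = 100, t = 0L)
  }

  # scalar hand check: v' = 0.5*1 + 1*0.5*(2-0) + 1*0.5*(4-0) = 3.5
  st <- pso_step(mk_state(0, 1, 2, 4),
                 params = list(omega = 0.5, c1 = 1, c2 = 1, r1 = 0.5, r2 = 0.5),
                 objective = sphere)
  expect_equal(as.numeric(st$v), 3.5)
  expect_equal(as.numeric(st$x), 3.5)

  # omega = 1, c1 = c2 = 0: velocity unchanged, pure drift
  st <- pso_step(mk_state(1, 2, 5, 7),
                 params = list(omega = 1, c1 = 0, c2 = 0),
                 objective = sphere)
  expect_equal(as.numeric(st$v), 2)
  expect_equal(as.numeric(st$x), 3)

  # at x = pbest = gbest the attraction terms vanish: v' = omega * v
  st <- pso_step(mk_state(2, 1, 2, 2),
                 params = list(omega = 0.25, c1 = 1.5, c2 = 1.5),
                 objective = sphere)
  expect_equal(as.numeric(st$v), 0.25)
})

test_that("gwo_step reproduces the leader-average update by hand", {
  mk_state <- function(x, leaders, t, t_max) {
    list(x = matrix(x), alpha = leaders[1], alpha_val = 1,
         beta = leaders[2], beta_val = 2, delta = leaders[3], delta_val = 3,
         lower = -100, upper = 100, t = t, t_max = t_max)
  }

  # a = 1 (t = Tmax/2), r1 = r2 = 0.5: A = 0, C = 1, so X_i = leader_i
  st <- gwo_step(mk_state(0, c(1, 2, 3), t = 1L, t_max = 2L), sphere,
                 draws = list(r1 = 0.5, r2 = 0.5))
  expect_equal(as.numeric(st$x), 2)

  # a = 0 at the final iteration: A = 0 for every draw regardless of r1
  st <- gwo_step(mk_state(5, c(1, 2, 3), t = 2L, t_max = 2L), sphere,
                 draws = list(r1 = 0.9, r2 = 0.5))
  expect_equal(as.numeric(st$x), 2)

  # all leaders at the same point, A = 0, C = 1: the wolf moves there
  st <- gwo_step(mk_state(-4, c(7, 7, 7), t = 1L, t_max = 2L), sphere,
                 draws = list(r1 = 0.5, r2 = 0.5))
  expect_equal(as.numeric(st$x), 7)

  # leaders stay ranked by objective after the step
  expect_lte(st$alpha_val, st$beta_val)
  expect_lte(st$beta_val, st$delta_val)
})

test_that("woa_step reproduces the encircle and spiral updates by hand", {
  mk_state <- function(x, best, t = 1L, t_max = 2L) {
    list(x = matrix(x), best = best, best_val = sphere(best),
         lower = -100, upper = 100, b = 1, t = t, t_max = t_max)
  }

  # p < 0.5 with A = 0 (r1 = 0.5): the whale moves exactly to the best
  st <- woa_step(mk_state(9, 2), sphere,
                 draws = list(r1 = 0.5, r2 = 0.5, p = 0.1, k = 0))
  expect_equal(as.numeric(st$x), 2)

  # spiral with D* = 0: a whale at the best stays there
  st <- woa_step(mk_state(2, 2), sphere,
                 draws = list(r1 = 0.5, r2 = 0.5, p = 0.9, k = 0.3))
  expect_equal(as.numeric(st$x), 2)

  # spiral hand check: x = 0, X* = 2, b = 1, k = 0 -> 2*e^0*cos(0) + 2 = 4
  st <- woa_step(mk_state(0, 2), sphere,
                 draws = list(r1 = 0.5, r2 = 0.5, p = 0.9, k = 0))
  expect_equal(as.numeric(st$x), 4)
})

test_that("the driver respects bounds, determinism, and running-best history", {
  for (alg in c("pso", "gwo", "woa")) {
    # constant objective: any in-bounds point, flat history
    res <- swarm_optimize(function(x) 1, c(-2, 0), c(3, 5), algorithm = alg,
                          n_agents = 5, n_iterations = 4, seed = 1)
    expect_equal(res$history, rep(1, 5))
    expect_true(all(res$best_position >= c(-2, 0) - 1e-12))
    expect_true(all(res$best_position <= c(3, 5) + 1e-12))

    # every evaluated position stays inside the box
    worst <- 0
    watcher <- function(x) {
      worst <<- max(worst, max(x - 5), max(-5 - x))
      sum(x^2)
    }
    res <- swarm_optimize(watcher, rep(-5, 3), rep(5, 3), algorithm = alg,
                          n_agents = 8, n_iterations = 10, seed = 2)
    expect_lte(worst, 1e-12)

    # history is the monotone running best and ends at the reported value
    set.seed(3)
    a <- rnorm(4)
    quad <- function(x) sum((x - a)^2) + 1
    res <- swarm_optimize(quad, rep(-5, 4), rep(5, 4), algorithm = alg,
                          n_agents = 10, n_iterations = 15, seed = 3)
    expect_length(res$history, 16)
    expect_true(all(diff(res$history) <= 0))
    expect_equal(res$history[16], res$best_value)
    expect_equal(res$best_value, quad(res$best_position))

    # same seed, same trajectory
    res2 <- swarm_optimize(quad, rep(-5, 4), rep(5, 4), algorithm = alg,
                           n_agents = 10, n_iterations = 15, seed = 3)
    expect_identical(res$history, res2$history)
    expect_identical(res$best_position, res2$best_position)
  }
})

test_that("invalid bounds and non-finite objectives are rejected", {
  expect_error(swarm_optimize(sphere, c(0, 0), c(1, -1)), "lower < upper")
  expect_error(swarm_optimize(sphere, c(0, Inf), c(1, 2)), "finite")
  expect_error(
    swarm_optimize(function(x) NaN, 0, 1, n_agents = 3, n_iterations = 2,
                   seed = 1),
    "non-finite"
  )
})

test_that("injected initial positions seed the population", {
  # with an injected optimum the history starts at (and keeps) the optimum
  res <- swarm_optimize(sphere, rep(-5, 3), rep(5, 3), algorithm = "gwo",
                        n_agents = 5, n_iterations = 3, seed = 4,
                        init = matrix(0, 1, 3))
  expect_equal(res$history[1], 0)
  expect_equal(res$best_value, 0)
})
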