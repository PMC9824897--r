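sphere <- function(x) -sum(x^2)

test_that("swarm initialization is seeded, in bounds, with memory = position", {
  cfg <- hybrid_seek_config(population_size = 5, bounds = c(0, 1), seed = 3)
  set.seed(3); st1 <- initialize_swarm(cfg, 2, sphere)
  set.seed(3); st2 <- initialize_swarm(cfg, 2, sphere)
  expect_identical(st1$positions, st2$positions)
  expect_true(all(st1$positions >= 0 & st1$positions <= 1))
  expect_identical(st1$memory, st1$positions)
  expect_identical(st1$memory_fitness, st1$fitness)
  expect_equal(st1$evaluations, 5)
  expect_error(hybrid_seek_config(population_size = 1), "at least 2")
})

test_that("corvid step follows a flock-mate's memory or relocates uniformly", {
  cfg <- hybrid_seek_config(population_size = 4, flight_length = 2,
                            awareness_probability = 0, bounds = c(-5, 5),
                            seed = 1)
  set.seed(10)
  st <- initialize_swarm(cfg, 3, sphere)
  for (i in 1:50) {
    prop <- corvid_step(1, st, cfg)
    # proposal must equal J_1 + lambda * a * (Z_f - J_1) for some mate f
    # and lambda in [0, 1]
    match_found <- FALSE
    for (f in 2:4) {
      dir <- st$memory[f, ] - st$positions[1, ]
      coef <- (prop - st$positions[1, ]) / dir
      if (all(abs(coef - coef[1]) < 1e-9) && coef[1] >= 0 &&
          coef[1] <= cfg$flight_length) {
        match_found <- TRUE
      }
    }
    expect_true(match_found)
  }

  # fully aware flock: relocations are uniform over the bounds
  cfg_aw <- hybrid_seek_config(population_size = 4,
                               awareness_probability = 1, bounds = c(-5, 5))
  set.seed(11)
  st <- initialize_swarm(cfg_aw, 1, sphere)
  draws <- replicate(1000, corvid_step(1, st, cfg_aw))
  expect_gt(stats::ks.test(draws, "punif", -5, 5)$p.value, 0.01)
})

test_that("gregarious step has the documented fixed point and stays finite", {
  cfg <- hybrid_seek_config(population_size = 3, bounds = c(-5, 5), seed = 1)
  st <- list(positions = matrix(c(1, 1, 0.5, 0.5, 0, 0), 3, 2, byrow = TRUE),
             memory = matrix(c(1, 1, 0.5, 0.5, 0, 0), 3, 2, byrow = TRUE),
             memory_fitness = c(3, 2, 1), fitness = c(3, 2, 1),
             velocity = c(0, 0))
  # non-best agent sitting on a zero J_best with zero velocity stays put
  # (the velocity augmentation term vanishes with J_best = 0)
  st_fp <- st
  st_fp$memory[1, ] <- c(0, 0)
  st_fp$positions[2, ] <- c(0, 0)
  set.seed(4)
  expect_equal(gregarious_step(2, st_fp, cfg), c(0, 0))

  # best agent: J_e + chi * |J_e - J_worst| / gap for one chi in [-1, 1]
  set.seed(5)
  prop <- gregarious_step(1, st, cfg)
  gap <- (3 - 1) + cfg$epsilon
  chi_hat <- (prop - st$positions[1, ]) * gap / abs(st$positions[1, ] - st$memory[3, ])
  expect_true(all(abs(chi_hat - chi_hat[1]) < 1e-9))
  expect_gte(chi_hat[1], -1)
  expect_lte(chi_hat[1], 1)

  # all-equal fitnesses: epsilon guards the denominator
  st_eq <- st
  st_eq$memory_fitness <- c(1, 1, 1)
  set.seed(6)
  expect_true(all(is.finite(gregarious_step(1, st_eq, cfg))))
})

test_that("hybrid step is the exact midpoint", {
  expect_equal(hybrid_step(c(1, 2), c(1, 2)), c(1, 2))
  expect_equal(hybrid_step(c(0, 0), c(4, 4)), c(2, 2))
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(4)
    expect_identical(hybrid_step(a, b), 0.5 * a + 0.5 * b)
  }
  expect_error(hybrid_step(1:2, 1:3), "dimension")
})

test_that("feasibility keeps the old position instead of clipping", {
  b <- matrix(c(0, 0, 1, 1), 2)
  expect_true(clamp_feasible(c(0.5, 0.5), b)$feasible)
  expect_false(clamp_feasible(c(0.5, 1.5), b)$feasible)
  expect_true(clamp_feasible(c(0, 1), b)$feasible)  # closed bounds
})

test_that("memory updates only on strict improvement", {
  st <- list(positions = matrix(c(9, 1), 2, 1), memory = matrix(c(5, 1), 2, 1),
             fitness = c(0.4, 0.2), memory_fitness = c(0.5, 0.2))
  worse <- update_memory(st, 1, 0.3)
  expect_equal(worse$memory[1, ], 5)
  tie <- update_memory(st, 1, 0.5)
  expect_equal(tie$memory[1, ], 5)
  better <- update_memory(st, 1, 0.9)
  expect_equal(better$memory[1, ], 9)
  expect_equal(better$memory_fitness[1], 0.9)
})

test_that("the optimizer solves the 5-D sphere and is reproducible", {
  cfg <- hybrid_seek_config(population_size = 30, max_iterations = 200,
                            bounds = c(-5, 5), seed = 11)
  r1 <- hs_optimize(sphere, 5, cfg)
  r2 <- hs_optimize(sphere, 5, cfg)
  expect_identical(r1, r2)
  expect_gte(r1$best_fitness, -0.05)
  expect_true(all(abs(r1$best_position) <= 0.2))
  expect_false(is.unsorted(r1$history))
  expect_equal(r1$best_fitness, r1$history[length(r1$history)])
  expect_equal(r1$evaluations, 30 * (200 + 1))
})

test_that("the optimizer beats random search at an equal evaluation budget", {
  errs_opt <- errs_rand <- numeric(10)
  for (s in 1:10) {
    cfg <- hybrid_seek_config(population_size = 20, max_iterations = 50,
                              bounds = c(-5, 5), seed = s)
    r <- hs_optimize(sphere, 5, cfg)
    errs_opt[s] <- -r$best_fitness
    set.seed(1000 + s)
    cand <- matrix(runif(r$evaluations * 5, -5, 5), ncol = 5)
    errs_rand[s] <- -max(apply(cand, 1, sphere))
  }
  expect_lt(median(errs_opt), median(errs_rand))
})

test_that("non-finite fitness values are reported as errors", {
  cfg <- hybrid_seek_config(population_size = 5, max_iterations = 2,
                            bounds = c(0, 1), seed = 2)
  expect_error(hs_optimize(function(x) NA_real_, 2, cfg), "non-finite")
})
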