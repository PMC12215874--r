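test_that("environment schedule matches its closed forms and is monotone", {
  cfg <- optimizer_config()
  expect_equal(swarm_environment(0, 50, cfg)$temp, 1, tolerance = 1e-12)
  expect_equal(swarm_environment(50, 50, cfg)$q, 0.5, tolerance = 1e-12)
  # independently evaluated closed forms at the endpoints
  expect_equal(swarm_environment(0, 50, cfg)$q, 0.5 * exp(-1), tolerance = 1e-12)
  expect_equal(swarm_environment(50, 50, cfg)$temp, exp(-1), tolerance = 1e-12)

  env <- vapply(0:50, function(C) unlist(swarm_environment(C, 50, cfg)), c(q = 0, temp = 0))
  expect_true(all(diff(env["q", ]) > 0))
  expect_true(all(diff(env["temp", ]) < 0))
  expect_error(swarm_environment(1, 0, cfg), "invalid")
})

test_that("behaviour coefficient follows exp(-f_ref/f_self)", {
  cfg <- optimizer_config()
  expect_equal(behavior_coefficient(0, 5, cfg), 1)
  expect_equal(behavior_coefficient(3, 3, cfg), exp(-1), tolerance = 1e-12)
  expect_equal(behavior_coefficient(2, 1, cfg), exp(-2), tolerance = 1e-12)
  expect_error(behavior_coefficient(NaN, 1, cfg), "invalid fitness")
})

test_that("population initialization respects counts, box and elitist seeding", {
  b <- bounds_spec(1, 100, 3)
  st <- init_swarm(function(x) sum(x), b, optimizer_config(n_pop = 10, seed = 4))
  expect_equal(sum(st$roles == "male"), 5)
  expect_equal(sum(st$roles == "female"), 5)
  expect_true(all(st$positions >= 1 & st$positions <= 100))
  expect_equal(st$food_fitness, min(st$fitness))

  st11 <- init_swarm(function(x) sum(x), b, optimizer_config(n_pop = 11, seed = 4))
  expect_equal(sum(st11$roles == "male"), 5)
  expect_equal(sum(st11$roles == "female"), 6)

  stc <- init_swarm(function(x) 7, b, optimizer_config(n_pop = 10, seed = 4))
  expect_equal(stc$food_fitness, 7)
  expect_true(all(stc$fitness == 7))

  expect_error(init_swarm(function(x) NaN, b, optimizer_config(n_pop = 10, seed = 1)),
               "invalid objective")
})

test_that("movement kernels reproduce hand-evaluated steps", {
  # food-following: 50 + 2*0.8*0.5*(50-40) = 58
  expect_equal(snakeswarm:::so_food_step(food = 50, pos = 40, temp = 0.8,
                                         r = 0.5, sgn = 1, k3 = 2), 58)
  # exploration: 10 + 0.05*1*((100-1)*0.5 + 1) = 12.525
  expect_equal(snakeswarm:::so_explore_step(ref_pos = 10, ab = 1, r = 0.5, sgn = 1,
                                            lower = 1, upper = 100, k2 = 0.05),
               12.525)
  # replacement endpoints: r=0 -> lower, r=1 -> upper
  b <- bounds_spec(1, 100, 1)
  expect_equal(b$lower + 0 * (b$upper - b$lower), 1)
  expect_equal(b$lower + 1 * (b$upper - b$lower), 100)
  # PSO velocity: 0.5*1 + 0.8*1*(1-0) + 0.9*1*(2-0) = 3.1
  expect_equal(snakeswarm:::pso_velocity(v = 1, x = 0, p_best = 1, g_best = 2,
                                         w = 0.5, c1 = 0.8, c2 = 0.9,
                                         r1 = 1, r2 = 1), 3.1)
  # fixed point: x = p = g, v = 0
  expect_equal(snakeswarm:::pso_velocity(0, 3, 3, 3, 0.5, 0.8, 0.9, 1, 1), 0)
  # clamp at the box fraction: vmax = 0.1 * 99 = 9.9
  expect_equal(snakeswarm:::clamp_velocity(50, b, 0.1), 9.9)
  expect_equal(snakeswarm:::clamp_velocity(-50, b, 0.1), -9.9)
  # hybrid displacement: 2*0.5*1*2 = 2 added on top of the PSO term
  expect_equal(3.1 + 2 * 0.5 * 1 * 2, 5.1)
})

test_that("all three algorithms keep elitism, box feasibility and determinism", {
  b <- analytic_benchmark("sphere", dim = 4)
  for (alg in c("so", "pso", "psso")) {
    for (seed in c(2, 9)) {
      cfg <- quick_config(seed = seed)
      r <- optimize_swarm(b$objective, b$bounds, cfg, alg)
      expect_length(r$trace, cfg$n_iter)
      expect_true(all(diff(r$trace) <= 0), info = paste(alg, seed))
      expect_equal(r$best_fitness, r$trace[length(r$trace)])
      fs <- r$final_state
      expect_true(all(fs$positions >= -5 & fs$positions <= 5))
      r2 <- optimize_swarm(b$objective, b$bounds, quick_config(seed = seed), alg)
      expect_identical(r$trace, r2$trace)
      expect_identical(r$best_position, r2$best_position)
    }
  }
})

test_that("constant objectives yield flat traces at the constant", {
  b <- bounds_spec(-1, 1, 2)
  r <- optimize_swarm(function(x) 7, b, quick_config(seed = 1), "psso")
  expect_true(all(r$trace == 7))
  expect_equal(r$best_fitness, 7)
})

test_that("suppressing the snake displacement reduces PSSO to PSO exactly", {
  set.seed(42)
  for (k in 1:5) {
    d <- sample(2:5, 1)
    A <- matrix(stats::rnorm(d * d), d)
    obj <- local({
      A <- A
      function(x) sum((A %*% x)^2) + sum(x)
    })
    b <- bounds_spec(-3, 3, d)
    cfg <- optimizer_config(n_pop = 8, n_iter = 15, seed = 100 + k, delta_so = FALSE)
    r_psso <- optimize_swarm(obj, b, cfg, "psso")
    r_pso <- optimize_swarm(obj, b, cfg, "pso")
    expect_identical(r_psso$trace, r_pso$trace)
    expect_identical(r_psso$best_position, r_pso$best_position)
    expect_identical(r_psso$final_state$positions, r_pso$final_state$positions)
  }
})

test_that("small-scale optima match analytic minimizers across seeds", {
  q <- analytic_benchmark("quadratic1d")
  hits <- sum(vapply(1:20, function(s) {
    r <- optimize_swarm(q$objective, q$bounds,
                        optimizer_config(n_pop = 10, n_iter = 50, seed = s), "psso")
    abs(r$best_position - 3) <= 0.1
  }, TRUE))
  expect_gte(hits, 18)

  s2 <- analytic_benchmark("sphere", dim = 2)
  hits2 <- sum(vapply(1:20, function(s) {
    r <- optimize_swarm(s2$objective, s2$bounds,
                        optimizer_config(n_pop = 10, n_iter = 50, seed = s), "psso")
    sqrt(sum(r$best_position^2)) <= 0.1
  }, TRUE))
  expect_gte(hits2, 18)
})

test_that("config validation rejects out-of-range constants", {
  expect_error(optimizer_config(n_pop = 3), "at least 4")
  expect_error(optimizer_config(q_threshold = 1.2), "q_threshold")
  expect_error(optimizer_config(sign_prob = -0.1), "sign_prob")
  expect_error(bounds_spec(5, 5, 1), "strictly below")
  b <- analytic_benchmark("sphere", dim = 2)
  expect_error(optimize_swarm(b$objective, b$bounds, quick_config(), "genetic"),
               "arg")
})

test_that("convergence traces export to CSV and JSON", {
  b <- analytic_benchmark("quadratic1d")
  r <- optimize_swarm(b$objective, b$bounds, quick_config(seed = 1), "pso")
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_trace(r, csv, "csv")
  write_trace(r, js, "json")
  df <- read.csv(csv)
  expect_equal(names(df), c("iteration", "best_fitness"))
  expect_equal(df$best_fitness, r$trace)
  expect_equal(jsonlite::read_json(js, simplifyVector = TRUE)$best_fitness, r$trace)
})
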