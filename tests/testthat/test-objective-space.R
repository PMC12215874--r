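test_that("mask decoding thresholds at 0.5 and repairs empty masks", {
  space <- search_space(c("a", "b", "c"))
  enc <- decode(c(0.7, 0.2, 0.5), space)
  expect_equal(enc$feature_mask, c(1L, 0L, 1L))
  expect_equal(enc$n_selected, 2L)

  repaired <- decode(c(0.4, 0.1, 0.3), space)
  expect_equal(repaired$feature_mask, c(1L, 0L, 0L))

  expect_error(decode(c(0.5, 0.5), space), "invalid position")
})

test_that("hyperparameter dimensions map raw [1,100] to native scales", {
  space <- search_space(character(0), "svm")
  # log dims: raw endpoints hit the native endpoints
  enc_lo <- decode(c(1, 1), space)
  enc_hi <- decode(c(100, 100), space)
  expect_equal(enc_lo$hyperparams$cost, 1e-2, tolerance = 1e-12)
  expect_equal(enc_hi$hyperparams$cost, 1e3, tolerance = 1e-9)
  expect_equal(enc_lo$hyperparams$gamma, 1e-4, tolerance = 1e-12)
  expect_equal(enc_hi$hyperparams$gamma, 1e1, tolerance = 1e-9)

  rf_space <- search_space(character(0), "rf")
  expect_equal(decode(c(1, 100), rf_space)$hyperparams,
               list(num_trees = 1L, max_depth = 100L))
  # integer rounding: half-up at the midpoint
  mid <- decode(c(50.5, 50.5), rf_space)$hyperparams$num_trees
  expect_equal(mid, 51L)
})

test_that("selection fitness reproduces the error/parsimony trade-off", {
  expect_equal(selection_fitness(0.1, 5, 31, 0.9), 0.9 * 0.1 + 0.1 * 5 / 31,
               tolerance = 1e-12)
  expect_equal(selection_fitness(0.1, 5, 31, 0.9), 0.1061290, tolerance = 1e-6)
  expect_equal(selection_fitness(0, 0, 31, 0.9), 0)
  expect_equal(selection_fitness(1, 31, 31, 0.9), 1)
})

test_that("wrapper fitness is an audit-recomputable combination of its parts", {
  ds <- make_blobs(n_per_class = 25, d = 4, delta = 3, seed = 2)
  spec <- fitness_spec(alpha = 0.9, model = "dt", cv_folds = 5, seed = 3)
  enc <- decode(c(0.9, 0.9, 0.1, 0.1), search_space(names(ds$X)))
  res <- wrapper_fitness(ds, enc, spec)
  expect_equal(res$fitness,
               selection_fitness(res$error, res$n_selected, res$n_total, spec$alpha),
               tolerance = 1e-12)
  # deterministic given the seed
  res2 <- wrapper_fitness(ds, enc, spec)
  expect_identical(res, res2)
})

test_that("with a constant-error stub, fitness increases strictly in subset size", {
  ds <- make_blobs(n_per_class = 20, d = 6, seed = 5)
  stub <- function(X_train, y_train, X_test, hyper) rep("a", nrow(X_test))
  spec <- fitness_spec(alpha = 0.9, model = stub, cv_folds = 5, seed = 1)
  space <- search_space(names(ds$X))
  fits <- vapply(1:6, function(k) {
    raw <- rep(0, 6)
    raw[seq_len(k)] <- 1
    wrapper_fitness(ds, decode(raw, space), spec)$fitness
  }, 0)
  expect_true(all(diff(fits) > 0))
})

test_that("PSSO finds the exhaustive-enumeration optimum on a mask error table", {
  d <- 6L
  errors <- mask_error_table(d)
  alpha <- 0.99
  space <- search_space(paste0("f", 1:d))
  truth <- exhaustive_table_optimum(errors, d, alpha)
  obj <- table_fitness_objective(space, errors, alpha)
  hits <- sum(vapply(1:10, function(s) {
    r <- optimize_swarm(obj, attr(space, "bounds"),
                        optimizer_config(n_pop = 20, n_iter = 50, seed = s), "psso")
    isTRUE(all.equal(r$best_fitness, truth, tolerance = 1e-12))
  }, TRUE))
  expect_gte(hits, 9)
})

test_that("select_and_tune recovers the single informative feature of a toy", {
  toy <- make_separable_toy(d = 6, n = 150, seed = 3)
  spec <- fitness_spec(alpha = 0.99, model = "dt", cv_folds = 3, seed = 3)
  hits <- sum(vapply(1:5, function(s) {
    sel <- select_and_tune(toy$dataset, spec,
                           optimizer_config(n_pop = 10, n_iter = 15, seed = s),
                           "psso")
    1L %in% which(sel$feature_mask == 1L)
  }, TRUE))
  expect_gte(hits, 4)
})

test_that("selection results serialize to JSON with an audit-consistent fitness", {
  toy <- make_separable_toy(d = 5, n = 100, seed = 7)
  sel <- select_and_tune(toy$dataset,
                         fitness_spec(alpha = 0.9, model = "dt", cv_folds = 3, seed = 1),
                         optimizer_config(n_pop = 8, n_iter = 8, seed = 1), "psso")
  expect_equal(sel$fitness,
               selection_fitness(sel$cv_error, sel$n_selected, sel$n_total, sel$alpha),
               tolerance = 1e-12)
  parsed <- jsonlite::fromJSON(selection_to_json(sel))
  expect_equal(parsed$fitness, sel$fitness, tolerance = 1e-9)
  expect_equal(parsed$selected_features, sel$selected_features)
})

test_that("jaccard index behaves on sets and masks", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c(1, 0, 1, 0), c(1, 1, 0, 0)), 1 / 3)
  expect_equal(jaccard_index(character(0), character(0)), 1)
})
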