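test_that("rows with most cells missing are dropped, the rest imputed", {
  X <- data.frame(a = c(1, 3, NA, NA), b = c("x", "y", NA, "x"),
                  c = c(NA, 2, NA, 4), d = c(1, 1, NA, 0),
                  stringsAsFactors = FALSE)
  ds <- tabular_dataset(X, c("p", "p", "q", "q"))
  out <- clean_impute(ds)
  # row 3 has 4/4 missing -> dropped
  expect_equal(nrow(out$X), 3)
  # numeric gap <- column mean of [1,3] = 2
  expect_equal(out$X$a[3], 2)
  # categorical gap <- mode "x"
  expect_equal(out$X$b[1], "x")
  expect_false(anyNA(out$X))
})

test_that("clean_impute is idempotent and rejects all-missing columns", {
  ds <- make_blobs(n_per_class = 10, seed = 1)
  once <- clean_impute(ds)
  twice <- clean_impute(once)
  expect_equal(once$X, twice$X)
  expect_equal(once$y, twice$y)

  bad <- tabular_dataset(data.frame(a = c(NA_real_, NA_real_, NA_real_),
                                    b = c(1, 2, 3)),
                         c("p", "p", "q"))
  expect_error(clean_impute(bad), "unimputable")
})

test_that("duplicate rows are removed", {
  X <- data.frame(a = c(1, 1, 2), b = c(5, 5, 6))
  ds <- tabular_dataset(X, c("p", "p", "q"))
  expect_equal(nrow(clean_impute(ds)$X), 2)
})

test_that("standardization uses train statistics only", {
  tr <- tabular_dataset(data.frame(v = c(0, 2)), c("p", "q"))
  out <- transform_columns(tr)
  expect_equal(out$X$v, c(-1, 1))

  # applying to shifted test data must reuse the train fit (mean 1, sd 1)
  te <- tabular_dataset(data.frame(v = c(100, 200)), c("p", "q"))
  fit1 <- fit_column_transform(tr)
  te_out <- transform_columns(tr, te, fit = fit1)
  expect_equal(te_out$X$v, c(99, 199))
  # perturbing test values does not alter the fitted parameters
  te2 <- tabular_dataset(data.frame(v = c(-999, 999)), c("p", "q"))
  fit2 <- attr(transform_columns(tr, te2), "transform")
  expect_identical(fit1, fit2)
})

test_that("transformed training numerics have mean 0 and sd 1", {
  set.seed(3)
  tr <- tabular_dataset(data.frame(v = stats::rnorm(50, 10, 4)),
                        rep(c("p", "q"), 25))
  out <- transform_columns(tr)
  expect_equal(mean(out$X$v), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(out$X$v^2)), 1, tolerance = 1e-9)
})

test_that("one-hot encoding expands categories and zero-fills unseen ones", {
  tr <- tabular_dataset(data.frame(g = c("A", "B", "C"), stringsAsFactors = FALSE),
                        c("p", "q", "p"))
  out <- transform_columns(tr)
  expect_equal(names(out$X), c("g_A", "g_B", "g_C"))
  expect_equal(as.numeric(out$X[2, ]), c(0, 1, 0))

  te <- tabular_dataset(data.frame(g = "D", stringsAsFactors = FALSE), "p")
  te_out <- transform_columns(tr, te)
  expect_equal(as.numeric(te_out$X[1, ]), c(0, 0, 0))
})

test_that("zero-variance numeric columns are scaled by 1 and flagged", {
  tr <- tabular_dataset(data.frame(v = c(5, 5, 5, 5)), rep(c("p", "q"), 2))
  fit <- fit_column_transform(tr)
  expect_true(fit$fits[[1]]$zero_variance)
  expect_equal(transform_columns(tr, fit = fit)$X$v, rep(0, 4))
})

test_that("train/test split is stratified, sized and deterministic", {
  ds <- make_blobs(n_per_class = 50, seed = 9)
  sp <- split_train_test(ds, 0.8, seed = 2)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), 100)
  expect_equal(nrow(sp$train$X), 80)
  expect_equal(as.numeric(table(sp$test$y)), c(10, 10))

  sp2 <- split_train_test(ds, 0.8, seed = 2)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- split_train_test(ds, 0.8, seed = 3)
  expect_false(identical(sp$train_idx, sp3$train_idx))

  singleton <- tabular_dataset(data.frame(a = 1:3), c("p", "p", "q"))
  expect_error(split_train_test(singleton), "unsplittable")
})

test_that("CSV round trip preserves data and schema kinds", {
  sd <- generate_thyroid_like(generator_spec(n_samples = 40, n_features = 6,
                                             n_classes = 3,
                                             class_priors = c(0.5, 0.3, 0.2),
                                             informative_set = 1:2, seed = 5))
  csv <- tempfile(fileext = ".csv")
  yml <- tempfile(fileext = ".yaml")
  write_dataset_csv(sd$dataset, csv, yml)
  back <- read_dataset_csv(csv, yml)
  expect_equal(back$X, sd$dataset$X, tolerance = 1e-12)
  expect_equal(as.character(back$y), as.character(sd$dataset$y))
  expect_equal(vapply(back$schema, `[[`, "", "kind"),
               vapply(sd$dataset$schema, `[[`, "", "kind"))
})
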