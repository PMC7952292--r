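# Model-based construct validity: split, forest fit, error-distribution
# comparison.

toy5 <- toy_value_set("5L")

test_that("train/test split is disjoint, exhaustive and reproducible", {
  ds <- generate_population(generator_config(n = 100, seed = 2))
  idx <- index_column(ds, toy5)
  spec <- theoretical_model_spec(seed = 7)
  sp <- split_train_test(ds, idx, spec)
  cc <- which(!is.na(idx) & !is.na(ds$education) & !is.na(ds$economic_status) &
                !is.na(ds$diabetes))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), cc)
  expect_equal(length(sp$train), round(0.6 * length(cc)))
  expect_identical(split_train_test(ds, idx, spec), sp)
  expect_error(split_train_test(tiny_survey(3), rep(1, 3), spec), "at least 10")
})

test_that("a constant outcome is fit exactly and gives zero RMSE", {
  ds <- generate_population(generator_config(n = 60, seed = 4))
  cv <- construct_validity(ds, rep(0.9, 60), theoretical_model_spec(n_trees = 25))
  expect_equal(cv$rmse_int, 0)
  expect_equal(cv$rmse_val, 0)
  expect_equal(unique(cv$errors_val), 0)
})

test_that("a deterministic function of fully populated cells is learned to ~0 training error", {
  ds <- generate_population(generator_config(n = 400, seed = 6))
  y <- 0.95 - 0.1 * (ds$sex == "female") - 0.2 * ds$diabetes
  spec <- theoretical_model_spec(n_trees = 60, mtry = 5, min_node_size = 1,
                                 seed = 11)
  sp <- split_train_test(ds, y, spec)
  fit <- fit_theoretical_model(ds[sp$train, ], y[sp$train], spec)
  pred <- predict(fit, ds[sp$train, ])
  expect_lt(sqrt(mean((pred - y[sp$train])^2)), 1e-6)
})

test_that("the full procedure is a pure function of (data, spec seed)", {
  ds <- generate_population(generator_config(n = 250, seed = 14))
  spec <- theoretical_model_spec(n_trees = 40, seed = 9)
  cv1 <- construct_validity(ds, toy5, spec)
  cv2 <- construct_validity(ds, toy5, spec)
  expect_identical(cv1$rmse_int, cv2$rmse_int)
  expect_identical(cv1$errors_val, cv2$errors_val)
  expect_identical(cv1$coverage, cv2$coverage)
})

test_that("q95 follows the linear-interpolation empirical quantile on tiny vectors", {
  ds <- generate_population(generator_config(n = 40, seed = 16))
  cv <- construct_validity(ds, toy5, theoretical_model_spec(n_trees = 15, seed = 2))
  e <- sort(cv$errors_int)
  n <- length(e)
  h <- (n - 1) * 0.95 + 1                       # type-7 plotting position
  lo <- floor(h)
  q_oracle <- e[lo] + (h - lo) * (e[min(lo + 1, n)] - e[lo])
  expect_equal(cv$q95_int, q_oracle, tolerance = 1e-12)
  expect_equal(cv$coverage, 100 * mean(cv$errors_val <= q_oracle))
})

test_that("a held-out-only shift in the outcome collapses coverage", {
  ds <- generate_population(generator_config(n = 800, seed = 18))
  idx <- index_column(ds, toy5)
  spec <- theoretical_model_spec(n_trees = 100, seed = 5)
  sp <- split_train_test(ds, idx, spec)
  shifted <- idx
  shifted[sp$test] <- shifted[sp$test] + 0.3
  cv <- construct_validity(ds, shifted, spec)
  expect_lt(cv$coverage, 50)
})

test_that("shuffling the outcome leaves exchangeable errors (coverage near 95)", {
  ds <- generate_population(generator_config(n = 1500, seed = 19))
  idx <- index_column(ds, toy5)
  set.seed(31)
  shuffled <- idx[sample(length(idx))]
  cv <- construct_validity(ds, shuffled, theoretical_model_spec(n_trees = 100, seed = 8))
  expect_gt(cv$coverage, 85)
  # resubstitution optimism keeps the ratio a little above 1 even without signal
  ratio <- cv$rmse_val / cv$rmse_int
  expect_true(ratio >= 0.95 && ratio <= 1.4)
  expect_lt(abs(cv$rmse_val - sd(idx, na.rm = TRUE)) / sd(idx, na.rm = TRUE), 0.15)
})

test_that("out-of-bag internal errors are available behind the flag", {
  ds <- generate_population(generator_config(n = 300, seed = 22))
  cv <- construct_validity(ds, toy5, theoretical_model_spec(n_trees = 50, seed = 3),
                           internal = "oob")
  expect_gte(cv$rmse_int, 0)
  expect_identical(cv$internal, "oob")
  # OOB internal errors are no smaller than resubstitution ones on average
  cv_rs <- construct_validity(ds, toy5, theoretical_model_spec(n_trees = 50, seed = 3))
  expect_gte(mean(cv$errors_int), mean(cv_rs$errors_int))
})
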