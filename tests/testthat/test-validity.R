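# Known-groups ANOVA, age regressions, Spearman convergent validity.

test_that("ANOVA F matches the textbook between/within mean-square ratio", {
  df <- tiny_survey_df(9)
  df$id <- sprintf("a%02d", 1:9)
  df$sf1 <- rep(1:3, each = 3)
  set.seed(1)
  idx <- rep(c(1, 0.9, 0.8), each = 3) + rnorm(9, 0, 1e-3)
  kg <- known_groups(eq5d_survey(df), index5 = idx)
  # textbook oracle
  groups <- split(idx, df$sf1)
  k <- length(groups); n <- length(idx)
  gm <- mean(idx)
  ss_between <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  f_oracle <- (ss_between / (k - 1)) / (ss_within / (n - k))
  expect_equal(kg$instrument_5L$sf1$F, f_oracle, tolerance = 1e-10)
  expect_equal(kg$instrument_5L$sf1$p,
               pf(f_oracle, k - 1, n - k, lower.tail = FALSE), tolerance = 1e-10)
  expect_true(kg$instrument_5L$sf1$direction_ok)
})

test_that("identical group values give F = 0 and single-group factors are skipped", {
  df <- tiny_survey_df(6)
  df$id <- sprintf("b%02d", 1:6)
  df$diabetes <- rep(c(TRUE, FALSE), 3)
  kg <- known_groups(eq5d_survey(df), index5 = rep(0.9, 6))
  expect_equal(kg$instrument_5L$diabetes$F, 0)
  df$diabetes <- TRUE
  expect_warning(kg2 <- known_groups(eq5d_survey(df), index5 = rep(0.9, 6)),
                 "fewer than 2")
  expect_null(kg2$instrument_5L$diabetes)
})

test_that("an exact linear age trend is recovered to machine precision", {
  df <- tiny_survey_df(40)
  df$id <- sprintf("r%02d", 1:40)
  df$age <- as.integer(round(seq(20, 85, length.out = 40)))
  df$sex <- "male"
  idx <- 1.0674 - 0.0029 * df$age
  ar <- age_regression(eq5d_survey(df), idx, "male")
  expect_equal(ar$slope, -0.0029, tolerance = 1e-12)
  expect_equal(ar$intercept, 1.0674, tolerance = 1e-12)
  # constant outcome: slope exactly 0
  ar0 <- age_regression(eq5d_survey(df), rep(0.9, 40), "male")
  expect_equal(ar0$slope, 0, tolerance = 1e-12)
  # degenerate design
  df$age <- 50L
  expect_error(age_regression(eq5d_survey(df), idx, "male"), "degenerate")
})

test_that("Spearman cells behave on perfect monotone and tied fixtures", {
  df <- tiny_survey_df(5)
  df$id <- sprintf("s%02d", 1:5)
  df$mo5 <- 1:5
  df$eq_vas <- c(90L, 80L, 70L, 60L, 50L)
  cm <- suppressWarnings(convergent_matrix(eq5d_survey(df), index5 = seq(1, 0.6, by = -0.1)))
  expect_equal(cm$rho["mobility_5L", "eq_vas"], -1)
  expect_equal(cm$rho["index_5L", "eq_vas"], 1)
  # tied fixture against a brute-force rank evaluation
  x <- c(1L, 2L, 2L, 3L, 3L, 3L)
  y <- c(10L, 30L, 20L, 30L, 50L, 40L)
  df6 <- tiny_survey_df(6)
  df6$id <- sprintf("t%02d", 1:6)
  df6$mo5 <- x
  df6$eq_vas <- y
  cm6 <- suppressWarnings(convergent_matrix(eq5d_survey(df6), index5 = rep(c(0.9, 0.8), 3)))
  rho_oracle <- cor(rank(x), rank(y))   # average ranks, Pearson on ranks
  expect_equal(cm6$rho["mobility_5L", "eq_vas"], rho_oracle, tolerance = 1e-12)
})

test_that("Spearman is invariant under monotone transforms and flags constants", {
  ds <- generate_population(generator_config(n = 200, seed = 21))
  i5 <- index_column(ds, toy_value_set("5L"))
  cm <- convergent_matrix(ds, i5)
  cm2 <- convergent_matrix(ds, (i5 + 1)^3)  # strictly monotone transform
  expect_equal(cm2$rho["index_5L", ], cm$rho["index_5L", ], tolerance = 1e-12)
  # constant variable -> NA with warning
  df <- tiny_survey_df(8)
  df$id <- sprintf("u%02d", 1:8)
  df$mo5 <- 2L
  cmc <- suppressWarnings(convergent_matrix(eq5d_survey(df), rep(0.9, 8)))
  expect_true(is.na(cmc$rho["mobility_5L", "eq_vas"]))
  # pairwise-complete n is recorded per cell
  expect_equal(unname(cmc$n["mobility_5L", "eq_vas"]), 8)
})
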