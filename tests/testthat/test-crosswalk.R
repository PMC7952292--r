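# Janssen consistency classification, redistribution, ceiling effects.

test_that("classify_pair agrees with an independently coded lookup on all 15 pairs", {
  # independent encoding of the scheme as a logical matrix
  lookup <- matrix(FALSE, 3, 5)
  lookup[1, c(1, 2)] <- TRUE
  lookup[2, c(2, 3, 4)] <- TRUE
  lookup[3, c(4, 5)] <- TRUE
  for (l3 in 1:3) for (l5 in 1:5)
    expect_identical(classify_pair(l3, l5) == "consistent", lookup[l3, l5],
                     info = sprintf("pair (%d, %d)", l3, l5))
  expect_identical(sum(lookup), 7L)  # exactly 7 of 15 pairs are consistent
  expect_error(classify_pair(4, 1), "3L level")
  expect_error(classify_pair(1, 6), "5L level")
})

test_that("redistribution conditional percentages and inconsistency are correct on a hand-built table", {
  # one dimension carries the pain/discomfort 3L3 block (70 vs 10) plus two
  # inconsistent pairs; remaining dimensions are all (1,1)
  df <- tiny_survey_df(100)
  df$id <- sprintf("h%03d", 1:100)
  for (col in c("mo5", "sc5", "ua5", "ad5")) df[[col]] <- 1L
  for (col in c("mo3", "sc3", "ua3", "ad3")) df[[col]] <- 1L
  df$pd3 <- rep(3L, 100)
  df$pd5 <- c(rep(4L, 70), rep(5L, 10), rep(4L, 18), rep(1L, 2))
  df$pd3[81:98] <- 2L                 # consistent (2,4) pairs
  ds <- eq5d_survey(df)
  r <- redistribution(ds)
  pd <- r$dimensions$pain_discomfort
  expect_equal(pd$consistent_pct[3, 4], 87.5)
  expect_equal(pd$consistent_pct[3, 5], 12.5)
  expect_equal(pd$inconsistency_pct, 2)         # 2 of 100 pairs inconsistent
  expect_equal(r$mean_inconsistency_pct, 2 / 5) # other dimensions are clean
  expect_equal(unname(r$n_pairs), rep(100, 5))
})

test_that("per-3L-level consistent percentages sum to 100 and counts to n_pairs", {
  ds <- generate_population(generator_config(n = 600, seed = 5))
  r <- redistribution(ds)
  for (d in r$dimensions) {
    expect_equal(sum(d$counts), d$n_pairs)
    for (l3 in 1:3) {
      s <- sum(d$consistent_pct[l3, ], na.rm = TRUE)
      if (s > 0) expect_equal(s, 100, tolerance = 1e-9)
    }
  }
})

test_that("redistribution and ceiling statistics are permutation invariant", {
  ds <- generate_population(generator_config(n = 300, seed = 8))
  perm <- sample(nrow(ds))
  ds2 <- eq5d_survey(as.data.frame(ds)[perm, ])
  r1 <- redistribution(ds); r2 <- redistribution(ds2)
  expect_equal(r2$inconsistency_pct, r1$inconsistency_pct)
  expect_equal(lapply(r2$dimensions, `[[`, "counts"),
               lapply(r1$dimensions, `[[`, "counts"))
  expect_equal(ceiling_report(ds2)$table, ceiling_report(ds)$table)
})

test_that("a zero-inconsistency generator yields zero inconsistency everywhere", {
  ds <- generate_population(generator_config(n = 500, seed = 3,
                                             inconsistency_rate = 0))
  r <- redistribution(ds)
  expect_equal(unname(r$inconsistency_pct), rep(0, 5))
  expect_equal(r$mean_inconsistency_pct, 0)
})

test_that("ceiling report reproduces a hand-computed chi-square contrast", {
  # 466 of 1000 at the 3L best state, 380 of 1000 at the 5L best state
  df <- tiny_survey_df(1000)
  df$id <- sprintf("c%04d", 1:1000)
  for (col in c("sc5", "ua5", "pd5", "ad5")) df[[col]] <- 1L
  for (col in c("sc3", "ua3", "pd3", "ad3")) df[[col]] <- 1L
  df$mo5 <- rep(c(1L, 2L), c(380, 620))
  df$mo3 <- rep(c(1L, 2L), c(466, 534))
  cr <- ceiling_report(df <- eq5d_survey(df))
  expect_equal(cr$table["profile_11111", "change"], 46.6 - 38.0)
  # Pearson chi-square oracle without continuity correction
  a <- 466; b <- 534; c <- 380; d <- 620; n <- 2000
  chi2 <- n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  p_oracle <- pchisq(chi2, df = 1, lower.tail = FALSE)
  expect_equal(cr$table["profile_11111", "p_value"], p_oracle, tolerance = 1e-12)
  expect_lt(p_oracle, 0.01)
  # McNemar variant runs on the paired table
  expect_s3_class(ceiling_report(df, test = "mcnemar"), "eq5d_ceiling")
})

test_that("degenerate ceilings are handled: all-best data and a single record", {
  cr <- ceiling_report(best_state_survey(4))
  expect_equal(unname(cr$table$ceiling_3L), rep(100, 6))
  expect_equal(unname(cr$table$change), rep(0, 6))
  # one record at the 3L ceiling but not the 5L ceiling
  df <- tiny_survey_df(1)
  for (col in c("mo3", "sc3", "ua3", "pd3", "ad3")) df[[col]] <- 1L
  df$mo5 <- 2L; df$sc5 <- df$ua5 <- df$pd5 <- df$ad5 <- 1L
  cr1 <- ceiling_report(eq5d_survey(df))
  expect_equal(cr1$table["profile_11111", "change"], 100)
})
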