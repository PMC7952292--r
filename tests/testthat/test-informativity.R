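# Shannon informativity H', analytic variance, evenness, 3L->5L change.

# independent term-by-term evaluation of both formulas
shannon_oracle <- function(counts) {
  N <- sum(counts)
  p <- counts / N
  h_terms <- vapply(p, function(pi) if (pi > 0) pi * log2(pi) else 0, 0)
  v_terms <- vapply(p, function(pi) if (pi > 0) pi * log2(pi)^2 else 0, 0)
  list(H = -sum(h_terms), var_H = (sum(v_terms) - sum(h_terms)^2) / N)
}

test_that("uniform and degenerate distributions hit the analytic extremes", {
  s <- shannon(rep(137, 5))
  expect_equal(s$H, log2(5))
  expect_equal(s$J, 1)
  expect_equal(s$var_H, 0)           # all log2 p_i equal: variance bracket vanishes
  expect_equal(s$ci_low, s$ci_high)
  d <- shannon(c(1000, 0, 0))
  expect_equal(d$H, 0)
  expect_equal(d$J, 0)
  expect_error(shannon(c(0, 0, 0)), "no observations")
  expect_error(shannon(c(5)), "at least 2 levels")
})

test_that("H and var(H) match the formula oracle on fixed and random count vectors", {
  s <- shannon(c(500, 200, 150, 100, 50))
  o <- shannon_oracle(c(500, 200, 150, 100, 50))
  expect_equal(s$H, o$H, tolerance = 1e-12)
  expect_equal(s$var_H, o$var_H, tolerance = 1e-12)
  expect_equal(s$ci_low, s$H - qnorm(0.975) * sqrt(s$var_H), tolerance = 1e-12)
  set.seed(421)
  for (rep in 1:25) {
    L <- sample(c(3, 5), 1)
    counts <- rpois(L, lambda = sample(5:200, 1)) + (rep %% 2)  # allow zeros
    if (sum(counts) == 0) next
    s <- shannon(counts); o <- shannon_oracle(counts)
    expect_equal(s$H, o$H, tolerance = 1e-12)
    expect_equal(s$var_H, o$var_H, tolerance = 1e-12)
    expect_gte(s$J, 0); expect_lte(s$J, 1 + 1e-12)
    expect_equal(s$H, shannon(rev(counts))$H)  # permutation invariance
  }
})

test_that("var(H) shrinks like 1/N at fixed proportions", {
  p <- c(0.5, 0.2, 0.15, 0.1, 0.05)
  v <- vapply(c(1e2, 1e4, 1e6), function(N) shannon(p * N)$var_H, 0)
  expect_equal(v[1] / v[2], 1e2, tolerance = 1e-9)
  expect_equal(v[2] / v[3], 1e2, tolerance = 1e-9)
})

test_that("merging adjacent levels never increases H", {
  set.seed(77)
  for (rep in 1:40) {
    counts <- rpois(5, 40)
    if (sum(counts) == 0) next
    h5 <- shannon(counts)$H
    for (j in 1:4) {
      merged <- counts
      merged[j] <- merged[j] + merged[j + 1]
      merged <- merged[-(j + 1)]
      expect_lte(shannon(merged)$H, h5 + 1e-12)
    }
  }
})

test_that("the report equals per-dimension shannon() on manually tallied counts", {
  ds <- generate_population(generator_config(n = 400, seed = 12))
  rep_ <- informativity_report(ds)
  for (code in names(eq5d_dimensions)) {
    dm <- eq5d_dimensions[[code]]
    x5 <- ds[[paste0(code, "5")]]; x5 <- x5[!is.na(x5)]
    expect_equal(rep_$shannon_5L[[dm]]$H, shannon(tabulate(x5, 5))$H)
    x3 <- ds[[paste0(code, "3")]]; x3 <- x3[!is.na(x3)]
    expect_equal(rep_$shannon_3L[[dm]]$H, shannon(tabulate(x3, 3))$H)
    expect_equal(rep_$pct_change_J[[dm]],
                 100 * (rep_$shannon_5L[[dm]]$J - rep_$shannon_3L[[dm]]$J) /
                   rep_$shannon_3L[[dm]]$J)
  }
})

test_that("as-printed mode computes the change from 3-decimal-rounded evenness", {
  ds <- generate_population(generator_config(n = 400, seed = 12))
  full <- informativity_report(ds, mode = "full")
  printed <- informativity_report(ds, mode = "as_printed")
  for (dm in names(full$pct_change_J)) {
    j3 <- round(full$shannon_3L[[dm]]$J, 3)
    j5 <- round(full$shannon_5L[[dm]]$J, 3)
    expect_equal(printed$pct_change_J[[dm]], 100 * (j5 - j3) / j3)
  }
})

test_that("an all-level-1 instrument yields J = 0 and an undefined change", {
  ds <- best_state_survey(6)
  rep_ <- suppressWarnings(informativity_report(ds))
  expect_equal(unname(vapply(rep_$shannon_3L, `[[`, 0, "J")), rep(0, 5))
  expect_true(all(is.na(rep_$pct_change_J)))
  expect_warning(evenness_change(0, 0.5), "undefined")
})
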