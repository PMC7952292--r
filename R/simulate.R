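# Synthetic general-population generator. Emulates the structure of a Polish
# adult paired 3L/5L survey: Table-1-style demographics, an age-linear latent
# utility per sex, threshold-discretised 5L items, a probabilistic consistent
# 5L->3L collapse with a tunable inconsistency rate, EQ VAS and SF-1 links,
# and instrument-level MCAR missingness.

# Target marginal level distributions of the 5L items (level 1 = the
# published per-dimension ceilings; levels 2-5 fill the remainder in the
# proportions implied by the published redistribution counts). The default
# cutpoints below are the quantiles of the simulated noisy disability at
# these cumulative proportions (frozen one-off calibration; see the methods
# vignette).
eq5d_level_targets <- rbind(
  mobility           = c(0.737, 0.119, 0.074, 0.066, 0.004),
  self_care          = c(0.903, 0.048, 0.032, 0.014, 0.003),
  usual_activities   = c(0.821, 0.100, 0.049, 0.026, 0.004),
  pain_discomfort    = c(0.472, 0.288, 0.164, 0.073, 0.003),
  anxiety_depression = c(0.579, 0.291, 0.094, 0.033, 0.003)
)

#' Configuration of the synthetic-population generator
#'
#' Defaults emulate a Polish adult general-population survey: age-group,
#' education and household-income weights and the female and diabetes
#' proportions from the published sample table; per-sex age-linear latent
#' utility trends equal to the published regression equations; 5L cutpoints
#' calibrated so the per-dimension ceilings match the published values;
#' a 4.4\% 3L/5L inconsistency rate; and missing rates 0.4\%/0.9\%/0.1\%
#' (5L/3L/VAS).
#'
#' @param n number of respondents.
#' @param seed integer seed; generation is fully reproducible given the
#'   config.
#' @param age_group_weights six proportions over age groups 18-29 ... 70+.
#' @param female_prop,diabetes_prop marginal proportions.
#' @param education_weights,economic_weights category proportions (orders of
#'   \code{eqvalid:::education_levels} / \code{eqvalid:::economic_levels}).
#' @param latent_trend list with per-sex \code{c(intercept, slope)} of the
#'   latent 5L utility on age in years.
#' @param latent_sd sd of the person-level latent utility noise.
#' @param diabetes_effect additive latent-utility shift for diabetes.
#' @param latent_range admissible latent-utility range (clamped).
#' @param item_sd sd of the per-dimension noise added to the latent
#'   disability before thresholding.
#' @param dimension_cutpoints 5 x 4 matrix of strictly increasing disability
#'   thresholds per dimension; item level = 1 + number of cutpoints below
#'   the noisy disability.
#' @param inconsistency_rate probability that a 3L item is drawn uniformly
#'   from the levels \emph{inconsistent} with its 5L item instead of via the
#'   consistent collapse.
#' @param collapse_probs \code{c(p21, p42)}: probabilities that a consistent
#'   collapse maps 5L2 to 3L1 (rather than 3L2) and 5L4 to 3L2 (rather than
#'   3L3); 5L1/5L3/5L5 map deterministically to 3L1/3L2/3L3.
#' @param vas_link \code{c(scale, offset, sd)}: EQ VAS =
#'   \code{clip(round(offset + scale * u + noise), 0, 100)}.
#' @param sf1_cutpoints four increasing disability thresholds mapping the
#'   latent to SF-1 (1 = excellent ... 5 = poor), deterministically.
#' @param missing_rates \code{c(p5, p3, vas)}: instrument-level MCAR rates.
#' @return an \code{eq5d_generator_config}.
#' @export
generator_config <- function(
    n = 3978, seed = 1L,
    age_group_weights = c(0.192, 0.161, 0.154, 0.176, 0.191, 0.126),
    female_prop = 0.532, diabetes_prop = 0.068,
    education_weights = c(0.171, 0.249, 0.329, 0.030, 0.213, 0.008),
    economic_weights = c(0.100, 0.096, 0.138, 0.178, 0.216, 0.087, 0.185),
    latent_trend = list(male = c(intercept = 1.0674, slope = -0.0029),
                        female = c(intercept = 1.0903, slope = -0.0036)),
    latent_sd = 0.106, diabetes_effect = -0.07, latent_range = c(-0.6, 1.6),
    item_sd = 0.083,
    dimension_cutpoints = default_cutpoints,
    inconsistency_rate = 0.044,
    collapse_probs = c(p21 = 0.60, p42 = 0.35),
    vas_link = c(scale = 60, offset = 20, sd = 10),
    sf1_cutpoints = default_sf1_cutpoints,
    missing_rates = c(p5 = 0.004, p3 = 0.009, vas = 0.001)) {
  cfg <- list(n = as.integer(n), seed = as.integer(seed),
              age_group_weights = age_group_weights, female_prop = female_prop,
              diabetes_prop = diabetes_prop,
              education_weights = education_weights,
              economic_weights = economic_weights,
              latent_trend = latent_trend, latent_sd = latent_sd,
              diabetes_effect = diabetes_effect, latent_range = latent_range,
              item_sd = item_sd,
              dimension_cutpoints = as.matrix(dimension_cutpoints),
              inconsistency_rate = inconsistency_rate,
              collapse_probs = collapse_probs, vas_link = vas_link,
              sf1_cutpoints = sf1_cutpoints, missing_rates = missing_rates)
  validate_generator_config(cfg)
  class(cfg) <- "eq5d_generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  chk_prop_vec <- function(x, len, what) {
    if (length(x) != len) stop(what, " must have length ", len)
    if (any(x < 0)) stop(what, " must be non-negative")
    if (abs(sum(x) - 1) > 1e-9) stop(what, " must sum to 1 (got ", sum(x), ")")
  }
  if (cfg$n < 0) stop("n must be non-negative")
  chk_prop_vec(cfg$age_group_weights, 6, "age_group_weights")
  chk_prop_vec(cfg$education_weights, length(education_levels), "education_weights")
  chk_prop_vec(cfg$economic_weights, length(economic_levels), "economic_weights")
  for (p in c(cfg$female_prop, cfg$diabetes_prop, cfg$inconsistency_rate,
              cfg$collapse_probs, cfg$missing_rates))
    if (is.na(p) || p < 0 || p > 1) stop("proportions must lie in [0, 1]")
  if (!identical(dim(cfg$dimension_cutpoints), c(5L, 4L)))
    stop("dimension_cutpoints must be a 5 x 4 matrix")
  if (any(apply(cfg$dimension_cutpoints, 1, diff) <= 0))
    stop("dimension cutpoints must be strictly increasing")
  if (any(diff(cfg$sf1_cutpoints) <= 0) || length(cfg$sf1_cutpoints) != 4)
    stop("sf1_cutpoints must be 4 strictly increasing values")
  if (cfg$latent_sd < 0 || cfg$item_sd < 0 || cfg$vas_link["sd"] < 0)
    stop("noise scales must be non-negative")
  if (diff(cfg$latent_range) <= 0) stop("latent_range must be increasing")
  for (s in c("male", "female"))
    stopifnot(is.numeric(cfg$latent_trend[[s]]), length(cfg$latent_trend[[s]]) == 2)
  invisible(cfg)
}

#' @export
print.eq5d_generator_config <- function(x, ...) {
  cat(sprintf("Synthetic-population config: n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  female %.1f%%, diabetes %.1f%%, inconsistency rate %.1f%%\n",
              100 * x$female_prop, 100 * x$diabetes_prop,
              100 * x$inconsistency_rate))
  invisible(x)
}

# --- internal sampling stages (also used by the calibration script) ---------

draw_demographics <- function(cfg, n) {
  gi <- sample.int(6L, n, replace = TRUE, prob = cfg$age_group_weights)
  age <- age_group_lo[gi] +
    floor(stats::runif(n) * (age_group_hi[gi] - age_group_lo[gi] + 1L))
  data.frame(
    age = as.integer(age),
    sex = factor(ifelse(stats::runif(n) < cfg$female_prop, "female", "male"),
                 sex_levels),
    education = factor(sample(education_levels, n, replace = TRUE,
                              prob = cfg$education_weights), education_levels),
    economic_status = factor(sample(economic_levels, n, replace = TRUE,
                                    prob = cfg$economic_weights), economic_levels),
    diabetes = stats::runif(n) < cfg$diabetes_prop,
    stringsAsFactors = FALSE)
}

draw_latent <- function(cfg, demo) {
  n <- nrow(demo)
  tr <- cfg$latent_trend
  intercept <- ifelse(demo$sex == "female", tr$female[1], tr$male[1])
  slope <- ifelse(demo$sex == "female", tr$female[2], tr$male[2])
  u <- intercept + slope * demo$age + cfg$diabetes_effect * demo$diabetes +
    stats::rnorm(n, 0, cfg$latent_sd)
  pmin(pmax(u, cfg$latent_range[1]), cfg$latent_range[2])
}

# levels inconsistent with each 5L level under the Janssen scheme
inconsistent_3L <- list(c(2L, 3L), 3L, c(1L, 3L), 1L, c(1L, 2L))

collapse_3L <- function(lv5, cfg) {
  n <- length(lv5)
  lv3 <- c(1L, NA, 2L, NA, 3L)[lv5]
  i2 <- which(lv5 == 2L)
  lv3[i2] <- ifelse(stats::runif(length(i2)) < cfg$collapse_probs["p21"], 1L, 2L)
  i4 <- which(lv5 == 4L)
  lv3[i4] <- ifelse(stats::runif(length(i4)) < cfg$collapse_probs["p42"], 2L, 3L)
  # inconsistent responses: uniform over the levels outside the scheme
  flip <- stats::runif(n) < cfg$inconsistency_rate
  if (any(flip)) {
    pick <- stats::runif(sum(flip))
    lv3[flip] <- vapply(seq_len(sum(flip)), function(k) {
      cand <- inconsistent_3L[[lv5[which(flip)[k]]]]
      cand[1L + (pick[k] >= 0.5 & length(cand) > 1)]
    }, 0L)
  }
  lv3
}

#' Generate a synthetic paired survey
#'
#' Per record: (1) draw age group, integer age within it (70+ capped at 87),
#' sex, education, economic status and diabetes; (2) latent utility
#' \eqn{u = a_{sex} + b_{sex} \cdot age + \delta \cdot diabetes + N(0,
#' \sigma_L)}, clamped to the admissible range; (3) each 5L item = 1 + number
#' of dimension cutpoints below a noisy copy of the disability \eqn{1 - u};
#' (4) each 3L item via the consistent collapse with probability
#' \eqn{1 - \epsilon}, else a uniform draw from the inconsistent levels;
#' (5) EQ VAS and (6) SF-1 from \eqn{u}; (7) instrument-level MCAR
#' missingness. Identical configs give byte-identical datasets.
#'
#' @param config an \code{\link{generator_config}}.
#' @return an \code{\link{eq5d_survey}} with the generating parameters
#'   recorded in its metadata (see \code{\link{truth_record}}).
#' @export
generate_population <- function(config = generator_config()) {
  validate_generator_config(config)
  n <- config$n
  md <- list(source = "eqvalid synthetic generator", truth = truth_record(config))
  if (n == 0) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(survey_columns)))
    names(empty) <- survey_columns
    return(eq5d_survey(empty, metadata = md))
  }
  with_seed(config$seed, {
    demo <- draw_demographics(config, n)
    u <- draw_latent(config, demo)
    d <- 1 - u
    lv5 <- matrix(0L, n, 5)
    for (j in 1:5) {
      dj <- d + stats::rnorm(n, 0, config$item_sd)
      lv5[, j] <- 1L + as.integer(rowSums(outer(dj, config$dimension_cutpoints[j, ], ">")))
    }
    lv3 <- matrix(0L, n, 5)
    for (j in 1:5) lv3[, j] <- collapse_3L(lv5[, j], config)
    vas <- as.integer(pmin(pmax(round(config$vas_link["offset"] +
                                        config$vas_link["scale"] * u +
                                        stats::rnorm(n, 0, config$vas_link["sd"])),
                                0), 100))
    sf1 <- 1L + as.integer(rowSums(outer(d, config$sf1_cutpoints, ">")))
    miss5 <- stats::runif(n) < config$missing_rates[1]
    miss3 <- stats::runif(n) < config$missing_rates[2]
    missv <- stats::runif(n) < config$missing_rates[3]
    lv5[miss5, ] <- NA
    lv3[miss3, ] <- NA
    vas[missv] <- NA
    df <- data.frame(id = sprintf("R%05d", seq_len(n)), demo,
                     stringsAsFactors = FALSE)
    colnames(lv5) <- paste0(names(eq5d_dimensions), "5")
    colnames(lv3) <- paste0(names(eq5d_dimensions), "3")
    df <- cbind(df, lv5, lv3)
    df$eq_vas <- vas
    df$sf1 <- sf1
    eq5d_survey(df, metadata = md)
  })
}

#' Machine-readable record of the generating parameters
#'
#' Flattens a generator config into a plain named list (embedded in the
#' metadata of every generated dataset) so that parameter-recovery tests can
#' compare estimates against the generating truth.
#'
#' @param config an \code{\link{generator_config}}.
#' @return a named list of every generating parameter.
#' @export
truth_record <- function(config) {
  out <- unclass(config)
  out$dimension_cutpoints <- config$dimension_cutpoints
  out
}
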