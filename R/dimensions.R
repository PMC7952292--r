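# Shared constants: dimension and category codings used across all modules.

#' EQ-5D dimension short codes and labels
#'
#' The five EQ-5D dimensions in their canonical instrument order. Column names
#' in survey files are \code{<code><version>}, e.g. \code{mo5}, \code{pd3}.
#'
#' @format \code{eq5d_dimensions} is a named character vector mapping the
#'   two-letter code to the full dimension label.
#' @export
eq5d_dimensions <- c(
  mo = "mobility",
  sc = "self_care",
  ua = "usual_activities",
  pd = "pain_discomfort",
  ad = "anxiety_depression"
)

dim_cols <- function(version) paste0(names(eq5d_dimensions), if (version == "5L") "5" else "3")

max_level <- function(version) if (version == "5L") 5L else 3L

# Category codings (fixed schema, documented in README)
sex_levels <- c("female", "male")
education_levels <- c("primary", "vocational", "secondary", "post_secondary",
                      "higher", "other")
economic_levels <- c("up_to_120", "121_180", "181_240", "241_360", "over_360",
                     "hard_to_say", "no_response")
age_group_levels <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70+")

age_group_lo <- c(18L, 30L, 40L, 50L, 60L, 70L)
age_group_hi <- c(29L, 39L, 49L, 59L, 69L, 87L)  # upper bucket capped at the
                                                 # oldest age the generator emits

#' Derive the age group of an age in years
#'
#' Buckets: 18-29, 30-39, 40-49, 50-59, 60-69, 70+. Total on ages >= 18.
#'
#' @param age integer vector of ages in years (>= 18).
#' @return factor with levels \code{"18-29"} ... \code{"70+"}.
#' @export
#' @examples
#' age_group(c(18, 29, 30, 69, 70, 87))
age_group <- function(age) {
  if (any(!is.na(age) & age < 18)) stop("age must be >= 18")
  cut(age, breaks = c(18, 30, 40, 50, 60, 70, Inf), labels = age_group_levels,
      right = FALSE)
}

# restore the caller's RNG state after running `code` under seed `seed`
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

fmt_num <- function(x, digits) formatC(x, format = "f", digits = digits)
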