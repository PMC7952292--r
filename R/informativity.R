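# Shannon informativity H', analytic variance, evenness J', 3L->5L change.

#' Shannon informativity of a response-level distribution
#'
#' For level proportions \eqn{p_i = n_i/N} over \eqn{L} levels,
#' \deqn{H' = -\sum_i p_i \log_2 p_i, \qquad
#'       \mathrm{var}\,H' = \frac{\sum_i p_i (\log_2 p_i)^2 -
#'         (\sum_i p_i \log_2 p_i)^2}{N},}
#' with \eqn{0 \log_2 0 \equiv 0} by continuity. The 95\% confidence interval
#' is the normal approximation \eqn{H' \pm 1.96 \sqrt{\mathrm{var}\,H'}}.
#' Evenness is \eqn{J' = H'/\log_2 L}, in [0, 1]; \eqn{H'} is maximal
#' (\eqn{\log_2 L}) for a uniform distribution and 0 for a degenerate one.
#'
#' @param counts non-negative integer vector of observations per level;
#'   its length is the level count \eqn{L} (3 or 5 for EQ-5D items).
#' @param conf_level confidence level of the interval.
#' @return an object of class \code{shannon}: list with \code{H},
#'   \code{var_H}, \code{ci_low}, \code{ci_high} (bits), \code{H_max}
#'   (\eqn{\log_2 L}), \code{J}, \code{L}, \code{N} and the proportions
#'   \code{p}.
#' @export
#' @examples
#' shannon(c(200, 200, 200, 200, 200))  # uniform: H = log2(5), J = 1, var 0
#' shannon(c(100, 0, 0))                # degenerate: H = 0, J = 0
shannon <- function(counts, conf_level = 0.95) {
  counts <- as.numeric(counts)
  L <- length(counts)
  if (L < 2) stop("need at least 2 levels")
  if (any(is.na(counts) | counts < 0)) stop("counts must be non-negative")
  N <- sum(counts)
  if (N < 1) stop("no observations")
  p <- counts / N
  lp <- ifelse(p > 0, log2(p), 0)     # 0 * log2(0) := 0
  H <- -sum(p * lp)
  var_H <- (sum(p * lp^2) - sum(p * lp)^2) / N
  var_H <- max(var_H, 0)              # guard tiny negative round-off
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  H_max <- log2(L)
  out <- list(H = H, var_H = var_H,
              ci_low = H - z * sqrt(var_H), ci_high = H + z * sqrt(var_H),
              H_max = H_max, J = H / H_max, L = L, N = N, p = p)
  class(out) <- "shannon"
  out
}

#' @export
print.shannon <- function(x, digits = 3, ...) {
  cat(sprintf("Shannon H' = %s bits (95%% CI %s-%s), J' = %s (L = %d, N = %d)\n",
              fmt_num(x$H, digits), fmt_num(x$ci_low, digits),
              fmt_num(x$ci_high, digits), fmt_num(x$J, digits), x$L,
              as.integer(x$N)))
  invisible(x)
}

#' Relative informativity change between two evenness values
#'
#' Percentage change in Shannon evenness from the 3L to the 5L instrument,
#' \eqn{100 (J'_{5L} - J'_{3L}) / J'_{3L}}; undefined when \eqn{J'_{3L} = 0}.
#'
#' @param j3,j5 evenness values of the 3L and 5L item.
#' @return percentage change, or \code{NA} (with a warning) when undefined.
#' @export
evenness_change <- function(j3, j5) {
  if (is.na(j3) || j3 == 0) {
    warning("evenness change undefined: 3L evenness is zero")
    return(NA_real_)
  }
  100 * (j5 - j3) / j3
}

#' Informativity report for a paired survey
#'
#' Computes \code{\link{shannon}} per dimension and instrument from the
#' non-missing response counts, and the percentage change in evenness from 3L
#' to 5L per dimension.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param mode \code{"full"} (default): the change is computed from
#'   full-precision evenness values; \code{"as_printed"}: from evenness
#'   rounded to 3 decimals first, reproducing arithmetic done on tabulated
#'   values.
#' @return an \code{eq5d_informativity} object: lists \code{shannon_3L} and
#'   \code{shannon_5L} of per-dimension \code{\link{shannon}} results, and
#'   the vector \code{pct_change_J}.
#' @export
informativity_report <- function(dataset, mode = c("full", "as_printed")) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  mode <- match.arg(mode)
  per_instr <- function(version) {
    L <- max_level(version)
    res <- lapply(names(eq5d_dimensions), function(code) {
      x <- dataset[[paste0(code, if (version == "5L") "5" else "3")]]
      x <- x[!is.na(x)]
      if (!length(x)) stop("dimension ", eq5d_dimensions[code],
                           " has no non-missing ", version, " responses")
      shannon(tabulate(x, nbins = L))
    })
    names(res) <- unname(eq5d_dimensions)
    res
  }
  s3 <- per_instr("3L"); s5 <- per_instr("5L")
  j3 <- vapply(s3, `[[`, 0, "J"); j5 <- vapply(s5, `[[`, 0, "J")
  if (mode == "as_printed") { j3 <- round(j3, 3); j5 <- round(j5, 3) }
  chg <- vapply(seq_along(j3), function(i) {
    if (j3[i] == 0) { warning("evenness change undefined for ", names(j3)[i]); NA_real_ }
    else 100 * (j5[i] - j3[i]) / j3[i]
  }, 0)
  names(chg) <- names(j3)
  out <- list(shannon_3L = s3, shannon_5L = s5, pct_change_J = chg, mode = mode)
  class(out) <- "eq5d_informativity"
  out
}

#' @export
print.eq5d_informativity <- function(x, digits = 3, ...) {
  cat("Informativity (Shannon H' and evenness J')\n")
  tab <- data.frame(
    `H'3L` = fmt_num(vapply(x$shannon_3L, `[[`, 0, "H"), digits),
    `H'5L` = fmt_num(vapply(x$shannon_5L, `[[`, 0, "H"), digits),
    `J'3L` = fmt_num(vapply(x$shannon_3L, `[[`, 0, "J"), digits),
    `J'5L` = fmt_num(vapply(x$shannon_5L, `[[`, 0, "J"), digits),
    `% change J'` = fmt_num(x$pct_change_J, 1),
    check.names = FALSE, row.names = names(x$shannon_3L))
  print(tab)
  invisible(x)
}
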