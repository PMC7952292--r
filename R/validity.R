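# Known-groups validity (one-way ANOVA), age regressions by sex,
# convergent validity (Spearman matrix).

known_group_factors <- c("age_group", "sex", "diabetes", "sf1")

#' Known-groups validity of index values
#'
#' One-way ANOVA of the index value on each known-group factor (age group,
#' sex, diabetes, SF-1 self-rated health), per instrument, with listwise
#' deletion on the (factor, index) pair. The a-priori hypotheses are that
#' older, female, diabetic and worse self-rated-health groups have lower mean
#' index values; each is reported as a pass/fail direction flag computed from
#' the observed group means (oldest vs youngest, female vs male, diabetic vs
#' not, poor vs excellent), not as a one-sided test.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param index5,index3 numeric index-value vectors aligned to the records
#'   (e.g. from \code{\link{index_column}}); either may be \code{NULL} to
#'   skip that instrument.
#' @return an \code{eq5d_known_groups} object: per instrument and factor,
#'   group \code{means}, \code{n}, ANOVA \code{F} and \code{p}, and
#'   \code{direction_ok}.
#' @export
known_groups <- function(dataset, index5, index3 = NULL) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  analyse <- function(index) {
    res <- list()
    for (fac in known_group_factors) {
      g <- dataset[[fac]]
      if (fac == "diabetes") g <- factor(ifelse(g, "yes", "no"), c("no", "yes"))
      if (fac == "sf1") g <- factor(g, 1:5,
                                    c("excellent", "very_good", "good", "fair", "poor"))
      ok <- !is.na(g) & !is.na(index)
      g2 <- droplevels(g[ok]); y <- index[ok]
      if (nlevels(g2) < 2) {
        warning("factor ", fac, " has fewer than 2 non-empty groups; skipped")
        next
      }
      fit <- stats::lm(y ~ g2)
      av <- withCallingHandlers(stats::anova(fit), warning = function(w) {
        # perfect within-group fits are legitimate here (F reported as-is or 0)
        if (grepl("essentially perfect fit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
      f_stat <- av$`F value`[1]; p_val <- av$`Pr(>F)`[1]
      if (stats::var(y) == 0) { f_stat <- 0; p_val <- 1 }  # degenerate: no variation at all
      means <- tapply(y, g2, mean)
      # hypothesised direction: the "worse" extreme group scores lower
      dir_ok <- switch(fac,
        age_group = unname(means[length(means)] < means[1]),
        sex       = if (all(c("female", "male") %in% names(means)))
                      unname(means["female"] < means["male"]) else NA,
        diabetes  = if (all(c("yes", "no") %in% names(means)))
                      unname(means["yes"] < means["no"]) else NA,
        sf1       = unname(means[length(means)] < means[1]))
      res[[fac]] <- list(means = means, n = table(g2),
                         F = f_stat, p = p_val,
                         direction_ok = dir_ok)
    }
    res
  }
  out <- list(instrument_5L = if (!is.null(index5)) analyse(index5),
              instrument_3L = if (!is.null(index3)) analyse(index3))
  class(out) <- "eq5d_known_groups"
  out
}

#' @export
print.eq5d_known_groups <- function(x, digits = 3, ...) {
  for (instr in names(x)) {
    if (is.null(x[[instr]])) next
    cat(sprintf("Known-groups validity, %s\n", sub("instrument_", "EQ-5D-", instr)))
    for (fac in names(x[[instr]])) {
      r <- x[[instr]][[fac]]
      cat(sprintf("  %s: F = %s, p = %s, direction %s\n", fac,
                  fmt_num(r$F, 2), format.pval(r$p, digits = 3),
                  if (isTRUE(r$direction_ok)) "as hypothesised" else "NOT as hypothesised"))
      cat("    means:", paste(sprintf("%s %s", names(r$means),
                                      fmt_num(r$means, digits)), collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Linear regression of index value on age, per sex
#'
#' Ordinary least squares of the index value on age in years, restricted to
#' one sex, with listwise deletion. A negative slope quantifies the expected
#' decline of health utility with age.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param index numeric index vector aligned to records.
#' @param sex \code{"male"} or \code{"female"}.
#' @return an \code{eq5d_age_regression} object: \code{slope},
#'   \code{intercept}, \code{se_slope}, \code{se_intercept},
#'   \code{conf_int} (95\% CI of the slope), \code{n}, \code{sex} and the
#'   underlying \code{lm} fit.
#' @export
age_regression <- function(dataset, index, sex = c("male", "female")) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  sex <- match.arg(sex)
  ok <- !is.na(index) & !is.na(dataset$sex) & dataset$sex == sex
  age <- dataset$age[ok]; y <- index[ok]
  if (length(y) < 3) stop("need at least 3 complete (age, index) pairs for sex ", sex)
  if (length(unique(age)) < 2) stop("degenerate design: all ages equal")
  fit <- stats::lm(y ~ age)
  quiet_perfect_fit <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      # exact linear data are legitimate input (noise-free recovery checks)
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- quiet_perfect_fit(summary(fit)$coefficients)
  ci <- quiet_perfect_fit(unname(stats::confint(fit)["age", ]))
  out <- list(slope = unname(cf["age", "Estimate"]),
              intercept = unname(cf["(Intercept)", "Estimate"]),
              se_slope = unname(cf["age", "Std. Error"]),
              se_intercept = unname(cf["(Intercept)", "Std. Error"]),
              conf_int = ci,
              n = length(y), sex = sex, fit = fit)
  class(out) <- "eq5d_age_regression"
  out
}

#' @export
print.eq5d_age_regression <- function(x, ...) {
  cat(sprintf("index = %s * age + %s  (%s, n = %d; slope 95%% CI %s to %s)\n",
              fmt_num(x$slope, 4), fmt_num(x$intercept, 4), x$sex, x$n,
              fmt_num(x$conf_int[1], 4), fmt_num(x$conf_int[2], 4)))
  invisible(x)
}

#' Convergent validity: Spearman correlation matrix
#'
#' Spearman rank correlations (average ranks for ties) of each EQ-5D-5L
#' dimension and of the 5L index against EQ VAS, each EQ-5D-3L dimension and
#' SF-1, with pairwise-complete deletion per cell. Note the sign
#' orientation: dimension levels code \emph{problems} (higher = worse) while
#' the index and EQ VAS code \emph{health} (higher = better), so
#' dimension-vs-VAS correlations are expected negative and index-vs-VAS
#' positive.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param index5 numeric 5L index vector aligned to records.
#' @return an \code{eq5d_convergent} object: matrices \code{rho}, \code{p}
#'   and \code{n} with rows the 5L variables and columns the comparators.
#' @export
convergent_matrix <- function(dataset, index5) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  rows <- c(stats::setNames(paste0(names(eq5d_dimensions), "5"),
                            paste0(unname(eq5d_dimensions), "_5L")),
            index_5L = "index")
  cols <- c(eq_vas = "eq_vas",
            stats::setNames(paste0(names(eq5d_dimensions), "3"),
                            paste0(unname(eq5d_dimensions), "_3L")),
            sf1 = "sf1")
  get_var <- function(key) if (key == "index") index5 else dataset[[key]]
  rho <- p <- nmat <- matrix(NA_real_, length(rows), length(cols),
                             dimnames = list(names(rows), names(cols)))
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    x <- get_var(rows[i]); y <- get_var(cols[j])
    ok <- !is.na(x) & !is.na(y)
    nmat[i, j] <- sum(ok)
    if (sum(ok) < 3) { warning("cell ", names(rows)[i], " vs ", names(cols)[j],
                               " has fewer than 3 complete pairs"); next }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("constant variable in cell ", names(rows)[i], " vs ", names(cols)[j],
              "; correlation undefined")
      next
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  out <- list(rho = rho, p = p, n = nmat)
  class(out) <- "eq5d_convergent"
  out
}

#' @export
print.eq5d_convergent <- function(x, digits = 2, ...) {
  cat("Convergent validity (Spearman rho; rows 5L, columns comparators)\n")
  print(round(x$rho, digits))
  invisible(x)
}
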