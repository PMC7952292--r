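# Redistribution tables, Janssen inconsistency, ceiling-effect comparison.

# consistent 5L levels for each 3L level (Janssen scheme):
# 3L1 -> {5L1, 5L2}; 3L2 -> {5L2, 5L3, 5L4}; 3L3 -> {5L4, 5L5}
janssen_scheme <- list(`1` = c(1L, 2L), `2` = c(2L, 3L, 4L), `3` = c(4L, 5L))

#' Classify a paired 3L/5L response as consistent or inconsistent
#'
#' A pair is consistent under the Janssen scheme iff the 5L level lies in the
#' admissible set for its 3L level: 3L1 -> \{5L1, 5L2\}, 3L2 -> \{5L2, 5L3,
#' 5L4\}, 3L3 -> \{5L4, 5L5\}. Exactly 7 of the 15 possible pairs are
#' consistent. Vectorised.
#'
#' @param level3 integer 3L level(s), 1-3.
#' @param level5 integer 5L level(s), 1-5.
#' @return character vector, \code{"consistent"} or \code{"inconsistent"}.
#' @export
#' @examples
#' classify_pair(1, 2)  # consistent
#' classify_pair(1, 3)  # inconsistent
classify_pair <- function(level3, level5) {
  level3 <- as.integer(level3); level5 <- as.integer(level5)
  if (anyNA(level3) || anyNA(level5)) stop("levels must be non-missing")
  if (any(level3 < 1 | level3 > 3)) stop("3L level outside 1..3")
  if (any(level5 < 1 | level5 > 5)) stop("5L level outside 1..5")
  ok <- mapply(function(l3, l5) l5 %in% janssen_scheme[[l3]], level3, level5)
  ifelse(ok, "consistent", "inconsistent")
}

consistency_mask <- function() {
  m <- matrix(FALSE, 3, 5, dimnames = list(1:3, 1:5))
  for (l3 in 1:3) m[l3, janssen_scheme[[l3]]] <- TRUE
  m
}

#' Redistribution report from per-dimension 3L x 5L count matrices
#'
#' Core computation behind \code{\link{redistribution}}, exposed so that
#' published cross-tabulations can be analysed directly. For each 3L level the
#' conditional percentages are computed among the \emph{consistent} pairs at
#' that level (so each 3L-level block sums to 100); inconsistent pairs are
#' summarised separately as the per-dimension inconsistency percentage, and
#' the mean inconsistency is the unweighted arithmetic mean over the five
#' dimensions.
#'
#' @param counts named list of five 3 x 5 matrices (rows = 3L levels,
#'   columns = 5L levels), one per dimension in instrument order.
#' @return an \code{eq5d_redistribution} object; see
#'   \code{\link{redistribution}}.
#' @export
redistribution_from_counts <- function(counts) {
  if (!is.list(counts) || length(counts) != 5)
    stop("counts must be a list of five 3x5 matrices")
  if (is.null(names(counts))) names(counts) <- unname(eq5d_dimensions)
  mask <- consistency_mask()
  per_dim <- lapply(names(counts), function(dm) {
    m <- as.matrix(counts[[dm]])
    if (!identical(dim(m), c(3L, 5L))) stop("counts for ", dm, " are not 3x5")
    dimnames(m) <- list(1:3, 1:5)
    n_pairs <- sum(m)
    if (n_pairs == 0) stop("dimension ", dm, " has zero complete pairs")
    cons_pct <- matrix(NA_real_, 3, 5, dimnames = dimnames(m))
    for (l3 in 1:3) {
      cons <- janssen_scheme[[l3]]
      tot <- sum(m[l3, cons])
      if (tot > 0) cons_pct[l3, cons] <- 100 * m[l3, cons] / tot
    }
    inc <- 100 * sum(m[!mask]) / n_pairs
    list(counts = m, consistent_pct = cons_pct, inconsistency_pct = inc,
         n_pairs = n_pairs)
  })
  names(per_dim) <- names(counts)
  out <- list(
    dimensions = per_dim,
    inconsistency_pct = vapply(per_dim, `[[`, 0, "inconsistency_pct"),
    mean_inconsistency_pct = mean(vapply(per_dim, `[[`, 0, "inconsistency_pct")),
    n_pairs = vapply(per_dim, `[[`, 0, "n_pairs")
  )
  class(out) <- "eq5d_redistribution"
  out
}

#' Redistribution of paired 3L/5L responses and Janssen inconsistency
#'
#' Cross-tabulates, per dimension, the 3L level against the 5L level over
#' records where both items of the pair are non-missing, and classifies each
#' pair under the Janssen consistency scheme (see
#' \code{\link{classify_pair}}).
#'
#' @param dataset an \code{\link{eq5d_survey}} with at least one complete
#'   pair in every dimension.
#' @return an \code{eq5d_redistribution} object with components
#'   \code{dimensions} (per dimension: \code{counts} 3x5, conditional
#'   \code{consistent_pct}, \code{inconsistency_pct}, \code{n_pairs}),
#'   \code{inconsistency_pct} (vector over dimensions) and
#'   \code{mean_inconsistency_pct}.
#' @export
redistribution <- function(dataset) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  counts <- lapply(seq_along(eq5d_dimensions), function(i) {
    l3 <- dataset[[paste0(names(eq5d_dimensions)[i], "3")]]
    l5 <- dataset[[paste0(names(eq5d_dimensions)[i], "5")]]
    ok <- !is.na(l3) & !is.na(l5)
    if (!any(ok)) stop("dimension ", eq5d_dimensions[i], " has zero complete pairs")
    table(factor(l3[ok], 1:3), factor(l5[ok], 1:5))
  })
  names(counts) <- unname(eq5d_dimensions)
  redistribution_from_counts(counts)
}

#' @export
print.eq5d_redistribution <- function(x, digits = 1, ...) {
  cat("Redistribution from EQ-5D-3L to EQ-5D-5L (consistent-pair percentages)\n")
  for (dm in names(x$dimensions)) {
    d <- x$dimensions[[dm]]
    cat(sprintf("\n%s (n pairs = %d, inconsistency = %s%%)\n", dm,
                as.integer(d$n_pairs), fmt_num(d$inconsistency_pct, digits)))
    for (l3 in 1:3) {
      cons <- janssen_scheme[[l3]]
      cells <- sprintf("5L%d: %d (%s%%)", cons, d$counts[l3, cons],
                       fmt_num(d$consistent_pct[l3, cons], digits))
      cat(sprintf("  3L%d -> %s\n", l3, paste(cells, collapse = ", ")))
    }
  }
  cat(sprintf("\nMean inconsistency over dimensions: %s%%\n",
              fmt_num(x$mean_inconsistency_pct, digits)))
  invisible(x)
}

#' Ceiling-effect comparison between the 3L and 5L instruments
#'
#' The ceiling is the proportion of "no problems" (level 1) answers per
#' dimension, and the proportion of best-state (11111) profiles for the full
#' descriptive system. Per-dimension ceilings use the non-missing items of
#' that dimension; profile ceilings use complete profiles. \code{change} is
#' \code{ceiling_3L - ceiling_5L} in percentage points (positive when the 3L
#' ceiling is higher, the hypothesised direction).
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param test \code{"pearson"} (default): Pearson chi-square on the 2x2
#'   instrument-by-at-ceiling table without continuity correction, treating
#'   the two instruments as independent samples; \code{"mcnemar"}: McNemar's
#'   test on the paired at-ceiling indicators (the statistically proper
#'   paired test), restricted to records complete on both items/profiles.
#' @return an \code{eq5d_ceiling} object: data frame \code{table} with rows
#'   for each dimension plus \code{profile_11111}, columns \code{ceiling_3L},
#'   \code{ceiling_5L} (percent), \code{change} and \code{p_value}.
#' @export
ceiling_report <- function(dataset, test = c("pearson", "mcnemar")) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  test <- match.arg(test)
  one <- function(at3, at5) {
    a3 <- at3[!is.na(at3)]; a5 <- at5[!is.na(at5)]
    if (!length(a3) || !length(a5)) stop("empty denominator in ceiling computation")
    c3 <- 100 * mean(a3); c5 <- 100 * mean(a5)
    p <- if (test == "pearson") {
      tab <- rbind(c(sum(a3), sum(!a3)), c(sum(a5), sum(!a5)))
      if (any(colSums(tab) == 0)) NA_real_
      else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    } else {
      ok <- !is.na(at3) & !is.na(at5)
      tab <- table(factor(at3[ok], c(TRUE, FALSE)), factor(at5[ok], c(TRUE, FALSE)))
      if (sum(tab[1, 2], tab[2, 1]) == 0) NA_real_
      else suppressWarnings(stats::mcnemar.test(tab)$p.value)
    }
    c(ceiling_3L = c3, ceiling_5L = c5, change = c3 - c5, p_value = p)
  }
  rows <- lapply(seq_along(eq5d_dimensions), function(i) {
    l3 <- dataset[[paste0(names(eq5d_dimensions)[i], "3")]]
    l5 <- dataset[[paste0(names(eq5d_dimensions)[i], "5")]]
    one(ifelse(is.na(l3), NA, l3 == 1L), ifelse(is.na(l5), NA, l5 == 1L))
  })
  rows <- c(rows, list(one(best_state(dataset, "3L"), best_state(dataset, "5L"))))
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- c(unname(eq5d_dimensions), "profile_11111")
  out <- list(table = tab, test = test,
              n_3L = sum(complete_profile(dataset, "3L")),
              n_5L = sum(complete_profile(dataset, "5L")))
  class(out) <- "eq5d_ceiling"
  out
}

#' @export
print.eq5d_ceiling <- function(x, digits = 1, ...) {
  cat(sprintf("Ceiling effect (test: %s; complete profiles 3L: %d, 5L: %d)\n",
              x$test, x$n_3L, x$n_5L))
  tab <- x$table
  disp <- data.frame(`3L %` = fmt_num(tab$ceiling_3L, digits),
                     `5L %` = fmt_num(tab$ceiling_5L, digits),
                     change = fmt_num(tab$change, digits),
                     p = format.pval(tab$p_value, digits = 3),
                     check.names = FALSE, row.names = rownames(tab))
  print(disp)
  invisible(x)
}
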