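# Published reference tables bundled as plain-text fixtures.

#' Published redistribution reference counts
#'
#' Consistent-transition counts (3L level x 5L level, per dimension) and
#' per-dimension inconsistency percentages as published for a Polish adult
#' general-population survey (N = 3978) in which both EQ-5D versions were
#' administered. Inconsistent transitions are published only as per-dimension
#' percentages, so the count matrices carry zeros in the inconsistent cells;
#' conditional consistent percentages computed from them are unaffected
#' (they condition on consistent pairs).
#'
#' @return list with \code{counts} (named list of five 3x5 matrices, usable
#'   with \code{\link{redistribution_from_counts}}) and
#'   \code{inconsistency_pct} (named vector of published per-dimension
#'   inconsistency percentages).
#' @export
reference_redistribution <- function() {
  tab <- utils::read.csv(system.file("extdata", "reference_redistribution_counts.csv",
                                     package = "eqvalid"), stringsAsFactors = FALSE)
  counts <- lapply(unname(eq5d_dimensions), function(dm) {
    m <- matrix(0, 3, 5, dimnames = list(1:3, 1:5))
    sub <- tab[tab$dimension == dm, ]
    m[cbind(sub$level_3L, sub$level_5L)] <- sub$n
    m
  })
  names(counts) <- unname(eq5d_dimensions)
  inc <- utils::read.csv(system.file("extdata", "reference_inconsistency_pct.csv",
                                     package = "eqvalid"), stringsAsFactors = FALSE)
  list(counts = counts,
       inconsistency_pct = stats::setNames(inc$inconsistency_pct, inc$dimension))
}
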