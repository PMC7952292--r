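# Survey container, validation, delimited-text I/O, feasibility assessment.

survey_columns <- c("id", "age", "sex", "education", "economic_status",
                    "diabetes", paste0(names(eq5d_dimensions), "5"),
                    paste0(names(eq5d_dimensions), "3"), "eq_vas", "sf1")

#' Construct a validated survey dataset
#'
#' An \code{eq5d_survey} is a data frame with one row per respondent and a
#' fixed column schema: \code{id}, \code{age}, \code{sex}, \code{education},
#' \code{economic_status}, \code{diabetes}, the five 5L items
#' (\code{mo5,sc5,ua5,pd5,ad5}, levels 1-5), the five 3L items
#' (\code{mo3,sc3,ua3,pd3,ad3}, levels 1-3), \code{eq_vas} (0-100) and
#' \code{sf1} (1=excellent ... 5=poor). Missing values are \code{NA}.
#' An \code{age_group} factor is derived from \code{age}. Extra columns are
#' passed through untouched. Out-of-range levels are rejected, not coerced.
#'
#' @param data data frame holding the columns above.
#' @param metadata optional named list of free-form labels (source, seed,
#'   generation parameters); stored as the \code{"metadata"} attribute.
#' @return an object of class \code{c("eq5d_survey", "data.frame")}.
#' @export
eq5d_survey <- function(data, metadata = list()) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  missing_cols <- setdiff(survey_columns, names(data))
  if (length(missing_cols))
    stop("survey is missing required columns: ", paste(missing_cols, collapse = ", "))

  data$id <- as.character(data$id)
  if (anyDuplicated(data$id))
    stop("record ids are not unique (first duplicate: ",
         data$id[anyDuplicated(data$id)][1], ")")

  check_int_range <- function(col, lo, hi) {
    x <- data[[col]]
    if (is.factor(x)) x <- as.character(x)
    x <- suppressWarnings(as.integer(x))
    bad_parse <- which(!is.na(data[[col]]) & data[[col]] != "" & is.na(x))
    if (length(bad_parse))
      stop(sprintf("row %d, column '%s': value '%s' is not an integer",
                   bad_parse[1], col, as.character(data[[col]][bad_parse[1]])))
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad))
      stop(sprintf("row %d, column '%s': value %d outside allowed range %d..%d",
                   bad[1], col, x[bad[1]], lo, hi))
    x
  }

  data$age <- check_int_range("age", 18L, 130L)
  bad_age <- which(is.na(data$age))
  if (length(bad_age)) stop(sprintf("row %d, column 'age': age is required", bad_age[1]))
  for (col in paste0(names(eq5d_dimensions), "5")) data[[col]] <- check_int_range(col, 1L, 5L)
  for (col in paste0(names(eq5d_dimensions), "3")) data[[col]] <- check_int_range(col, 1L, 3L)
  data$eq_vas <- check_int_range("eq_vas", 0L, 100L)
  data$sf1 <- check_int_range("sf1", 1L, 5L)

  check_cat <- function(col, levels) {
    x <- as.character(data[[col]])
    x[!is.na(x) & x == ""] <- NA
    bad <- which(!is.na(x) & !(x %in% levels))
    if (length(bad))
      stop(sprintf("row %d, column '%s': unknown category '%s' (allowed: %s)",
                   bad[1], col, x[bad[1]], paste(levels, collapse = ", ")))
    factor(x, levels = levels)
  }
  data$sex <- check_cat("sex", sex_levels)
  bad_sex <- which(is.na(data$sex))
  if (length(bad_sex)) stop(sprintf("row %d, column 'sex': sex is required", bad_sex[1]))
  data$education <- check_cat("education", education_levels)
  data$economic_status <- check_cat("economic_status", economic_levels)

  dia <- data$diabetes
  if (!is.logical(dia)) {
    dia <- tolower(as.character(dia))
    dia[!is.na(dia) & dia == ""] <- NA
    bad <- which(!is.na(dia) & !(dia %in% c("yes", "no", "true", "false", "1", "0")))
    if (length(bad))
      stop(sprintf("row %d, column 'diabetes': unknown value '%s' (allowed: yes, no)",
                   bad[1], as.character(data$diabetes[bad[1]])))
    dia <- dia %in% c("yes", "true", "1") & !is.na(dia)
    dia[is.na(data$diabetes) | data$diabetes == ""] <- NA
  }
  data$diabetes <- dia

  data$age_group <- age_group(data$age)

  extra <- setdiff(names(data), c(survey_columns, "age_group"))
  data <- data[, c(survey_columns, "age_group", extra), drop = FALSE]
  rownames(data) <- NULL
  attr(data, "metadata") <- metadata
  class(data) <- c("eq5d_survey", "data.frame")
  data
}

#' @export
print.eq5d_survey <- function(x, ...) {
  cat(sprintf("EQ-5D paired survey: %d respondents\n", nrow(x)))
  md <- attr(x, "metadata")
  if (length(md) && !is.null(md$source)) cat("  source:", md$source, "\n")
  NextMethod()
  invisible(x)
}

#' Extract survey metadata
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @return the metadata list attached to the dataset.
#' @export
survey_metadata <- function(dataset) attr(dataset, "metadata")

#' Read a paired EQ-5D survey from delimited text
#'
#' Expects a header row naming at least the schema columns of
#' \code{\link{eq5d_survey}}. Missing values are encoded as empty fields.
#' Malformed rows are rejected with an error naming the row and column.
#'
#' @param path file path.
#' @param sep field separator; comma by default, tab accepted.
#' @return an \code{\link{eq5d_survey}}.
#' @export
read_survey <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", na.strings = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  eq5d_survey(raw, metadata = list(source = path))
}

#' Write a paired EQ-5D survey to delimited text
#'
#' Lossless, stable column order; missing values written as empty fields.
#' \code{write_survey} followed by \code{\link{read_survey}} reproduces the
#' original dataset.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param path file path to write.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_survey <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "eq5d_survey"))
  out <- as.data.frame(dataset)
  out$age_group <- NULL
  out$diabetes <- ifelse(is.na(out$diabetes), NA,
                         ifelse(out$diabetes, "yes", "no"))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Assess feasibility (missing-data rates) of a paired survey
#'
#' A record counts as missing for an instrument iff at least one of its five
#' items is missing; the EQ VAS is a single item. Denominator is the full
#' sample size N.
#'
#' @param dataset an \code{\link{eq5d_survey}} with at least one record.
#' @return an \code{eq5d_feasibility} list: \code{missing_5L},
#'   \code{missing_3L}, \code{missing_vas} (proportions in [0,1]) and
#'   \code{n_total}.
#' @export
assess_feasibility <- function(dataset) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  n <- nrow(dataset)
  if (n < 1) stop("empty dataset")
  any_missing <- function(cols)
    rowSums(is.na(as.matrix(dataset[, cols, drop = FALSE]))) > 0
  out <- list(
    missing_5L = mean(any_missing(dim_cols("5L"))),
    missing_3L = mean(any_missing(dim_cols("3L"))),
    missing_vas = mean(is.na(dataset$eq_vas)),
    n_total = n
  )
  class(out) <- "eq5d_feasibility"
  out
}

#' @export
print.eq5d_feasibility <- function(x, ...) {
  cat("Feasibility (missing data), N =", x$n_total, "\n")
  cat(sprintf("  EQ-5D-5L: %s%%\n  EQ-5D-3L: %s%%\n  EQ VAS:   %s%%\n",
              fmt_num(100 * x$missing_5L, 1), fmt_num(100 * x$missing_3L, 1),
              fmt_num(100 * x$missing_vas, 1)))
  invisible(x)
}

# rows with a complete profile for an instrument
complete_profile <- function(dataset, version) {
  rowSums(is.na(as.matrix(dataset[, dim_cols(version), drop = FALSE]))) == 0
}

#' Test whether profiles are at the best state (11111)
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param version \code{"5L"} or \code{"3L"}.
#' @return logical vector, \code{NA} where the profile is incomplete.
#' @export
best_state <- function(dataset, version = c("5L", "3L")) {
  version <- match.arg(version)
  m <- as.matrix(dataset[, dim_cols(version), drop = FALSE])
  ifelse(rowSums(is.na(m)) > 0, NA, rowSums(m == 1L) == 5L)
}
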