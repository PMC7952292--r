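# Additive EQ-5D value sets: container, file I/O, index computation.

#' Construct an additive EQ-5D value set
#'
#' A value set maps a complete descriptive-system profile to a single index
#' value (utility):
#' \deqn{U = U_{full} - \sum_{d} decrement(d, level_d) - \sum_{t} coef_t \cdot I_t(profile)}
#' where each extra term \eqn{t} is a threshold indicator of the form "any
#' dimension at level >= L" (e.g. the N3 constant of some 3L value sets).
#' Level-1 decrements are zero by definition; utilities below 0 are allowed
#' (worse-than-dead states exist in published sets).
#'
#' @param version \code{"5L"} or \code{"3L"}.
#' @param decrements numeric matrix, rows = the five dimensions (in the order
#'   of \code{\link{eq5d_dimensions}}), columns = levels \code{1..L}; entry
#'   \code{[d, l]} is the utility decrement for dimension \code{d} at level
#'   \code{l}. Column 1 must be all zero.
#' @param label free-form label (country/method).
#' @param full_health_value utility of the best state, typically 1.
#' @param extra_terms list of extra terms, each a list with elements
#'   \code{name}, \code{min_level} (the indicator is "any dimension >=
#'   min_level") and \code{coefficient} (subtracted when the indicator holds).
#' @return an object of class \code{eq5d_value_set}.
#' @export
value_set <- function(version = c("5L", "3L"), decrements, label = "unlabelled",
                      full_health_value = 1.0, extra_terms = list()) {
  version <- match.arg(version)
  L <- max_level(version)
  decrements <- as.matrix(decrements)
  if (!identical(dim(decrements), c(5L, L)))
    stop(sprintf("decrements must be a 5 x %d matrix for version %s", L, version))
  if (any(is.na(decrements)))
    stop("decrement table has missing cells")
  if (any(decrements[, 1] != 0))
    stop("level-1 decrements must be zero")
  dimnames(decrements) <- list(unname(eq5d_dimensions), 1:L)
  if (any(apply(decrements, 1, diff) < 0))
    warning("decrements are not nondecreasing in level within every dimension")
  for (t in extra_terms)
    stopifnot(is.character(t$name), t$min_level %in% 2:L, is.numeric(t$coefficient))
  structure(list(version = version, label = label,
                 full_health_value = full_health_value,
                 decrements = decrements, extra_terms = extra_terms),
            class = "eq5d_value_set")
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat(sprintf("EQ-5D-%s value set '%s' (full health = %g)\n",
              x$version, x$label, x$full_health_value))
  print(round(x$decrements, 4))
  for (t in x$extra_terms)
    cat(sprintf("  extra term %s: any dimension >= %d -> -%g\n",
                t$name, t$min_level, t$coefficient))
  invisible(x)
}

#' Load a value set from a delimited coefficient file
#'
#' The file format is a header block of \code{key=value} lines (keys
#' \code{version}, \code{label}, \code{full_health_value}, and zero or more
#' \code{extra_term=name,min_level,coefficient} lines) followed by a CSV
#' table with columns \code{dimension,level,decrement} covering every
#' (dimension, level) cell of the version.
#'
#' @param path file path.
#' @return an \code{\link{value_set}} object.
#' @export
load_value_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  hdr_end <- match("dimension,level,decrement", trimws(lines))
  if (is.na(hdr_end)) stop("value-set file lacks the 'dimension,level,decrement' table header")
  header <- lines[seq_len(hdr_end - 1)]
  kv <- strsplit(header, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get_key <- function(k, default = NULL) {
    i <- which(trimws(keys) == k)
    if (!length(i)) {
      if (is.null(default)) stop("value-set file lacks required header key '", k, "'")
      return(default)
    }
    trimws(vals[i[1]])
  }
  version <- get_key("version")
  if (!version %in% c("3L", "5L")) stop("version must be 3L or 5L, got '", version, "'")
  L <- max_level(version)
  tab <- utils::read.csv(text = paste(lines[hdr_end:length(lines)], collapse = "\n"),
                         stringsAsFactors = FALSE)
  tab$dimension <- trimws(tab$dimension)
  bad <- setdiff(tab$dimension, unname(eq5d_dimensions))
  if (length(bad)) stop("unknown dimension '", bad[1], "' in value-set file")
  dec <- matrix(NA_real_, 5, L, dimnames = list(unname(eq5d_dimensions), 1:L))
  dec[cbind(match(tab$dimension, unname(eq5d_dimensions)), tab$level)] <- tab$decrement
  if (any(is.na(dec))) {
    miss <- which(is.na(dec), arr.ind = TRUE)[1, ]
    stop(sprintf("value-set file lacks a decrement for %s level %d",
                 rownames(dec)[miss[1]], miss[2]))
  }
  extra <- lapply(which(trimws(keys) == "extra_term"), function(i) {
    parts <- trimws(strsplit(vals[i], ",", fixed = TRUE)[[1]])
    if (length(parts) != 3) stop("malformed extra_term line: ", vals[i])
    list(name = parts[1], min_level = as.integer(parts[2]),
         coefficient = as.numeric(parts[3]))
  })
  value_set(version, dec, label = get_key("label", "unlabelled"),
            full_health_value = as.numeric(get_key("full_health_value", "1")),
            extra_terms = extra)
}

#' Save a value set to the coefficient file format
#'
#' @param vs an \code{\link{value_set}}.
#' @param path file path to write.
#' @return \code{path}, invisibly.
#' @export
save_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("version=", vs$version),
               paste0("label=", vs$label),
               paste0("full_health_value=", format(vs$full_health_value, digits = 15))),
             con)
  for (t in vs$extra_terms)
    writeLines(sprintf("extra_term=%s,%d,%s", t$name, t$min_level,
                       format(t$coefficient, digits = 15)), con)
  writeLines("dimension,level,decrement", con)
  for (d in seq_len(5))
    for (l in seq_len(ncol(vs$decrements)))
      writeLines(sprintf("%s,%d,%s", rownames(vs$decrements)[d], l,
                         format(vs$decrements[d, l], digits = 15)), con)
  invisible(path)
}

#' Compute the index value of a single complete profile
#'
#' @param profile integer vector of five levels in instrument order
#'   (mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression).
#' @param vs an \code{\link{value_set}} of matching version.
#' @return the index value (utility), a single number.
#' @export
#' @examples
#' vs <- toy_value_set("5L")
#' compute_index(c(1, 1, 1, 1, 1), vs)  # full health -> 1
#' compute_index(c(2, 1, 1, 1, 1), vs)  # 1 - 0.05
compute_index <- function(profile, vs) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  profile <- as.integer(profile)
  if (length(profile) != 5 || anyNA(profile))
    stop("profile must be five non-missing levels; incomplete profiles cannot be scored")
  L <- max_level(vs$version)
  if (any(profile < 1 | profile > L))
    stop("profile level outside 1..", L, " for version ", vs$version)
  v <- vs$full_health_value - sum(vs$decrements[cbind(1:5, profile)])
  for (t in vs$extra_terms)
    if (any(profile >= t$min_level)) v <- v - t$coefficient
  v
}

#' Index values for every record of a survey
#'
#' Applies \code{\link{compute_index}} record-wise; records with an incomplete
#' profile on the value set's version yield \code{NA}.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param vs an \code{\link{value_set}}.
#' @return numeric vector of length \code{nrow(dataset)}.
#' @export
index_column <- function(dataset, vs) {
  stopifnot(inherits(dataset, "eq5d_survey"), inherits(vs, "eq5d_value_set"))
  m <- as.matrix(dataset[, dim_cols(vs$version), drop = FALSE])
  ok <- rowSums(is.na(m)) == 0
  out <- rep(NA_real_, nrow(m))
  if (any(ok)) {
    mm <- m[ok, , drop = FALSE]
    dec <- matrix(vs$decrements[cbind(rep(1:5, each = sum(ok)), as.vector(mm))],
                  ncol = 5)
    v <- vs$full_health_value - rowSums(dec)
    for (t in vs$extra_terms)
      v <- v - t$coefficient * (rowSums(mm >= t$min_level) > 0)
    out[ok] <- v
  }
  out
}

#' Bundled toy value sets
#'
#' Deliberately simple fixtures for tests and examples: the 5L toy set uses
#' decrements \code{0.05 * (level - 1)} in every dimension (so 11111 scores 1
#' and 55555 scores 0); the 3L toy set uses \code{0.1 * (level - 1)} (33333
#' scores 0). Real analyses should load a published national value set with
#' \code{\link{load_value_set}}.
#'
#' @param version \code{"5L"} or \code{"3L"}.
#' @return an \code{\link{value_set}}.
#' @export
toy_value_set <- function(version = c("5L", "3L")) {
  version <- match.arg(version)
  L <- max_level(version)
  step <- if (version == "5L") 0.05 else 0.1
  dec <- matrix(rep(step * (0:(L - 1)), each = 5), 5, L)
  value_set(version, dec, label = paste0("toy-", version))
}
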