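# Full-pipeline orchestration and rendering (text / JSON).

#' Run the complete validation pipeline
#'
#' Executes every stage in order — feasibility, redistribution, ceiling,
#' informativity, known-groups (with per-sex age regressions), convergent
#' validity, model-based construct validity — recording any stage failure
#' and continuing with the remaining stages.
#'
#' @param dataset an \code{\link{eq5d_survey}}, or a file path readable by
#'   \code{\link{read_survey}}.
#' @param vs5,vs3 value sets (\code{\link{value_set}} objects or file paths
#'   for \code{\link{load_value_set}}) for the 5L and 3L index.
#' @param spec a \code{\link{theoretical_model_spec}} for the
#'   construct-validity stage.
#' @return an \code{eq5d_validation} object: one component per stage (each
#'   either the stage result or a list with an \code{error} message), plus
#'   \code{meta} (value-set labels, seed, package version, N).
#' @export
run_full_validation <- function(dataset, vs5 = toy_value_set("5L"),
                                vs3 = toy_value_set("3L"),
                                spec = theoretical_model_spec()) {
  if (is.character(dataset)) dataset <- read_survey(dataset)
  if (is.character(vs5)) vs5 <- load_value_set(vs5)
  if (is.character(vs3)) vs3 <- load_value_set(vs3)
  stopifnot(inherits(dataset, "eq5d_survey"),
            inherits(vs5, "eq5d_value_set"), inherits(vs3, "eq5d_value_set"))
  if (vs5$version != "5L" || vs3$version != "3L")
    stop("value-set versions do not match their roles")
  stage <- function(expr) tryCatch(expr, error = function(e)
    structure(list(error = conditionMessage(e)), class = "eqvalid_stage_error"))
  index5 <- index_column(dataset, vs5)
  index3 <- index_column(dataset, vs3)
  out <- list(
    feasibility = stage(assess_feasibility(dataset)),
    redistribution = stage(redistribution(dataset)),
    ceiling = stage(ceiling_report(dataset)),
    informativity = stage(informativity_report(dataset)),
    known_groups = stage(known_groups(dataset, index5, index3)),
    age_regressions = stage(list(
      male = age_regression(dataset, index5, "male"),
      female = age_regression(dataset, index5, "female"))),
    convergent = stage(convergent_matrix(dataset, index5)),
    construct_validity = stage(construct_validity(dataset, index5, spec)),
    meta = list(n = nrow(dataset), seed = spec$seed,
                value_set_5L = vs5$label, value_set_3L = vs3$label,
                n_index5 = sum(!is.na(index5)), n_index3 = sum(!is.na(index3)),
                package_version = as.character(utils::packageVersion("eqvalid")))
  )
  class(out) <- "eq5d_validation"
  out
}

#' @export
print.eq5d_validation <- function(x, ...) {
  cat(sprintf("Full EQ-5D-5L validation report (N = %d, value sets: 5L '%s', 3L '%s')\n\n",
              x$meta$n, x$meta$value_set_5L, x$meta$value_set_3L))
  for (nm in setdiff(names(x), "meta")) {
    cat("==", nm, "==\n")
    if (inherits(x[[nm]], "eqvalid_stage_error"))
      cat("  stage failed:", x[[nm]]$error, "\n")
    else if (nm == "age_regressions") { print(x[[nm]]$male); print(x[[nm]]$female) }
    else print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' Render a validation report as JSON
#'
#' Schema-stable JSON (top-level keys = stages + \code{meta}; failed stages
#' carry an \code{error} string). Numeric values keep full precision; display
#' rounding is a concern of the text renderer only.
#'
#' @param report an \code{eq5d_validation} from
#'   \code{\link{run_full_validation}}.
#' @param path optional file to write; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly, when \code{path} given).
#' @export
render_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "eq5d_validation"))
  strip <- function(x) {
    if (inherits(x, "eqvalid_stage_error")) return(list(error = x$error))
    if (inherits(x, "eq5d_construct_validity"))
      x <- x[c("rmse_int", "rmse_val", "q95_int", "coverage",
               "n_train", "n_test", "internal")]
    if (inherits(x, "eq5d_age_regression"))
      x <- x[c("slope", "intercept", "se_slope", "se_intercept", "conf_int",
               "n", "sex")]
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.table(x)) return(as.vector(x))
    if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
    x
  }
  body <- lapply(unclass(report), strip)
  json <- jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE, force = TRUE)
  if (!is.null(path)) { writeLines(json, path); return(invisible(as.character(json))) }
  as.character(json)
}
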