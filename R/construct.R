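# Model-based construct validity: a random-forest "theoretical model" of the
# 5L index from five demographic predictors, assessed by comparing internal
# (training resubstitution) and held-out error distributions.

theoretical_predictors <- c("age_group", "sex", "education", "economic_status",
                            "diabetes")

#' Specification of the theoretical model
#'
#' Fixes every tunable of the construct-validity procedure: the five
#' categorical predictors (age group, sex, education, economic status,
#' diabetes), the ensemble size, the train fraction of the random split, the
#' seed, and the tree hyperparameters.
#'
#' @param n_trees number of regression trees (default 300).
#' @param train_fraction proportion of complete cases used for training
#'   (default 0.60; the rest is the held-out test set).
#' @param seed integer seed governing both the split and the forest.
#' @param mtry predictors sampled per split; \code{NULL} uses the regression
#'   default \code{max(floor(p/3), 1)} of the \pkg{randomForest} package.
#' @param min_node_size minimum terminal-node size (regression default 5).
#' @param replace bootstrap-resample observations per tree (default
#'   \code{TRUE}).
#' @return an object of class \code{theoretical_model_spec}.
#' @export
theoretical_model_spec <- function(n_trees = 300, train_fraction = 0.6,
                                   seed = 1L, mtry = NULL, min_node_size = 5,
                                   replace = TRUE) {
  stopifnot(n_trees >= 1, train_fraction > 0, train_fraction < 1,
            min_node_size >= 1)
  structure(list(predictors = theoretical_predictors, n_trees = as.integer(n_trees),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 mtry = mtry, min_node_size = min_node_size, replace = replace),
            class = "theoretical_model_spec")
}

# complete cases on the five predictors and the outcome
construct_complete <- function(dataset, index) {
  ok <- !is.na(index)
  for (v in theoretical_predictors) ok <- ok & !is.na(dataset[[v]])
  which(ok)
}

#' Split complete cases into training and test sets
#'
#' Uniform random split at \code{spec$train_fraction}, seeded by
#' \code{spec$seed}; the two index sets are disjoint and exhaust the complete
#' cases (complete on the five predictors and on the index).
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param index numeric index vector aligned to records.
#' @param spec a \code{\link{theoretical_model_spec}}.
#' @return list with integer row-index vectors \code{train} and \code{test}.
#' @export
split_train_test <- function(dataset, index, spec = theoretical_model_spec()) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  cc <- construct_complete(dataset, index)
  if (length(cc) < 10) stop("need at least 10 complete cases, have ", length(cc))
  n_train <- round(spec$train_fraction * length(cc))
  tr <- with_seed(spec$seed, sample(cc, n_train))
  list(train = sort(tr), test = setdiff(cc, tr))
}

#' Fit the random-forest theoretical model
#'
#' Bagged ensemble of \code{spec$n_trees} regression trees of the index value
#' on the five categorical predictors (fit via the \pkg{randomForest}
#' package); the prediction is the mean over trees. Seeded and reproducible.
#'
#' @param data data frame containing the predictor columns (factors /
#'   logical) for the training records.
#' @param y numeric outcome (index values) aligned to \code{data}.
#' @param spec a \code{\link{theoretical_model_spec}}.
#' @return an \code{eq5d_theoretical_model}; use \code{predict} on new data.
#' @export
fit_theoretical_model <- function(data, y, spec = theoretical_model_spec()) {
  stopifnot(nrow(data) >= 1, length(y) == nrow(data), !anyNA(y))
  df <- data[, theoretical_predictors, drop = FALSE]
  df$diabetes <- factor(ifelse(df$diabetes, "yes", "no"), c("no", "yes"))
  df <- as.data.frame(df)  # keep the full schema levels so test data always maps
  mtry <- if (is.null(spec$mtry)) max(floor(length(theoretical_predictors) / 3), 1)
          else spec$mtry
  fit <- with_seed(spec$seed, withCallingHandlers(
    randomForest::randomForest(x = df, y = y, ntree = spec$n_trees,
                               mtry = mtry, nodesize = spec$min_node_size,
                               replace = spec$replace),
    # a (near-)constant outcome is a valid degenerate fit, not a user error
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  structure(list(forest = fit, spec = spec,
                 levels = lapply(df, levels)),
            class = "eq5d_theoretical_model")
}

#' @export
predict.eq5d_theoretical_model <- function(object, newdata, ...) {
  df <- newdata[, theoretical_predictors, drop = FALSE]
  df$diabetes <- factor(ifelse(df$diabetes, "yes", "no"), c("no", "yes"))
  df <- as.data.frame(df)
  for (v in names(object$levels))
    df[[v]] <- factor(as.character(df[[v]]), levels = object$levels[[v]])
  unname(stats::predict(object$forest, newdata = df))
}

#' @export
print.eq5d_theoretical_model <- function(x, ...) {
  cat(sprintf("Theoretical model: random forest, %d trees, predictors: %s\n",
              x$spec$n_trees, paste(theoretical_predictors, collapse = ", ")))
  invisible(x)
}

#' Model-based construct validity of the 5L index
#'
#' Implements the full procedure: score the survey with the value set,
#' restrict to complete cases, split 60/40 (per \code{spec}), fit the
#' theoretical model on the training set, and compare the error
#' distributions. Per-observation errors are \emph{absolute} prediction
#' errors; internal errors are training-set resubstitution errors by default
#' (\code{internal = "oob"} substitutes the stricter out-of-bag errors).
#' The headline statistics are the two RMSEs, the empirical 95th percentile
#' \code{q95_int} of the internal errors (linear-interpolation quantile,
#' \code{\link[stats]{quantile}} type 7), and \code{coverage}: the percentage
#' of held-out errors not exceeding \code{q95_int} (non-strict, so the
#' noiseless limit where every error is exactly zero reports full coverage;
#' for continuous errors ties have probability zero and the choice is
#' immaterial). A well-specified model
#' yields near-overlapping distributions (coverage near 95); misspecification
#' that affects only unseen data drives coverage down.
#'
#' @param dataset an \code{\link{eq5d_survey}}.
#' @param vs an \code{\link{value_set}} (5L) used to score the index, or a
#'   precomputed numeric index vector aligned to records.
#' @param spec a \code{\link{theoretical_model_spec}}.
#' @param internal \code{"resubstitution"} (default) or \code{"oob"}.
#' @return an \code{eq5d_construct_validity} object: \code{rmse_int},
#'   \code{rmse_val}, \code{errors_int}, \code{errors_val}, \code{q95_int},
#'   \code{coverage} (percent), \code{n_train}, \code{n_test}, the fitted
#'   \code{model} and the \code{split}.
#' @export
construct_validity <- function(dataset, vs, spec = theoretical_model_spec(),
                               internal = c("resubstitution", "oob")) {
  stopifnot(inherits(dataset, "eq5d_survey"))
  internal <- match.arg(internal)
  index <- if (inherits(vs, "eq5d_value_set")) index_column(dataset, vs)
           else as.numeric(vs)
  if (length(index) != nrow(dataset))
    stop("index vector must align with the dataset records")
  split <- split_train_test(dataset, index, spec)
  train <- dataset[split$train, , drop = FALSE]
  test <- dataset[split$test, , drop = FALSE]
  model <- fit_theoretical_model(train, index[split$train], spec)
  pred_int <- if (internal == "oob") unname(model$forest$predicted)
              else predict(model, train)
  pred_val <- predict(model, test)
  err_int <- abs(index[split$train] - pred_int)
  err_val <- abs(index[split$test] - pred_val)
  q95 <- unname(stats::quantile(err_int, 0.95, type = 7))
  out <- list(rmse_int = sqrt(mean((index[split$train] - pred_int)^2)),
              rmse_val = sqrt(mean((index[split$test] - pred_val)^2)),
              errors_int = err_int, errors_val = err_val,
              q95_int = q95, coverage = 100 * mean(err_val <= q95),
              n_train = length(split$train), n_test = length(split$test),
              internal = internal, model = model, split = split)
  class(out) <- "eq5d_construct_validity"
  out
}

#' @export
print.eq5d_construct_validity <- function(x, digits = 3, ...) {
  cat("Model-based construct validity (theoretical model: random forest)\n")
  cat(sprintf("  RMSE internal (%s): %s   RMSE validation: %s\n", x$internal,
              fmt_num(x$rmse_int, digits), fmt_num(x$rmse_val, digits)))
  cat(sprintf("  95th quantile of internal errors: %s\n", fmt_num(x$q95_int, digits)))
  cat(sprintf("  %% held-out errors at or below it: %s (n train %d, n test %d)\n",
              fmt_num(x$coverage, 1), x$n_train, x$n_test))
  invisible(x)
}

#' Plot internal vs held-out error distributions
#'
#' Overlaid density curves of the internal and held-out absolute-error
#' distributions, with the 95th percentile of the internal errors marked;
#' near-complete overlap supports construct validity.
#'
#' @param x an \code{eq5d_construct_validity} result.
#' @param ... passed to \code{\link[graphics]{plot}}.
#' @export
plot.eq5d_construct_validity <- function(x, ...) {
  d_int <- stats::density(x$errors_int, from = 0)
  d_val <- stats::density(x$errors_val, from = 0)
  graphics::plot(d_int, col = "firebrick", lwd = 2,
                 xlim = range(d_int$x, d_val$x), ylim = range(0, d_int$y, d_val$y),
                 xlab = "absolute prediction error (utility units)",
                 main = "Theoretical-model error distributions", ...)
  graphics::lines(d_val, col = "grey40", lwd = 2)
  graphics::abline(v = x$q95_int, lty = 2)
  graphics::legend("topright", c("internal (training)", "held-out (validation)",
                                 "95th pct internal"),
                   col = c("firebrick", "grey40", "black"),
                   lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}
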