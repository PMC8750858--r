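#' Fit an automatic AHP risk-scoring model
#'
#' The end-to-end estimator: given a follow-up cohort and a factor
#' hierarchy, it (1) splits the data into stratified training and test
#' parts, (2) ranks the leaf factors with the six-indicator importance
#' ensemble, (3) discretizes continuous leaves by supervised
#' confidence-interval merging, (4) fits a Cox proportional-hazards model
#' of the event time on the leaf factors, (5) seeds every pairwise
#' comparison matrix in the hierarchy from the normalized |log-hazard|
#' magnitudes, quantizes to the Saaty scale and repairs any matrix failing
#' the CR < 0.10 consistency test, (6) synthesizes leaf global weights and
#' the combination consistency report, (7) builds the level scorecard from
#' training log-odds, and (8) chooses the F1-optimal threshold on the
#' training scores. Metrics are reported on both splits.
#'
#' @param data Cohort \code{data.frame}: one row per patient-course with
#'   the leaf covariates, a binary outcome column and an event/follow-up
#'   time column.
#' @param hierarchy A \code{\link{factor_hierarchy}} whose leaves name
#'   columns of \code{data}; default \code{\link{default_hierarchy}}.
#' @param outcome Binary event column name.
#' @param time Event/censoring time column name (days).
#' @param split_ratio Train:test ratio (default 2:1).
#' @param confidence Wilson level for supervised discretization.
#' @param min_frac Minimum bin occupancy fraction.
#' @param max_levels A numeric leaf with more distinct values than this is
#'   discretized; others are treated as categorical.
#' @param quantize Quantize generated comparison matrices to the Saaty
#'   scale.
#' @param repair Consistency-repair unacceptable matrices.
#' @param seed Seed driving the split and ReliefF sampling.
#' @return An object of class \code{"ahp_risk"}; see
#'   \code{\link{summary.ahp_risk}}, \code{\link{predict.ahp_risk}}.
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 400, seed = 1))$data
#' fit <- ahp_risk(cohort)
#' fit
#' head(predict(fit, cohort))
#' @export
ahp_risk <- function(data, hierarchy = default_hierarchy(),
                     outcome = "event", time = "event_time_days",
                     split_ratio = c(2, 1), confidence = 0.95,
                     min_frac = 0.05, max_levels = 6L,
                     quantize = TRUE, repair = TRUE, seed = 1L) {
  stopifnot(is.data.frame(data), outcome %in% names(data),
            time %in% names(data))
  leaves <- hierarchy_leaves(hierarchy)
  missing <- setdiff(leaves, names(data))
  if (length(missing))
    stop(sprintf("ahprisk_model_error: hierarchy leaf column(s) missing: %s",
                 paste(missing, collapse = ", ")))
  sp <- train_test_split(data[[outcome]], ratio = split_ratio, seed = seed)
  train <- data[sp$train, , drop = FALSE]
  test <- data[sp$test, , drop = FALSE]

  ranking <- rank_features(train[, leaves, drop = FALSE], train[[outcome]],
                           seed = seed)

  continuous <- leaves[vapply(leaves, function(v)
    is.numeric(train[[v]]) && length(unique(train[[v]])) > max_levels,
    logical(1))]
  bins <- lapply(continuous, function(v)
    supervised_discretize(train[[v]], train[[outcome]],
                          confidence = confidence, min_frac = min_frac,
                          variable = v))
  names(bins) <- continuous

  cox <- fit_cox(train[[time]], train[[outcome]],
                 train[, leaves, drop = FALSE])
  seed_w <- cox_weight_seed(cox, factors = intersect(leaves, rownames(cox)))
  full_w <- stats::setNames(rep(0, length(leaves)), leaves)
  full_w[names(seed_w)] <- seed_w
  h <- set_hierarchy_weights(hierarchy, full_w, quantize = quantize,
                             repair = repair)
  card <- build_scorecard(h, train, outcome = outcome, bins = bins)

  s_train <- risk_score(card, train, unknown_level = "nearest")
  thr <- choose_threshold(s_train, train[[outcome]])
  card$threshold <- thr
  s_test <- risk_score(card, test, unknown_level = "nearest")

  structure(list(
    hierarchy = h, scorecard = card, cox = cox, ranking = ranking,
    bins = bins, threshold = thr,
    split = sp, outcome = outcome, time = time, seed = seed,
    metrics = list(
      train = evaluate_scores(s_train, train[[outcome]], thr),
      test = evaluate_scores(s_test, test[[outcome]], thr)),
    n = nrow(data), call = match.call()), class = "ahp_risk")
}

#' @method print ahp_risk
#' @export
print.ahp_risk <- function(x, ...) {
  cat("Automatic AHP risk-scoring model\n")
  cat(sprintf("  n = %d (train %d / test %d), outcome '%s'\n",
              x$n, length(x$split$train), length(x$split$test), x$outcome))
  cat(sprintf("  %d leaf factors, combination CR = %.4f [%s]\n",
              length(x$scorecard$weights), x$scorecard$consistency$cr,
              if (x$scorecard$consistency$acceptable) "acceptable" else "NOT acceptable"))
  cat("  test split: ")
  print(x$metrics$test)
  invisible(x)
}

#' Summary of a fitted AHP risk model
#'
#' @param object An \code{ahp_risk} fit.
#' @param ... Unused.
#' @return The object, invisibly, after printing the global weights, Cox
#'   table, consistency report and metrics for both splits.
#' @method summary ahp_risk
#' @export
summary.ahp_risk <- function(object, ...) {
  cat("Automatic AHP risk-scoring model\n\n")
  cat("Leaf global weights (eigenvector synthesis):\n")
  w <- sort(object$scorecard$weights, decreasing = TRUE)
  for (v in names(w)) cat(sprintf("  %-30s %.4f\n", v, w[[v]]))
  cat("\nCombination consistency: ")
  print(object$scorecard$consistency)
  cat("\nCox coefficient table:\n")
  print(object$cox)
  cat("\nMetrics:\n  train: ")
  print(object$metrics$train)
  cat("  test:  ")
  print(object$metrics$test)
  invisible(object)
}

#' Leaf global weights of a fitted model
#'
#' @param object An \code{ahp_risk} fit.
#' @param ... Unused.
#' @return Named numeric vector summing to 1.
#' @export
coef.ahp_risk <- function(object, ...) object$scorecard$weights

#' Predict risk scores or classes
#'
#' @param object An \code{ahp_risk} fit.
#' @param newdata Records to score (default: refuse; scoring needs data).
#' @param type \code{"score"} for the [0, 1] risk score, \code{"class"}
#'   for the thresholded 0/1 prediction.
#' @param ... Unused.
#' @return Numeric scores or integer classes.
#' @export
predict.ahp_risk <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  s <- risk_score(object$scorecard, newdata, unknown_level = "nearest")
  if (type == "score") s else as.integer(s >= object$threshold)
}

#' Plot the leaf global weights
#'
#' Horizontal barplot of the synthesized global weights, largest on top.
#'
#' @param x An \code{ahp_risk} fit.
#' @param ... Passed to \code{graphics::barplot}.
#' @export
plot.ahp_risk <- function(x, ...) {
  w <- sort(coef(x))
  op <- graphics::par(mar = c(4, 12, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(w, horiz = TRUE, las = 1,
                    xlab = "global weight",
                    main = "AHP leaf global weights", ...)
  invisible(x)
}
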