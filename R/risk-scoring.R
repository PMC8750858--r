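#' Build a risk scorecard from hierarchy, bins and cohort data
#'
#' Combines the leaf global weights of a consistent hierarchy with
#' per-level scores for every leaf factor to form the multidimensional
#' patient rating scale. A leaf's levels come from its bin scheme
#' (continuous variables) or its observed categories; each level's score
#' is the empirical log-odds of the event at that level, min-max
#' normalized within the leaf so the lowest-risk level scores 0 and the
#' highest 1. A leaf observed at a single level scores 0.5 constantly
#' (with a warning).
#'
#' @param h A \code{factor_hierarchy} with local weights set (see
#'   \code{\link{set_hierarchy_weights}}).
#' @param data Training cohort \code{data.frame}.
#' @param outcome Name of the binary event column.
#' @param bins Named list of \code{bin_scheme}s for continuous leaves;
#'   leaves without a scheme are treated as categorical.
#' @return A \code{risk_scorecard}: list with \code{weights} (leaf global
#'   weights, sum 1), \code{levels} (per leaf: level labels, scores,
#'   majority level), \code{bins}, \code{consistency} (combination
#'   consistency report) and \code{threshold} (NA until chosen).
#' @export
build_scorecard <- function(h, data, outcome = "event", bins = list()) {
  syn <- synthesize_global_weights(h)
  leaves <- names(syn$weights)
  missing <- setdiff(setdiff(leaves, names(bins)), names(data))
  if (length(missing))
    stop(sprintf("ahprisk_score_error: leaf variable(s) absent from data: %s",
                 paste(missing, collapse = ", ")))
  y <- data[[outcome]]
  n <- length(y)
  eps <- 0.5 / max(1, n)
  lodds <- function(p) log((p + eps) / (1 - p + eps))
  levels_map <- lapply(leaves, function(v) {
    lev <- if (v %in% names(bins)) as.character(bin_assign(bins[[v]], data[[v]]))
           else as.character(data[[v]])
    labs <- sort(unique(lev))
    if (length(labs) < 2L) {
      warning(sprintf("leaf '%s' has a single observed level; constant score 0.5", v))
      return(list(labels = labs, scores = stats::setNames(0.5, labs),
                  majority = labs[1]))
    }
    lo <- vapply(labs, function(l) lodds(mean(y[lev == l])), numeric(1))
    s <- (lo - min(lo)) / (max(lo) - min(lo))
    list(labels = labs, scores = stats::setNames(s, labs),
         majority = labs[which.max(tabulate(factor(lev, levels = labs)))])
  })
  names(levels_map) <- leaves
  structure(list(weights = syn$weights, levels = levels_map,
                 bins = bins, consistency = syn$report,
                 threshold = NA_real_, outcome = outcome),
            class = "risk_scorecard")
}

#' @method print risk_scorecard
#' @export
print.risk_scorecard <- function(x, ...) {
  cat(sprintf("Risk scorecard: %d leaf factors, weights sum = %.6f\n",
              length(x$weights), sum(x$weights)))
  w <- sort(x$weights, decreasing = TRUE)
  for (v in names(w))
    cat(sprintf("  %-30s w = %.4f, %d level(s)\n", v, w[[v]],
                length(x$levels[[v]]$labels)))
  print(x$consistency)
  if (!is.na(x$threshold))
    cat(sprintf("  classification threshold: %.4f\n", x$threshold))
  invisible(x)
}

#' Score patient records with a scorecard
#'
#' The risk score of a record is the weight-by-score inner product
#' \eqn{\sum_l w_l s_l(\mathrm{level}_l)} over the leaves, bounded in
#' [0, 1]. Continuous leaves are binned through the card's schemes. A
#' record missing a leaf value is imputed with the training-majority level
#' (one warning per call); a level never seen in training is an error
#' naming the leaf.
#'
#' @param card A \code{risk_scorecard}.
#' @param data \code{data.frame} of records (or a single-row list).
#' @param unknown_level \code{"error"} (default) rejects levels never seen
#'   in training; \code{"nearest"} clamps a numeric-labelled level (counts,
#'   ordinal ratings) to the numerically nearest training level, which only
#'   applies when every training label is numeric.
#' @return Numeric risk scores in [0, 1].
#' @export
risk_score <- function(card, data, unknown_level = c("error", "nearest")) {
  stopifnot(inherits(card, "risk_scorecard"))
  unknown_level <- match.arg(unknown_level)
  data <- as.data.frame(data)
  n <- nrow(data)
  total <- numeric(n)
  imputed <- character(0)
  for (v in names(card$weights)) {
    lvmap <- card$levels[[v]]
    if (!v %in% names(data)) {
      lev <- rep(lvmap$majority, n)
      imputed <- c(imputed, v)
    } else {
      lev <- if (v %in% names(card$bins))
        as.character(bin_assign(card$bins[[v]], data[[v]]))
      else as.character(data[[v]])
      nas <- is.na(lev)
      if (any(nas)) {
        lev[nas] <- lvmap$majority
        imputed <- c(imputed, v)
      }
    }
    unknown <- setdiff(unique(lev), lvmap$labels)
    if (length(unknown)) {
      num_labs <- suppressWarnings(as.numeric(lvmap$labels))
      num_unk <- suppressWarnings(as.numeric(unknown))
      if (unknown_level == "nearest" && !anyNA(num_labs) && !anyNA(num_unk)) {
        for (u in seq_along(unknown)) {
          nearest <- lvmap$labels[which.min(abs(num_labs - num_unk[u]))]
          lev[lev == unknown[u]] <- nearest
        }
      } else {
        stop(sprintf("ahprisk_score_error: unknown level(s) %s for leaf '%s'",
                     paste(unknown, collapse = ", "), v))
      }
    }
    total <- total + card$weights[[v]] * unname(lvmap$scores[lev])
  }
  if (length(imputed))
    warning(sprintf("imputed training-majority level for: %s",
                    paste(unique(imputed), collapse = ", ")))
  pmin(1, pmax(0, total))
}

#' Classification metric report
#'
#' AUC by the midrank (Wilcoxon) statistic, plus accuracy and
#' class-weighted precision, recall and F1 at the given threshold
#' (predicted positive when score >= threshold). Per-class F1 is the
#' harmonic mean of that class's precision and recall; the report weights
#' the per-class values by class support, which makes the reported
#' accuracy and weighted recall identical.
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels Binary labels.
#' @param threshold Classification threshold in (0, 1).
#' @return A \code{metric_report}: list with \code{auc}, \code{accuracy},
#'   \code{precision}, \code{recall}, \code{f1}.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("ahprisk_metric_error: AUC undefined for single-class labels")
  y <- as.integer(labels == max(labels))
  r <- rank(scores, ties.method = "average")
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  auc <- (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  per_class <- function(cls) {
    tp <- sum(pred == cls & y == cls)
    prec <- if (sum(pred == cls) > 0) tp / sum(pred == cls) else 0
    rec <- if (sum(y == cls) > 0) tp / sum(y == cls) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec = prec, rec = rec, f1 = f1, support = sum(y == cls))
  }
  m <- vapply(c(0L, 1L), per_class, numeric(4))
  wts <- m["support", ] / sum(m["support", ])
  structure(list(
    auc = auc,
    accuracy = mean(pred == y),
    precision = sum(wts * m["prec", ]),
    recall = sum(wts * m["rec", ]),
    f1 = sum(wts * m["f1", ]),
    threshold = threshold, n = length(y)), class = "metric_report")
}

#' @method print metric_report
#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "AUC %.3f | accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f (threshold %.3f, n = %d)\n",
    x$auc, x$accuracy, x$precision, x$recall, x$f1, x$threshold, x$n))
  invisible(x)
}

#' Choose a classification threshold by F1
#'
#' Scans the observed score values as candidate thresholds and returns the
#' one maximizing the class-weighted F1; ties break to the lowest
#' threshold. Because candidates are the scores themselves, any strictly
#' monotone transform of the scores leaves the induced classification
#' unchanged.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return The chosen threshold.
#' @export
choose_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  f1s <- vapply(cand, function(t)
    evaluate_scores(scores, labels, threshold = t)$f1, numeric(1))
  cand[which.max(f1s)]  # which.max takes the first (lowest) maximizer
}

#' Stratified train/test split
#'
#' Splits rows into training and test parts (default ratio 2:1) with the
#' event prevalence preserved in both parts.
#'
#' @param y Binary outcome vector.
#' @param ratio Two positive numbers \code{c(train, test)}.
#' @param seed RNG seed.
#' @return List with integer index vectors \code{train} and \code{test}.
#' @export
train_test_split <- function(y, ratio = c(2, 1), seed = 1L) {
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  set.seed(seed)
  frac <- ratio[1] / sum(ratio)
  idx <- seq_along(y)
  train <- unlist(lapply(split(idx, y), function(ii)
    sample(ii, round(frac * length(ii)))))
  train <- sort(unname(train))
  list(train = train, test = setdiff(idx, train))
}

#' Greedy 1:1 propensity-score matching within a caliper
#'
#' Matches cases to controls 1:1 without replacement: admissible
#' case-control pairs (score distance within \code{caliper_sd} pooled
#' standard deviations) are consumed globally closest first, so each
#' matched pair is as tight as the remaining pool allows. Reports the
#' standardized mean difference of the scores before and after matching.
#'
#' @param scores Propensity / risk scores.
#' @param group Binary flag (1 = case / experimental, 0 = control).
#' @param caliper_sd Caliper width in pooled-SD units (default 0.2).
#' @return List with \code{pairs} (data.frame \code{case}, \code{control},
#'   row indices), \code{smd_before}, \code{smd_after}. Zero matchable
#'   pairs yields an empty pairing with a warning.
#' @export
propensity_match <- function(scores, group, caliper_sd = 0.2) {
  stopifnot(length(scores) == length(group), all(group %in% c(0, 1)))
  cases <- which(group == 1)
  controls <- which(group == 0)
  if (!length(cases) || !length(controls))
    stop("ahprisk_match_error: both groups must be non-empty")
  smd <- function(i, j) {
    s <- sqrt((stats::var(scores[i]) + stats::var(scores[j])) / 2)
    if (!is.finite(s) || s == 0) return(0)
    (mean(scores[i]) - mean(scores[j])) / s
  }
  caliper <- caliper_sd * stats::sd(scores)
  D <- abs(outer(scores[cases], scores[controls], "-"))
  D[D > caliper] <- NA
  ord <- order(D, na.last = NA)
  avail_case <- rep(TRUE, length(cases))
  avail_ctrl <- rep(TRUE, length(controls))
  pairs <- matrix(integer(0), ncol = 2)
  for (idx in ord) {
    i <- (idx - 1L) %% length(cases) + 1L
    j <- (idx - 1L) %/% length(cases) + 1L
    if (avail_case[i] && avail_ctrl[j]) {
      pairs <- rbind(pairs, c(cases[i], controls[j]))
      avail_case[i] <- FALSE
      avail_ctrl[j] <- FALSE
    }
  }
  if (!nrow(pairs)) {
    warning("no matches within the caliper")
    return(list(pairs = data.frame(case = integer(0), control = integer(0)),
                smd_before = smd(cases, controls), smd_after = NA_real_))
  }
  list(pairs = data.frame(case = pairs[, 1], control = pairs[, 2]),
       smd_before = smd(cases, controls),
       smd_after = smd(pairs[, 1], pairs[, 2]))
}
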