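# Entropies are in bits (log2) so a perfect predictor of a balanced binary
# outcome scores exactly 1 bit of information gain.

.entropy <- function(x) {
  p <- table(x)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

.cond_entropy <- function(y, x) {
  tab <- table(x)
  tot <- sum(tab)
  sum(vapply(names(tab), function(v) {
    tab[[v]] / tot * .entropy(y[x == v])
  }, numeric(1)))
}

#' Information gain of a feature for a binary outcome
#'
#' \eqn{IG(x; y) = H(y) - H(y | x)} in bits.
#'
#' @param x Categorical feature (factor/character/integer levels).
#' @param y Binary outcome, same length.
#' @return Nonnegative information gain in bits.
#' @export
info_gain <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("ahprisk_ranking_error: empty input")
  if (length(x) != length(y))
    stop("ahprisk_ranking_error: x and y lengths differ")
  max(0, .entropy(y) - .cond_entropy(y, x))
}

#' Gain ratio
#'
#' Information gain normalized by the feature's own entropy,
#' \eqn{IG(x;y)/H(x)}; defined as 0 for a constant feature.
#'
#' @inheritParams info_gain
#' @return Value in [0, 1].
#' @export
gain_ratio <- function(x, y) {
  hx <- .entropy(x)
  if (hx == 0) return(0)
  info_gain(x, y) / hx
}

.gini <- function(y) {
  p <- table(y)
  p <- p / sum(p)
  1 - sum(p^2)
}

#' Gini impurity reduction
#'
#' \eqn{Gini(y) - \sum_v p(x = v)\, Gini(y | x = v)}.
#'
#' @inheritParams info_gain
#' @return Nonnegative impurity reduction.
#' @export
gini_gain <- function(x, y) {
  if (length(x) == 0L) stop("ahprisk_ranking_error: empty input")
  tab <- table(x)
  tot <- sum(tab)
  cond <- sum(vapply(names(tab), function(v)
    tab[[v]] / tot * .gini(y[x == v]), numeric(1)))
  max(0, .gini(y) - cond)
}

#' Pearson chi-square statistic of a feature-outcome contingency table
#'
#' \eqn{\chi^2 = \sum (O - E)^2 / E} over the cells of the x-by-y table.
#' Levels with a zero margin are dropped with a warning.
#'
#' @inheritParams info_gain
#' @return The chi-square statistic (not a p-value).
#' @export
chi_square <- function(x, y) {
  tab <- table(x, y)
  rz <- rowSums(tab) == 0
  cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin levels from the contingency table")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(0)
  unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic)
}

#' ReliefF feature weights
#'
#' Instance-based feature weighting for a binary outcome: features are
#' min-max scaled, and for each sampled instance the weight of a feature is
#' decreased by its mean distance to the k nearest same-class neighbours
#' (hits) and increased by its mean distance to the k nearest
#' opposite-class neighbours (misses). Weights lie in [-1, 1]; an
#' uninformative feature drifts toward 0, a class-aligned feature up.
#'
#' @param data \code{data.frame} of numeric features.
#' @param y Binary outcome.
#' @param k_neighbors Neighbours per class (clipped, with a warning, when a
#'   class is too small).
#' @param n_samples Instances sampled for the update (default: all rows, in
#'   which case the result is row-order invariant).
#' @param seed RNG seed used when subsampling.
#' @return Named numeric vector of feature weights.
#' @export
relieff <- function(data, y, k_neighbors = 10L, n_samples = nrow(data),
                    seed = 1L) {
  X <- as.matrix(data.frame(lapply(data, as.numeric)))
  n <- nrow(X)
  if (n == 0L) stop("ahprisk_ranking_error: empty input")
  if (k_neighbors < 1L) stop("ahprisk_ranking_error: k_neighbors must be >= 1")
  rng <- apply(X, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  Xs <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")
  cls <- as.integer(factor(y))
  kmax <- min(table(cls)) - 1L
  if (k_neighbors > kmax) {
    warning(sprintf("k_neighbors clipped from %d to %d (class size limit)",
                    k_neighbors, max(1L, kmax)))
    k_neighbors <- max(1L, kmax)
  }
  idx <- if (n_samples >= n) seq_len(n) else {
    set.seed(seed)
    sample.int(n, n_samples)
  }
  p <- ncol(Xs)
  W <- numeric(p)
  m <- length(idx)
  for (i in idx) {
    di <- rowSums(abs(sweep(Xs, 2, Xs[i, ], "-")))
    di[i] <- Inf
    same <- which(cls == cls[i])
    diff <- which(cls != cls[i])
    hits <- same[order(di[same])][seq_len(min(k_neighbors, sum(is.finite(di[same]))))]
    miss <- diff[order(di[diff])][seq_len(min(k_neighbors, length(diff)))]
    dh <- colMeans(abs(sweep(Xs[hits, , drop = FALSE], 2, Xs[i, ], "-")))
    dm <- colMeans(abs(sweep(Xs[miss, , drop = FALSE], 2, Xs[i, ], "-")))
    W <- W + (dm - dh) / m
  }
  stats::setNames(W, colnames(X))
}

#' Symmetric uncertainty
#'
#' \eqn{SU(x, y) = 2\,IG(x;y) / (H(x) + H(y))}, a normalized mutual
#' information in [0, 1].
#'
#' @inheritParams info_gain
#' @return Value in [0, 1]; 0 when both entropies vanish.
#' @export
symmetric_uncertainty <- function(x, y) {
  hx <- .entropy(x)
  hy <- .entropy(y)
  if (hx + hy == 0) return(0)
  2 * info_gain(x, y) / (hx + hy)
}

#' Fast correlation-based filter (FCBF)
#'
#' Ranks discretized features by symmetric uncertainty with the outcome,
#' keeps those at or above \code{su_threshold}, then walks the ranking and
#' removes every feature dominated by a predominant one: feature j is
#' redundant to an earlier-kept feature i when
#' \eqn{SU(x_i, x_j) \ge SU(x_j, y)}.
#'
#' @param data \code{data.frame} of discretized features.
#' @param y Binary outcome.
#' @param su_threshold Relevance threshold on SU(x, y); the default 0 keeps
#'   all features and prunes redundancy only.
#' @return \code{data.frame} with \code{feature}, \code{su}, and
#'   \code{selected} flag (unselected features kept for reporting).
#' @export
fcbf <- function(data, y, su_threshold = 0) {
  if (ncol(data) == 0L || length(y) == 0L)
    stop("ahprisk_ranking_error: empty input")
  su_y <- vapply(data, symmetric_uncertainty, numeric(1), y = y)
  ord <- order(-su_y, names(su_y))
  keep <- su_y >= su_threshold
  selected <- logical(length(su_y))
  names(selected) <- names(su_y)
  active <- names(su_y)[ord][keep[ord]]
  while (length(active)) {
    f <- active[1]
    selected[f] <- TRUE
    active <- active[-1]
    if (length(active)) {
      redundant <- vapply(active, function(g)
        symmetric_uncertainty(data[[f]], data[[g]]) >= su_y[[g]], logical(1))
      active <- active[!redundant]
    }
  }
  data.frame(feature = names(su_y), su = unname(su_y),
             selected = unname(selected), row.names = NULL)
}

#' Feature-ranking table over the six importance indicators
#'
#' Computes information gain, gain ratio, Gini reduction, chi-square,
#' ReliefF and FCBF symmetric uncertainty for every feature, plus each
#' feature's mean rank across the indicators (\code{ensemble_rank}).
#' Continuous features are discretized (equal-frequency bins) for the
#' entropy-based indicators; ReliefF sees the raw numeric values. FCBF
#' symmetric uncertainty is reported only for features the filter selects;
#' for the others the cell is NA and, like any undefined indicator value,
#' is excluded from that feature's mean rank rather than imputed.
#'
#' @param data \code{data.frame} of features.
#' @param y Binary outcome.
#' @param k_neighbors,relieff_samples,seed ReliefF controls.
#' @param su_threshold FCBF relevance threshold.
#' @param n_bins Equal-frequency bins used to discretize continuous
#'   features for entropy-based indicators.
#' @return \code{ranking_table}: data.frame with one row per feature, the
#'   six indicator columns and \code{ensemble_rank}, sorted best first.
#' @export
rank_features <- function(data, y, k_neighbors = 10L,
                          relieff_samples = nrow(data), seed = 1L,
                          su_threshold = 0, n_bins = 10L) {
  stopifnot(nrow(data) == length(y))
  disc <- as.data.frame(lapply(data, function(col) {
    if (is.numeric(col) && length(unique(col)) > n_bins) {
      cuts <- unique(stats::quantile(col, probs = seq(0, 1, length.out = n_bins + 1)))
      as.integer(cut(col, breaks = cuts, include.lowest = TRUE))
    } else col
  }))
  ig  <- vapply(disc, info_gain, numeric(1), y = y)
  gr  <- vapply(disc, gain_ratio, numeric(1), y = y)
  gg  <- vapply(disc, gini_gain, numeric(1), y = y)
  ch  <- vapply(disc, chi_square, numeric(1), y = y)
  rf  <- relieff(data, y, k_neighbors = k_neighbors,
                 n_samples = relieff_samples, seed = seed)
  fc  <- fcbf(disc, y, su_threshold = su_threshold)
  fcv <- ifelse(fc$selected, fc$su, NA_real_)
  names(fcv) <- fc$feature
  tab <- data.frame(
    feature = names(data),
    info_gain = unname(ig), gain_ratio = unname(gr), gini = unname(gg),
    chi2 = unname(ch), relieff = unname(rf[names(data)]),
    fcbf = unname(fcv[names(data)]), row.names = NULL)
  tab$ensemble_rank <- ensemble_rank(tab)
  tab <- tab[order(tab$ensemble_rank, tab$feature), ]
  rownames(tab) <- NULL
  class(tab) <- c("ranking_table", "data.frame")
  tab
}

#' Mean rank across importance indicators
#'
#' Ranks each indicator column (1 = best, midpoint ties) and averages the
#' ranks per feature, skipping NA indicator values.
#'
#' @param table \code{data.frame} with a \code{feature} column and one or
#'   more indicator columns among \code{info_gain}, \code{gain_ratio},
#'   \code{gini}, \code{chi2}, \code{relieff}, \code{fcbf}.
#' @return Numeric vector of mean ranks aligned to the table's rows.
#' @export
ensemble_rank <- function(table) {
  cols <- intersect(c("info_gain", "gain_ratio", "gini", "chi2",
                      "relieff", "fcbf"), names(table))
  if (!length(cols))
    stop("ahprisk_ranking_error: no indicator columns present")
  ranks <- vapply(cols, function(cn) {
    v <- table[[cn]]
    r <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    r[ok] <- rank(-v[ok], ties.method = "average")
    r
  }, numeric(nrow(table)))
  if (nrow(table) == 1L) ranks <- matrix(ranks, nrow = 1L)
  rowMeans(ranks, na.rm = TRUE)
}

#' Screen features by ensemble rank with expert overrides
#'
#' Keeps the top \code{keep_k} features by mean rank (deterministic
#' alphabetical tie-break), then unions the expert keep-list and removes
#' the expert drop-list — mirroring screening by machine ranking plus
#' clinical opinion.
#'
#' @param ranked A \code{ranking_table} (see \code{\link{rank_features}}).
#' @param keep_k Number of top-ranked features to keep (default 23).
#' @param expert_keep,expert_drop Character vectors of feature names.
#' @return Character vector of selected features.
#' @export
select_features <- function(ranked, keep_k = 23L,
                            expert_keep = character(), expert_drop = character()) {
  ord <- ranked$feature[order(ranked$ensemble_rank, ranked$feature)]
  top <- utils::head(ord, keep_k)
  setdiff(union(top, expert_keep), expert_drop)
}
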