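#' Wilson score confidence interval for a binomial proportion
#'
#' @param events Event count(s).
#' @param n Trial count(s).
#' @param confidence Coverage level in (0, 1).
#' @return Matrix with columns \code{low}, \code{high}.
#' @export
wilson_ci <- function(events, n, confidence = 0.95) {
  stopifnot(all(n > 0), all(events >= 0), all(events <= n),
            confidence > 0, confidence < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- events / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Event-rate profile of a continuous variable
#'
#' Grids the observed range of a continuous variable and reports, per
#' cell, the occupancy, event count, event rate and its Wilson interval —
#' the statistics behind density/event-rate visualizations of candidate
#' risk variables.
#'
#' @param x Numeric variable.
#' @param y Binary event flag.
#' @param grid_size Number of equal-width cells.
#' @param confidence Wilson interval level.
#' @return \code{data.frame} with \code{lo}, \code{hi}, \code{count},
#'   \code{events}, \code{rate}, \code{ci_low}, \code{ci_high}. All-equal
#'   \code{x} collapses to a single degenerate cell.
#' @export
event_rate_profile <- function(x, y, grid_size = 20L, confidence = 0.95) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(x) == 0L) stop("ahprisk_discretize_error: empty input")
  r <- range(x)
  if (r[1] == r[2]) {
    ci <- wilson_ci(sum(y), length(y), confidence)
    return(data.frame(lo = r[1], hi = r[2], count = length(x),
                      events = sum(y), rate = mean(y),
                      ci_low = ci[1], ci_high = ci[2]))
  }
  breaks <- seq(r[1], r[2], length.out = grid_size + 1L)
  cell <- as.integer(cut(x, breaks = breaks, include.lowest = TRUE))
  out <- do.call(rbind, lapply(seq_len(grid_size), function(k) {
    in_cell <- cell == k
    cnt <- sum(in_cell)
    ev <- sum(y[in_cell])
    if (cnt > 0) {
      ci <- wilson_ci(ev, cnt, confidence)
      data.frame(lo = breaks[k], hi = breaks[k + 1L], count = cnt,
                 events = ev, rate = ev / cnt,
                 ci_low = ci[1], ci_high = ci[2])
    } else {
      data.frame(lo = breaks[k], hi = breaks[k + 1L], count = 0L,
                 events = 0L, rate = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Supervised discretization by significance merging
#'
#' Splits a continuous variable into equal-frequency seed bins and merges
#' adjacent bins bottom-up while their event rates are statistically
#' indistinguishable — a pooled two-proportion z-test at the given
#' confidence level, most-similar pair first — so the final bins separate
#' regions whose event probabilities differ beyond sampling noise. Bins
#' smaller than \code{min_frac} of the data are merged into the neighbour
#' with the closer rate. Intervals are half-open \code{[lo, hi)} with the
#' last bin closed. Each bin reports its event rate with a Wilson interval
#' and carries a nomogram-style score: its log-odds relative to the
#' marginal event rate.
#'
#' @param x Numeric variable.
#' @param y Binary event flag.
#' @param confidence Confidence level of the merge test and the reported
#'   Wilson intervals.
#' @param min_frac Minimum fraction of rows per final bin, in (0, 0.5].
#' @param seed_bins Number of equal-frequency seed bins.
#' @param variable Variable name recorded in the scheme.
#' @return A \code{bin_scheme}: list with \code{variable}, \code{cuts}
#'   (interior cut points, strictly increasing), \code{range} and
#'   \code{levels} (per bin: \code{lo}, \code{hi}, \code{count},
#'   \code{events}, \code{rate}, \code{ci_low}, \code{ci_high},
#'   \code{log_odds}).
#' @export
supervised_discretize <- function(x, y, confidence = 0.95, min_frac = 0.05,
                                  seed_bins = 20L, variable = "x") {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)),
            confidence > 0, confidence < 1,
            min_frac > 0, min_frac <= 0.5)
  n <- length(x)
  if (n == 0L) stop("ahprisk_discretize_error: empty input")
  if (n * min_frac > n / 2 || n < 2 / min_frac) {
    warning("too few rows for the requested min_frac; returning a single bin")
    return(.finalize_scheme(variable, numeric(0), range(x), x, y, confidence))
  }
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = seed_bins + 1L),
                               type = 7))
  cuts <- qs[-c(1, length(qs))]
  cuts <- cuts[cuts > min(x) & cuts < max(x)]
  # family-wise merge test: the (1 - confidence) error budget is split
  # Bonferroni-style over the seed pairs AND the candidate cut windows the
  # refinement step can select within a pair (~ pairs^2 comparisons), so
  # the chance of any spurious surviving cut stays below 1 - confidence
  # even though refined cuts are maximally selected
  z_crit <- stats::qnorm(1 - (1 - confidence) / 2 / max(1L, length(cuts))^2)
  for (round in 1:5) {
    cuts <- .merge_cuts(x, y, cuts, z_crit, min_frac, n)
    refined <- .refine_cuts(x, y, cuts)
    if (isTRUE(all.equal(refined, cuts))) break
    cuts <- refined
  }
  cuts <- .merge_cuts(x, y, cuts, z_crit, min_frac, n)
  .finalize_scheme(variable, cuts, range(x), x, y, confidence)
}

# Bottom-up merging: drop the cut with the weakest adjacent two-proportion
# z statistic until every surviving cut separates rates beyond z_crit and
# every bin holds at least min_frac of the rows.
.merge_cuts <- function(x, y, cuts, z_crit, min_frac, n) {
  repeat {
    bin <- findInterval(x, cuts) + 1L   # half-open [lo, hi)
    k <- length(cuts) + 1L
    if (k == 1L) break
    cnt <- tabulate(bin, nbins = k)
    ev <- vapply(seq_len(k), function(b) sum(y[bin == b]), numeric(1))
    rate <- ev / pmax(cnt, 1)
    n1 <- cnt[-k]; n2 <- cnt[-1]
    p_pool <- (ev[-k] + ev[-1]) / pmax(n1 + n2, 1)
    v <- p_pool * (1 - p_pool) * (1 / pmax(n1, 1) + 1 / pmax(n2, 1))
    z <- ifelse(v > 0, abs(rate[-k] - rate[-1]) / sqrt(v), 0)
    small <- which(cnt < min_frac * n)
    if (length(small)) {
      b <- small[1]
      j <- if (b == 1L) 1L
           else if (b == k) k - 1L
           else if (abs(rate[b - 1] - rate[b]) <= abs(rate[b + 1] - rate[b])) b - 1L
           else b
      cuts <- cuts[-j]
    } else if (any(z < z_crit)) {
      cuts <- cuts[-which.min(z)]
    } else break
  }
  cuts
}

# Boundary refinement: each surviving cut is moved to the maximum-likelihood
# two-piece split of the data in its two flanking bins, so cuts inherited
# from the equal-frequency seed grid snap onto the true rate change points.
.refine_cuts <- function(x, y, cuts) {
  if (!length(cuts)) return(cuts)
  out <- cuts
  for (j in seq_along(cuts)) {
    lo <- if (j == 1L) -Inf else out[j - 1L]
    hi <- if (j == length(cuts)) Inf else cuts[j + 1L]
    sel <- x >= lo & x < hi
    xs <- x[sel]; ys <- y[sel]
    o <- order(xs)
    xs <- xs[o]; ys <- ys[o]
    m <- length(xs)
    if (m < 4L) next
    cum_e <- cumsum(ys)
    tot_e <- cum_e[m]
    i <- seq_len(m - 1L)
    # binomial log-likelihood of splitting after position i
    ll <- function(e, nn) {
      p <- e / nn
      ifelse(e > 0 & e < nn,
             e * log(p) + (nn - e) * log(1 - p), 0)
    }
    lik <- ll(cum_e[i], i) + ll(tot_e - cum_e[i], m - i)
    lik[xs[i + 1L] == xs[i]] <- -Inf   # no cut inside a tie group
    best <- which.max(lik)
    out[j] <- (xs[best] + xs[best + 1L]) / 2
  }
  sort(out)
}

.finalize_scheme <- function(variable, cuts, rng, x, y, confidence) {
  bin <- findInterval(x, cuts) + 1L
  k <- length(cuts) + 1L
  levels <- lapply(seq_len(k), function(b) {
    cnt <- sum(bin == b)
    ev <- sum(y[bin == b])
    rate <- if (cnt > 0) ev / cnt else NA_real_
    ci <- if (cnt > 0) wilson_ci(ev, cnt, confidence) else
      cbind(low = NA_real_, high = NA_real_)
    list(lo = if (b == 1L) rng[1] else cuts[b - 1L],
         hi = if (b == k) rng[2] else cuts[b],
         count = cnt, events = ev, rate = rate,
         ci_low = unname(ci[1, "low"]), ci_high = unname(ci[1, "high"]))
  })
  p0 <- mean(y)
  lodds <- function(p) log((p + 0.5 / max(1, length(y))) /
                           (1 - p + 0.5 / max(1, length(y))))
  for (b in seq_len(k))
    levels[[b]]$log_odds <- if (is.na(levels[[b]]$rate)) NA_real_ else
      lodds(levels[[b]]$rate) - lodds(p0)
  structure(list(variable = variable, cuts = as.numeric(cuts),
                 range = rng, confidence = confidence, levels = levels),
            class = "bin_scheme")
}

#' @method print bin_scheme
#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("Bin scheme for '%s': %d bin(s), half-open [lo, hi), last bin closed\n",
              x$variable, length(x$levels)))
  for (b in seq_along(x$levels)) {
    lv <- x$levels[[b]]
    cat(sprintf("  [%g, %g%s  n = %d, events = %d, rate = %.3f [%.3f, %.3f]\n",
                lv$lo, lv$hi, if (b == length(x$levels)) "]" else ")",
                lv$count, lv$events, lv$rate, lv$ci_low, lv$ci_high))
  }
  invisible(x)
}

#' Assign values to bins of a scheme
#'
#' Half-open convention: a value equal to a cut point falls in the upper
#' bin; values outside the training range clip to the end bins.
#'
#' @param scheme A \code{bin_scheme}.
#' @param x_new Numeric values.
#' @return Integer level indices in \code{1..length(scheme$levels)}.
#' @export
bin_assign <- function(scheme, x_new) {
  stopifnot(inherits(scheme, "bin_scheme"))
  findInterval(x_new, scheme$cuts) + 1L
}

#' Serialize / read a bin scheme as JSON
#'
#' @param scheme A \code{bin_scheme}.
#' @param path File path.
#' @export
write_bin_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bin_scheme
#' @export
read_bin_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$cuts <- as.numeric(x$cuts)
  x$range <- as.numeric(x$range)
  structure(x, class = "bin_scheme")
}
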