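# Saaty random-index table, orders 1..9. Order is capped at 9: the random
# index is tabulated for small matrices only and hierarchies are kept that
# narrow by construction.
.RI_TABLE <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45)

#' The admissible Saaty scale
#'
#' The 17 admissible entries of a quantized pairwise comparison matrix:
#' the integer grades 1..9 and their reciprocals.
#'
#' @return Numeric vector of length 17, sorted increasing.
#' @export
saaty_scale <- function() {
  sort(c(1 / (9:2), 1:9))
}

#' Numeric value of a Saaty importance judgement
#'
#' Maps a verbal importance grade to its value on the 1-9 comparison scale.
#' The named grades are \code{"equal"} (1), \code{"moderate"} (3),
#' \code{"essential"} (5), \code{"strong"} (7) and \code{"extreme"} (9);
#' \code{"intermediate"} with \code{n} in 1..4 gives the even grade
#' \code{2n}, lying between the odd grades \code{2n - 1} and \code{2n + 1}.
#'
#' @param grade Character scalar, one of the grades above.
#' @param n Integer in 1..4, required when \code{grade = "intermediate"}.
#' @return The scale value, a number in \code{1:9}.
#' @examples
#' saaty_value("equal")           # 1
#' saaty_value("strong")          # 7
#' saaty_value("intermediate", 2) # 4
#' @export
saaty_value <- function(grade, n = NULL) {
  grades <- c(equal = 1, moderate = 3, essential = 5, strong = 7, extreme = 9)
  if (!is.character(grade) || length(grade) != 1L)
    stop("ahprisk_grade_error: 'grade' must be a single character string")
  if (grade == "intermediate") {
    if (is.null(n) || !(n %in% 1:4))
      stop("ahprisk_grade_error: intermediate grade requires n in 1..4")
    return(2 * as.integer(n))
  }
  if (!grade %in% names(grades))
    stop(sprintf("ahprisk_grade_error: unknown importance grade '%s'", grade))
  unname(grades[[grade]])
}

#' Nearest admissible Saaty value
#'
#' Quantizes a positive ratio to the nearest member of the Saaty scale in
#' log-space, so that x and 1/x are treated symmetrically. Ties break toward
#' the smaller absolute grade (toward 1).
#'
#' @param x Positive numeric vector of ratios.
#' @return Numeric vector of the same length with entries on the Saaty scale.
#' @export
saaty_quantize <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  scale <- saaty_scale()
  vapply(x, function(xi) {
    d <- abs(log(scale) - log(xi))
    cand <- scale[d <= min(d) + 1e-12]
    # tie toward grade 1: the candidate with the smaller |log|
    cand[which.min(abs(log(cand)))]
  }, numeric(1))
}

#' Construct a pairwise comparison matrix
#'
#' Builds the reciprocal pairwise comparison matrix \eqn{A = (a_{ij})} with
#' \eqn{a_{ij} = w_i / w_j} from a weight vector, the automatic
#' initialization used to seed the hierarchy from machine-learned weights.
#' Unquantized output is perfectly consistent; with \code{quantize = TRUE}
#' every entry is snapped to the nearest admissible Saaty value
#' (\code{\link{saaty_quantize}}) while reciprocity is preserved.
#'
#' @param w Nonnegative weight vector, length 2..9. Normalized to sum 1;
#'   zero weights are floored at \code{weight_floor} before ratio formation.
#' @param quantize Snap entries to the Saaty scale?
#' @param weight_floor Floor applied to zero/near-zero weights.
#' @return A \code{pairwise_matrix}: a base matrix with class attribute.
#' @examples
#' matrix_from_weights(c(0.6, 0.3, 0.1))
#' matrix_from_weights(c(0.55, 0.30, 0.15), quantize = TRUE)
#' @export
matrix_from_weights <- function(w, quantize = FALSE, weight_floor = 1e-6) {
  if (length(w) < 2L)
    stop("ahprisk_matrix_error: need at least 2 weights")
  if (length(w) > 9L)
    stop("ahprisk_matrix_error: matrix order must not exceed 9")
  if (any(!is.finite(w)) || any(w < 0))
    stop("ahprisk_matrix_error: weights must be finite and nonnegative")
  if (all(w == 0))
    stop("ahprisk_matrix_error: all-zero weight vector")
  w <- pmax(w, weight_floor)
  w <- w / sum(w)
  A <- outer(w, w, "/")
  if (quantize) {
    n <- length(w)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        A[i, j] <- saaty_quantize(A[i, j])
        A[j, i] <- 1 / A[i, j]
      }
    }
    diag(A) <- 1
  }
  as_pairwise_matrix(A)
}

#' Validate and class a pairwise comparison matrix
#'
#' @param A Square positive matrix with unit diagonal and reciprocal entries.
#' @param tol Relative tolerance for the reciprocity check.
#' @return \code{A} with class \code{"pairwise_matrix"}.
#' @export
as_pairwise_matrix <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("ahprisk_matrix_error: matrix must be square")
  if (n < 2L || n > 9L)
    stop("ahprisk_matrix_error: order must be between 2 and 9")
  if (any(!is.finite(A)) || any(A <= 0))
    stop("ahprisk_matrix_error: entries must be finite and positive")
  if (any(abs(diag(A) - 1) > tol))
    stop("ahprisk_matrix_error: diagonal entries must equal 1")
  if (any(abs(A * t(A) - 1) > tol))
    stop("ahprisk_matrix_error: matrix is not reciprocal (a_ji != 1/a_ij)")
  structure(A, class = c("pairwise_matrix", "matrix", "array"))
}

#' Principal eigenvector weights of a pairwise comparison matrix
#'
#' Power iteration with L1-normalized iterates. The normalized principal
#' (Perron) eigenvector is the weight vector of the compared elements and
#' the principal eigenvalue \eqn{\lambda_{max}} feeds the consistency test;
#' \eqn{\lambda_{max} \ge n} for every reciprocal matrix, with equality
#' exactly when the matrix is consistent.
#'
#' @param A A \code{pairwise_matrix} (or coercible matrix).
#' @param tol Convergence tolerance on the L1 change of the iterate.
#' @param max_iter Maximum power-iteration steps.
#' @return List with \code{weights} (sums to 1), \code{lambda_max} and
#'   \code{iterations}.
#' @export
principal_weights <- function(A, tol = 1e-10, max_iter = 10000L) {
  A <- as_pairwise_matrix(A)
  n <- nrow(A)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    v <- as.vector(A %*% w)
    v <- v / sum(v)
    if (sum(abs(v - w)) < tol) {
      w <- v
      lam <- sum(A %*% w)  # w is L1-normalized, so sum(Aw) = lambda at the fixed point
      return(list(weights = w, lambda_max = lam, iterations = it))
    }
    w <- v
  }
  stop(sprintf(
    "ahprisk_convergence_error: power iteration did not converge in %d steps (last iterate: %s)",
    max_iter, paste(signif(w, 6), collapse = ", ")))
}

#' Lambda-max estimate from a matrix and a weight vector
#'
#' The classical consistency-check estimate
#' \eqn{\lambda_{max} = \frac{1}{n}\sum_i (AW)_i / W_i}: exact when the
#' matrix is consistent, and a cross-check on the power-iteration value
#' otherwise.
#'
#' @param A A \code{pairwise_matrix}.
#' @param W Positive weight vector aligned to the rows of \code{A}.
#' @return The scalar estimate.
#' @export
lambda_max_eq <- function(A, W) {
  A <- as_pairwise_matrix(A)
  if (length(W) != nrow(A))
    stop("ahprisk_matrix_error: weight vector length must match matrix order")
  if (any(W <= 0))
    stop("ahprisk_matrix_error: all weights must be strictly positive")
  mean(as.vector(A %*% W) / W)
}

#' Consistency index
#'
#' \eqn{CI = (\lambda_{max} - n) / (n - 1)}. Tiny negative values arising
#' from floating-point noise are clipped to zero; CI is zero exactly for a
#' consistent matrix.
#'
#' @param lambda_max Principal eigenvalue.
#' @param n Matrix order, at least 2.
#' @return Nonnegative scalar.
#' @export
consistency_index <- function(lambda_max, n) {
  if (n < 2L) stop("ahprisk_matrix_error: order must be at least 2")
  if (lambda_max < n - 1e-6)
    stop("ahprisk_matrix_error: lambda_max below matrix order; not a reciprocal matrix result")
  max(0, (lambda_max - n) / (n - 1))
}

#' Consistency ratio and acceptance report
#'
#' \eqn{CR = CI / RI} with the random index RI taken from Saaty's standard
#' table for orders up to 9. A matrix is acceptably consistent when
#' CR < 0.10; for orders 1-2 the random index is zero, CR is defined as 0
#' and the matrix is always acceptable (2x2 reciprocal matrices are
#' consistent by construction).
#'
#' @param ci Consistency index.
#' @param n Matrix order, 2..9.
#' @param lambda_max Optionally the eigenvalue the CI came from (reported).
#' @return A \code{consistency_report}: list with \code{lambda_max},
#'   \code{ci}, \code{ri}, \code{cr}, \code{acceptable}.
#' @export
consistency_ratio <- function(ci, n, lambda_max = ci * (n - 1) + n) {
  if (n < 2L) stop("ahprisk_matrix_error: order must be at least 2")
  if (n > 9L) stop("ahprisk_matrix_error: order must not exceed 9")
  ri <- .RI_TABLE[n]
  cr <- if (ri > 0) ci / ri else 0
  structure(
    list(lambda_max = lambda_max, ci = ci, ri = ri, cr = cr,
         acceptable = cr < 0.10, n = n),
    class = "consistency_report")
}

#' @method print consistency_report
#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf(
    "Consistency report (order %d): lambda_max = %.6f, CI = %.6f, RI = %.2f, CR = %.4f [%s]\n",
    x$n, x$lambda_max, x$ci, x$ri, x$cr,
    if (x$acceptable) "acceptable, CR < 0.10" else "NOT acceptable"))
  invisible(x)
}

#' Full consistency report for a matrix
#'
#' Convenience wrapper: power-iteration eigenvalue, CI and CR in one call.
#'
#' @param A A \code{pairwise_matrix}.
#' @return A \code{consistency_report}.
#' @export
consistency_report <- function(A) {
  A <- as_pairwise_matrix(A)
  pw <- principal_weights(A)
  ci <- consistency_index(pw$lambda_max, nrow(A))
  consistency_ratio(ci, nrow(A), lambda_max = pw$lambda_max)
}

.is_saaty_admissible <- function(A, tol = 1e-9) {
  all(vapply(as.vector(A), function(x) any(abs(x - saaty_scale()) < tol), logical(1)))
}

#' Repair an inconsistent pairwise comparison matrix
#'
#' Iterative consistency repair: while CR >= 0.10, the entry most at odds
#' with the current principal eigenvector (largest
#' \eqn{|\log(a_{ij} w_j / w_i)|}) is replaced by the admissible value
#' nearest \eqn{w_i / w_j}, reciprocity restored, and the test re-run.
#' Replacements stay on the Saaty scale whenever the input was
#' Saaty-admissible. Already-acceptable matrices are returned unchanged.
#'
#' @param A A \code{pairwise_matrix}.
#' @param max_iter Maximum repair rounds.
#' @return An acceptable \code{pairwise_matrix} (CR < 0.10).
#' @export
repair_matrix <- function(A, max_iter = 50L) {
  A <- as_pairwise_matrix(A)
  n <- nrow(A)
  quantized <- .is_saaty_admissible(A)
  rep0 <- consistency_report(A)
  if (rep0$acceptable) return(A)
  for (it in seq_len(max_iter)) {
    pw <- principal_weights(A)
    w <- pw$weights
    dev <- abs(log(A * outer(w, w, function(a, b) b / a)))
    dev[lower.tri(dev, diag = TRUE)] <- -Inf
    ord <- order(dev, decreasing = TRUE)
    changed <- FALSE
    for (idx in ord) {
      if (!is.finite(dev[idx])) break
      i <- (idx - 1L) %% n + 1L
      j <- (idx - 1L) %/% n + 1L
      target <- w[i] / w[j]
      newval <- if (quantized) saaty_quantize(target) else target
      if (abs(newval - A[i, j]) > 1e-12) {
        A[i, j] <- newval
        A[j, i] <- 1 / newval
        changed <- TRUE
        break
      }
    }
    if (!changed) break
    rep1 <- consistency_report(A)
    if (rep1$acceptable) return(as_pairwise_matrix(unclass(A)))
  }
  pw <- principal_weights(A)
  w <- pw$weights
  dev <- abs(log(A * outer(w, w, function(a, b) b / a)))
  dev[lower.tri(dev, diag = TRUE)] <- -Inf
  worst <- which(dev == max(dev), arr.ind = TRUE)[1, ]
  stop(sprintf(
    "ahprisk_repair_error: could not reach CR < 0.10 in %d rounds; worst entry a[%d,%d] = %.4g",
    max_iter, worst[1], worst[2], A[worst[1], worst[2]]))
}

#' Read / write a pairwise matrix as header-free CSV
#'
#' @param path File path.
#' @return For \code{read_pairwise_matrix}, a \code{pairwise_matrix}.
#' @export
read_pairwise_matrix <- function(path) {
  A <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(A) <- NULL
  as_pairwise_matrix(A)
}

#' @rdname read_pairwise_matrix
#' @param A Matrix to write.
#' @export
write_pairwise_matrix <- function(A, path) {
  utils::write.table(unclass(A), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
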