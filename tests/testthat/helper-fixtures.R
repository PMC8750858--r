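# Shared fixtures, all generated in code.

# The classic cyclically inconsistent 3x3 comparison matrix: a > b > c > a.
cyclic3 <- function() {
  as_pairwise_matrix(matrix(c(1, 3, 1/3,
                              1/3, 1, 3,
                              3, 1/3, 1), 3, 3, byrow = TRUE))
}

# Dense eigen-solver oracle for the principal eigenvalue / eigenvector.
eigen_oracle <- function(A) {
  e <- eigen(unclass(A))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  list(lambda_max = Re(e$values[i]), weights = v)
}

# Brute-force nearest Saaty value in log space (independent of the
# implementation's search).
saaty_nearest_oracle <- function(x) {
  scale <- sort(c(1 / (9:2), 1:9))
  d <- abs(log(scale) - log(x))
  cand <- scale[d == min(d)]
  cand[which.min(abs(log(cand)))]
}

# Seeded Dirichlet(1,...,1) weight vector.
rdirichlet1 <- function(n) {
  g <- stats::rexp(n)
  g / sum(g)
}

# O(n^2) concordance-count AUC oracle with half-credit ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Small two-group survival data with identical event processes.
null_surv_data <- function(n = 400, seed = 11) {
  set.seed(seed)
  data.frame(time = rexp(n, 0.1) + 0.01,
             event = rbinom(n, 1, 0.7),
             group = rep(0:1, length.out = n))
}
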