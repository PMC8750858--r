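test_that("Saaty grade values follow the 1-9 scheme", {
  expect_equal(saaty_value("equal"), 1)
  expect_equal(saaty_value("moderate"), 3)
  expect_equal(saaty_value("essential"), 5)
  expect_equal(saaty_value("strong"), 7)
  expect_equal(saaty_value("extreme"), 9)
  # intermediate grade 2n lies between 2n-1 and 2n+1
  for (n in 1:4) {
    v <- saaty_value("intermediate", n)
    expect_equal(v, 2 * n)
    expect_gt(v, 2 * n - 1)
    expect_lt(v, 2 * n + 1)
  }
  expect_error(saaty_value("sorta important"), "grade")
  expect_error(saaty_value("intermediate", 5), "grade")
})

test_that("quantization snaps to the nearest scale value in log space", {
  set.seed(101)
  ratios <- exp(runif(200, log(1 / 12), log(12)))
  for (x in ratios)
    expect_equal(saaty_quantize(x), saaty_nearest_oracle(x))
  # symmetry: quantize(1/x) == 1/quantize(x)
  for (x in ratios[1:50])
    expect_equal(saaty_quantize(1 / x), 1 / saaty_quantize(x), tolerance = 1e-12)
})

test_that("matrix_from_weights builds exact-ratio and quantized matrices", {
  expect_equal(unclass(matrix_from_weights(rep(1 / 3, 3))),
               matrix(1, 3, 3))
  A <- matrix_from_weights(c(0.6, 0.3, 0.1))
  expect_equal(A[1, 2], 2)
  expect_equal(A[1, 3], 6)
  expect_equal(A[2, 3], 3)
  Q <- matrix_from_weights(c(0.55, 0.30, 0.15), quantize = TRUE)
  w <- c(0.55, 0.30, 0.15)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(Q[i, j], saaty_nearest_oracle(w[i] / w[j]))
  expect_error(matrix_from_weights(0.5), "at least 2")
  expect_error(matrix_from_weights(c(0, 0, 0)), "all-zero")
  # zero weights floored, matrix stays finite and reciprocal
  F <- matrix_from_weights(c(0.7, 0.3, 0))
  expect_true(all(is.finite(F)))
  expect_equal(unclass(F * t(F)), matrix(1, 3, 3), tolerance = 1e-9)
})

test_that("reciprocity and unit diagonal hold after every constructor", {
  set.seed(7)
  for (r in 1:20) {
    n <- sample(2:7, 1)
    A <- matrix_from_weights(rdirichlet1(n), quantize = r %% 2 == 0)
    expect_equal(diag(unclass(A)), rep(1, n))
    expect_equal(unclass(A * t(A)), matrix(1, n, n), tolerance = 1e-9)
  }
})

test_that("principal_weights recovers generating weights on consistent matrices", {
  pw <- principal_weights(matrix_from_weights(c(0.6, 0.3, 0.1)))
  expect_equal(pw$weights, c(0.6, 0.3, 0.1), tolerance = 1e-9)
  expect_equal(pw$lambda_max, 3, tolerance = 1e-9)
  set.seed(42)
  for (r in 1:1000) {
    n <- sample(3:7, 1)
    w <- pmax(rdirichlet1(n), 1e-6)
    w <- w / sum(w)
    pw <- principal_weights(matrix_from_weights(w))
    expect_equal(pw$weights, w, tolerance = 1e-9)
    expect_equal(pw$lambda_max, n, tolerance = 1e-8)
  }
})

test_that("any 2x2 reciprocal matrix is consistent with lambda_max = 2", {
  for (a in c(1/7, 1/2, 1, 3, 9)) {
    A <- as_pairwise_matrix(matrix(c(1, a, 1 / a, 1), 2, 2, byrow = TRUE))
    expect_equal(principal_weights(A)$lambda_max, 2, tolerance = 1e-9)
    expect_true(consistency_report(A)$acceptable)
  }
})

test_that("power iteration agrees with the dense eigen oracle", {
  A <- cyclic3()
  o <- eigen_oracle(A)
  pw <- principal_weights(A)
  expect_equal(pw$lambda_max, o$lambda_max, tolerance = 1e-8)
  expect_equal(pw$weights, o$weights, tolerance = 1e-7)
  # lambda_max >= n on random Saaty matrices, equality iff consistent
  set.seed(13)
  scale <- saaty_scale()
  for (r in 1:100) {
    a12 <- sample(scale, 1); a13 <- sample(scale, 1); a23 <- sample(scale, 1)
    A <- as_pairwise_matrix(matrix(c(1, a12, a13,
                                     1 / a12, 1, a23,
                                     1 / a13, 1 / a23, 1), 3, 3, byrow = TRUE))
    lam <- principal_weights(A)$lambda_max
    expect_gte(lam, 3 - 1e-9)
    consistent <- abs(a13 - a12 * a23) < 1e-12
    if (consistent) expect_equal(lam, 3, tolerance = 1e-8)
    else expect_gt(lam, 3 + 1e-12)
  }
})

test_that("the lambda-max estimator matches the eigen solution", {
  A <- matrix_from_weights(c(0.5, 0.25, 0.25))
  expect_equal(lambda_max_eq(A, c(0.5, 0.25, 0.25)), 3)
  B <- as_pairwise_matrix(matrix(c(1, 3, 1/3, 1), 2, 2, byrow = TRUE))
  expect_equal(lambda_max_eq(B, c(0.75, 0.25)), 2)
  C <- cyclic3()
  o <- eigen_oracle(C)
  expect_equal(lambda_max_eq(C, o$weights), o$lambda_max, tolerance = 1e-6)
  expect_error(lambda_max_eq(A, c(0.5, 0.5, 0)), "positive")
})

test_that("consistency index and ratio implement the CI/CR definitions", {
  expect_equal(consistency_index(3, 3), 0)
  expect_equal(consistency_index(2, 2), 0)
  lam <- eigen_oracle(cyclic3())$lambda_max
  expect_equal(consistency_index(lam, 3), (lam - 3) / 2)
  expect_error(consistency_index(3, 1), "at least 2")

  rep0 <- consistency_ratio(0, 5)
  expect_equal(rep0$cr, 0)
  expect_true(rep0$acceptable)
  # CR just under the 10% rule is acceptable
  rep9 <- consistency_ratio(0.09 * 0.90, 4)
  expect_equal(rep9$cr, 0.09, tolerance = 1e-12)
  expect_true(rep9$acceptable)
  # cyclic 3x3: CR = CI / 0.58, rejected
  ci <- consistency_index(lam, 3)
  repc <- consistency_ratio(ci, 3, lambda_max = lam)
  expect_equal(repc$cr, ci / 0.58)
  expect_false(repc$acceptable)
  expect_error(consistency_ratio(0.1, 10), "exceed 9")
})

test_that("repair leaves acceptable matrices untouched and fixes the rest", {
  A <- matrix_from_weights(c(0.5, 0.3, 0.2))
  expect_equal(unclass(repair_matrix(A)), unclass(A))
  I2 <- as_pairwise_matrix(diag(2) + matrix(c(0, 1, 1, 0), 2, 2) - 0)
  expect_equal(unclass(repair_matrix(I2)), unclass(I2))

  R <- repair_matrix(cyclic3())
  rep <- consistency_report(R)
  expect_true(rep$acceptable)
  expect_equal(unclass(R * t(R)), matrix(1, 3, 3), tolerance = 1e-9)
  # Saaty-admissible input stays on the scale
  expect_true(all(vapply(as.vector(R), function(v)
    any(abs(v - saaty_scale()) < 1e-9), logical(1))))
})

test_that("repaired random quantized matrices always pass the CR test", {
  set.seed(99)
  for (r in 1:60) {
    n <- sample(3:7, 1)
    A <- matrix_from_weights(rdirichlet1(n), quantize = TRUE)
    R <- repair_matrix(A)
    expect_true(consistency_report(R)$acceptable)
  }
})

test_that("matrix CSV round-trip preserves entries", {
  A <- matrix_from_weights(c(0.55, 0.3, 0.15), quantize = TRUE)
  f <- tempfile(fileext = ".csv")
  write_pairwise_matrix(A, f)
  expect_equal(unclass(read_pairwise_matrix(f)), unclass(A), tolerance = 1e-12)
  unlink(f)
})
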