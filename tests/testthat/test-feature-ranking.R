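# Hand entropy oracle for a 2x2 layout: x in {0,1} with counts
# [[30,10],[10,30]] against y.
entropy2 <- function(p) ifelse(p %in% c(0, 1), 0, -p * log2(p) - (1 - p) * log2(1 - p))

make_2x2 <- function(counts) {
  # counts[i, j]: x = i-1, y = j-1
  x <- rep(c(0, 0, 1, 1), times = as.vector(t(counts)))
  y <- rep(c(0, 1, 0, 1), times = as.vector(t(counts)))
  list(x = x, y = y)
}

test_that("information gain matches direct entropy arithmetic", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(info_gain(y, y), 1.0)           # perfect balanced predictor
  expect_equal(info_gain(rep(1, 100), y), 0)   # constant x
  d <- make_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  # H(y) = 1 bit; H(y|x) = entropy of 10/40 in both halves
  expected <- 1 - entropy2(0.25)
  expect_equal(info_gain(d$x, d$y), expected, tolerance = 1e-12)
  expect_error(info_gain(numeric(0), numeric(0)), "empty")
})

test_that("gain ratio normalizes by feature entropy", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(gain_ratio(y, y), 1.0)
  expect_equal(gain_ratio(rep(1, 100), y), 0)
  d <- make_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(gain_ratio(d$x, d$y), (1 - entropy2(0.25)) / 1, tolerance = 1e-12)
})

test_that("gini reduction matches the impurity formula", {
  y <- rep(c(0, 1), each = 50)
  expect_equal(gini_gain(y, y), 0.5)           # perfect balanced predictor
  expect_equal(gini_gain(rep(1, 100), y), 0)
  d <- make_2x2(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expected <- 0.5 - (0.5 * 2 * 0.25 * 0.75 + 0.5 * 2 * 0.25 * 0.75)
  expect_equal(gini_gain(d$x, d$y), expected, tolerance = 1e-12)
})

test_that("chi-square equals the Pearson statistic", {
  d0 <- make_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(chi_square(d0$x, d0$y), 0)
  d1 <- make_2x2(matrix(c(20, 0, 0, 20), 2, byrow = TRUE))
  expect_equal(chi_square(d1$x, d1$y), 40)     # n * phi^2 with phi = 1
  # 2x3 table against the textbook formula
  x <- rep(c(0, 0, 0, 1, 1, 1), times = c(10, 20, 30, 30, 20, 10))
  y3 <- rep(c(0, 1, 2, 0, 1, 2), times = c(10, 20, 30, 30, 20, 10))
  O <- table(x, y3)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(chi_square(x, y3), sum((O - E)^2 / E), tolerance = 1e-10)
})

test_that("ReliefF separates informative from noise features", {
  set.seed(21)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  d <- data.frame(
    informative = y + rnorm(n, sd = 0.2),
    noise = rnorm(n),
    constant = rep(1, n))
  d$copy <- d$informative
  w <- relieff(d, y, k_neighbors = 10)
  expect_equal(unname(w["constant"]), 0)
  expect_gt(w[["informative"]], w[["noise"]])
  expect_equal(w[["informative"]], w[["copy"]], tolerance = 1e-9)
  expect_true(all(w >= -1 & w <= 1))
  # full-sample ReliefF is invariant to row shuffling
  set.seed(22)
  perm <- sample(n)
  w2 <- relieff(d[perm, ], y[perm], k_neighbors = 10)
  expect_equal(w2, w, tolerance = 1e-9)
  expect_warning(relieff(d[1:8, ], y[c(1:4, 151:154)], k_neighbors = 10),
                 "clipped")
})

test_that("symmetric uncertainty and FCBF behave on canonical cases", {
  set.seed(31)
  x <- sample(0:3, 200, replace = TRUE)
  expect_equal(symmetric_uncertainty(x, x), 1.0)
  y <- rep(c(0, 1), each = 100)
  d <- data.frame(informative = y,
                  noisy_copy = ifelse(runif(200) < 0.9, y, 1 - y),
                  noise = sample(0:1, 200, replace = TRUE))
  res <- fcbf(d, y)
  expect_true(res$selected[res$feature == "informative"])
  # the degraded copy is dominated by the informative feature
  expect_false(res$selected[res$feature == "noisy_copy"])
  # exact duplicate of a selected feature is removed as redundant
  d2 <- data.frame(a = y, b = y)
  r2 <- fcbf(d2, y)
  expect_equal(sum(r2$selected), 1L)
})

test_that("ensemble ranks average indicator ranks and break ties by name", {
  tab <- data.frame(feature = c("a", "b", "c"),
                    info_gain = c(0.3, 0.2, 0.1),
                    chi2 = c(30, 20, 10))
  expect_equal(ensemble_rank(tab), c(1, 2, 3))
  # exactly reversed indicators: all mean ranks equal
  tab2 <- data.frame(feature = c("a", "b", "c"),
                     info_gain = c(0.3, 0.2, 0.1),
                     chi2 = c(10, 20, 30))
  expect_equal(ensemble_rank(tab2), c(2, 2, 2))
  tab2$ensemble_rank <- ensemble_rank(tab2)
  expect_equal(select_features(tab2, keep_k = 3), c("a", "b", "c"))
  # NA cells are excluded from the mean, not imputed
  tab3 <- data.frame(feature = c("a", "b"),
                     info_gain = c(0.1, 0.2),
                     fcbf = c(NA, 0.5))
  expect_equal(ensemble_rank(tab3), c(2, 1))
})

test_that("feature screening honours keep-k and expert overrides", {
  tab <- data.frame(feature = letters[1:5],
                    info_gain = c(0.5, 0.4, 0.3, 0.2, 0.1))
  tab$ensemble_rank <- ensemble_rank(tab)
  expect_equal(select_features(tab, keep_k = 3), c("a", "b", "c"))
  expect_equal(select_features(tab, keep_k = 3, expert_drop = "a"),
               c("b", "c"))
  expect_setequal(select_features(tab, keep_k = 2, expert_keep = "e"),
                  c("a", "b", "e"))
  expect_setequal(
    select_features(tab, keep_k = 3, expert_keep = c("d", "e"),
                    expert_drop = c("b", "c")),
    c("a", "d", "e"))
})

test_that("ranking table satisfies the indicator bounds and flags a perfect predictor", {
  set.seed(41)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  d <- data.frame(perfect = y,
                  weak = ifelse(runif(n) < 0.7, y, 1 - y),
                  noise = rnorm(n))
  tab <- rank_features(d, y, seed = 1)
  expect_true(all(tab$info_gain >= 0))
  expect_true(all(tab$gain_ratio <= 1 + 1e-12))
  expect_true(all(tab$fcbf >= 0 & tab$fcbf <= 1, na.rm = TRUE))
  expect_equal(tab$feature[1], "perfect")
  p <- tab[tab$feature == "perfect", ]
  expect_equal(p$info_gain, 1)
  expect_equal(p$gain_ratio, 1)
  expect_equal(p$gini, 0.5)
  expect_equal(p$chi2, n)
})
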