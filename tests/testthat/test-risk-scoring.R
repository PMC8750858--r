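make_card <- function(weights, scores) {
  # hand-built scorecard: scores is a named list of named numeric vectors
  structure(list(
    weights = weights,
    levels = lapply(scores, function(s)
      list(labels = names(s), scores = s, majority = names(s)[1])),
    bins = list(), threshold = 0.5, outcome = "event",
    consistency = consistency_ratio(0, 3)), class = "risk_scorecard")
}

test_that("level scores are normalized log-odds over training levels", {
  # three levels with event rates 0.1 / 0.2 / 0.4, 1000 rows each
  lev <- rep(c("a", "b", "c"), each = 1000)
  y <- c(rbinom(0, 1, 0), rep(c(1, 0), c(100, 900)),
         rep(c(1, 0), c(200, 800)), rep(c(1, 0), c(400, 600)))
  h <- factor_hierarchy(list(
    name = "t", weights = 1,
    children = list(list(name = "c1", weights = 1,
                         children = list(list(name = "x"))))))
  d <- data.frame(x = lev, event = y)
  card <- build_scorecard(h, d, outcome = "event")
  s <- card$levels$x$scores
  logit <- function(p) log(p / (1 - p))
  mid <- (logit(0.2) - logit(0.1)) / (logit(0.4) - logit(0.1))
  expect_equal(unname(s[c("a", "b", "c")]), c(0, mid, 1), tolerance = 1e-2)
  expect_equal(sum(card$weights), 1)
})

test_that("binary leaf with equal level rates scores 0.5 everywhere after weighting", {
  card <- make_card(c(x = 1), list(x = c(`0` = 0.5, `1` = 0.5)))
  expect_equal(risk_score(card, data.frame(x = c(0, 1))), c(0.5, 0.5))
})

test_that("single-level leaves warn and score a constant 0.5", {
  h <- factor_hierarchy(list(
    name = "t", weights = 1,
    children = list(list(name = "c1", weights = 1,
                         children = list(list(name = "x"))))))
  d <- data.frame(x = rep("only", 50), event = rbinom(50, 1, 0.3))
  expect_warning(card <- build_scorecard(h, d), "single observed level")
  expect_equal(unname(risk_score(card, d)), rep(0.5, 50))
})

test_that("the risk score is the weighted sum of leaf level scores", {
  card <- make_card(
    c(f1 = 0.5, f2 = 0.3, f3 = 0.2),
    list(f1 = c(lo = 0, hi = 1), f2 = c(lo = 0, hi = 1),
         f3 = c(lo = 0, mid = 0.5, hi = 1)))
  rec <- data.frame(f1 = "hi", f2 = "lo", f3 = "mid")
  expect_equal(risk_score(card, rec), 0.5 * 1 + 0.3 * 0 + 0.2 * 0.5)
  # extreme records hit the bounds
  expect_equal(risk_score(card, data.frame(f1 = "lo", f2 = "lo", f3 = "lo")), 0)
  expect_equal(risk_score(card, data.frame(f1 = "hi", f2 = "hi", f3 = "hi")), 1)
  expect_error(risk_score(card, data.frame(f1 = "hi", f2 = "lo", f3 = "nope")),
               "unknown level.*f3")
  # monotonicity: raising one leaf level never lowers the score
  s_lo <- risk_score(card, data.frame(f1 = "lo", f2 = "lo", f3 = "lo"))
  s_hi <- risk_score(card, data.frame(f1 = "lo", f2 = "lo", f3 = "hi"))
  expect_gte(s_hi, s_lo)
})

test_that("missing leaf values impute the training-majority level with a warning", {
  card <- make_card(c(f1 = 0.6, f2 = 0.4),
                    list(f1 = c(lo = 0, hi = 1), f2 = c(lo = 0, hi = 1)))
  expect_warning(s <- risk_score(card, data.frame(f1 = "hi")), "imputed")
  expect_equal(unname(s), 0.6 * 1 + 0.4 * 0)   # f2 imputed to its majority "lo"
})

test_that("AUC equals the O(n^2) concordance oracle on small fixtures", {
  set.seed(71)
  for (r in 1:20) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), 2)   # rounding forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(evaluate_scores(scores, labels)$auc,
                 auc_oracle(scores, labels), tolerance = 1e-12)
  }
  s6 <- c(0.9, 0.8, 0.7, 0.4, 0.4, 0.1)
  l6 <- c(1, 0, 1, 1, 0, 0)
  expect_equal(evaluate_scores(s6, l6)$auc, auc_oracle(s6, l6))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(72)
  scores <- runif(500)
  labels <- rbinom(500, 1, plogis(3 * scores - 1.5))
  expect_equal(evaluate_scores(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("metrics hit the boundary cases and the accuracy-recall identity", {
  m <- evaluate_scores(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), threshold = 0.5)
  expect_equal(unlist(m[c("auc", "accuracy", "precision", "recall", "f1")]),
               c(auc = 1, accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # random scores: AUC near 1/2, accuracy == weighted recall always
  set.seed(73)
  scores <- runif(10000)
  labels <- rbinom(10000, 1, 0.5)
  m2 <- evaluate_scores(scores, labels, threshold = 0.5)
  expect_lt(abs(m2$auc - 0.5), 0.02)
  expect_equal(m2$accuracy, m2$recall)
  # identity holds for imbalanced classes and any threshold
  for (thr in c(0.2, 0.5, 0.8)) {
    lab <- rbinom(2000, 1, 0.15)
    sc <- runif(2000)
    m3 <- evaluate_scores(sc, lab, threshold = thr)
    expect_equal(m3$accuracy, m3$recall)
  }
  expect_error(evaluate_scores(runif(5), rep(1, 5)), "single-class")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(74)
  scores <- runif(300)
  labels <- rbinom(300, 1, scores)
  if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
  a0 <- evaluate_scores(scores, labels)$auc
  expect_equal(evaluate_scores(plogis(5 * scores - 2), labels)$auc, a0)
  expect_equal(evaluate_scores(scores^3, labels)$auc, a0)
})

test_that("threshold choice maximizes F1 with deterministic low tie-break", {
  # perfectly separated scores: the lowest separating candidate is returned
  s <- c(0.1, 0.2, 0.8, 0.9)
  l <- c(0, 0, 1, 1)
  thr <- choose_threshold(s, l)
  expect_equal(thr, 0.8)
  # brute-force grid oracle agreement on seeded cases
  set.seed(75)
  for (r in 1:100) {
    n <- sample(10:40, 1)
    sc <- round(runif(n), 2)
    lab <- rbinom(n, 1, 0.5)
    if (length(unique(lab)) < 2) next
    cand <- sort(unique(sc))
    f1 <- vapply(cand, function(t) evaluate_scores(sc, lab, t)$f1, numeric(1))
    expect_equal(choose_threshold(sc, lab), cand[which.max(f1)])
  }
  # monotone transform leaves the induced classification unchanged
  set.seed(76)
  sc <- runif(200); lab <- rbinom(200, 1, sc)
  t1 <- choose_threshold(sc, lab)
  t2 <- choose_threshold(sc^2, lab)
  expect_equal(sc >= t1, sc^2 >= t2)
})

test_that("stratified splitting preserves prevalence at the 2:1 ratio", {
  y <- rbinom(3000, 1, 0.2)
  sp <- train_test_split(y, seed = 5)
  expect_equal(length(sp$train) + length(sp$test), 3000)
  expect_equal(length(intersect(sp$train, sp$test)), 0L)
  expect_equal(length(sp$train) / 3000, 2 / 3, tolerance = 0.01)
  expect_equal(mean(y[sp$train]), mean(y[sp$test]), tolerance = 0.03)
})

test_that("propensity matching is 1:1 within the caliper without replacement", {
  set.seed(77)
  scores <- c(runif(300), runif(300))
  group <- rep(c(1, 0), each = 300)
  m <- propensity_match(scores, group)
  expect_false(any(duplicated(m$pairs$control)))
  expect_false(any(duplicated(m$pairs$case)))
  expect_gt(nrow(m$pairs), 250)
  expect_lt(abs(m$smd_after), 0.1)
  # disjoint ranges beyond the caliper give zero pairs
  s2 <- c(rep(0.1, 20), rep(0.9, 20))
  g2 <- rep(c(1, 0), each = 20)
  expect_warning(m2 <- propensity_match(s2, g2, caliper_sd = 0.1), "no matches")
  expect_equal(nrow(m2$pairs), 0L)
  expect_error(propensity_match(runif(5), rep(1, 5)), "non-empty")
})

test_that("shifted-Gaussian groups match to a small standardized difference", {
  set.seed(78)
  n <- 2000
  scores <- plogis(c(rnorm(n / 2, 0.3), rnorm(n / 2, 0)))
  group <- rep(c(1, 0), each = n / 2)
  m <- propensity_match(scores, group)
  expect_gt(abs(m$smd_before), abs(m$smd_after))
  expect_lt(abs(m$smd_after), 0.1)
})

test_that("baselines reach perfect metrics on separable data and reject unknown methods", {
  set.seed(79)
  n <- 240
  y <- rep(c(0, 1), each = n / 2)
  d <- data.frame(x = y + rnorm(n, sd = 0.05), event = y)
  sp <- train_test_split(d$event, seed = 2)
  res <- run_baselines(d[sp$train, ], d[sp$test, ],
                       configs = list(baseline_config("logistic_regression"),
                                      baseline_config("knn"),
                                      baseline_config("naive_bayes"),
                                      baseline_config("random_forest")),
                       seed = 3)
  for (mth in names(res)) {
    expect_equal(res[[mth]]$f1, 1.0)
    expect_equal(res[[mth]]$auc, 1.0)
  }
  expect_error(baseline_config("quantum_forest"), "unknown method")
  # harness identity: scoring the labels themselves is perfect
  mm <- evaluate_scores(as.numeric(y), y, threshold = 0.5)
  expect_equal(mm$precision, 1)
  expect_equal(mm$recall, 1)
})
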