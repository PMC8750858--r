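# Baseline classifier harness. The seven standard methods the risk model is
# compared against, each configured with the fixed hyper-parameter set of
# the comparison protocol: random forest (1000 trees, 5 attributes per
# split), single-hidden-layer neural network (100 neurons, weight-decay
# regularization), ridge logistic regression (C = 1), elastic-net logistic
# regression (the stochastic-gradient variant is mapped onto glmnet's
# coordinate-descent solver), kNN (K = 9, Euclidean, uniform weights),
# RBF-kernel SVM (C = 1, gamma = 0.1) and Gaussian naive Bayes.

#' Baseline method configurations
#'
#' @param method One of \code{"random_forest"}, \code{"neural_network"},
#'   \code{"logistic_regression"}, \code{"sgd"}, \code{"knn"},
#'   \code{"svm"}, \code{"naive_bayes"}.
#' @param ... Overrides of the default hyper-parameters.
#' @return A \code{baseline_config} list.
#' @export
baseline_config <- function(method, ...) {
  defaults <- list(
    random_forest       = list(ntree = 1000L, mtry = 5L),
    neural_network      = list(size = 100L, decay = 1e-4, maxit = 200L),
    logistic_regression = list(alpha = 0, C = 1),
    sgd                 = list(alpha = 0.5, epsilon = 0.1, maxit = 1000L),
    knn                 = list(k = 9L),
    svm                 = list(cost = 1, gamma = 0.1, maxit = 100L),
    naive_bayes         = list())
  if (!method %in% names(defaults))
    stop(sprintf("ahprisk_baseline_error: unknown method '%s'", method))
  cfg <- utils::modifyList(defaults[[method]], list(...))
  structure(c(list(method = method), cfg), class = "baseline_config")
}

.fit_predict_baseline <- function(cfg, X_train, y_train, X_test) {
  Xtr <- as.matrix(X_train)
  Xte <- as.matrix(X_test)
  if (ncol(Xtr) == 1L) {
    # glmnet needs >= 2 columns; pad with a constant that earns zero weight
    Xtr <- cbind(Xtr, .pad = 0)
    Xte <- cbind(Xte, .pad = 0)
  }
  yf <- factor(y_train, levels = c(0, 1))
  switch(cfg$method,
    random_forest = {
      fit <- randomForest::randomForest(
        x = Xtr, y = yf, ntree = cfg$ntree,
        mtry = min(cfg$mtry, ncol(Xtr)))
      stats::predict(fit, Xte, type = "prob")[, "1"]
    },
    neural_network = {
      fit <- nnet::nnet(x = Xtr, y = as.numeric(y_train), size = cfg$size,
                        decay = cfg$decay, maxit = cfg$maxit,
                        entropy = TRUE, MaxNWts = 1e5, trace = FALSE)
      as.vector(stats::predict(fit, Xte))
    },
    logistic_regression = {
      fit <- glmnet::glmnet(Xtr, yf, family = "binomial", alpha = cfg$alpha,
                            lambda = 1 / (cfg$C * nrow(Xtr)))
      as.vector(stats::predict(fit, Xte, type = "response"))
    },
    sgd = {
      fit <- glmnet::glmnet(Xtr, yf, family = "binomial", alpha = cfg$alpha,
                            lambda = cfg$epsilon / nrow(Xtr),
                            maxit = cfg$maxit * 100L)
      as.vector(stats::predict(fit, Xte, type = "response"))
    },
    knn = {
      pr <- class::knn(Xtr, Xte, cl = yf, k = cfg$k, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    svm = {
      fit <- e1071::svm(x = Xtr, y = yf, kernel = "radial", cost = cfg$cost,
                        gamma = cfg$gamma, probability = TRUE)
      attr(stats::predict(fit, Xte, probability = TRUE),
           "probabilities")[, "1"]
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(x = as.data.frame(Xtr), y = yf)
      stats::predict(fit, as.data.frame(Xte), type = "raw")[, "1"]
    },
    stop(sprintf("ahprisk_baseline_error: unknown method '%s'", cfg$method)))
}

#' Run baseline classifiers through the metric harness
#'
#' Fits each configured baseline on the training split, scores the test
#' split, chooses its F1-optimal threshold on the training predictions and
#' reports the shared metric set, so the risk model and every baseline are
#' judged by the identical harness.
#'
#' @param train,test \code{data.frame}s with the feature columns plus the
#'   outcome column.
#' @param configs List of \code{\link{baseline_config}}s (default: all
#'   seven methods).
#' @param outcome Name of the binary outcome column.
#' @param seed RNG seed (forest / network initialization).
#' @return Named list of \code{metric_report}s, one per method.
#' @export
run_baselines <- function(train, test,
                          configs = lapply(c("random_forest", "neural_network",
                                             "logistic_regression", "sgd",
                                             "knn", "svm", "naive_bayes"),
                                           baseline_config),
                          outcome = "event", seed = 1L) {
  stopifnot(outcome %in% names(train), outcome %in% names(test))
  feats <- setdiff(names(train), outcome)
  Xtr <- train[, feats, drop = FALSE]
  Xte <- test[, feats, drop = FALSE]
  ytr <- train[[outcome]]
  yte <- test[[outcome]]
  out <- list()
  for (cfg in configs) {
    set.seed(seed)
    p_all <- .fit_predict_baseline(cfg, Xtr, ytr, rbind(Xtr, Xte))
    p_tr <- p_all[seq_len(nrow(Xtr))]
    p_te <- p_all[-seq_len(nrow(Xtr))]
    thr <- choose_threshold(p_tr, ytr)
    out[[cfg$method]] <- evaluate_scores(p_te, yte, threshold = thr)
  }
  out
}
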