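#' Read a cohort CSV
#'
#' Typed read of a follow-up cohort table; empty strings and "NA" are
#' missing. The row count is logged.
#'
#' @param path CSV path.
#' @return \code{data.frame}.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("ahprisk_io_error: no such file: %s", path))
  d <- utils::read.csv(path, na.strings = c("", "NA"),
                       stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    stop(sprintf("ahprisk_io_error: empty cohort file: %s", path))
  message(sprintf("[read_cohort] %s: %d rows, %d columns", path, nrow(d), ncol(d)))
  d
}

#' Pipeline configuration
#'
#' @param cohort Path to a cohort CSV, or NULL to simulate one.
#' @param n Rows to simulate when \code{cohort} is NULL.
#' @param hierarchy Path to a hierarchy JSON/YAML, or NULL for the default.
#' @param outdir Output directory for all artifacts.
#' @param seed Master seed for the run.
#' @param split_ratio Train:test ratio.
#' @param keep_k Features kept by the ranking screen.
#' @param confidence Discretization Wilson level.
#' @param min_frac Minimum bin occupancy fraction.
#' @param run_apc Run the age-period-cohort stage?
#' @param run_baselines_stage Run the baseline-classifier comparison?
#' @param run_match Run propensity matching (cases vs controls on the
#'   compliance flag)?
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(cohort = NULL, n = 2000L, hierarchy = NULL,
                            outdir = tempfile("ahprisk_run_"), seed = 1L,
                            split_ratio = c(2, 1), keep_k = 23L,
                            confidence = 0.95, min_frac = 0.05,
                            run_apc = TRUE, run_baselines_stage = FALSE,
                            run_match = FALSE) {
  structure(list(cohort = cohort, n = as.integer(n), hierarchy = hierarchy,
                 outdir = outdir, seed = as.integer(seed),
                 split_ratio = split_ratio, keep_k = as.integer(keep_k),
                 confidence = confidence, min_frac = min_frac,
                 run_apc = isTRUE(run_apc),
                 run_baselines_stage = isTRUE(run_baselines_stage),
                 run_match = isTRUE(run_match)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file (.yaml/.yml/.json); fields as in
#'   \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("ahprisk_io_error: config must be .json, .yaml or .yml"))
  do.call(pipeline_config, x)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full risk-analysis pipeline
#'
#' Executes the stages simulate/load -> rank -> discretize -> cox -> apc ->
#' build-ahp -> score -> evaluate, persisting every intermediate artifact
#' (cohort CSV, ranking table, bin schemes, Cox table, hierarchy with
#' matrices and consistency reports, scorecard, metric reports) plus a
#' manifest with the configuration hash and seeds, so an identical
#' config + seed reproduces the run bit for bit. A stage failure halts the
#' run with the stage name; artifacts persisted so far remain on disk.
#'
#' @param cfg A \code{\link{pipeline_config}} (or path to one).
#' @return List with the fitted \code{\link{ahp_risk}} model, the cohort,
#'   stage artifacts and the manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  step <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(force(expr), error = function(e)
      stop(sprintf("ahprisk_pipeline_error at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  art <- function(...) file.path(cfg$outdir, ...)

  cohort <- step("simulate", {
    if (is.null(cfg$cohort)) {
      g <- generate_cohort(cohort_params(n = cfg$n, seed = cfg$seed))
      utils::write.csv(g$data, art("cohort.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(baseline_log_hazard = g$truth$baseline_log_hazard,
             realized_event_rate = g$truth$realized_event_rate,
             coefficients = as.list(g$truth$params$coefficients),
             seed = g$truth$params$seed),
        art("cohort_truth.json"), auto_unbox = TRUE, digits = NA)
      .stage_log("simulate", "generated %d rows (seed %d)", nrow(g$data), cfg$seed)
      g$data
    } else {
      d <- read_cohort(cfg$cohort)
      .stage_log("simulate", "loaded %d rows from %s", nrow(d), cfg$cohort)
      d
    }
  })

  hierarchy <- step("build-ahp", {
    if (is.null(cfg$hierarchy)) default_hierarchy()
    else read_hierarchy(cfg$hierarchy)
  })

  fit <- step("fit", ahp_risk(
    cohort, hierarchy = hierarchy, split_ratio = cfg$split_ratio,
    confidence = cfg$confidence, min_frac = cfg$min_frac, seed = cfg$seed))

  step("rank", {
    utils::write.csv(as.data.frame(fit$ranking), art("ranking_table.csv"),
                     row.names = FALSE)
    selected <- select_features(fit$ranking, keep_k = cfg$keep_k)
    writeLines(selected, art("selected_features.txt"))
    .stage_log("rank", "%d features ranked, %d selected",
               nrow(fit$ranking), length(selected))
  })

  step("discretize", {
    for (v in names(fit$bins))
      write_bin_scheme(fit$bins[[v]], art(sprintf("bins_%s.json", v)))
    .stage_log("discretize", "%d bin scheme(s) written", length(fit$bins))
  })

  step("cox", {
    utils::write.csv(cbind(variable = rownames(fit$cox),
                           as.data.frame(fit$cox)),
                     art("cox_table.csv"), row.names = FALSE)
    .stage_log("cox", "%d coefficients", nrow(fit$cox))
  })

  apc <- NULL
  if (cfg$run_apc) {
    apc <- step("apc", {
      grid <- apc_grid(cohort)
      utils::write.csv(grid, art("apc_grid.csv"), row.names = FALSE)
      m <- fit_apc(grid)
      per <- stats::aggregate(cbind(events, exposure) ~ period, grid, sum)
      per$rate <- per$events / per$exposure
      per$adjusted_rate <- period_adjust(per$rate, per$period, m)
      utils::write.csv(per, art("apc_period_rates.csv"), row.names = FALSE)
      .stage_log("apc", "grid %d cells, cohort variance %.5f",
                 nrow(grid), m$cohort_variance)
      m
    })
  } else {
    .stage_log("apc", "stage disabled")
  }

  step("score", {
    scorecard_json <- list(
      weights = as.list(fit$scorecard$weights),
      threshold = fit$threshold,
      consistency = fit$scorecard$consistency[c("ci", "ri", "cr", "acceptable")],
      levels = lapply(fit$scorecard$levels, function(l)
        list(labels = l$labels, scores = as.list(l$scores),
             majority = l$majority)))
    jsonlite::write_json(scorecard_json, art("scorecard.json"),
                         auto_unbox = TRUE, digits = NA)
    write_hierarchy(fit$hierarchy, art("hierarchy.json"))
    .stage_log("score", "scorecard over %d leaves, threshold %.4f",
               length(fit$scorecard$weights), fit$threshold)
  })

  baselines <- NULL
  if (cfg$run_baselines_stage) {
    baselines <- step("baselines", {
      leaves <- intersect(hierarchy_leaves(hierarchy), names(cohort))
      cols <- c(leaves, fit$outcome)
      run_baselines(cohort[fit$split$train, cols],
                    cohort[fit$split$test, cols],
                    outcome = fit$outcome, seed = cfg$seed)
    })
  }

  match_result <- NULL
  if (cfg$run_match && "compliance" %in% names(cohort)) {
    match_result <- step("match", {
      s <- predict(fit, cohort)
      propensity_match(s, cohort$compliance)
    })
  }

  metrics <- step("evaluate", {
    rows <- data.frame(
      method = "ahp_risk",
      split = c("train", "test"),
      auc = c(fit$metrics$train$auc, fit$metrics$test$auc),
      accuracy = c(fit$metrics$train$accuracy, fit$metrics$test$accuracy),
      precision = c(fit$metrics$train$precision, fit$metrics$test$precision),
      recall = c(fit$metrics$train$recall, fit$metrics$test$recall),
      f1 = c(fit$metrics$train$f1, fit$metrics$test$f1))
    if (!is.null(baselines)) {
      for (mth in names(baselines)) {
        b <- baselines[[mth]]
        rows <- rbind(rows, data.frame(
          method = mth, split = "test", auc = b$auc, accuracy = b$accuracy,
          precision = b$precision, recall = b$recall, f1 = b$f1))
      }
    }
    utils::write.csv(rows, art("metrics.csv"), row.names = FALSE)
    .stage_log("evaluate", "test AUC %.3f, F1 %.3f",
               fit$metrics$test$auc, fit$metrics$test$f1)
    rows
  })

  manifest <- step("manifest", {
    cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                                 null = "null")
    tmp <- tempfile()
    writeLines(as.character(cfg_json), tmp)
    m <- list(config = unclass(cfg),
              config_md5 = unname(tools::md5sum(tmp)),
              seed = cfg$seed, stages = stages,
              package_version = as.character(utils::packageVersion("ahprisk")),
              n_rows = nrow(cohort))
    unlink(tmp)
    jsonlite::write_json(m, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    m
  })

  list(fit = fit, cohort = cohort, apc = apc, baselines = baselines,
       match = match_result, metrics = metrics, manifest = manifest,
       outdir = cfg$outdir)
}
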