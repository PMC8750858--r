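#' Factor hierarchy for AHP risk scoring
#'
#' A rooted tree whose top node is the target ("risk score"), whose internal
#' nodes are criteria / sub-criteria, and whose leaves are factors bound to
#' dataset variables. Each internal node carries a local weight vector over
#' its children, usually derived from a pairwise comparison matrix.
#'
#' @param x A nested list: each node is \code{list(name =, children = list(...))}
#'   for internal nodes or \code{list(name =, variable =)} for leaves; internal
#'   nodes may carry \code{weights} (numeric over children) and/or
#'   \code{matrix} (row-major numeric vector or matrix).
#' @return The validated tree with class \code{"factor_hierarchy"}.
#' @export
factor_hierarchy <- function(x) {
  root <- .validate_node(x, depth = 0L)
  structure(root, class = "factor_hierarchy")
}

.validate_node <- function(node, depth) {
  if (is.null(node$name) || !nzchar(node$name))
    stop("ahprisk_hierarchy_error: every node needs a non-empty 'name'")
  if (!is.null(node$children) && length(node$children) > 0L) {
    k <- length(node$children)
    if (k > 9L)
      stop(sprintf(
        "ahprisk_hierarchy_error: node '%s' has %d children; at most 9 supported",
        node$name, k))
    node$children <- lapply(node$children, .validate_node, depth = depth + 1L)
    if (!is.null(node$matrix)) {
      m <- node$matrix
      if (!is.matrix(m)) m <- matrix(as.numeric(unlist(m)), nrow = k, byrow = TRUE)
      node$matrix <- as_pairwise_matrix(m)
    }
    if (!is.null(node$weights)) {
      w <- as.numeric(node$weights)
      if (length(w) != k || any(w < 0))
        stop(sprintf(
          "ahprisk_hierarchy_error: node '%s': weights must be %d nonnegative values",
          node$name, k))
      node$weights <- w / sum(w)
    }
  } else {
    if (is.null(node$variable)) node$variable <- node$name
    node$children <- NULL
  }
  node
}

#' Default risk-factor hierarchy
#'
#' The three-criterion hierarchy used throughout: a "risk score" target over
#' the main criteria Demography, Treatment and Disease course, each holding
#' the sub-criterion factors bound to the synthetic-cohort variables
#' (referral history stands in for prior risk events; calendar period
#' carries the annual-policy factor).
#'
#' @return A \code{factor_hierarchy}.
#' @export
default_hierarchy <- function() {
  leaf <- function(name, variable = name) list(name = name, variable = variable)
  factor_hierarchy(list(
    name = "risk score",
    children = list(
      list(name = "Demography", children = list(
        leaf("region"), leaf("age_rating"), leaf("gender"), leaf("education"),
        leaf("disability_rating"), leaf("social_function"),
        leaf("economic_status"))),
      list(name = "Treatment", children = list(
        leaf("adverse_reaction_times"), leaf("compliance"),
        leaf("drug_combination"), leaf("auxiliary_drug_combination"))),
      list(name = "Disease course", children = list(
        leaf("hospitalization_times"), leaf("referral_times"),
        leaf("annual_policy", "period_year"), leaf("course_duration"))))))
}

#' Leaf variables of a hierarchy
#'
#' @param h A \code{factor_hierarchy}.
#' @return Character vector of the dataset variables bound to the leaves,
#'   in depth-first order.
#' @export
hierarchy_leaves <- function(h) {
  walk <- function(node) {
    if (is.null(node$children)) return(node$variable)
    unlist(lapply(node$children, walk))
  }
  walk(h)
}

#' Seed hierarchy weights from per-leaf weights
#'
#' The automatic construction step: given a weight for every leaf factor
#' (typically Cox-derived, see \code{\link{cox_weight_seed}}), each internal
#' node's local weights are the normalized sums of the leaf weights beneath
#' each child. A pairwise comparison matrix is generated per internal node
#' from those local weights, optionally quantized to the Saaty scale and
#' consistency-repaired, and the node's stored weight vector is the
#' principal eigenvector of the final matrix.
#'
#' @param h A \code{factor_hierarchy}.
#' @param leaf_weights Named nonnegative numeric vector covering every leaf
#'   variable of \code{h}.
#' @param quantize Quantize generated matrices to the Saaty scale?
#' @param repair Run \code{\link{repair_matrix}} on unacceptable matrices?
#' @return The hierarchy with \code{matrix}, \code{weights} and
#'   \code{consistency} filled in at every internal node.
#' @export
set_hierarchy_weights <- function(h, leaf_weights, quantize = TRUE,
                                  repair = TRUE) {
  leaves <- hierarchy_leaves(h)
  missing <- setdiff(leaves, names(leaf_weights))
  if (length(missing))
    stop(sprintf("ahprisk_hierarchy_error: no weight for leaf(s): %s",
                 paste(missing, collapse = ", ")))
  leaf_sum <- function(node) {
    if (is.null(node$children)) return(unname(leaf_weights[[node$variable]]))
    sum(vapply(node$children, leaf_sum, numeric(1)))
  }
  fill <- function(node) {
    if (is.null(node$children)) return(node)
    node$children <- lapply(node$children, fill)
    local_w <- vapply(node$children, leaf_sum, numeric(1))
    if (length(local_w) == 1L) {
      node$weights <- 1
      node$consistency <- consistency_ratio(0, 2)
      return(node)
    }
    A <- matrix_from_weights(local_w, quantize = quantize)
    rep <- consistency_report(A)
    if (!rep$acceptable && repair) {
      A <- repair_matrix(A)
      rep <- consistency_report(A)
    }
    node$matrix <- A
    node$weights <- principal_weights(A)$weights
    node$consistency <- rep
    node
  }
  structure(fill(h), class = "factor_hierarchy")
}

#' Synthesize global leaf weights and the combination consistency test
#'
#' Combines the local weight vectors level by level down to the target:
#' each leaf's global weight is the product of the local weights along its
#' root path, and the globals sum to 1 (conservation). The combination
#' consistency test aggregates the per-matrix indices as
#' weighted-CI / weighted-RI, each internal node weighted by its own global
#' weight, with the same CR < 0.10 acceptance rule.
#'
#' @param h A \code{factor_hierarchy} whose internal nodes all carry local
#'   weights (see \code{\link{set_hierarchy_weights}}); nodes carrying a
#'   matrix must individually pass the consistency test.
#' @return List with \code{weights} (named vector over leaf variables,
#'   summing to 1) and \code{report} (a \code{consistency_report} for the
#'   combination test; \code{lambda_max} is not defined at the hierarchy
#'   level and is reported as NA).
#' @export
synthesize_global_weights <- function(h) {
  acc <- new.env(parent = emptyenv())
  acc$w <- numeric(0)
  acc$ci <- 0
  acc$ri <- 0
  walk <- function(node, g) {
    if (is.null(node$children)) {
      acc$w[node$variable] <- g
      return(invisible())
    }
    if (is.null(node$weights))
      stop(sprintf(
        "ahprisk_hierarchy_error: internal node '%s' has no local weights",
        node$name))
    rep <- if (!is.null(node$consistency)) node$consistency
           else if (!is.null(node$matrix)) consistency_report(node$matrix)
           else consistency_ratio(0, max(2L, length(node$children)))
    if (!rep$acceptable)
      stop(sprintf(
        "ahprisk_hierarchy_error: node '%s' fails the consistency test (CR = %.3f); repair it first",
        node$name, rep$cr))
    acc$ci <- acc$ci + g * rep$ci
    acc$ri <- acc$ri + g * rep$ri
    for (k in seq_along(node$children)) walk(node$children[[k]], g * node$weights[k])
  }
  walk(h, 1)
  cr <- if (acc$ri > 0) acc$ci / acc$ri else 0
  list(weights = acc$w,
       report = structure(
         list(lambda_max = NA_real_, ci = acc$ci, ri = acc$ri, cr = cr,
              acceptable = cr < 0.10, n = length(acc$w)),
         class = "consistency_report"))
}

#' Read / write a hierarchy configuration
#'
#' JSON or YAML (decided by file extension) nested tree
#' \code{{name, children[], weights?, matrix?}}; matrices serialized
#' row-major.
#'
#' @param path File path (.json, .yaml or .yml).
#' @return A \code{factor_hierarchy}.
#' @export
read_hierarchy <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("ahprisk_io_error: hierarchy config must be .json, .yaml or .yml"))
  factor_hierarchy(x)
}

#' @rdname read_hierarchy
#' @param h Hierarchy to write.
#' @export
write_hierarchy <- function(h, path) {
  strip <- function(node) {
    out <- list(name = node$name)
    if (!is.null(node$children)) {
      out$children <- lapply(node$children, strip)
      if (!is.null(node$weights)) out$weights <- as.numeric(node$weights)
      if (!is.null(node$matrix))
        out$matrix <- as.numeric(t(unclass(node$matrix)))
    } else out$variable <- node$variable
    out
  }
  ext <- tolower(tools::file_ext(path))
  x <- strip(h)
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @method print factor_hierarchy
#' @export
print.factor_hierarchy <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$children)) {
      cat(sprintf("%s- %s [%s]\n", pad, node$name, node$variable))
    } else {
      w <- if (is.null(node$weights)) "" else
        sprintf(" (weights: %s)", paste(sprintf("%.3f", node$weights), collapse = ", "))
      cat(sprintf("%s+ %s%s\n", pad, node$name, w))
      for (ch in node$children) show(ch, indent + 1L)
    }
  }
  show(x, 0L)
  invisible(x)
}
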