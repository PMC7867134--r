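# Out-of-distribution correction: distances of cohort samples to training
# class centroids, RBF-kernel similarity, and the dual
# confidence/similarity threshold defining ILC2-high calls.

#' Gate parameters
#'
#' @param gamma RBF bandwidth (> 0), or `NULL` to use the median
#'   heuristic ([median_heuristic_gamma()]) at run time.
#' @param tau_conf confidence threshold, strict (default 0.20).
#' @param tau_sim similarity threshold, strict (default 0.90).
#' @param similarity_rule `"max"` (nearest centroid, default) or
#'   `"ilc2"` (ILC2 centroid only).
#' @return list of class `GateParams`.
#' @export
gate_params <- function(gamma = NULL, tau_conf = 0.20, tau_sim = 0.90,
                        similarity_rule = c("max", "ilc2")) {
  similarity_rule <- match.arg(similarity_rule)
  stopifnot(tau_conf > 0, tau_conf < 1, tau_sim > 0, tau_sim < 1)
  if (!is.null(gamma)) stopifnot(gamma > 0)
  structure(list(gamma = gamma, tau_conf = tau_conf, tau_sim = tau_sim,
                 similarity_rule = similarity_rule),
            class = "GateParams")
}

#' Per-class centroids of the training data
#'
#' Arithmetic mean of the feature rows of each class over the signature
#' genes.
#'
#' @param train a [labeled_training_set()].
#' @return list of class `ClassCentroids` with elements `ilc2` (class 1)
#'   and `rest` (class 0), named numeric vectors in signature gene order.
#' @export
compute_centroids <- function(train) {
  stopifnot(inherits(train, "LabeledTrainingSet"))
  if (!any(train$labels == 1) || !any(train$labels == 0))
    stop("both classes are required to form centroids")
  structure(
    list(ilc2 = colMeans(train$features[train$labels == 1, , drop = FALSE]),
         rest = colMeans(train$features[train$labels == 0, , drop = FALSE])),
    class = "ClassCentroids")
}

#' Euclidean distance of a profile to each class centroid
#'
#' @param profile numeric vector over the signature genes (model gene
#'   order), or a samples x genes matrix.
#' @param centroids a `ClassCentroids`.
#' @return matrix with columns `ilc2` and `rest`, one row per profile.
#' @export
centroid_distance <- function(profile, centroids) {
  stopifnot(inherits(centroids, "ClassCentroids"))
  m <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1)
  if (ncol(m) != length(centroids$ilc2))
    stop(sprintf("profile length %d does not match signature length %d",
                 ncol(m), length(centroids$ilc2)))
  d <- cbind(
    ilc2 = sqrt(rowSums(sweep(m, 2, centroids$ilc2)^2)),
    rest = sqrt(rowSums(sweep(m, 2, centroids$rest)^2)))
  rownames(d) <- rownames(m)
  d
}

#' Median-heuristic RBF bandwidth
#'
#' sigma = median of all pairwise Euclidean distances among training
#' rows; gamma = 1 / (2 sigma^2). Deterministic.
#'
#' @param train a [labeled_training_set()] or a samples x genes matrix.
#' @return gamma (positive scalar).
#' @export
median_heuristic_gamma <- function(train) {
  feats <- if (inherits(train, "LabeledTrainingSet")) train$features
           else as.matrix(train)
  if (nrow(feats) < 2) stop("need at least 2 training samples")
  sigma <- stats::median(stats::dist(feats))
  if (sigma == 0)
    stop("all pairwise distances are zero; supply an explicit gamma")
  1 / (2 * sigma^2)
}

#' RBF similarity of a distance
#'
#' s = exp(-gamma d^2): 1 at distance 0, strictly decreasing in d.
#'
#' @param distance non-negative distance(s).
#' @param gamma positive bandwidth.
#' @return similarity in (0, 1].
#' @export
rbf_similarity <- function(distance, gamma) {
  if (any(distance < 0)) stop("distance must be non-negative")
  stopifnot(gamma > 0)
  exp(-gamma * distance^2)
}

#' Apply the dual confidence/similarity gate
#'
#' A sample is called ILC2-high iff confidence > tau_conf AND similarity
#' > tau_sim (both strict, following "greater than 20%" / "more than
#' 90%").
#'
#' @param confidences per-sample classifier confidence in \[0,1\].
#' @param similarities per-sample RBF similarity in \[0,1\].
#' @param params a [gate_params()].
#' @param sample_ids optional ids (defaults to names of `confidences`).
#' @return data.frame of class `gate_result`: `sample_id`, `confidence`,
#'   `similarity`, `call` (integer 0/1).
#' @export
gate_samples <- function(confidences, similarities, params = gate_params(),
                         sample_ids = names(confidences)) {
  if (length(confidences) != length(similarities))
    stop("confidence and similarity vectors differ in length")
  if (any(confidences < 0 | confidences > 1, na.rm = TRUE))
    stop("confidences outside [0,1]")
  if (any(similarities < 0 | similarities > 1, na.rm = TRUE))
    stop("similarities outside [0,1]")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_along(confidences))
  call <- as.integer(confidences > params$tau_conf &
                     similarities > params$tau_sim)
  msg("gate: %d / %d samples called ILC2-high (tau_conf = %g, tau_sim = %g)",
      sum(call), length(call), params$tau_conf, params$tau_sim)
  out <- data.frame(sample_id = sample_ids, confidence = confidences,
                    similarity = similarities, call = call,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gate_result", "data.frame")
  out
}

#' Full gate evaluation of a cohort against a trained model
#'
#' Convenience wrapper: confidences, centroid distances, similarities
#' (under `params$similarity_rule`) and calls in one table.
#'
#' @param model a `TrainedModel` (carries centroids).
#' @param cohort a `NormalizedMatrix` aligned to the model's signature.
#' @param params a [gate_params()]; if `params$gamma` is `NULL` the
#'   median heuristic on the training features is unavailable here, so an
#'   explicit `gamma` or a `train` set must be given.
#' @param train optional [labeled_training_set()] used only to derive the
#'   median-heuristic gamma.
#' @return data.frame: `sample_id`, `confidence`, `distance_ilc2`,
#'   `distance_rest`, `similarity`, `call`.
#' @export
gate_cohort <- function(model, cohort, params = gate_params(),
                        train = NULL) {
  feats <- cohort_features(cohort, model$signature_genes)
  gamma <- params$gamma
  if (is.null(gamma)) {
    if (is.null(train))
      stop("gamma is NULL: supply train= for the median heuristic or an explicit gamma")
    gamma <- median_heuristic_gamma(train)
  }
  conf <- sigmoid(model$bias + drop(feats %*% model$weights))
  d <- centroid_distance(feats, model$centroids)
  s_all <- rbf_similarity(d, gamma)
  sim <- if (params$similarity_rule == "ilc2") s_all[, "ilc2"]
         else apply(s_all, 1, max)
  res <- gate_samples(conf, sim, params, sample_ids = rownames(feats))
  data.frame(sample_id = res$sample_id, confidence = res$confidence,
             distance_ilc2 = d[, "ilc2"], distance_rest = d[, "rest"],
             similarity = res$similarity, call = res$call,
             row.names = NULL, stringsAsFactors = FALSE)
}
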