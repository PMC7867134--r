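# The ILC2-vs-rest classifier: an additive linear model fitted by rounds
# of boosting (cyclic coordinate descent) under binary logistic loss with
# L1 shrinkage — the "linear booster" configuration.

#' Labelled training set
#'
#' @param features samples x signature-genes numeric matrix of logCPM
#'   values; column order must equal the signature gene order.
#' @param labels binary vector, 1 = ILC2, 0 = any other ILC subset.
#' @param sample_ids character; defaults to rownames(features).
#' @return list of class `LabeledTrainingSet`.
#' @export
labeled_training_set <- function(features, labels,
                                 sample_ids = rownames(features)) {
  features <- as.matrix(features)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(features)))
  labels <- as.integer(labels)
  stopifnot(nrow(features) == length(labels),
            length(sample_ids) == nrow(features))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  rownames(features) <- sample_ids
  structure(list(features = features, labels = labels,
                 sample_ids = sample_ids),
            class = "LabeledTrainingSet")
}

#' Model hyperparameters
#'
#' Defaults reproduce the published training configuration: linear
#' booster, binary logistic objective, 3 boosting rounds, L1 penalty
#' 0.05, 70/30 train/test split. The learning rate (`eta`, not stated in
#' the source configuration) is pinned here so runs are reproducible.
#'
#' @param n_rounds boosting rounds (default 3).
#' @param l1_alpha L1 shrinkage per coordinate update (default 0.05).
#' @param train_fraction training fraction for [split_train_test()]
#'   (default 0.70).
#' @param seed integer RNG seed for the split.
#' @param eta learning rate of the coordinate updates (default 0.5).
#' @return list of class `ModelHyperparams`.
#' @export
model_hyperparams <- function(n_rounds = 3, l1_alpha = 0.05,
                              train_fraction = 0.70, seed = 1, eta = 0.5) {
  stopifnot(n_rounds >= 1, l1_alpha >= 0,
            train_fraction > 0, train_fraction < 1, eta > 0)
  structure(list(booster = "linear", objective = "binary-logistic",
                 n_rounds = as.integer(n_rounds), l1_alpha = l1_alpha,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 eta = eta),
            class = "ModelHyperparams")
}

#' Stratified train/test split
#'
#' Exhaustive, disjoint, stratified by label (both classes present on
#' both sides), deterministic given the seed. The total training size is
#' round(fraction * n); per-class quotas are apportioned by largest
#' remainder and clamped so each class keeps at least one sample per side.
#'
#' @param data a [labeled_training_set()].
#' @param fraction training fraction in (0,1).
#' @param seed integer seed.
#' @return list with elements `train` and `test`, both
#'   `LabeledTrainingSet`s.
#' @export
split_train_test <- function(data, fraction = 0.7, seed = 1) {
  stopifnot(inherits(data, "LabeledTrainingSet"),
            fraction > 0, fraction < 1)
  y <- data$labels
  if (any(table(y) < 2)) stop("each class needs at least 2 samples to split")
  n <- length(y)
  n_train <- round(fraction * n)
  cls <- sort(unique(y))
  quota <- fraction * tabulate(factor(y, levels = cls))
  base <- floor(quota)
  rem <- quota - base
  extra <- n_train - sum(base)
  if (extra > 0) {
    ord <- order(-rem, cls)   # largest remainder, class 0 first on ties
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  # both classes on both sides
  base <- pmin(pmax(base, 1), tabulate(factor(y, levels = cls)) - 1)
  idx_train <- integer(0)
  with_seed(seed, {
    for (k in seq_along(cls)) {
      members <- which(y == cls[k])
      idx_train <- c(idx_train, sample(members, base[k]))
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)
  subset_lts <- function(i)
    labeled_training_set(data$features[i, , drop = FALSE], y[i],
                         data$sample_ids[i])
  list(train = subset_lts(idx_train), test = subset_lts(idx_test))
}

#' Train the boosted L1-regularised linear classifier
#'
#' Fits margin(x) = bias + w.x by `n_rounds` boosting rounds. Each round
#' performs one Newton update of the unpenalised intercept and one cyclic
#' pass of coordinate updates over the gene weights: for gene j with
#' current predictions p, gradient g = sum((p - y) x_j) and Hessian
#' h = sum(p (1 - p) x_j^2), the proposed weight solves the
#' soft-thresholded quadratic subproblem with L1 penalty `l1_alpha` and
#' is applied with learning rate `eta`. As l1_alpha grows all weights
#' shrink to exactly 0.
#'
#' @param train a [labeled_training_set()].
#' @param hp a [model_hyperparams()].
#' @param signature optional `SignatureGeneSet` recorded in the model
#'   (defaults to the feature column names).
#' @return list of class `TrainedModel`: `weights` (named), `bias`,
#'   `hyperparams`, `signature_genes`, `centroids` (see
#'   [compute_centroids()]).
#' @export
train_boosted_linear <- function(train, hp = model_hyperparams(),
                                 signature = NULL) {
  stopifnot(inherits(train, "LabeledTrainingSet"),
            inherits(hp, "ModelHyperparams"))
  X0 <- train$features
  y <- train$labels
  if (!all(is.finite(X0))) stop("non-finite feature values")
  # optimise on centred features for conditioning; the centring is folded
  # back into the intercept below, so the model family is unchanged
  ctr <- colMeans(X0)
  X <- sweep(X0, 2, ctr)
  p <- ncol(X)
  w <- numeric(p)
  bias <- 0
  margin <- numeric(nrow(X))
  for (r in seq_len(hp$n_rounds)) {
    # unpenalised intercept, one Newton step
    pr <- sigmoid(margin)
    h0 <- sum(pr * (1 - pr)) + 1e-10
    db <- hp$eta * (-sum(pr - y) / h0)
    bias <- bias + db
    margin <- margin + db
    for (j in seq_len(p)) {
      xj <- X[, j]
      pr <- sigmoid(margin)
      g <- sum((pr - y) * xj)
      h <- sum(pr * (1 - pr) * xj^2) + 1e-10
      z <- w[j] * h - g
      w_new <- if (z > hp$l1_alpha) (z - hp$l1_alpha) / h
               else if (z < -hp$l1_alpha) (z + hp$l1_alpha) / h
               else 0
      dw <- hp$eta * (w_new - w[j])
      if (dw != 0) {
        w[j] <- w[j] + dw
        margin <- margin + dw * xj
      }
    }
  }
  bias <- bias - sum(w * ctr)
  sig_genes <- if (!is.null(signature)) signature$gene_ids else colnames(X0)
  structure(list(weights = stats::setNames(w, colnames(X0)), bias = bias,
                 hyperparams = hp, signature_genes = sig_genes,
                 centroids = compute_centroids(train)),
            class = "TrainedModel")
}

#' Predict per-sample ILC2 confidence scores
#'
#' confidence = logistic(bias + w.x), the raw class-1 probability.
#'
#' @param model a `TrainedModel`.
#' @param x a `NormalizedMatrix` aligned to the model's signature gene
#'   order, or a samples x genes matrix with matching column names.
#' @return named numeric vector of confidences in (0,1).
#' @export
predict_confidence <- function(model, x) {
  stopifnot(inherits(model, "TrainedModel"))
  feats <- cohort_features(x, model$signature_genes)
  stats::setNames(sigmoid(model$bias + drop(feats %*% model$weights)),
                  rownames(feats))
}

#' @keywords internal
cohort_features <- function(x, genes) {
  feats <- if (inherits(x, "NormalizedMatrix")) t(x$values)
           else if (inherits(x, "LabeledTrainingSet")) x$features
           else as.matrix(x)
  if (is.null(colnames(feats)) || !identical(colnames(feats), genes))
    stop("gene space mismatch: align the cohort to the model's signature ",
         "gene order first (see align_genes())")
  feats
}

#' Evaluate a model on held-out data
#'
#' Accuracy at a 0.5 decision threshold plus the confusion counts.
#'
#' @param model a `TrainedModel`.
#' @param test a [labeled_training_set()].
#' @return list: `accuracy`, `confusion` (tp, fp, tn, fn), `n`.
#' @export
evaluate_holdout <- function(model, test) {
  stopifnot(inherits(test, "LabeledTrainingSet"))
  conf <- predict_confidence(model, test$features)
  pred <- as.integer(conf > 0.5)
  y <- test$labels
  list(accuracy = mean(pred == y),
       confusion = c(tp = sum(pred == 1 & y == 1),
                     fp = sum(pred == 1 & y == 0),
                     tn = sum(pred == 0 & y == 0),
                     fn = sum(pred == 0 & y == 1)),
       n = length(y))
}

#' Serialise / load a trained model (JSON)
#'
#' Full-precision JSON so a save/load round trip predicts bit-identically.
#'
#' @param model a `TrainedModel`.
#' @param path file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   `TrainedModel`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "TrainedModel"))
  obj <- list(weights = as.list(model$weights), bias = model$bias,
              hyperparams = unclass(model$hyperparams),
              signature_genes = model$signature_genes,
              centroids = list(ilc2 = as.list(model$centroids$ilc2),
                               rest = as.list(model$centroids$rest)))
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly,
  # so load_model() reproduces predictions bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- do.call(model_hyperparams,
                obj$hyperparams[c("n_rounds", "l1_alpha", "train_fraction",
                                  "seed", "eta")])
  structure(list(weights = unlist(obj$weights), bias = obj$bias,
                 hyperparams = hp, signature_genes = obj$signature_genes,
                 centroids = structure(list(ilc2 = unlist(obj$centroids$ilc2),
                                            rest = unlist(obj$centroids$rest)),
                                       class = "ClassCentroids")),
            class = "TrainedModel")
}
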