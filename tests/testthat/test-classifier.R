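toy_lts <- function(n_per_class = 5, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * p), n_per_class, p),
             matrix(rnorm(n_per_class * p, mean = sep), n_per_class, p))
  colnames(X) <- paste0("g", seq_len(p))
  labeled_training_set(X, rep(0:1, each = n_per_class))
}

test_that("stratified split honours fraction, classes and determinism", {
  lts <- toy_lts(5)
  sp <- split_train_test(lts, 0.7, seed = 42)
  expect_equal(length(sp$train$labels), 7)
  expect_equal(length(sp$test$labels), 3)
  expect_setequal(unique(sp$train$labels), 0:1)
  expect_setequal(unique(sp$test$labels), 0:1)
  sp2 <- split_train_test(lts, 0.7, seed = 42)
  expect_identical(sp$train$sample_ids, sp2$train$sample_ids)

  # 4 samples (2/2), fraction 0.5 -> one of each class per side
  lts4 <- toy_lts(2)
  sp4 <- split_train_test(lts4, 0.5, seed = 1)
  expect_equal(sort(sp4$train$labels), 0:1)
  expect_equal(sort(sp4$test$labels), 0:1)

  expect_error(split_train_test(
    labeled_training_set(matrix(rnorm(8), 4, 2,
                                dimnames = list(NULL, c("a", "b"))),
                         c(0, 0, 0, 1)), 0.5, 1),
    "at least 2")
})

test_that("split is an exhaustive disjoint partition across seeds", {
  lts <- toy_lts(8)
  for (seed in 1:30) {
    sp <- split_train_test(lts, 0.7, seed)
    ids <- c(sp$train$sample_ids, sp$test$sample_ids)
    expect_setequal(ids, lts$sample_ids)
    expect_equal(anyDuplicated(ids), 0)
  }
})

test_that("well-separated classes are learned; permuted labels are not", {
  accs <- perm_hits <- perm_n <- numeric(3)
  for (k in 1:3) {
    cfg <- sim_config(n_genes = 500, n_signature_genes = 50,
                      panel_size = 60, n_ref_samples = 100,
                      effect_size = 3, seed = 400 + k)
    lts <- sim_training_features(cfg)$lts
    sp <- split_train_test(lts, 0.7, seed = k)
    model <- train_boosted_linear(sp$train, model_hyperparams())
    accs[k] <- evaluate_holdout(model, sp$test)$accuracy

    set.seed(k)
    plts <- labeled_training_set(lts$features, sample(lts$labels),
                                 lts$sample_ids)
    psp <- split_train_test(plts, 0.7, seed = k)
    pm <- train_boosted_linear(psp$train, model_hyperparams())
    pe <- evaluate_holdout(pm, psp$test)
    perm_hits[k] <- pe$accuracy * pe$n
    perm_n[k] <- pe$n
  }
  expect_gte(mean(accs), 0.95)
  # pooled permuted accuracy inside the central 95% binomial band at 0.5
  n <- sum(perm_n)
  band <- 1.96 * sqrt(0.25 / n)
  expect_lt(abs(sum(perm_hits) / n - 0.5), band + 1e-12)
})

test_that("infinite L1 collapses all weights; confidences go flat", {
  lts <- toy_lts(20, p = 6, sep = 2)
  m <- train_boosted_linear(lts, model_hyperparams(l1_alpha = 1e6))
  expect_true(all(m$weights == 0))
  conf <- predict_confidence(m, lts$features)
  expect_equal(max(conf) - min(conf), 0)
})

test_that("total |weights| is non-increasing in l1_alpha", {
  lts <- toy_lts(30, p = 8, sep = 1.5, seed = 3)
  tot <- vapply(c(0, 0.05, 0.5, 5, 50, 1e3),
                function(a) sum(abs(train_boosted_linear(
                  lts, model_hyperparams(l1_alpha = a))$weights)),
                numeric(1))
  expect_true(all(diff(tot) <= 1e-8))
})

test_that("prediction contracts: logistic identities, alignment, order", {
  lts <- toy_lts(10, p = 3, sep = 2, seed = 5)
  m <- train_boosted_linear(lts, model_hyperparams())
  m0 <- m; m0$weights[] <- 0; m0$bias <- 0
  expect_equal(unname(predict_confidence(m0, lts$features)),
               rep(0.5, 20))
  m0$bias <- 50
  expect_equal(unname(predict_confidence(m0, lts$features)),
               rep(1, 20), tolerance = 1e-15)

  bad <- lts$features[, c(2, 1, 3)]
  expect_error(predict_confidence(m, bad), "align")

  conf <- predict_confidence(m, lts$features)
  perm <- sample(nrow(lts$features))
  expect_equal(unname(predict_confidence(m, lts$features[perm, ])),
               unname(conf[perm]))
  expect_error(train_boosted_linear(
    labeled_training_set(matrix(c(1, NA, 2, Inf, 0, 1), 3, 2,
                                dimnames = list(NULL, c("a", "b"))),
                         c(0, 1, 1)),
    model_hyperparams()), "finite")
})

test_that("holdout evaluation equals an independent tally", {
  lts <- toy_lts(15, p = 5, sep = 3, seed = 7)
  sp <- split_train_test(lts, 0.7, 1)
  m <- train_boosted_linear(sp$train, model_hyperparams())
  ev <- evaluate_holdout(m, sp$test)
  conf <- predict_confidence(m, sp$test$features)
  manual <- sum((conf > 0.5) == (sp$test$labels == 1)) / length(conf)
  expect_equal(ev$accuracy, manual)
  expect_equal(sum(ev$confusion), ev$n)
  expect_equal(ev$confusion[["tp"]] + ev$confusion[["fn"]],
               sum(sp$test$labels))
})

test_that("model serialisation round-trips bit-identically", {
  lts <- toy_lts(12, p = 6, sep = 2, seed = 9)
  m <- train_boosted_linear(lts, model_hyperparams(seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(unname(m2$weights), unname(m$weights))
  expect_identical(m2$bias, m$bias)
  expect_identical(predict_confidence(m2, lts$features),
                   predict_confidence(m, lts$features))
  expect_equal(m2$centroids$ilc2, m$centroids$ilc2)
})
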