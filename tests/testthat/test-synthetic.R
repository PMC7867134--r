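small_cfg <- function(...) {
  defaults <- list(n_genes = 400, n_signature_genes = 40, panel_size = 80,
                   n_ref_samples = 15, n_cells = 40, n_patients = 60,
                   seed = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("generators are bit-reproducible and produce valid matrices", {
  cfg <- small_cfg()
  expect_identical(simulate_reference(cfg)$matrix$counts,
                   simulate_reference(cfg)$matrix$counts)
  expect_identical(simulate_sc_source(cfg)$matrix$counts,
                   simulate_sc_source(cfg)$matrix$counts)
  co1 <- simulate_cohort(cfg); co2 <- simulate_cohort(cfg)
  expect_identical(co1$matrix$counts, co2$matrix$counts)
  expect_identical(co1$clinical$time, co2$clinical$time)
  # invariants enforced by the constructor
  expect_s3_class(co1$matrix, "ExpressionMatrix")
  expect_true(all(co1$matrix$counts >= 0))
  # different seeds differ
  expect_false(identical(co1$matrix$counts,
                         simulate_cohort(small_cfg(seed = 2))$matrix$counts))
})

test_that("effect_size = 0 leaves signature genes null; 3 separates classes", {
  cfg <- small_cfg(effect_size = 0, n_ref_samples = 30)
  ref <- simulate_reference(cfg)
  nm <- suppressMessages(normalize_counts(ref$matrix))
  v <- nm$values[match(ref$signature_genes, nm$gene_ids), ]
  tstats <- apply(v, 1, function(row) {
    t.test(row[ref$labels == 1], row[ref$labels == 0])$statistic
  })
  # per-gene t statistics centred on zero (location test at alpha 0.01)
  expect_gt(t.test(tstats)$p.value, 0.01)

  acc <- vapply(1:3, function(k) {
    c3 <- small_cfg(effect_size = 3, n_ref_samples = 30, seed = 700 + k)
    lts <- sim_training_features(c3)$lts
    sp <- split_train_test(lts, 0.7, k)
    evaluate_holdout(train_boosted_linear(sp$train, model_hyperparams()),
                     sp$test)$accuracy
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("planted fraction arithmetic mirrors the cohort bookkeeping", {
  cfg <- sim_config(n_genes = 50, n_signature_genes = 5, panel_size = 10,
                    n_patients = 518, pi_infiltrated = 0.278, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$truth), 144)
  expect_error(simulate_cohort(small_cfg(n_patients = 2,
                                         pi_infiltrated = 0.1)),
               "nothing to plant")
  expect_error(small_cfg(effect_size = -1), "non-negative")
})

test_that("censoring behaves as configured", {
  co0 <- simulate_cohort(small_cfg(censor_rate = 0, n_patients = 200))
  expect_true(all(co0$clinical$event == 1))
  co3 <- simulate_cohort(small_cfg(censor_rate = 0.3, n_patients = 400,
                                   seed = 11))
  er <- mean(co3$clinical$event)
  expect_lt(abs(er - 0.7), 3 * sqrt(0.3 * 0.7 / 400))
})

test_that("true_hr = 1 gives a null log-rank on truth labels", {
  ps <- vapply(1:40, function(k) {
    co <- simulate_cohort(small_cfg(n_genes = 40, n_signature_genes = 4,
                                    panel_size = 8, true_hr = 1,
                                    pi_infiltrated = 0.5,
                                    n_patients = 80, seed = 800 + k))
    logrank_test(co$clinical$time, co$clinical$event, co$truth)$p_value
  }, numeric(1))
  # roughly uniform: mean near 0.5 and no pile-up below 0.05
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("increasing domain shift monotonically lowers gate similarity", {
  for (seed in c(31, 32, 33)) {
    cfg0 <- small_cfg(n_signature_genes = 120, n_genes = 600,
                      panel_size = 150, n_ref_samples = 20,
                      n_patients = 30, seed = seed)
    tr <- sim_training_features(cfg0)
    gamma <- median_heuristic_gamma(tr$lts)
    cen <- compute_centroids(tr$lts)
    mean_sim <- vapply(c(0, 0.3, 0.6, 1.0), function(ds) {
      cfg <- small_cfg(n_signature_genes = 120, n_genes = 600,
                       panel_size = 150, n_ref_samples = 20,
                       n_patients = 30, seed = seed, domain_shift = ds)
      ch <- sim_cohort_features(cfg, tr$signature_genes)
      mean(apply(rbf_similarity(centroid_distance(ch$features, cen), gamma),
                 1, max))
    }, numeric(1))
    expect_true(all(diff(mean_sim) < 0))
  }
})

test_that("write_simulation emits a loadable, consistent input set", {
  d <- withr::local_tempdir()
  paths <- write_simulation(small_cfg(seed = 5), d)
  expect_true(all(file.exists(paths)))
  ref <- load_counts_matrix(paths["ref_counts"])
  expect_equal(dim(ref$counts), c(400, 30))
  panel <- load_gene_panel(paths["panel"])
  expect_equal(length(panel$gene_ids), 80)
  truth <- read.table(paths["truth"], header = TRUE, sep = "\t")
  expect_equal(nrow(truth), 60)
  cl <- suppressMessages(load_clinical_table(paths["clinical"]))
  expect_true(all(cl$valid_survival))
})
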