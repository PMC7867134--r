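fixed_lts <- function(seed = 1, n = 6, p = 4) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
  labeled_training_set(X, rep(0:1, length.out = n))
}

test_that("class centroids are the per-class means", {
  lts <- fixed_lts()
  cen <- compute_centroids(lts)
  # brute-force elementwise mean
  for (cls in 0:1) {
    rows <- lts$features[lts$labels == cls, , drop = FALSE]
    manual <- apply(rows, 2, function(v) sum(v) / length(v))
    got <- if (cls == 1) cen$ilc2 else cen$rest
    expect_lt(max(abs(got - manual)), 1e-12)
  }
  # one sample per class: centroid equals the sample
  one <- labeled_training_set(lts$features[1:2, ], c(0, 1))
  c1 <- compute_centroids(one)
  expect_equal(unname(c1$ilc2), unname(lts$features[2, ]))
  # duplicating class-1 rows leaves the class-1 centroid unchanged
  dup <- labeled_training_set(
    rbind(lts$features, lts$features[lts$labels == 1, ]),
    c(lts$labels, rep(1, sum(lts$labels == 1))))
  expect_equal(compute_centroids(dup)$ilc2, cen$ilc2)
})

test_that("centroid distances are Euclidean", {
  cen <- structure(list(ilc2 = c(0, 0), rest = c(1, 1)),
                   class = "ClassCentroids")
  d <- centroid_distance(c(3, 4), cen)
  expect_equal(unname(d[1, "ilc2"]), 5)            # 3-4-5 triangle
  expect_equal(unname(centroid_distance(c(0, 0), cen)[1, "ilc2"]), 0)
  set.seed(2)
  x <- rnorm(10); mu <- rnorm(10)
  cen10 <- structure(list(ilc2 = mu, rest = rep(0, 10)),
                     class = "ClassCentroids")
  expect_lt(abs(centroid_distance(x, cen10)[1, "ilc2"] -
                sqrt(sum((x - mu)^2))), 1e-12)
  expect_error(centroid_distance(c(1, 2, 3), cen), "length")
})

test_that("median-heuristic gamma equals brute-force enumeration", {
  set.seed(3)
  X <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, paste0("g", 1:3)))
  g <- median_heuristic_gamma(X)
  dists <- c()
  for (i in 1:4) for (j in (i + 1):5)
    dists <- c(dists, sqrt(sum((X[i, ] - X[j, ])^2)))
  expect_lt(abs(g - 1 / (2 * median(dists)^2)), 1e-12)
  # homogeneity: scaling rows by c divides gamma by c^2
  expect_equal(median_heuristic_gamma(3 * X), g / 9, tolerance = 1e-12)
  # two identical rows + one distinct: sigma = the positive distance
  Y <- rbind(X[1, ], X[1, ], X[2, ])
  d12 <- sqrt(sum((X[1, ] - X[2, ])^2))
  expect_equal(median_heuristic_gamma(Y), 1 / (2 * d12^2),
               tolerance = 1e-12)
  expect_error(median_heuristic_gamma(rbind(X[1, ], X[1, ])), "gamma")
})

test_that("RBF similarity follows the kernel", {
  expect_equal(rbf_similarity(0, 5), 1)
  expect_equal(rbf_similarity(2, 0.5), exp(-2), tolerance = 1e-12)
  set.seed(4)
  d <- sort(runif(10, 0, 3))
  s <- rbf_similarity(d, 1.3)
  expect_true(all(diff(s) < 0))       # strictly decreasing
  expect_true(all(s > 0 & s <= 1))
  expect_error(rbf_similarity(-1, 1), "non-negative")
})

test_that("dual-threshold gating uses strict inequalities", {
  g <- gate_params()
  res <- suppressMessages(
    gate_samples(c(0.25, 0.19, 0.50), c(0.95, 0.99, 0.90), g))
  expect_equal(res$call, c(1L, 0L, 0L))
  expect_error(suppressMessages(gate_samples(1.2, 0.5, g)), "\\[0,1\\]")
  expect_error(suppressMessages(gate_samples(0.5, -0.1, g)), "\\[0,1\\]")
})

test_that("gating is monotone in both thresholds and order-invariant", {
  set.seed(5)
  conf <- runif(50); sim <- runif(50)
  n_calls <- function(tc, ts) sum(suppressMessages(
    gate_samples(conf, sim, gate_params(tau_conf = tc, tau_sim = ts)))$call)
  for (tc in c(0.1, 0.2, 0.4)) {
    calls <- vapply(c(0.5, 0.7, 0.9, 0.95), function(ts) n_calls(tc, ts),
                    numeric(1))
    expect_true(all(diff(calls) <= 0))
  }
  for (ts in c(0.5, 0.9)) {
    calls <- vapply(c(0.1, 0.3, 0.6, 0.9), function(tc) n_calls(tc, ts),
                    numeric(1))
    expect_true(all(diff(calls) <= 0))
  }
  perm <- sample(50)
  r1 <- suppressMessages(gate_samples(conf, sim, gate_params(),
                                      sample_ids = as.character(1:50)))
  r2 <- suppressMessages(gate_samples(conf[perm], sim[perm], gate_params(),
                                      sample_ids = as.character(perm)))
  expect_equal(r2$call[order(perm)], r1$call)
})

test_that("in-distribution cohorts pass the gate; shifted cohorts fail", {
  acc <- rej <- numeric(3)
  for (k in 1:3) {
    cfg <- sim_config(n_genes = 1000, n_signature_genes = 241,
                      panel_size = 300, n_patients = 60,
                      domain_shift = 0, seed = 600 + k)
    tr <- sim_training_features(cfg)
    gamma <- median_heuristic_gamma(tr$lts)
    cen <- compute_centroids(tr$lts)
    ch <- sim_cohort_features(cfg, tr$signature_genes)
    s <- apply(rbf_similarity(centroid_distance(ch$features, cen), gamma),
               1, max)
    acc[k] <- mean(s > 0.9)
    sigma <- sqrt(1 / (2 * gamma))
    set.seed(k)
    shift <- rnorm(ncol(ch$features))
    shift <- shift / sqrt(sum(shift^2)) * 5 * sigma
    s2 <- apply(rbf_similarity(
      centroid_distance(sweep(ch$features, 2, -shift), cen), gamma), 1, max)
    rej[k] <- mean(s2 <= 0.9)
  }
  expect_gte(mean(acc), 0.8)
  expect_gte(mean(rej), 0.99)
})
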