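# Shared fixtures and independent oracles. Oracles are deliberately
# written as plain loops, independent of the package code paths they
# check.

make_counts <- function(n_genes, n_samples, seed = 1, mu = 80, size = 5) {
  set.seed(seed)
  matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
         n_genes, n_samples,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

small_em <- function(...) expression_matrix(make_counts(...))

# --- TMM oracle: direct loop evaluation of the trimmed weighted-mean
# formula (reference by upper-quartile rule, double trim by rank,
# inverse-asymptotic-variance weights, geometric-mean rescaling).
tmm_oracle <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  libs <- colSums(counts)
  uq <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts)))
    uq[s] <- quantile(counts[, s] / libs[s], 0.75)
  r <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    ms <- as <- ws <- c()
    for (g in seq_len(nrow(counts))) {
      c_s <- counts[g, s]; c_r <- counts[g, r]
      if (c_s > 0 && c_r > 0) {
        ms <- c(ms, log2((c_s / libs[s]) / (c_r / libs[r])))
        as <- c(as, 0.5 * log2((c_s / libs[s]) * (c_r / libs[r])))
        ws <- c(ws, (libs[s] - c_s) / (libs[s] * c_s) +
                     (libs[r] - c_r) / (libs[r] * c_r))
      }
    }
    if (!length(ms) || max(abs(ms)) < 1e-6) { f[s] <- 1; next }
    n <- length(ms)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(ms) >= lo_m & rank(ms) <= hi_m &
            rank(as) >= lo_a & rank(as) <= hi_a
    if (sum(keep) < 10) { f[s] <- 1; next }
    f[s] <- 2^(sum(ms[keep] / ws[keep]) / sum(1 / ws[keep]))
  }
  f / exp(mean(log(f)))
}

# --- log-rank oracle: per-event-time O/E/V accumulation by loop.
logrank_oracle <- function(time, event, g1) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (u in ts) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == u & event == 1)
    O1 <- O1 + sum(time == u & event == 1 & g1)
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# --- Cox partial log-likelihood for one covariate, untied data (grid
# oracle).
cox_partial_loglik <- function(beta, time, event, x) {
  risk <- exp(beta * x)
  ll <- 0
  for (i in which(event == 1)) {
    at <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(risk[at]))
  }
  ll
}

# Small simulated training world: reference logCPM features over the
# planted signature genes, as a LabeledTrainingSet.
sim_training_features <- function(cfg) {
  ref <- simulate_reference(cfg)
  nm <- suppressMessages(normalize_counts(ref$matrix))
  feats <- t(nm$values[match(ref$signature_genes, nm$gene_ids), ,
                       drop = FALSE])
  colnames(feats) <- ref$signature_genes
  list(lts = labeled_training_set(feats, ref$labels),
       signature_genes = ref$signature_genes)
}

# Cohort logCPM features aligned to the planted signature genes.
sim_cohort_features <- function(cfg, genes) {
  co <- simulate_cohort(cfg)
  cn <- suppressMessages(normalize_counts(co$matrix))
  feats <- t(cn$values[match(genes, cn$gene_ids), , drop = FALSE])
  colnames(feats) <- genes
  list(features = feats, truth = co$truth, clinical = co$clinical)
}
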