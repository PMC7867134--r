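# Synthetic-data generator: negative-binomial reference / single-cell /
# tumour-cohort matrices with known ground truth (planted infiltration
# fraction, domain shift, hazard ratio), replacing the external
# accessions for development and testing.

#' Simulation configuration
#'
#' Defaults state the emulated world once: a 20,000-gene transcriptome, a
#' 700-gene immune panel whose 241 signature genes are the planted
#' ILC2-discriminating genes, 40 reference samples per class, 200
#' single-cell profiles, and a 518-patient cohort with planted fraction
#' 0.278 (exactly 144 infiltrated), a 3-within-SD signature shift, NB
#' dispersion 0.1, a 0.3 log2-SD domain shift, true hazard ratio 0.72
#' and 30% censoring. See the methods vignette for the rationale of each
#' default.
#'
#' @param n_genes total genes.
#' @param n_signature_genes planted ILC2 signature genes.
#' @param panel_size immune panel size (signature genes + decoys).
#' @param n_ref_samples reference samples per class (class 1 = ILC2,
#'   class 0 = pooled other subsets).
#' @param n_cells single-cell profiles for HVG selection.
#' @param n_patients tumour cohort size.
#' @param pi_infiltrated planted ILC2-high fraction in (0,1).
#' @param effect_size mean log2 shift of signature genes in class-1 /
#'   infiltrated samples, in units of the within-class SD of logCPM.
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param hvg_dispersion_mult dispersion multiplier of planted genes in
#'   the single-cell source (default 10).
#' @param domain_shift SD (log2 units) of the fixed per-gene offset
#'   applied to every cohort sample — out-of-distribution severity.
#' @param true_hr hazard ratio of infiltrated vs non-infiltrated.
#' @param censor_rate expected fraction of censored records in \[0,1).
#' @param baseline_hazard exponential baseline hazard (per day).
#' @param lib_size_bulk,lib_size_sc mean library sizes.
#' @param seed master integer seed; every generator draws from a
#'   stage-derived sub-seed so streams are independent.
#' @return list of class `SimulationConfig`.
#' @export
sim_config <- function(n_genes = 20000, n_signature_genes = 241,
                       panel_size = 700, n_ref_samples = 40,
                       n_cells = 200, n_patients = 518,
                       pi_infiltrated = 0.278, effect_size = 3,
                       nb_dispersion = 0.1, hvg_dispersion_mult = 10,
                       domain_shift = 0.3, true_hr = 0.72,
                       censor_rate = 0.3, baseline_hazard = 1e-3,
                       lib_size_bulk = 5e6, lib_size_sc = 2e5,
                       seed = 1) {
  cfg <- structure(as.list(environment()), class = "SimulationConfig")
  stopifnot(cfg$n_genes >= 2, cfg$n_signature_genes >= 1,
            cfg$n_signature_genes <= cfg$n_genes,
            cfg$panel_size >= cfg$n_signature_genes,
            cfg$panel_size <= cfg$n_genes,
            cfg$n_ref_samples >= 2, cfg$n_cells >= 2, cfg$n_patients >= 2,
            cfg$pi_infiltrated > 0, cfg$pi_infiltrated < 1,
            cfg$nb_dispersion > 0, cfg$true_hr > 0,
            cfg$censor_rate >= 0, cfg$censor_rate < 1,
            cfg$baseline_hazard > 0)
  if (cfg$effect_size < 0) stop("effect_size must be non-negative")
  cfg
}

#' Shared gene-level world of a simulation
#'
#' Deterministic given the config seed: log2 gene baselines (log-normal
#' abundances), which genes carry the signature, the within-class logCPM
#' SD of every gene (delta method at the nominal depth), the fixed
#' domain-shift direction, and the decoy panel members.
#' @param config a [sim_config()].
#' @return list: `gene_ids`, `base_log2`, `sig_idx`, `within_sd`,
#'   `shift_dir`, `panel_ids`.
#' @keywords internal
sim_world <- function(config) {
  with_seed(derive_seed(config$seed, "world"), {
    gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
    base <- stats::rnorm(config$n_genes, mean = 5, sd = 2)
    sig_idx <- sort(sample.int(config$n_genes, config$n_signature_genes))
    # signature genes get moderate-to-high abundance so they are
    # quantifiable in both bulk and single cells
    base[sig_idx] <- stats::rnorm(config$n_signature_genes, mean = 6, sd = 1)
    q <- 2^base / sum(2^base)
    mu_nominal <- config$lib_size_bulk * q
    within_sd <- sqrt(1 / mu_nominal + config$nb_dispersion) / log(2)
    shift_dir <- stats::rnorm(config$n_genes)
    decoys <- sample(setdiff(seq_len(config$n_genes), sig_idx),
                     config$panel_size - config$n_signature_genes)
    panel_ids <- gene_ids[sort(c(sig_idx, decoys))]
    list(gene_ids = gene_ids, base_log2 = base, sig_idx = sig_idx,
         within_sd = within_sd, shift_dir = shift_dir,
         panel_ids = panel_ids)
  })
}

#' @keywords internal
nb_counts_matrix <- function(log2_mean_per_sample, lib_sizes, dispersion,
                             gene_ids, sample_ids) {
  # log2_mean_per_sample: genes x samples matrix of log2 relative means
  n_genes <- nrow(log2_mean_per_sample)
  m <- matrix(0, n_genes, length(lib_sizes),
              dimnames = list(gene_ids, sample_ids))
  for (s in seq_along(lib_sizes)) {
    rel <- 2^log2_mean_per_sample[, s]
    mu <- lib_sizes[s] * rel / sum(rel)
    m[, s] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  m
}

#' Simulate the labelled sorted-cell reference
#'
#' Two classes of bulk NB profiles; class 1 (ILC2) has its signature
#' genes shifted up by `effect_size` within-class SDs on the log2 scale.
#'
#' @param config a [sim_config()].
#' @return list: `matrix` ([expression_matrix()]), `labels` (0/1 per
#'   sample), `signature_genes` (the planted truth).
#' @export
simulate_reference <- function(config) {
  w <- sim_world(config)
  n <- config$n_ref_samples
  labels <- rep(c(0L, 1L), each = n)
  ids <- c(sprintf("ref_rest_%02d", seq_len(n)),
           sprintf("ref_ilc2_%02d", seq_len(n)))
  lm0 <- w$base_log2
  lm1 <- w$base_log2
  lm1[w$sig_idx] <- lm1[w$sig_idx] +
    config$effect_size * w$within_sd[w$sig_idx]
  with_seed(derive_seed(config$seed, "reference"), {
    libs <- round(stats::rlnorm(2 * n, log(config$lib_size_bulk), 0.15))
    lm <- cbind(matrix(lm0, config$n_genes, n),
                matrix(lm1, config$n_genes, n))
    m <- nb_counts_matrix(lm, libs, config$nb_dispersion, w$gene_ids, ids)
  })
  list(matrix = expression_matrix(m), labels = labels,
       signature_genes = w$gene_ids[w$sig_idx])
}

#' Simulate the single-cell HVG source
#'
#' NB counts at single-cell depth in which the signature genes have
#' `hvg_dispersion_mult`-fold elevated dispersion, so variance-based HVG
#' ranking can recover them.
#'
#' @param config a [sim_config()].
#' @return list: `matrix` ([expression_matrix()]), `planted_genes`.
#' @export
simulate_sc_source <- function(config) {
  w <- sim_world(config)
  disp <- rep(config$nb_dispersion, config$n_genes)
  disp[w$sig_idx] <- config$nb_dispersion * config$hvg_dispersion_mult
  ids <- sprintf("cell_%03d", seq_len(config$n_cells))
  with_seed(derive_seed(config$seed, "sc"), {
    libs <- round(stats::rlnorm(config$n_cells, log(config$lib_size_sc), 0.3))
    rel <- 2^w$base_log2
    m <- matrix(0, config$n_genes, config$n_cells,
                dimnames = list(w$gene_ids, ids))
    for (s in seq_len(config$n_cells)) {
      mu <- libs[s] * rel / sum(rel)
      m[, s] <- stats::rnbinom(config$n_genes, mu = mu, size = 1 / disp)
    }
  })
  list(matrix = expression_matrix(m),
       planted_genes = w$gene_ids[w$sig_idx])
}

#' Simulate the tumour cohort with planted infiltration and survival
#'
#' round(pi_infiltrated * n_patients) samples receive the signature
#' shift; every sample receives the fixed domain-shift offset
#' `domain_shift * shift_dir` on its log2 means. Survival times are
#' exponential with hazard `baseline_hazard * true_hr^label`; censoring
#' is independent given the label, calibrated so each record is censored
#' with probability `censor_rate`.
#'
#' @param config a [sim_config()].
#' @return list: `matrix` ([expression_matrix()]), `clinical`
#'   (`clinical_table`-shaped data.frame), `truth` (0/1 infiltration
#'   labels), `signature_genes`.
#' @export
simulate_cohort <- function(config) {
  w <- sim_world(config)
  n <- config$n_patients
  n_inf <- round(config$pi_infiltrated * n)
  if (n_inf < 1) stop("pi_infiltrated * n_patients < 1: nothing to plant")
  ids <- sprintf("pt_%04d", seq_len(n))
  with_seed(derive_seed(config$seed, "cohort"), {
    truth <- integer(n)
    truth[sample.int(n, n_inf)] <- 1L
    libs <- round(stats::rlnorm(n, log(config$lib_size_bulk), 0.15))
    base0 <- w$base_log2 + config$domain_shift * w$shift_dir
    base1 <- base0
    base1[w$sig_idx] <- base1[w$sig_idx] +
      config$effect_size * w$within_sd[w$sig_idx]
    lm <- matrix(base0, config$n_genes, n)
    lm[, truth == 1] <- base1
    m <- nb_counts_matrix(lm, libs, config$nb_dispersion, w$gene_ids, ids)
  })
  clinical <- with_seed(derive_seed(config$seed, "survival"), {
    lambda <- config$baseline_hazard * ifelse(truth == 1, config$true_hr, 1)
    t_event <- stats::rexp(n, rate = lambda)
    if (config$censor_rate > 0) {
      c_rate <- lambda * config$censor_rate / (1 - config$censor_rate)
      t_cens <- stats::rexp(n, rate = c_rate)
    } else t_cens <- rep(Inf, n)
    data.frame(
      sample_id = ids,
      time = pmin(t_event, t_cens),
      event = as.numeric(t_event <= t_cens),
      age = round(stats::rnorm(n, 68, 10), 1),
      sex = sample(c("female", "male"), n, replace = TRUE),
      node_positive = stats::rbinom(n, 1, 0.4),
      stage = sample(1:4, n, replace = TRUE,
                     prob = c(0.2, 0.35, 0.3, 0.15)),
      stringsAsFactors = FALSE)
  })
  clinical$valid_survival <- clinical$time > 0 & !is.na(clinical$event)
  class(clinical) <- c("clinical_table", "data.frame")
  list(matrix = expression_matrix(m), clinical = clinical,
       truth = truth, signature_genes = w$gene_ids[w$sig_idx])
}

#' Write a complete simulated input set to disk
#'
#' Emits every file the pipeline consumes, in the documented formats:
#' `ref_counts.tsv`, `ref_labels.tsv`, `sc_counts.tsv`, `panel.txt`,
#' `cohort_counts.tsv`, `clinical.tsv`, `truth.tsv`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return named character vector of file paths, invisibly.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- sim_world(config)
  ref <- simulate_reference(config)
  sc <- simulate_sc_source(config)
  co <- simulate_cohort(config)
  paths <- c(ref_counts = file.path(outdir, "ref_counts.tsv"),
             ref_labels = file.path(outdir, "ref_labels.tsv"),
             sc_counts = file.path(outdir, "sc_counts.tsv"),
             panel = file.path(outdir, "panel.txt"),
             cohort_counts = file.path(outdir, "cohort_counts.tsv"),
             clinical = file.path(outdir, "clinical.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_counts_matrix(ref$matrix, paths["ref_counts"])
  utils::write.table(
    data.frame(sample_id = ref$matrix$sample_ids, label = ref$labels),
    paths["ref_labels"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts_matrix(sc$matrix, paths["sc_counts"])
  writeLines(c("# synthetic immune panel", w$panel_ids), paths["panel"])
  write_counts_matrix(co$matrix, paths["cohort_counts"])
  cl <- co$clinical
  utils::write.table(
    data.frame(sample_id = cl$sample_id, time_days = cl$time,
               event = cl$event, age_years = cl$age, sex = cl$sex,
               node_positive = cl$node_positive, stage = cl$stage),
    paths["clinical"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = co$matrix$sample_ids, infiltrated = co$truth),
    paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
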