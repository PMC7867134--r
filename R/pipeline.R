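# Orchestration: one configured run from raw input files to gate calls
# and survival report, with logging and provenance.

#' Run configuration
#'
#' @param ref_counts,ref_labels,sc_counts,panel,cohort_counts,clinical
#'   input file paths (formats as documented in the io functions).
#' @param outdir output directory.
#' @param norm a [norm_params()].
#' @param hyperparams a [model_hyperparams()] (its `seed` is overridden
#'   by the run seed).
#' @param gate a [gate_params()] (`gamma = NULL` = median heuristic on
#'   the training set).
#' @param n_hvg top highly variable genes to intersect with the panel
#'   (default 1000).
#' @param covariates covariate names of the multivariate Cox model.
#' @param orthology_map optional two-column TSV mapping reference gene
#'   ids to cohort gene ids.
#' @param seed master seed; stage sub-seeds are derived from it.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(ref_counts, ref_labels, sc_counts, panel,
                       cohort_counts, clinical, outdir,
                       norm = norm_params(),
                       hyperparams = model_hyperparams(),
                       gate = gate_params(), n_hvg = 1000,
                       covariates = c("age_decades", "sex_male",
                                      "node_positive", "stage", "ilc2"),
                       orthology_map = NULL, seed = 1) {
  cfg <- structure(as.list(environment()), class = "RunConfig")
  files <- c(ref_counts, ref_labels, sc_counts, panel, cohort_counts,
             clinical, orthology_map)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  cfg
}

#' Execute the full pipeline
#'
#' normalize -> signature -> train -> evaluate -> gate -> survival.
#' Writes `gate_results.tsv`, `survival_report.json`, `model.json` and
#' `run.log` into `config$outdir`. Idempotent given the seed: a rerun
#' with an identical config produces byte-identical gate results.
#'
#' @param config a [run_config()].
#' @return list of class `RunReport`: `counts` (cohort, valid survival,
#'   gated positive), `holdout`, `signature`, `gate` (data.frame),
#'   `km`, `logrank`, `cox`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    msg("%s", line)
  }
  note("ilc2gate %s | seed %d", as.character(utils::packageVersion("ilc2gate")),
       config$seed)
  note("params: trim_m=%g trim_a=%g prior=%g | rounds=%d alpha=%g frac=%g | tau_conf=%g tau_sim=%g rule=%s | n_hvg=%d",
       config$norm$trim_m, config$norm$trim_a, config$norm$prior,
       config$hyperparams$n_rounds, config$hyperparams$l1_alpha,
       config$hyperparams$train_fraction, config$gate$tau_conf,
       config$gate$tau_sim, config$gate$similarity_rule, config$n_hvg)

  stage <- "load"
  report <- tryCatch({
    ref <- load_counts_matrix(config$ref_counts)
    labels_df <- utils::read.table(config$ref_labels, header = TRUE,
                                   sep = "\t", stringsAsFactors = FALSE)
    labels <- labels_df$label[match(ref$sample_ids, labels_df$sample_id)]
    if (anyNA(labels)) stop("labels missing for some reference samples")
    sc <- load_counts_matrix(config$sc_counts)
    panel <- load_gene_panel(config$panel)
    cohort <- load_counts_matrix(config$cohort_counts)
    clinical <- load_clinical_table(config$clinical)
    if (!is.null(config$orthology_map)) {
      stage <- "orthology"
      ref <- map_gene_ids(ref, load_orthology_map(config$orthology_map))
    }
    note("inputs: reference %d x %d, sc %d x %d, cohort %d x %d, clinical %d",
         nrow(ref$counts), ncol(ref$counts), nrow(sc$counts),
         ncol(sc$counts), nrow(cohort$counts), ncol(cohort$counts),
         nrow(clinical))

    stage <- "normalize"
    ref_norm <- normalize_counts(ref, config$norm)
    sc_norm <- normalize_counts(sc, config$norm)

    stage <- "signature"
    hvg <- select_hvg(sc_norm, config$n_hvg)
    sig <- intersect_panel(hvg, panel)
    note("signature: panel %d x top-%d HVG -> %d genes",
         length(panel$gene_ids), config$n_hvg, length(sig$gene_ids))

    stage <- "train"
    hp <- config$hyperparams
    hp$seed <- derive_seed(config$seed, "split")
    feats <- t(ref_norm$values[match(sig$gene_ids, ref_norm$gene_ids), ,
                               drop = FALSE])
    colnames(feats) <- sig$gene_ids
    lts <- labeled_training_set(feats, labels, ref$sample_ids)
    parts <- split_train_test(lts, hp$train_fraction, hp$seed)
    model <- train_boosted_linear(parts$train, hp, signature = sig)

    stage <- "evaluate"
    holdout <- evaluate_holdout(model, parts$test)
    note("holdout: accuracy %.3f on %d samples (train %d / test %d)",
         holdout$accuracy, holdout$n, length(parts$train$labels),
         length(parts$test$labels))

    stage <- "gate"
    cohort_norm <- normalize_counts(cohort, config$norm)
    sig_rows <- match(sig$gene_ids, cohort_norm$gene_ids)
    if (anyNA(sig_rows))
      stop("signature genes absent from cohort: ",
           paste(sig$gene_ids[is.na(sig_rows)], collapse = ", "),
           " (supply an orthology map or align the cohort)")
    cfeats <- t(cohort_norm$values[sig_rows, , drop = FALSE])
    colnames(cfeats) <- sig$gene_ids
    gate_res <- gate_cohort(model, cfeats, config$gate,
                            train = parts$train)
    note("cohort: %d samples, %d gated ILC2-high",
         nrow(gate_res), sum(gate_res$call))

    stage <- "survival"
    design <- survival_design(clinical, gate_res)
    note("survival: %d records valid for survival (of %d)",
         nrow(design), nrow(clinical))
    both_groups <- length(unique(design$ilc2)) == 2
    km <- logrank <- cox <- NULL
    if (both_groups) {
      km <- km_estimate(design$time, design$event, design$ilc2)
      logrank <- logrank_test(design$time, design$event, design$ilc2)
      note("log-rank: chi2 %.3f, p %.3g", logrank$statistic,
           logrank$p_value)
      cox <- tryCatch(cox_fit(design, intersect(config$covariates,
                                                names(design))),
                      error = function(e) {
                        note("cox skipped: %s", conditionMessage(e)); NULL
                      })
    } else note("survival comparison skipped: only one gate group present")

    stage <- "write"
    gate_path <- file.path(config$outdir, "gate_results.tsv")
    out_gate <- gate_res
    for (col in c("confidence", "distance_ilc2", "distance_rest",
                  "similarity"))
      out_gate[[col]] <- sprintf("%.10g", out_gate[[col]])
    utils::write.table(out_gate, gate_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    save_model(model, file.path(config$outdir, "model.json"))
    surv_report <- list(
      counts = list(cohort = nrow(gate_res),
                    valid_survival = nrow(design),
                    gated_positive = sum(gate_res$call)),
      holdout_accuracy = holdout$accuracy,
      logrank = if (!is.null(logrank))
        list(statistic = logrank$statistic, p_value = logrank$p_value),
      km = if (!is.null(km)) lapply(km, function(d) as.list(d)),
      cox = if (!is.null(cox)) cox$table)
    jsonlite::write_json(surv_report,
                         file.path(config$outdir, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(counts = surv_report$counts, holdout = holdout, signature = sig,
         gate = gate_res, km = km, logrank = logrank, cox = cox,
         files = c(gate = gate_path,
                   model = file.path(config$outdir, "model.json"),
                   survival = file.path(config$outdir,
                                        "survival_report.json"),
                   log = log_path))
  }, error = function(e) {
    log_lines <<- c(log_lines,
                    sprintf("ERROR in stage '%s': %s", stage,
                            conditionMessage(e)))
    writeLines(log_lines, log_path)
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  writeLines(log_lines, log_path)
  class(report) <- "RunReport"
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("ilc2gate run: cohort %d | valid survival %d | ILC2-high %d\n",
              x$counts$cohort, x$counts$valid_survival,
              x$counts$gated_positive))
  cat(sprintf("  holdout accuracy: %.3f\n", x$holdout$accuracy))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank chi2 = %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
  if (!is.null(x$cox)) print(x$cox)
  invisible(x)
}
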