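# Between-sample normalisation: trimmed mean of M-values (TMM) scale
# factors and logCPM transformation, implemented from the published
# definitions.

#' Normalisation parameters
#'
#' @param trim_m fraction of M-values (log-ratios) trimmed from each tail.
#'   Default 0.30, the published TMM setting.
#' @param trim_a fraction of A-values (log-abundances) trimmed from each
#'   tail. Default 0.05.
#' @param prior pseudo-count added before the log (default 0.5).
#' @param reference sample id to use as the TMM reference, or `NULL` for
#'   the automatic rule: the sample whose upper-quartile count proportion
#'   is closest to the mean upper quartile.
#' @return list of class `NormalizationParams`.
#' @export
norm_params <- function(trim_m = 0.30, trim_a = 0.05, prior = 0.5,
                        reference = NULL) {
  stopifnot(trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5, prior > 0)
  structure(list(trim_m = trim_m, trim_a = trim_a, prior = prior,
                 reference = reference),
            class = "NormalizationParams")
}

#' Compute TMM scale factors
#'
#' For each sample s against the reference r, over genes with nonzero
#' counts in both: M_g = log2((c_gs/N_s)/(c_gr/N_r)),
#' A_g = 0.5*log2((c_gs/N_s)*(c_gr/N_r)). M is doubly trimmed (by
#' `trim_m` on M-rank and `trim_a` on A-rank) and averaged with inverse
#' asymptotic-variance weights
#' 1/w_g, w_g = (N_s-c_gs)/(N_s c_gs) + (N_r-c_gr)/(N_r c_gr);
#' the factor is 2^(weighted mean M). Factors are rescaled so their
#' geometric mean is exactly 1. Matches the edgeR reference implementation
#' to machine precision on shared inputs.
#'
#' @param x an [expression_matrix()].
#' @param params a [norm_params()].
#' @return named numeric vector of strictly positive factors, one per
#'   sample, geometric mean 1.
#' @export
compute_tmm_factors <- function(x, params = norm_params()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  cn <- x$counts
  lib <- x$library_sizes
  if (any(lib == 0)) stop("all-zero sample: ",
                          paste(x$sample_ids[lib == 0], collapse = ", "))
  if (ncol(cn) < 2) stop("TMM needs at least 2 samples")
  if (is.null(params$reference)) {
    uq <- apply(sweep(cn, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_i <- which.min(abs(uq - mean(uq)))
  } else {
    ref_i <- match(params$reference, x$sample_ids)
    if (is.na(ref_i)) stop("reference sample not found: ", params$reference)
  }
  f <- vapply(seq_len(ncol(cn)), function(s) {
    tmm_pair_factor(cn[, s], cn[, ref_i], lib[s], lib[ref_i],
                    params$trim_m, params$trim_a, x$sample_ids[s])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, x$sample_ids)
}

#' @keywords internal
tmm_pair_factor <- function(obs, ref, n_o, n_r, trim_m, trim_a,
                            sample_id = "?") {
  keep0 <- obs > 0 & ref > 0       # log-safety: expressed in both
  obs <- obs[keep0]; ref <- ref[keep0]
  m <- log2((obs / n_o) / (ref / n_r))
  a <- 0.5 * log2((obs / n_o) * (ref / n_r))
  w <- (n_o - obs) / (n_o * obs) + (n_r - ref) / (n_r * ref)
  if (!length(m) || max(abs(m)) < 1e-6) return(1)  # identical composition
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
          rank(a) >= lo_a & rank(a) <= hi_a
  if (sum(keep) < 10) {
    warning(sprintf("sample '%s': fewer than 10 genes survive trimming; factor set to 1",
                    sample_id))
    return(1)
  }
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' logCPM transformation
#'
#' value(g,s) = log2( (c_gs + prior) / (N_s * f_s + 2 * prior) * 1e6 ).
#' Strictly increasing in the count and finite for all inputs. This is a
#' fixed dialect; other tools scale the pseudo-count differently, so
#' bit-identity with them is not a goal.
#'
#' @param x an [expression_matrix()].
#' @param factors positive per-sample scale factors (e.g. from
#'   [compute_tmm_factors()]); default all 1.
#' @param params a [norm_params()]; supplies the pseudo-count.
#' @return An object of class `NormalizedMatrix`: list with `gene_ids`,
#'   `sample_ids`, `values` (logCPM matrix), `factors`, `params`.
#' @export
logcpm_transform <- function(x, factors = NULL, params = norm_params()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (is.null(factors)) factors <- rep(1, length(x$sample_ids))
  if (length(factors) != length(x$sample_ids))
    stop("need one factor per sample")
  if (any(!is.finite(factors)) || any(factors <= 0))
    stop("scale factors must be strictly positive")
  eff <- x$library_sizes * factors + 2 * params$prior
  vals <- log2(sweep(x$counts + params$prior, 2, eff, "/") * 1e6)
  structure(list(gene_ids = x$gene_ids, sample_ids = x$sample_ids,
                 values = vals, factors = factors, params = params),
            class = "NormalizedMatrix")
}

#' TMM + logCPM in one call
#'
#' @inheritParams logcpm_transform
#' @return A `NormalizedMatrix` (see [logcpm_transform()]).
#' @export
normalize_counts <- function(x, params = norm_params()) {
  f <- compute_tmm_factors(x, params)
  logcpm_transform(x, f, params)
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (logCPM): %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
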