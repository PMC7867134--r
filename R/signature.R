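# Signature construction: highly-variable-gene (HVG) ranking on
# single-cell profiles and intersection with an immune gene panel.

#' Select highly variable genes
#'
#' Ranks genes by the variance of their logCPM values across cells
#' (descending); zero-variance genes are excluded. Ties are broken
#' lexicographically by gene id so the ranking is fully deterministic.
#' A mean--variance-trend residual score is available behind
#' `method = "trend"` (residual from a loess fit of variance on mean).
#'
#' @param x a `NormalizedMatrix` (logCPM) of single-cell profiles, or a
#'   plain numeric matrix with gene rownames.
#' @param n number of genes requested; clipped (with a warning) to the
#'   number of positive-variance genes.
#' @param method `"variance"` (default) or `"trend"`.
#' @return data.frame of class `hvg_ranking` with columns `gene_id`,
#'   `score`, `rank`, ordered by rank; holds the top `n`.
#' @export
select_hvg <- function(x, n, method = c("variance", "trend")) {
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  vals <- if (inherits(x, "NormalizedMatrix")) x$values else x
  if (is.null(rownames(vals))) stop("matrix must carry gene rownames")
  if (ncol(vals) < 2) stop("need at least 2 cells")
  mu <- rowMeans(vals)
  v <- rowSums((vals - mu)^2) / (ncol(vals) - 1)
  score <- if (method == "trend") {
    fit <- stats::loess(v ~ mu, degree = 1, span = 0.5)
    v - stats::fitted(fit)
  } else v
  keep <- v > 0
  if (!any(keep)) stop("no gene has positive variance")
  if (n > sum(keep)) {
    warning(sprintf("requested %d HVGs but only %d genes have positive variance",
                    as.integer(n), sum(keep)))
    n <- sum(keep)
  }
  ids <- rownames(vals)[keep]
  sc <- score[keep]
  ord <- order(-sc, ids)
  out <- data.frame(gene_id = ids[ord][seq_len(n)],
                    score = sc[ord][seq_len(n)],
                    rank = seq_len(n),
                    stringsAsFactors = FALSE)
  class(out) <- c("hvg_ranking", "data.frame")
  out
}

#' Intersect an HVG ranking with a gene panel
#'
#' The classifier's gene space: panel genes that are highly variable,
#' ordered by HVG rank.
#'
#' @param hvg an `hvg_ranking` from [select_hvg()] (or a character vector
#'   in rank order).
#' @param panel a [gene_panel()].
#' @return list of class `SignatureGeneSet`: `gene_ids` (ordered by HVG
#'   rank), `hvg_rank`, `provenance` (panel name, sizes).
#' @export
intersect_panel <- function(hvg, panel) {
  stopifnot(inherits(panel, "GenePanel"))
  hvg_ids <- if (is.data.frame(hvg)) hvg$gene_id else as.character(hvg)
  if (!length(hvg_ids)) stop("empty HVG list")
  keep <- hvg_ids %in% panel$gene_ids
  ids <- hvg_ids[keep]
  msg("panel '%s': |panel| = %d, |hvg| = %d, |intersection| = %d",
      panel$name, length(panel$gene_ids), length(hvg_ids), length(ids))
  if (!length(ids))
    stop("panel and HVG set are disjoint; cannot build a signature")
  structure(list(gene_ids = ids,
                 hvg_rank = which(keep),
                 provenance = list(panel = panel$name,
                                   n_panel = length(panel$gene_ids),
                                   n_hvg = length(hvg_ids))),
            class = "SignatureGeneSet")
}

#' @export
print.SignatureGeneSet <- function(x, ...) {
  cat(sprintf("SignatureGeneSet: %d genes (panel '%s' x top-%d HVGs)\n",
              length(x$gene_ids), x$provenance$panel, x$provenance$n_hvg))
  invisible(x)
}
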