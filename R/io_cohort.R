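# Data model and file I/O: count matrices, gene panels, clinical tables,
# gene-space alignment.

#' Construct an ExpressionMatrix
#'
#' The core container for raw RNA-seq counts: a genes x samples integer
#' matrix with unique gene and sample identifiers and per-sample library
#' sizes (column sums of counts).
#'
#' @param counts numeric matrix, genes x samples, non-negative integers,
#'   with rownames (gene ids) and colnames (sample ids).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `gene_ids`, `sample_ids`, `counts` (integer-valued numeric matrix) and
#'   `library_sizes`.
#' @export
expression_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and sample colnames")
  gene_ids <- trimws(rownames(counts))
  sample_ids <- trimws(colnames(counts))
  rownames(counts) <- gene_ids
  colnames(counts) <- sample_ids
  obj <- structure(
    list(gene_ids = gene_ids, sample_ids = sample_ids,
         counts = counts, library_sizes = colSums(counts)),
    class = "ExpressionMatrix")
  validate_expression_matrix(obj)
}

#' @keywords internal
validate_expression_matrix <- function(x) {
  cn <- x$counts
  if (nrow(cn) < 2 || ncol(cn) < 2)
    stop("ExpressionMatrix needs at least 2 genes and 2 samples")
  dup_g <- unique(x$gene_ids[duplicated(x$gene_ids)])
  if (length(dup_g))
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "))
  dup_s <- unique(x$sample_ids[duplicated(x$sample_ids)])
  if (length(dup_s))
    stop("duplicate sample identifiers: ", paste(dup_s, collapse = ", "))
  if (anyNA(cn) || !all(is.finite(cn)))
    stop("counts contain missing or non-finite values")
  bad <- which(cn < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 x$gene_ids[bad[1, 1]], x$sample_ids[bad[1, 2]]))
  nonint <- which(abs(cn - round(cn)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint))
    stop(sprintf("non-integer count at gene '%s', sample '%s' (value %g); %s",
                 x$gene_ids[nonint[1, 1]], x$sample_ids[nonint[1, 2]],
                 cn[nonint[1, , drop = FALSE]],
                 "use round_counts = TRUE to round expected counts on ingest"))
  stopifnot(all(x$library_sizes == colSums(cn)))
  x
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  cat(sprintf("  library sizes: %s ... \n",
              paste(utils::head(x$library_sizes, 3), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Load a count matrix from TSV/CSV or a MatrixMarket triplet
#'
#' TSV/CSV layout: first column gene identifier, header row of sample
#' identifiers. MatrixMarket (`format = "mtx"`) expects two sidecar files
#' with one gene / sample identifier per line.
#'
#' @param path file path.
#' @param format one of `"tsv"`, `"csv"`, `"mtx"`.
#' @param genes_file,samples_file sidecar identifier files, required for
#'   `"mtx"`; defaults replace the `.mtx` suffix with `_genes.txt` /
#'   `_samples.txt`.
#' @param round_counts round non-integer (e.g. expected-count) values on
#'   ingest instead of rejecting them. Default `FALSE`: TMM is defined on
#'   counts, so silent fractional input is refused.
#' @return An [expression_matrix()].
#' @export
load_counts_matrix <- function(path, format = c("tsv", "csv", "mtx"),
                               genes_file = NULL, samples_file = NULL,
                               round_counts = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    genes_file <- genes_file %||% sub("\\.mtx$", "_genes.txt", path)
    samples_file <- samples_file %||% sub("\\.mtx$", "_samples.txt", path)
    if (!file.exists(genes_file) || !file.exists(samples_file))
      stop("mtx triplet requires gene and sample identifier sidecar files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_file)
    colnames(m) <- readLines(samples_file)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, colClasses = "character",
                            quote = "\"", comment.char = "")
    ids <- trimws(df[[1]])
    vals <- df[, -1, drop = FALSE]
    m <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, colnames(vals)))
    for (j in seq_len(ncol(vals))) {
      v <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(v) & !is.na(vals[[j]]) & nzchar(vals[[j]]))
      if (length(bad))
        stop(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                     ids[bad[1]], colnames(vals)[j], vals[[j]][bad[1]]))
      m[, j] <- v
    }
  }
  if (round_counts) m <- round(m)
  expression_matrix(m)
}

#' Write a count matrix
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"` (triplet with sidecars).
#' @return `path`, invisibly.
#' @export
write_counts_matrix <- function(x, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, sub("\\.mtx$", "_genes.txt", path))
    writeLines(x$sample_ids, sub("\\.mtx$", "_samples.txt", path))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene_id = x$gene_ids, x$counts,
                     check.names = FALSE, row.names = NULL)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Load a gene panel
#'
#' Plain text, one identifier per line; `#` starts a comment.
#'
#' @param path file path.
#' @param name panel name (defaults to the file name).
#' @return A `GenePanel`: list with `gene_ids` (unique, trimmed) and `name`.
#' @export
load_gene_panel <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  gene_panel(lines[nzchar(lines)], name = name)
}

#' @rdname load_gene_panel
#' @param gene_ids character vector of identifiers.
#' @export
gene_panel <- function(gene_ids, name = "panel") {
  gene_ids <- unique(trimws(gene_ids))
  if (!length(gene_ids)) stop("gene panel is empty")
  structure(list(gene_ids = gene_ids, name = name), class = "GenePanel")
}

#' Load a clinical table
#'
#' TSV with columns `sample_id`, `time_days`, `event` and optionally
#' `age_years`, `sex` (female/male), `node_positive` (0/1), `stage`
#' (I--IV or 1--4). Unknown columns are ignored; missing fields stay
#' missing (no imputation). A record is *valid for survival* iff time and
#' event are present and time > 0.
#'
#' @param path file path.
#' @return A data.frame of class `clinical_table` with a logical column
#'   `valid_survival`; the count of valid records is reported via message.
#' @export
load_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("sample_id", "time_days", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing required columns: ",
         paste(miss, collapse = ", "))
  out <- data.frame(sample_id = trimws(as.character(df$sample_id)),
                    time = as.numeric(df$time_days),
                    event = as.numeric(df$event),
                    stringsAsFactors = FALSE)
  if (any(out$time < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(out$event %in% c(0, 1) | is.na(out$event)))
    stop("event indicator must be 0 (censored) or 1 (death)")
  out$age <- if ("age_years" %in% names(df)) as.numeric(df$age_years) else NA_real_
  out$sex <- if ("sex" %in% names(df)) {
    s <- tolower(trimws(as.character(df$sex)))
    ifelse(s %in% c("female", "male"), s, NA_character_)
  } else NA_character_
  out$node_positive <- if ("node_positive" %in% names(df)) {
    v <- as.numeric(df$node_positive)
    ifelse(v %in% c(0, 1), v, NA_real_)
  } else NA_real_
  out$stage <- if ("stage" %in% names(df)) parse_stage(df$stage) else NA_real_
  out$valid_survival <- !is.na(out$time) & !is.na(out$event) & out$time > 0
  msg("clinical table: %d records, %d valid for survival",
      nrow(out), sum(out$valid_survival))
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' @keywords internal
parse_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  roman <- c(I = 1, II = 2, III = 3, IV = 4)
  out <- ifelse(x %in% names(roman), roman[x],
                suppressWarnings(as.numeric(x)))
  out[!(out %in% 1:4)] <- NA_real_
  as.numeric(out)
}

#' Align an expression matrix to a requested gene order
#'
#' Used to put a cohort into the exact gene space of a trained model.
#' Output rows follow `genes` exactly; library sizes are recomputed on the
#' subset.
#'
#' @param x an [expression_matrix()].
#' @param genes ordered character vector of gene ids.
#' @param missing_policy `"error"` aborts naming absent genes; `"zero"`
#'   inserts all-zero rows for them (with a warning).
#' @return An [expression_matrix()] whose rows are exactly `genes`.
#' @export
align_genes <- function(x, genes, missing_policy = c("error", "zero")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(x, "ExpressionMatrix"))
  genes <- trimws(genes)
  if (!length(genes)) stop("requested gene list is empty")
  absent <- setdiff(genes, x$gene_ids)
  if (length(absent)) {
    if (missing_policy == "error")
      stop("genes absent from matrix: ", paste(absent, collapse = ", "))
    warning(sprintf("%d requested genes absent; zero-filled: %s",
                    length(absent),
                    paste(utils::head(absent, 5), collapse = ", ")))
  }
  m <- matrix(0, length(genes), length(x$sample_ids),
              dimnames = list(genes, x$sample_ids))
  present <- intersect(genes, x$gene_ids)
  m[present, ] <- x$counts[present, , drop = FALSE]
  expression_matrix(m)
}

#' Load / apply a two-column orthology map
#'
#' Optional cross-species support (e.g. mouse-trained model applied to a
#' human cohort): a headerless two-column TSV `from_id<TAB>to_id`.
#' `map_gene_ids()` renames matrix rows `from -> to`, dropping rows whose
#' id has no mapping when `drop_unmapped = TRUE`.
#'
#' @param path file path.
#' @return named character vector (names = from, values = to).
#' @export
load_orthology_map <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, col.names = c("from", "to"))
  stats::setNames(trimws(df$to), trimws(df$from))
}

#' @rdname load_orthology_map
#' @param x an [expression_matrix()].
#' @param map named character vector from [load_orthology_map()].
#' @param drop_unmapped drop genes without a mapping (default) or keep
#'   their original ids.
#' @export
map_gene_ids <- function(x, map, drop_unmapped = TRUE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  mapped <- unname(map[x$gene_ids])
  keep <- !is.na(mapped)
  if (drop_unmapped) {
    m <- x$counts[keep, , drop = FALSE]
    rownames(m) <- mapped[keep]
  } else {
    m <- x$counts
    rownames(m) <- ifelse(keep, mapped, x$gene_ids)
  }
  expression_matrix(m)
}
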