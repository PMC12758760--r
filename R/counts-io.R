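# Count-matrix I/O and validation. Counts are plain integer matrices with
# gene ids as rownames and sample ids as colnames; TSV carries gene ids in
# the first column, MatrixMarket uses sidecar *_genes.txt / *_samples.txt.

assert_count_matrix <- function(cm) {
  if (!is.matrix(cm) || !is.numeric(cm))
    stop("count matrix must be a numeric matrix")
  if (nrow(cm) == 0 || ncol(cm) == 0) stop("count matrix is empty")
  if (is.null(rownames(cm)) || is.null(colnames(cm)))
    stop("count matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(cm))) stop("format error: duplicate gene ids")
  if (anyDuplicated(colnames(cm))) stop("format error: duplicate sample ids")
  if (anyNA(cm)) stop("format error: missing values in counts")
  if (any(cm < 0)) stop("format error: negative counts")
  if (any(abs(cm - round(cm)) > 1e-8))
    stop("format error: non-integer counts")
  invisible(cm)
}

mtx_sidecars <- function(path) {
  base <- sub("\\.mtx$", "", path)
  list(genes = paste0(base, "_genes.txt"), samples = paste0(base, "_samples.txt"))
}

#' Read a gene-by-sample count matrix
#'
#' @param path File path. For `format = "tsv"`, a tab-delimited file with a
#'   header row and gene ids in the first column. For `format = "mtx"`, a
#'   MatrixMarket coordinate file with row/column ids in sidecar files
#'   `<base>_genes.txt` and `<base>_samples.txt` (one id per line).
#' @param format `"tsv"` or `"mtx"`.
#' @return A validated integer matrix with gene rownames and sample
#'   colnames, in file order.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("format error: no sample columns in ", path)
    cm <- as.matrix(df[, -1, drop = FALSE])
    rownames(cm) <- as.character(df[[1]])
    storage.mode(cm) <- "double"
  } else {
    side <- mtx_sidecars(path)
    if (!file.exists(side$genes) || !file.exists(side$samples))
      stop("format error: missing sidecar id files for ", path)
    m <- Matrix::readMM(path)
    cm <- as.matrix(m)
    rownames(cm) <- readLines(side$genes)
    colnames(cm) <- readLines(side$samples)
  }
  assert_count_matrix(cm)
  storage.mode(cm) <- "integer"
  cm
}

#' Write a count matrix
#'
#' @param cm Validated count matrix.
#' @param path Output path (`.mtx` recommended for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  assert_count_matrix(cm)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(cm), cm, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    side <- mtx_sidecars(path)
    Matrix::writeMM(Matrix::Matrix(cm, sparse = TRUE), path)
    writeLines(rownames(cm), side$genes)
    writeLines(colnames(cm), side$samples)
  }
  invisible(path)
}

#' Remove genes below a mean-count abundance threshold
#'
#' Drops every gene whose mean count across all samples of the supplied
#' matrix is strictly below `threshold_mean` (default 2 reads per
#' individual); a gene averaging exactly the threshold is retained. The
#' filter is intended to be applied after subsetting to one line, so the
#' average is per individual of that line.
#'
#' @param cm Count matrix.
#' @param threshold_mean Nonnegative mean-count threshold.
#' @return A list with `counts` (the retained submatrix) and
#'   `removed_gene_ids`.
#' @export
low_count_filter <- function(cm, threshold_mean = 2.0) {
  assert_count_matrix(cm)
  if (threshold_mean < 0) stop("threshold_mean must be >= 0")
  keep <- rowMeans(cm) >= threshold_mean
  list(counts = cm[keep, , drop = FALSE],
       removed_gene_ids = rownames(cm)[!keep])
}

#' Cross-validate a count matrix against sample metadata and annotation
#'
#' Checks that every sample of the matrix appears in the sample table and
#' every gene in the annotation; annotation rows for genes absent from the
#' matrix are tolerated (dropped with a warning).
#'
#' @param cm Count matrix.
#' @param samples Sample table with a `sample_id` column.
#' @param annotation Gene annotation with a `gene_id` column, or `NULL`.
#' @return A list `(counts, samples, annotation)` with `samples` and
#'   `annotation` reordered to match the matrix.
#' @export
align_tables <- function(cm, samples, annotation = NULL) {
  assert_count_matrix(cm)
  missing_smp <- setdiff(colnames(cm), samples$sample_id)
  if (length(missing_smp))
    stop("samples absent from SampleTable: ",
         paste(missing_smp, collapse = ", "))
  samples <- samples[match(colnames(cm), samples$sample_id), , drop = FALSE]
  if (!is.null(annotation)) {
    missing_gene <- setdiff(rownames(cm), annotation$gene_id)
    if (length(missing_gene))
      stop("genes absent from annotation: ",
           paste(utils::head(missing_gene, 5), collapse = ", "),
           if (length(missing_gene) > 5) " ...")
    extra <- setdiff(annotation$gene_id, rownames(cm))
    if (length(extra))
      warning(length(extra), " annotation genes not in matrix; ignored")
    annotation <- annotation[match(rownames(cm), annotation$gene_id), ,
                             drop = FALSE]
  }
  list(counts = cm, samples = samples, annotation = annotation)
}

#' Infer subgenome from gene id suffix
#'
#' Parses the trailing `.L` / `.S` gene-id convention of the allotetraploid
#' genome; ids without the suffix give `NA`.
#'
#' @param gene_ids Character vector.
#' @return Character vector of `"L"`, `"S"` or `NA`.
#' @export
subgenome_from_id <- function(gene_ids) {
  out <- rep(NA_character_, length(gene_ids))
  out[grepl("\\.L$", gene_ids)] <- "L"
  out[grepl("\\.S$", gene_ids)] <- "S"
  out
}
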