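#' Bulk count matrix with sample metadata
#'
#' Bundles a genes x samples matrix of raw integer counts with the per-sample
#' annotation (condition, group, dataset id) that the expression filters and
#' group comparisons require.  This is the raw-count container consumed by
#' [cpm()], [filter_cpm_half()] and [filter_mean_count()].
#'
#' @param counts Numeric matrix of nonnegative integer counts, genes in rows,
#'   samples in columns; both dimensions must carry unique names.
#' @param sample_meta Data frame with one row per sample (in column order of
#'   `counts`), containing at least `condition` and `group`; an optional
#'   `dataset_id` column tags the originating dataset.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `sample_meta`.
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(condition = rep(c("HSC", "MPP"), each = 2),
#'                    group = rep(c("WT", "KO"), 2))
#' count_matrix(m, meta)
#' @export
count_matrix <- function(counts, sample_meta) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_plagekit("`counts` must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_plagekit("`counts` must have gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop_plagekit("gene and sample identifiers must be unique")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_plagekit("counts must be nonnegative integers")
  }
  sample_meta <- as.data.frame(sample_meta)
  if (nrow(sample_meta) != ncol(counts)) {
    stop_plagekit("`sample_meta` must have one row per sample")
  }
  for (col in c("condition", "group")) {
    if (is.null(sample_meta[[col]])) {
      stop_plagekit(sprintf("`sample_meta` must contain a `%s` column", col))
    }
  }
  if (is.null(sample_meta$dataset_id)) sample_meta$dataset_id <- "dataset1"
  rownames(sample_meta) <- colnames(counts)
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("conditions:", paste(unique(x$sample_meta$condition), collapse = ", "),
      "\n")
  cat("groups:    ", paste(unique(x$sample_meta$group), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Normalized expression matrix
#'
#' A real-valued genes x samples (bulk) or cells x genes (single cell) matrix
#' together with the declared normalization scale, so downstream steps can
#' verify they are fed the scale they expect.
#'
#' @param values Numeric matrix with dimension names.
#' @param scale One of `"cpm"`, `"log2cpm1"`, `"log1p_tp10k"`,
#'   `"lognorm_other"`.
#' @param sample_meta Optional per-column metadata carried along from a
#'   [count_matrix()].
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values,
                        scale = c("cpm", "log2cpm1", "log1p_tp10k",
                                  "lognorm_other"),
                        sample_meta = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_plagekit("`values` must be a numeric matrix")
  }
  structure(list(values = values, scale = scale, sample_meta = sample_meta),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix (%s): %d x %d\n", x$scale,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept either an expr_matrix or a bare numeric matrix.
expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop_plagekit("expected an `expr_matrix` or a numeric matrix")
}

#' Single-cell count matrix for quality control
#'
#' Cells x genes raw counts plus the set of mitochondrial genes used for the
#' mitochondrial-content filter.  Per-cell totals are computed once at
#' construction.
#'
#' @param counts Numeric matrix of nonnegative counts, cells in rows, genes
#'   in columns, both named.
#' @param mito_genes Character vector of gene identifiers counted as
#'   mitochondrial (subset of `colnames(counts)`; may be empty).
#' @return An object of class `cell_matrix` with elements `counts`,
#'   `total` (per-cell sum) and `mito_genes`.
#' @export
cell_matrix <- function(counts, mito_genes = character()) {
  if (!is.matrix(counts) || !is.numeric(counts) || any(counts < 0)) {
    stop_plagekit("`counts` must be a nonnegative numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_plagekit("`counts` must have cell row names and gene column names")
  }
  mito_genes <- as.character(mito_genes)
  if (!all(mito_genes %in% colnames(counts))) {
    stop_plagekit("`mito_genes` must all be columns of `counts`")
  }
  structure(list(counts = counts, total = rowSums(counts),
                 mito_genes = mito_genes),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("cell_matrix: %d cells x %d genes (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts), length(x$mito_genes)))
  invisible(x)
}

#' Read and write single-cell matrices in MatrixMarket format
#'
#' Thin wrappers over [Matrix::readMM()]/[Matrix::writeMM()] with the usual
#' barcodes/genes sidecar files (one identifier per line).  The MatrixMarket
#' convention stores genes in rows and cells in columns; the returned
#' [cell_matrix()] is transposed to cells x genes.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param barcodes_path,genes_path Paths to the sidecar identifier files.
#' @param mito_prefix Genes whose name starts with this prefix are flagged
#'   mitochondrial (default `"mt-"`, the mouse convention).
#' @return `read_cell_mtx()` returns a [cell_matrix()].
#' @export
read_cell_mtx <- function(mtx_path, barcodes_path, genes_path,
                          mito_prefix = "mt-") {
  m <- as.matrix(Matrix::readMM(mtx_path))
  barcodes <- readLines(barcodes_path)
  genes <- readLines(genes_path)
  if (nrow(m) != length(genes) || ncol(m) != length(barcodes)) {
    stop_plagekit("MTX dimensions do not match the barcodes/genes sidecars")
  }
  dimnames(m) <- list(genes, barcodes)
  mito <- genes[startsWith(genes, mito_prefix)]
  cell_matrix(t(m), mito_genes = mito)
}

#' @param cells A [cell_matrix()] to write.
#' @param dir Output directory (created if needed); writes `matrix.mtx`,
#'   `barcodes.tsv` and `genes.tsv`.
#' @rdname read_cell_mtx
#' @export
write_cell_mtx <- function(cells, dir) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- Matrix::Matrix(t(cells$counts), sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "genes.tsv"))
  invisible(file.path(dir, "matrix.mtx"))
}

#' Read a bulk count matrix from TSV
#'
#' Genes in rows (first column = gene id), samples in columns.  Sample
#' metadata is supplied separately as a TSV with columns `sample`,
#' `condition`, `group` and optionally `dataset_id`.
#'
#' @param counts_path Path to the counts TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @return A [count_matrix()].
#' @export
read_count_tsv <- function(counts_path, meta_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  genes <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- genes
  meta <- utils::read.delim(meta_path)
  if (is.null(meta$sample)) stop_plagekit("metadata must have a `sample` column")
  idx <- match(colnames(m), meta$sample)
  if (anyNA(idx)) stop_plagekit("metadata missing entries for some samples")
  count_matrix(m, meta[idx, setdiff(names(meta), "sample"), drop = FALSE])
}
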