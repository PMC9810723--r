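#' Counts-per-million normalization
#'
#' `value[g, s] = counts[g, s] / colsum(s) * 1e6`; the unit in which the
#' half-the-samples expression filter is stated.
#'
#' @param counts A [count_matrix()].
#' @return An [expr_matrix()] with scale `"cpm"` (columns sum to 1e6).
#' @export
cpm <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- colSums(counts$counts)
  if (any(totals == 0)) {
    stop_plagekit(sprintf("sample(s) with zero total counts: %s",
                          paste(colnames(counts$counts)[totals == 0],
                                collapse = ", ")))
  }
  expr_matrix(sweep(counts$counts, 2L, totals, `/`) * 1e6, scale = "cpm",
              sample_meta = counts$sample_meta)
}

#' log2(CPM + 1) normalization
#'
#' The default scale fed to the activity-scoring PCA: mean-centring without
#' variance scaling is meaningful only on a roughly homoscedastic scale.
#'
#' @param counts A [count_matrix()].
#' @return An [expr_matrix()] with scale `"log2cpm1"`.
#' @export
log2cpm1 <- function(counts) {
  x <- cpm(counts)
  expr_matrix(log2(x$values + 1), scale = "log2cpm1",
              sample_meta = x$sample_meta)
}

# shared condition lookup for the bulk filters
condition_groups <- function(counts) {
  cond <- as.character(counts$sample_meta$condition)
  if (anyNA(cond)) stop_plagekit("unknown (missing) condition label")
  split(seq_len(ncol(counts$counts)), cond)
}

subset_count_matrix <- function(counts, keep, rule) {
  out <- count_matrix(counts$counts[keep, , drop = FALSE],
                      counts$sample_meta)
  attr(out, "filter_report") <- list(
    rule = rule, n_input = nrow(counts$counts), n_kept = sum(keep),
    n_dropped = sum(!keep))
  out
}

#' Expression filter: minimum CPM in at least half the samples of a condition
#'
#' A gene is kept when, in at least one condition, the number of samples
#' with CPM at or above `min_cpm` reaches `ceiling(frac * n_condition)`
#' ("at least half" of five samples is three).  A retained-gene report is
#' attached as the `"filter_report"` attribute.
#'
#' @param counts A [count_matrix()] with condition labels.
#' @param min_cpm CPM threshold (default 1, inclusive).
#' @param frac Required fraction of a condition's samples (default 0.5).
#' @return The filtered [count_matrix()].
#' @export
filter_cpm_half <- function(counts, min_cpm = 1, frac = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  if (frac <= 0 || frac > 1) stop_plagekit("`frac` must be in (0, 1]")
  groups <- condition_groups(counts)
  cpm_vals <- cpm(counts)$values
  keep_per_cond <- vapply(groups, function(idx) {
    need <- ceiling(frac * length(idx))
    rowSums(cpm_vals[, idx, drop = FALSE] >= min_cpm) >= need
  }, logical(nrow(cpm_vals)))
  keep <- rowSums(matrix(keep_per_cond, nrow = nrow(cpm_vals))) > 0
  subset_count_matrix(counts, keep, "cpm_half")
}

#' Expression filter: minimum mean raw count within a condition
#'
#' A gene is kept when its mean raw count across the samples of at least one
#' condition is at or above `threshold` (inclusive: a mean of exactly 16
#' passes the default).
#'
#' @param counts A [count_matrix()] with condition labels.
#' @param threshold Mean raw count threshold (default 16).
#' @return The filtered [count_matrix()].
#' @export
filter_mean_count <- function(counts, threshold = 16) {
  stopifnot(inherits(counts, "count_matrix"))
  groups <- condition_groups(counts)
  keep_per_cond <- vapply(groups, function(idx) {
    rowMeans(counts$counts[, idx, drop = FALSE]) >= threshold
  }, logical(nrow(counts$counts)))
  keep <- rowSums(matrix(keep_per_cond, nrow = nrow(counts$counts))) > 0
  subset_count_matrix(counts, keep, "mean_count")
}

#' Single-cell quality control
#'
#' Removes low-quality cells with fewer than `min_counts` total counts,
#' fewer than `min_genes` detected genes (count > 0), or more than
#' `max_mito_pct` percent of counts in mitochondrial genes.  The removal
#' conditions are strict inequalities, so boundary cells (exactly 2000
#' counts, exactly 800 genes, exactly 10% mitochondrial) are kept.
#'
#' @param cells A [cell_matrix()].
#' @param min_counts Minimum total counts per cell (default 2000).
#' @param min_genes Minimum detected genes per cell (default 800).
#' @param max_mito_pct Maximum mitochondrial content in percent (default 10).
#' @return The filtered [cell_matrix()], with a `"qc_report"` attribute
#'   giving the number of cells failing each rule.
#' @export
cell_qc <- function(cells, min_counts = 2000, min_genes = 800,
                    max_mito_pct = 10) {
  stopifnot(inherits(cells, "cell_matrix"))
  total <- cells$total
  detected <- rowSums(cells$counts > 0)
  mito_pct <- if (length(cells$mito_genes)) {
    100 * rowSums(cells$counts[, cells$mito_genes, drop = FALSE]) /
      pmax(total, 1)
  } else {
    rep(0, nrow(cells$counts))
  }
  low_counts <- total < min_counts
  low_genes <- detected < min_genes
  high_mito <- mito_pct > max_mito_pct
  keep <- !(low_counts | low_genes | high_mito)
  out <- cell_matrix(cells$counts[keep, , drop = FALSE], cells$mito_genes)
  attr(out, "qc_report") <- list(
    n_input = length(total), n_kept = sum(keep),
    n_low_counts = sum(low_counts), n_low_genes = sum(low_genes),
    n_high_mito = sum(high_mito))
  out
}

#' log1p(TP10K) normalization for single cells
#'
#' `value = ln(1 + count / cell_total * 1e4)`, the standard per-cell
#' depth normalization followed by natural log1p.
#'
#' @param cells A [cell_matrix()] with positive per-cell totals.
#' @return An [expr_matrix()] (cells x genes) with scale `"log1p_tp10k"`.
#' @export
lognorm_tp10k <- function(cells) {
  stopifnot(inherits(cells, "cell_matrix"))
  if (any(cells$total == 0)) {
    stop_plagekit(sprintf("cell(s) with zero total counts: %s",
                          paste(rownames(cells$counts)[cells$total == 0],
                                collapse = ", ")))
  }
  expr_matrix(log1p(sweep(cells$counts, 1L, cells$total, `/`) * 1e4),
              scale = "log1p_tp10k")
}

#' Combined significance/fold-change gene ranking for enrichment input
#'
#' Ranks genes by the Euclidean norm of `log2` fold change and `-log10`
#' adjusted p, so that genes with both higher significance and higher fold
#' change receive more weight.  By default the magnitude is signed by the
#' direction of the fold change (a purely unsigned magnitude cannot drive a
#' directional enrichment test); set `signed = FALSE` for the raw magnitude.
#'
#' @param records Data frame with columns `gene`, `log2fc`, `padj`
#'   (`padj` in `(0, 1]`).
#' @param signed Attach the sign of `log2fc` to the score (default `TRUE`).
#' @return Data frame (`gene`, `score`) sorted by decreasing score, ties
#'   broken by gene identifier.
#' @examples
#' gsea_rank(data.frame(gene = "a", log2fc = 3, padj = 1e-4))  # score 5
#' @export
gsea_rank <- function(records, signed = TRUE) {
  records <- as.data.frame(records)
  for (col in c("gene", "log2fc", "padj")) {
    if (is.null(records[[col]])) {
      stop_plagekit(sprintf("`records` must contain a `%s` column", col))
    }
  }
  if (any(records$padj <= 0) || any(records$padj > 1)) {
    stop_plagekit("`padj` must lie in (0, 1]")
  }
  magnitude <- sqrt(records$log2fc^2 + log10(records$padj)^2)
  score <- if (signed) sign(records$log2fc) * magnitude else magnitude
  out <- data.frame(gene = as.character(records$gene), score = score)
  out[order(-out$score, out$gene), , drop = FALSE]
}
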