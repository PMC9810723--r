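#' Derive cell-type gene signatures from a marker table
#'
#' For each cell type: keep markers with `log2fc` strictly over `min_lfc`,
#' take the top `top_n` by the table's ranking (an optional `rank_col`,
#' decreasing; otherwise the table's own row order), drop any gene that
#' appears in more than one cell type's candidate list, and restrict to the
#' measured gene universe.  This reproduces the top-100 / log2FC > 0.25 /
#' not-duplicated / present-in-dataset convention for building signatures
#' from a reference marker table.
#'
#' @param markers Data frame with columns `celltype`, `gene`, `log2fc` and
#'   optionally the column named by `rank_col`.
#' @param top_n Candidates kept per cell type after the fold-change filter
#'   (default 100).
#' @param min_lfc Strict lower bound on `log2fc` (default 0.25; a gene at
#'   exactly 0.25 is excluded).
#' @param universe Character vector of genes present in the dataset.
#' @param rank_col Optional column to rank candidates by (decreasing).
#' @return Named list of [gene_set()] objects, one per cell type.  A cell
#'   type left with zero genes is an error.
#' @export
derive_signatures <- function(markers, top_n = 100, min_lfc = 0.25,
                              universe, rank_col = NULL) {
  markers <- as.data.frame(markers)
  for (col in c("celltype", "gene", "log2fc")) {
    if (is.null(markers[[col]])) {
      stop_plagekit(sprintf("`markers` must contain a `%s` column", col))
    }
  }
  if (missing(universe) || length(universe) == 0L) {
    stop_plagekit("`universe` must be supplied")
  }
  types <- unique(as.character(markers$celltype))
  candidates <- lapply(types, function(tt) {
    tab <- markers[markers$celltype == tt & markers$log2fc > min_lfc, ,
                   drop = FALSE]
    if (!is.null(rank_col)) {
      if (is.null(tab[[rank_col]])) {
        stop_plagekit(sprintf("rank column `%s` not found", rank_col))
      }
      tab <- tab[order(-tab[[rank_col]]), , drop = FALSE]
    }
    unique(as.character(tab$gene))[seq_len(min(top_n, length(unique(tab$gene))))]
  })
  names(candidates) <- types
  pooled <- unlist(candidates, use.names = FALSE)
  dup <- unique(pooled[duplicated(pooled)])
  out <- lapply(types, function(tt) {
    genes <- setdiff(candidates[[tt]], dup)
    genes <- genes[genes %in% universe]
    if (length(genes) == 0L) {
      stop_plagekit(sprintf("cell type '%s' has no surviving signature genes", tt))
    }
    gene_set(tt, genes, species = "other",
             provenance = sprintf("top %d markers, log2FC > %g, deduplicated",
                                  top_n, min_lfc))
  })
  names(out) <- types
  out
}

#' Expression-bin-matched signature module score
#'
#' Per-cell score of a signature: the mean log-normalized expression of the
#' signature genes minus the mean of a pooled control set matched on
#' average expression.  All genes are binned into `n_bins` equal-frequency
#' bins of average expression across cells; each signature gene contributes
#' `n_ctrl` control genes drawn from its bin — without replacement when the
#' bin holds at least `n_ctrl` genes, with replacement when the bin is
#' smaller.  The draw is seeded, so a fixed seed gives identical scores.
#'
#' @param expr An [expr_matrix()] or numeric cells x genes matrix of
#'   log-normalized expression.
#' @param set A [gene_set()]; genes absent from the matrix are ignored,
#'   an empty intersection is an error.
#' @param n_bins Number of average-expression bins (default 24).
#' @param n_ctrl Control genes drawn per signature gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expr, set, n_bins = 24, n_ctrl = 100, seed) {
  if (missing(seed)) stop_plagekit("`seed` is required")
  vals <- expr_values(expr)
  stopifnot(inherits(set, "gene_set"))
  if (is.null(colnames(vals))) stop_plagekit("expression matrix needs gene column names")
  if (n_bins < 1L) stop_plagekit("`n_bins` must be >= 1")
  sig <- intersect(set$genes, colnames(vals))
  if (length(sig) == 0L) {
    stop_plagekit(sprintf("signature '%s' empty after intersection with the matrix",
                          set$name))
  }
  gene_means <- colMeans(vals)
  n_genes <- length(gene_means)
  # equal-frequency bins on average expression, ties broken by column order
  rank_idx <- rank(gene_means, ties.method = "first")
  bin_of <- ceiling(rank_idx * min(n_bins, n_genes) / n_genes)
  bins <- split(colnames(vals), bin_of)

  ctrl <- with_seed(derive_seed(seed, "module"), {
    unlist(lapply(sig, function(g) {
      pool <- bins[[as.character(bin_of[[match(g, colnames(vals))]])]]
      if (length(pool) <= n_ctrl) {
        if (length(pool) == n_ctrl) pool
        else sample(pool, n_ctrl, replace = TRUE)
      } else {
        sample(pool, n_ctrl, replace = FALSE)
      }
    }), use.names = FALSE)
  })
  scores <- rowMeans(vals[, sig, drop = FALSE]) -
    rowMeans(vals[, ctrl, drop = FALSE])
  stats::setNames(scores, rownames(vals))
}

#' Aggregate per-cell signature scores to cluster-level enrichment
#'
#' @param scores Numeric cells x signatures matrix (or data frame) of
#'   module scores; row names are cells.
#' @param labels Per-cell cluster labels (named vector matched to score
#'   rows, or positional).
#' @return An object of class `signature_score_table`: list with `cells`,
#'   `cluster_labels`, `signatures`, `cell_scores` and `cluster_enrichment`
#'   (clusters x signatures matrix of mean scores).
#' @export
cluster_enrichment <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("cell", seq_len(nrow(scores)))
  }
  labels <- if (!is.null(names(labels))) labels[rownames(scores)]
            else stats::setNames(as.character(labels), rownames(scores))
  if (anyNA(labels)) stop_plagekit("every cell must have a cluster label")
  cl <- sort(unique(as.character(labels)))
  enr <- t(vapply(cl, function(k) {
    colMeans(scores[labels == k, , drop = FALSE])
  }, numeric(ncol(scores))))
  dimnames(enr) <- list(cl, colnames(scores))
  structure(list(cells = rownames(scores), cluster_labels = labels,
                 signatures = colnames(scores), cell_scores = scores,
                 cluster_enrichment = enr),
            class = "signature_score_table")
}

#' @export
print.signature_score_table <- function(x, ...) {
  cat(sprintf("signature_score_table: %d cells, %d clusters, %d signatures\n",
              length(x$cells), nrow(x$cluster_enrichment),
              length(x$signatures)))
  print(round(x$cluster_enrichment, 3))
  invisible(x)
}

#' Assign clusters to cell types by the maximum-enrichment margin rule
#'
#' A cluster is labelled with its highest-scoring signature only when that
#' score exceeds the runner-up by more than `margin` (default 0.2);
#' otherwise it is flagged `AMBIGUOUS` for manual curation — never silently
#' reassigned.  An alternative reading of the rule, assignment whenever the
#' maximum score itself reaches `margin` (an absolute floor), is available
#' via `rule = "absolute"`.
#'
#' @param table A [cluster_enrichment()] result.
#' @param margin Required separation (gap rule) or floor (absolute rule).
#' @param rule `"gap"` (best minus runner-up must exceed `margin`) or
#'   `"absolute"` (best score must be at least `margin`).
#' @return Data frame with one row per cluster: `cluster`, `label`
#'   (signature name or `"AMBIGUOUS"`), `best`, `runner_up`, `gap`.
#' @export
assign_clusters <- function(table, margin = 0.2, rule = c("gap", "absolute")) {
  rule <- match.arg(rule)
  stopifnot(inherits(table, "signature_score_table"))
  enr <- table$cluster_enrichment
  if (ncol(enr) < 2L) stop_plagekit("need at least 2 signatures to assign")
  out <- lapply(rownames(enr), function(k) {
    row <- enr[k, ]
    ord <- order(row, decreasing = TRUE)
    best <- colnames(enr)[ord[1L]]
    runner <- colnames(enr)[ord[2L]]
    gap <- row[[ord[1L]]] - row[[ord[2L]]]
    assigned <- if (rule == "gap") gap > margin else row[[ord[1L]]] >= margin
    data.frame(cluster = k,
               label = if (assigned) best else "AMBIGUOUS",
               best = best, runner_up = runner, gap = gap,
               best_score = row[[ord[1L]]])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Apply a manual-curation override to cluster assignments
#'
#' Replaces labels for the listed clusters; the override provenance is kept
#' in an `overridden` column so curated relabels are always visible.
#'
#' @param assignments Output of [assign_clusters()].
#' @param overrides Data frame with columns `cluster`, `label`.
#' @return The amended assignment data frame.
#' @export
curate_assignments <- function(assignments, overrides) {
  overrides <- as.data.frame(overrides)
  stopifnot(!is.null(overrides$cluster), !is.null(overrides$label))
  idx <- match(overrides$cluster, assignments$cluster)
  if (anyNA(idx)) stop_plagekit("override refers to unknown cluster(s)")
  assignments$overridden <- FALSE
  assignments$label[idx] <- as.character(overrides$label)
  assignments$overridden[idx] <- TRUE
  assignments
}
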