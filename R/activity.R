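#' Gene-set activity by variance-unscaled first-principal-component scores
#'
#' Estimates per-sample activity of a gene set (here, typically an NF-kB
#' target list) as the sample scores on the first principal component of
#' the gene-set expression submatrix, in the spirit of pathway level
#' analysis of gene expression, with three RNA-seq adaptations:
#'
#' 1. gene rows are mean-centred but **not** scaled to unit variance, so
#'    low-count genes are not inflated;
#' 2. the arbitrary PCA sign is made comparable across datasets by
#'    [align_datasets()];
#' 3. scores are shifted by subtracting the per-dataset minimum, so
#'    reported activities are nonnegative.
#'
#' Concretely, with `X` the centred genes x samples submatrix, the gene
#' loading vector is the first left singular vector `u1` (unit Euclidean
#' norm) and the raw score of sample `s` is `sum_g u1[g] * X[g, s]`, i.e.
#' `sigma1 * v1` carrying the singular value.  Within one dataset the
#' overall sign is fixed deterministically (largest-magnitude loading made
#' positive); cross-dataset consistency is the job of [align_datasets()].
#'
#' @param expr An [expr_matrix()] or numeric genes x samples matrix on a
#'   roughly homoscedastic scale; `log2(CPM+1)` (see [log2cpm1()]) is the
#'   intended default for bulk counts.
#' @param set A [gene_set()]; at least two of its genes must be present.
#' @param dataset_id Label stored with the result (used in alignment
#'   reporting).
#' @return An object of class `activity_result`: list with `dataset_id`,
#'   `samples`, `scores` (min-shifted, so `min(scores) == 0`), `raw_scores`,
#'   `loadings` (named, unit norm), `genes_used`, `var_explained`.
#' @examples
#' m <- matrix(c(0, 2, 1, 3), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' compute_activity(m, gene_set("S", c("a", "b")))
#' @export
compute_activity <- function(expr, set, dataset_id = "dataset1") {
  vals <- expr_values(expr)
  stopifnot(inherits(set, "gene_set"))
  if (is.null(rownames(vals))) stop_plagekit("expression matrix needs gene row names")
  genes_used <- intersect(set$genes, rownames(vals))
  if (length(genes_used) < 2L) {
    stop_plagekit(sprintf("fewer than 2 genes of set '%s' present in the matrix",
                          set$name))
  }
  if (ncol(vals) < 2L) stop_plagekit("need at least 2 samples")
  sub <- vals[genes_used, , drop = FALSE]
  centered <- sub - rowMeans(sub)
  if (all(abs(centered) < 1e-12)) {
    stop_plagekit("degenerate input: all samples identical on the set genes")
  }
  sv <- svd(centered)
  loadings <- sv$u[, 1L]
  raw <- sv$d[1L] * sv$v[, 1L]
  # deterministic within-dataset sign: largest-magnitude loading positive
  if (loadings[which.max(abs(loadings))] < 0) {
    loadings <- -loadings
    raw <- -raw
  }
  new_activity_result(dataset_id, colnames(vals), raw,
                      stats::setNames(loadings, genes_used), genes_used,
                      sv$d[1L]^2 / sum(sv$d^2))
}

new_activity_result <- function(dataset_id, samples, raw, loadings,
                                genes_used, var_explained) {
  structure(list(dataset_id = dataset_id, samples = samples,
                 scores = stats::setNames(raw - min(raw), samples),
                 raw_scores = stats::setNames(raw, samples),
                 loadings = loadings, genes_used = genes_used,
                 var_explained = var_explained),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  cat(sprintf("activity_result '%s': %d samples, %d genes, %.1f%% variance on PC1\n",
              x$dataset_id, length(x$samples), length(x$genes_used),
              100 * x$var_explained))
  print(round(x$scores, 4))
  invisible(x)
}

#' Align activity-score signs across datasets
#'
#' The positive direction of a first principal component is arbitrary, so
#' activity levels computed independently per dataset are not directly
#' comparable.  This step chooses the positive direction to maximize
#' consistency of the PCA loadings between datasets: for every
#' non-reference result, the loadings and raw scores are negated when the
#' inner product of its loadings with the reference loadings (over their
#' shared genes) is negative; the minimum-shift scores are then recomputed.
#' An inner product of exactly zero keeps the unflipped orientation with a
#' warning.
#'
#' @param results List of [compute_activity()] results.
#' @param reference 1-based index of the reference dataset (unchanged).
#' @return The list with every element sign-aligned to the reference; each
#'   gains a logical `flipped` field.
#' @export
align_datasets <- function(results, reference = 1L) {
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "activity_result")))
  if (reference < 1L || reference > length(results)) {
    stop_plagekit("`reference` out of range")
  }
  ref <- results[[reference]]
  out <- results
  for (i in seq_along(results)) {
    res <- results[[i]]
    res$flipped <- FALSE
    if (i != reference) {
      shared <- intersect(res$genes_used, ref$genes_used)
      if (length(shared) < 2L) {
        stop_plagekit(sprintf(
          "alignment undefined: dataset '%s' shares %d < 2 loading genes with the reference",
          res$dataset_id, length(shared)))
      }
      ip <- sum(res$loadings[shared] * ref$loadings[shared])
      if (ip < 0) {
        res$loadings <- -res$loadings
        res$raw_scores <- -res$raw_scores
        res$scores <- res$raw_scores - min(res$raw_scores)
        res$flipped <- TRUE
      } else if (ip == 0) {
        warning(sprintf("loadings of '%s' orthogonal to reference; orientation kept",
                        res$dataset_id), call. = FALSE)
      }
    }
    out[[i]] <- res
  }
  out
}

#' Compare activity between two groups with a Student's t-test
#'
#' Pooled-variance two-sample two-tailed t-test on the shifted activity
#' scores (Welch's form available via `var_equal = FALSE`).  Degenerate
#' inputs follow fixed conventions: identical groups give `t = 0, p = 1`;
#' zero pooled variance with unequal means gives the smallest representable
#' p with a warning.
#'
#' @param result An [compute_activity()] result.
#' @param labels Per-sample group labels (exactly two groups, each with at
#'   least two samples); a named vector is matched to sample names.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return An object of class `group_comparison`: list with `groups`,
#'   `means`, `t_statistic`, `df`, `p_value`.
#' @export
compare_groups <- function(result, labels, var_equal = TRUE) {
  stopifnot(inherits(result, "activity_result"))
  labels <- if (!is.null(names(labels))) labels[result$samples]
            else stats::setNames(labels, result$samples)
  if (anyNA(labels) || length(labels) != length(result$samples)) {
    stop_plagekit("`labels` must cover every sample")
  }
  groups <- sort(unique(as.character(labels)))
  if (length(groups) != 2L) stop_plagekit("need exactly 2 groups")
  x <- result$scores[labels == groups[1L]]
  y <- result$scores[labels == groups[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    stop_plagekit("each group needs at least 2 samples")
  }
  nx <- length(x); ny <- length(y)
  means <- c(mean(x), mean(y))
  if (var_equal) {
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
    se <- sqrt(vx + vy)
    df <- if (se > 0) (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
          else nx + ny - 2
  }
  delta <- means[1L] - means[2L]
  if (se == 0) {
    if (delta == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(delta) * Inf
      p <- .Machine$double.xmin
      warning("zero pooled variance with unequal means; p set to smallest representable value",
              call. = FALSE)
    }
  } else {
    t_stat <- delta / se
    p <- 2 * stats::pt(-abs(t_stat), df)
    if (p == 0) p <- .Machine$double.xmin
    if (p > 1) p <- 1
  }
  structure(list(groups = groups,
                 means = stats::setNames(means, groups),
                 t_statistic = t_stat, df = df, p_value = p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison %s vs %s: means %.4g / %.4g, t = %.4g (df %.3g), p = %.4g\n",
              x$groups[1L], x$groups[2L], x$means[1L], x$means[2L],
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}
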