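#' Simulate bulk RNA-seq counts with a planted gene-set activity factor
#'
#' Generates a negative-binomial genes x samples count matrix in which a
#' designated gene set loads on a latent per-sample "activity" factor,
#' emulating the structure the activity-scoring method assumes: sample
#' `i` in group `k` (0-based index) draws `a_i ~ Normal(effect_size * k, 1)`;
#' each set gene `g` has a positive weight `w_g ~ LogNormal(0, 0.25)` and its
#' expected relative expression is multiplied by `exp(w_g * a_i)`, while
#' background genes are independent of the factor.  Expected counts are
#' rescaled per sample so the expected column total equals a library size
#' drawn uniformly from `libsize_range`, then counts are drawn
#' negative-binomial with `Var = mu + dispersion * mu^2` (`dispersion = 0`
#' uses the Poisson limit).
#'
#' The stored latent factor, set genes and weights make planted-signal
#' recovery directly testable.  Defaults correspond to the standard study
#' conditions used throughout the package's own validation: a 30-gene set,
#' two groups of five samples, a two-latent-SD group shift.
#'
#' @param n_bg_genes Number of background genes (independent of the factor).
#' @param set_size Number of genes in the planted set (>= 2).
#' @param group_sizes Integer vector of per-group sample counts (each >= 2).
#' @param effect_size Shift of the latent factor mean between consecutive
#'   groups, in latent SD units.
#' @param dispersion Negative-binomial dispersion `phi` in
#'   `Var = mu + phi mu^2`; must be `>= 0`, `0` means Poisson.
#' @param libsize_range Length-2 numeric range of expected library sizes.
#' @param seed Integer seed; identical calls with the same seed are
#'   byte-identical.
#' @return An object of class `simulated_bulk`: list with `counts`
#'   (a [count_matrix()]), `true_activity`, `set_genes`, `weights`,
#'   `effect_size`, `dispersion`, `seed`.
#' @examples
#' sim <- simulate_bulk(seed = 1)
#' dim(sim$counts)
#' @export
simulate_bulk <- function(n_bg_genes = 470, set_size = 30,
                          group_sizes = c(5, 5), effect_size = 2,
                          dispersion = 0.3,
                          libsize_range = c(5e5, 2e6), seed) {
  if (missing(seed)) stop_plagekit("`seed` is required")
  if (set_size < 2L) stop_plagekit("`set_size` must be >= 2")
  if (any(group_sizes < 2L)) stop_plagekit("all group sizes must be >= 2")
  if (!is.numeric(dispersion) || dispersion < 0) {
    stop_plagekit("`dispersion` must be >= 0")
  }
  n_genes <- n_bg_genes + set_size
  if (set_size > n_genes) stop_plagekit("`set_size` exceeds total genes")
  n_samples <- sum(group_sizes)
  group_idx <- rep(seq_along(group_sizes) - 1L, group_sizes)

  with_seed(derive_seed(seed, "bulk"), {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    set_genes <- genes[seq_len(set_size)]
    samples <- sprintf("sample%02d", seq_len(n_samples))

    a <- stats::rnorm(n_samples, mean = effect_size * group_idx, sd = 1)
    w <- stats::rlnorm(set_size, meanlog = 0, sdlog = 0.25)
    # baseline relative expression, heavy-tailed as in real libraries
    base <- stats::rlnorm(n_genes, meanlog = 1, sdlog = 1.5)

    rel <- matrix(base, n_genes, n_samples)
    rel[seq_len(set_size), ] <- rel[seq_len(set_size), ] *
      exp(outer(w, a))
    libsize <- stats::runif(n_samples, libsize_range[1L], libsize_range[2L])
    # scale by the baseline total, not the realized column sum, so that
    # background genes stay strictly independent of the latent factor
    mu <- sweep(rel, 2L, libsize / sum(base), `*`)

    counts <- if (dispersion == 0) {
      matrix(stats::rpois(length(mu), lambda = mu), n_genes, n_samples)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, n_samples)
    }
    dimnames(counts) <- list(genes, samples)
    meta <- data.frame(
      condition = paste0("group", group_idx + 1L),
      group = paste0("group", group_idx + 1L),
      dataset_id = "simulated_bulk")
    structure(list(counts = count_matrix(counts, meta),
                   true_activity = stats::setNames(a, samples),
                   set_genes = set_genes,
                   weights = stats::setNames(w, set_genes),
                   effect_size = effect_size, dispersion = dispersion,
                   seed = seed),
              class = "simulated_bulk")
  })
}

#' Simulate log-normalized single-cell matrices with planted signatures
#'
#' Builds a cells x genes log-normalized matrix in which each cluster has a
#' disjoint signature whose genes are elevated by `log(fold_change)` in that
#' cluster only, plus additive Gaussian noise, clipped at zero.  With
#' `fold_change = 1` there is no signature structure, the null case in which
#' downstream cluster assignment must abstain.
#'
#' @param cells_per_cluster Integer vector, cells in each cluster (>= 1).
#' @param genes Total number of genes; must be at least
#'   `sig_size * length(cells_per_cluster)` so signatures can be disjoint.
#' @param sig_size Signature size per cluster.
#' @param fold_change Expression fold elevation of a cluster's signature in
#'   that cluster (`>= 1`).
#' @param noise_sd SD of the additive Gaussian noise on the log scale.
#' @param seed Integer seed.
#' @return An object of class `simulated_cells`: list with `lognorm`
#'   (cells x genes matrix), `cluster_labels`, `signatures` (named list of
#'   [gene_set()]), `fold_change`, `noise_sd`, `seed`.
#' @export
simulate_cells <- function(cells_per_cluster = rep(50, 4), genes = 500,
                           sig_size = 25, fold_change = 8, noise_sd = 0.1,
                           seed) {
  if (missing(seed)) stop_plagekit("`seed` is required")
  n_clusters <- length(cells_per_cluster)
  if (any(cells_per_cluster < 1L)) {
    stop_plagekit("every cluster needs at least one cell")
  }
  if (fold_change < 1) stop_plagekit("`fold_change` must be >= 1")
  if (sig_size * n_clusters > genes) {
    stop_plagekit("overlapping signatures requested: sig_size * n_clusters > genes")
  }
  n_cells <- sum(cells_per_cluster)
  labels <- rep(paste0("cluster", seq_len(n_clusters)), cells_per_cluster)

  with_seed(derive_seed(seed, "cells"), {
    gene_ids <- sprintf("gene%04d", seq_len(genes))
    cell_ids <- sprintf("cell%04d", seq_len(n_cells))
    sig_idx <- split(seq_len(sig_size * n_clusters),
                     rep(seq_len(n_clusters), each = sig_size))
    # baseline mean log-expression per gene
    base <- stats::rgamma(genes, shape = 2, rate = 2)
    m <- matrix(rep(base, each = n_cells), n_cells, genes)
    for (k in seq_len(n_clusters)) {
      in_k <- labels == paste0("cluster", k)
      m[in_k, sig_idx[[k]]] <- m[in_k, sig_idx[[k]]] + log(fold_change)
    }
    m <- m + matrix(stats::rnorm(n_cells * genes, sd = noise_sd),
                    n_cells, genes)
    m[m < 0] <- 0
    dimnames(m) <- list(cell_ids, gene_ids)
    sigs <- lapply(seq_len(n_clusters), function(k) {
      gene_set(paste0("type", k), gene_ids[sig_idx[[k]]], species = "mouse",
               provenance = "planted signature")
    })
    names(sigs) <- paste0("type", seq_len(n_clusters))
    structure(list(lognorm = m,
                   cluster_labels = stats::setNames(labels, cell_ids),
                   signatures = sigs, fold_change = fold_change,
                   noise_sd = noise_sd, seed = seed),
              class = "simulated_cells")
  })
}

#' Simulate a right-censored survival cohort
#'
#' Patients carry a standard-normal log2 expression covariate `x`, an age
#' uniform on 18-90 years, and a discrete risk stratum with its own baseline
#' hazard.  Event times are exponential with rate
#' `baseline_rate * s_k * exp(true_beta * x + age_beta * age)` where `s_k`
#' is a per-stratum multiplier, so a stratified Cox model on `x` and age is
#' correctly specified with true log hazard ratio `true_beta`.  Censoring is
#' independent `Uniform(0, c_max)` with `c_max` solved numerically so the
#' expected censored fraction equals `censor_rate` (non-informative
#' censoring); `censor_rate = 0` observes every event.
#'
#' @param n Number of patients (>= 10).
#' @param true_beta Log hazard ratio per unit of expression.
#' @param baseline_rate Baseline event rate per day (> 0).
#' @param censor_rate Target censored fraction in `[0, 1]`.
#' @param n_strata Number of risk strata (>= 1); three strata are labelled
#'   favorable/intermediate/adverse in the cytogenetic convention.
#' @param age_beta Log hazard ratio per year of age.
#' @param seed Integer seed.
#' @return An object of class `simulated_cohort`: list with `cohort` (data
#'   frame: `id`, `time`, `event`, `expr`, `age`, `stratum`), `true_beta`,
#'   `censor_rate`, `n_strata`, `seed`.
#' @export
simulate_cohort <- function(n = 200, true_beta = 0.5, baseline_rate = 0.002,
                            censor_rate = 0.3, n_strata = 3,
                            age_beta = 0.02, seed) {
  if (missing(seed)) stop_plagekit("`seed` is required")
  if (n < 10L) stop_plagekit("`n` must be >= 10")
  if (baseline_rate <= 0) stop_plagekit("`baseline_rate` must be > 0")
  if (censor_rate < 0 || censor_rate > 1) {
    stop_plagekit("`censor_rate` must be in [0, 1]")
  }
  if (n_strata < 1L) stop_plagekit("`n_strata` must be >= 1")

  with_seed(derive_seed(seed, "cohort"), {
    x <- stats::rnorm(n)
    age <- stats::runif(n, 18, 90)
    stratum_id <- sample.int(n_strata, n, replace = TRUE)
    strat_mult <- exp(stats::rnorm(n_strata, sd = 0.5))
    rate <- baseline_rate * strat_mult[stratum_id] *
      exp(true_beta * x + age_beta * age)
    t_event <- stats::rexp(n, rate = rate)

    if (censor_rate == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else if (censor_rate == 1) {
      time <- t_event * stats::runif(n)
      event <- rep(0L, n)
    } else {
      # P(censored_i | c_max) = min(t_i / c_max, 1) for C ~ U(0, c_max)
      frac <- function(c_max) mean(pmin(t_event / c_max, 1)) - censor_rate
      upper <- max(t_event) / censor_rate + 1
      c_max <- stats::uniroot(frac, lower = min(t_event) * 1e-6,
                              upper = upper, tol = 1e-10)$root
      cens <- stats::runif(n, 0, c_max)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    labels <- if (n_strata == 3L) c("favorable", "intermediate", "adverse")
              else paste0("stratum", seq_len(n_strata))
    cohort <- data.frame(
      id = sprintf("patient%04d", seq_len(n)),
      time = time, event = event, expr = x, age = age,
      stratum = labels[stratum_id])
    structure(list(cohort = cohort, true_beta = true_beta,
                   censor_rate = censor_rate, n_strata = n_strata,
                   seed = seed),
              class = "simulated_cohort")
  })
}

#' Write simulated objects to their plain-text exchange formats
#'
#' Bulk counts as TSV plus a metadata TSV, cells as MatrixMarket with
#' barcodes/genes sidecars, cohorts as CSV
#' (`id,time_days,event,expr_log2,age_years,stratum`); ground-truth values
#' go to a JSON-like sidecar of plain `key<TAB>value` lines.
#'
#' @param sim A `simulated_bulk`, `simulated_cells` or `simulated_cohort`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_simulated <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (inherits(sim, "simulated_bulk")) {
    tab <- data.frame(gene = rownames(sim$counts$counts),
                      sim$counts$counts, check.names = FALSE)
    utils::write.table(tab, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- data.frame(sample = colnames(sim$counts$counts),
                       sim$counts$sample_meta)
    utils::write.table(meta, file.path(dir, "sample_meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = names(sim$true_activity),
                 true_activity = sim$true_activity),
      file.path(dir, "truth_activity.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    writeLines(sim$set_genes, file.path(dir, "set_genes.txt"))
  } else if (inherits(sim, "simulated_cells")) {
    tab <- data.frame(cell = rownames(sim$lognorm), sim$lognorm,
                      check.names = FALSE)
    utils::write.table(tab, file.path(dir, "lognorm.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(cell = names(sim$cluster_labels),
                 cluster = sim$cluster_labels),
      file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_gene_sets(sim$signatures, file.path(dir, "signatures.gmt"), "gmt")
  } else if (inherits(sim, "simulated_cohort")) {
    out <- sim$cohort
    names(out) <- c("id", "time_days", "event", "expr_log2", "age_years",
                    "stratum")
    utils::write.csv(out, file.path(dir, "cohort.csv"), row.names = FALSE)
    writeLines(sprintf("true_beta\t%.10g", sim$true_beta),
               file.path(dir, "truth_cohort.tsv"))
  } else {
    stop_plagekit("unknown simulated object")
  }
  invisible(dir)
}
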