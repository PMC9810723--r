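# Independent brute-force oracles. These are deliberately written as plain
# loops over definitions, sharing no code path with the package functions
# they check.

library(survival)  # formula specials (strata) in the cutpoint oracle

# First-PC sample scores via eigendecomposition of the sample Gram matrix
# (the package uses SVD): returns sigma1 * v1.
oracle_pc1_scores <- function(sub) {
  centered <- sub - rowMeans(sub)
  g <- crossprod(centered)            # samples x samples
  e <- eigen(g, symmetric = TRUE)
  sqrt(max(e$values[1L], 0)) * e$vectors[, 1L]
}

# agreement up to a global sign
max_dev_up_to_sign <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}

# Brute-force per-gene evaluation of the CPM-in-half-the-samples rule.
oracle_filter_cpm_half <- function(counts, meta, min_cpm = 1, frac = 0.5) {
  totals <- colSums(counts)
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    ok <- FALSE
    for (cond in unique(meta$condition)) {
      idx <- which(meta$condition == cond)
      n_pass <- 0
      for (s in idx) {
        if (counts[g, s] / totals[s] * 1e6 >= min_cpm) n_pass <- n_pass + 1
      }
      if (n_pass >= ceiling(frac * length(idx))) ok <- TRUE
    }
    keep[g] <- ok
  }
  rownames(counts)[keep]
}

# Brute-force per-gene evaluation of the mean-raw-count rule.
oracle_filter_mean_count <- function(counts, meta, threshold = 16) {
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    ok <- FALSE
    for (cond in unique(meta$condition)) {
      idx <- which(meta$condition == cond)
      if (mean(counts[g, idx]) >= threshold) ok <- TRUE
    }
    keep[g] <- ok
  }
  rownames(counts)[keep]
}

# Brute-force per-cell QC rule (strict removal inequalities).
oracle_cell_qc <- function(counts, mito_genes, min_counts = 2000,
                           min_genes = 800, max_mito_pct = 10) {
  keep <- logical(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    total <- sum(counts[i, ])
    detected <- sum(counts[i, ] > 0)
    mito <- if (length(mito_genes)) sum(counts[i, mito_genes]) else 0
    mito_pct <- if (total > 0) 100 * mito / total else 0
    keep[i] <- !(total < min_counts || detected < min_genes ||
                   mito_pct > max_mito_pct)
  }
  rownames(counts)[keep]
}

# Kaplan-Meier product-limit by direct recursion over distinct event times.
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  surv <- numeric(length(times))
  s <- 1
  for (j in seq_along(times)) {
    t_j <- times[j]
    n_risk <- sum(time >= t_j)
    d_j <- sum(time == t_j & event == 1)
    s <- s * (1 - d_j / n_risk)
    surv[j] <- s
  }
  data.frame(time = times, surv = surv)
}

# Two-group log-rank O-E-V from the textbook formula.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))  # 1/2
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t_j in times) {
    at_risk <- time >= t_j
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == t_j & event == 1)
    d1 <- sum(time == t_j & event == 1 & g == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- o_minus_e^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Breslow log partial likelihood for a single covariate, and its brute
# maximizer via one-dimensional optimize().
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_beta <- function(time, event, x) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  interval = c(-20, 20), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Exhaustive minimal-p cutpoint search, coded independently: loops over
# midpoints and calls survival:: directly.
oracle_optimal_cutoff <- function(cohort, min_group_frac = 0.05) {
  expr <- cohort$expr
  vals <- sort(unique(expr))
  best <- NULL
  for (j in seq_len(length(vals) - 1L)) {
    cc <- (vals[j] + vals[j + 1L]) / 2
    low <- expr <= cc
    if (sum(low) < min_group_frac * length(expr)) next
    if (sum(!low) < min_group_frac * length(expr)) next
    dat <- cohort
    dat$grp <- as.numeric(!low)
    full <- suppressWarnings(
      coxph(Surv(time, event) ~ grp + age + strata(stratum),
            data = dat, ties = "breslow"))
    red <- suppressWarnings(
      coxph(Surv(time, event) ~ age + strata(stratum),
            data = dat, ties = "breslow"))
    lrt <- 2 * (full$loglik[2L] - red$loglik[2L])
    p <- pchisq(lrt, 1, lower.tail = FALSE)
    if (is.null(best) || p < best$p) best <- list(cutoff = cc, p = p)
  }
  best
}

# Random bulk fixture for the filter oracles.
random_count_fixture <- function(seed, n_genes = 30, conds = c(3, 4, 4)) {
  set.seed(seed)
  n_samples <- sum(conds)
  m <- matrix(rnbinom(n_genes * n_samples, mu = exp(runif(n_genes, 0, 5)),
                      size = 2),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:n_samples)))
  meta <- data.frame(condition = rep(paste0("c", seq_along(conds)), conds),
                     group = rep(c("WT", "KO"), length.out = n_samples))
  list(counts = m, meta = meta, cm = count_matrix(m, meta))
}
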