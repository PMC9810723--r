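#' Read a survival cohort from CSV
#'
#' Expected columns: `id`, `time_days`, `event`, `expr_log2`, `age_years`,
#' `stratum` and optionally `fab` (the internal short names `time`, `expr`,
#' `age` are also accepted).  Missing age or stratum values are allowed and
#' handled by [apply_exclusions()].
#'
#' @param path CSV path.
#' @return Data frame with columns `id`, `time`, `event`, `expr`, `age`,
#'   `stratum` (and `fab` when present).
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  ren <- c(time_days = "time", expr_log2 = "expr", age_years = "age")
  for (from in names(ren)) {
    if (!is.null(tab[[from]])) names(tab)[names(tab) == from] <- ren[[from]]
  }
  validate_cohort(tab)
}

validate_cohort <- function(cohort) {
  cohort <- as.data.frame(cohort)
  for (col in c("time", "event", "expr")) {
    if (is.null(cohort[[col]])) {
      stop_plagekit(sprintf("cohort must contain a `%s` column", col))
    }
  }
  if (any(cohort$time <= 0, na.rm = TRUE)) {
    stop_plagekit("survival times must be > 0")
  }
  if (!all(cohort$event %in% c(0, 1))) {
    stop_plagekit("`event` must be 0/1")
  }
  cohort
}

#' Apply the cohort exclusion rules
#'
#' Drops patients with overall survival shorter than `min_os_days`
#' (strictly: a survival of exactly 16 days is kept under the default),
#' patients younger than `min_age` years, and patients of unknown age or
#' unknown risk stratum.  A per-reason exclusion report is attached as the
#' `"exclusion_report"` attribute (a patient violating several rules counts
#' in each).
#'
#' @param cohort Cohort data frame (see [read_cohort()]) with `age` and
#'   `stratum` columns.
#' @param min_os_days Minimum overall survival in days (default 16).
#' @param min_age Minimum age in years (default 18).
#' @return The filtered cohort; an empty result is an error.
#' @export
apply_exclusions <- function(cohort, min_os_days = 16, min_age = 18) {
  cohort <- validate_cohort(cohort)
  for (col in c("age", "stratum")) {
    if (is.null(cohort[[col]])) {
      stop_plagekit(sprintf("cohort must contain a `%s` column", col))
    }
  }
  short_os <- cohort$time < min_os_days
  young <- !is.na(cohort$age) & cohort$age < min_age
  no_age <- is.na(cohort$age)
  no_stratum <- is.na(cohort$stratum) | cohort$stratum == ""
  drop <- short_os | young | no_age | no_stratum
  out <- cohort[!drop, , drop = FALSE]
  if (nrow(out) == 0L) stop_plagekit("no patients left after exclusions")
  rownames(out) <- NULL
  attr(out, "exclusion_report") <- list(
    n_input = nrow(cohort), n_kept = nrow(out),
    n_short_os = sum(short_os), n_young = sum(young),
    n_unknown_age = sum(no_age), n_unknown_stratum = sum(no_stratum))
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] returning the step function as a
#' data frame.  Censored observations reduce the risk set only; tied event
#' times form a single step with multiplicity.
#'
#' @param time Positive survival times.
#' @param event 0/1 event indicators.
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `surv`
#'   (nonincreasing, starting from 1 at time 0 implicitly).
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0L) stop_plagekit("empty input")
  if (any(time <= 0)) stop_plagekit("survival times must be > 0")
  fit <- survival::survfit(Surv(time, event) ~ 1, conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square on 1 degree of freedom via
#' [survival::survdiff()], two-sided p.
#'
#' @param time Positive survival times.
#' @param event 0/1 event indicators.
#' @param group Two-level group labels.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop_plagekit("need exactly two groups")
  if (sum(event) < 1L) stop_plagekit("need at least one event")
  sd <- survival::survdiff(Surv(time, event) ~ group)
  stat <- sd$chisq
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Stratified Cox proportional-hazards fit with likelihood-ratio test
#'
#' Fits `Surv(time, event) ~ covariates (+ strata)` by partial likelihood
#' via [survival::coxph()] (Breslow tie handling by default) and reports the
#' likelihood-ratio test of the full model against the covariate-free null,
#' chi-square with one degree of freedom per covariate, alongside per-
#' coefficient Wald statistics.  The headline use is log2 expression
#' adjusted for age and stratified by cytogenetic risk.
#'
#' @param cohort Cohort data frame.
#' @param covariates Character vector of covariate column names (each must
#'   vary; a constant covariate is a non-identifiability error).
#' @param strata Optional stratum column name (separate baseline hazard per
#'   level, shared coefficients).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `cox_fit_result`: list with `coefficients`,
#'   `se`, `z`, `wald_p`, `hr` (hazard ratios), `lrt_statistic`, `lrt_df`,
#'   `lrt_p`, `n`, `n_events`, `n_strata`, `ties`.
#' @export
cox_fit <- function(cohort, covariates, strata = NULL,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  cohort <- validate_cohort(cohort)
  if (length(covariates) < 1L) stop_plagekit("need at least one covariate")
  for (cv in covariates) {
    v <- cohort[[cv]]
    if (is.null(v)) stop_plagekit(sprintf("covariate `%s` not in cohort", cv))
    if (length(unique(v[!is.na(v)])) < 2L) {
      stop_plagekit(sprintf("covariate `%s` is constant: model not identifiable", cv))
    }
  }
  if (sum(cohort$event) == 0L) stop_plagekit("no events in cohort")
  rhs <- paste(covariates, collapse = " + ")
  if (!is.null(strata)) {
    if (is.null(cohort[[strata]])) {
      stop_plagekit(sprintf("stratum column `%s` not in cohort", strata))
    }
    rhs <- paste(rhs, sprintf("+ strata(%s)", strata))
  }
  fml <- stats::as.formula(paste("Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = cohort, ties = ties)
  if (!is.null(fit$info) || anyNA(stats::coef(fit))) {
    stop_plagekit("Cox fit did not converge to a finite estimate")
  }
  lrt <- 2 * (fit$loglik[2L] - fit$loglik[1L])
  df <- length(stats::coef(fit))
  se <- stats::setNames(sqrt(diag(fit$var)), names(stats::coef(fit)))
  z <- stats::coef(fit) / se
  structure(list(coefficients = stats::coef(fit), se = se, z = z,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 hr = exp(stats::coef(fit)),
                 lrt_statistic = lrt, lrt_df = df,
                 lrt_p = stats::pchisq(lrt, df = df, lower.tail = FALSE),
                 n = fit$n, n_events = fit$nevent,
                 n_strata = if (is.null(strata)) 1L
                            else length(unique(cohort[[strata]])),
                 ties = ties),
            class = "cox_fit_result")
}

#' @export
print.cox_fit_result <- function(x, ...) {
  cat(sprintf("cox_fit_result: n = %d, events = %d, strata = %d, ties = %s\n",
              x$n, x$n_events, x$n_strata, x$ties))
  print(data.frame(coef = x$coefficients, hr = x$hr, se = x$se,
                   wald_p = x$wald_p))
  cat(sprintf("LRT: chi2 = %.4g on %d df, p = %.4g\n", x$lrt_statistic,
              x$lrt_df, x$lrt_p))
  invisible(x)
}

# p-value for one candidate dichotomization
cutoff_p <- function(cohort, low, p_source, covariates, strata, ties) {
  if (p_source == "logrank") {
    logrank_test(cohort$time, cohort$event,
                 ifelse(low, "low", "high"))$p_value
  } else {
    dat <- cohort
    dat$expr_high <- as.numeric(!low)
    # extreme candidate splits can give a monotone partial likelihood
    # (infinite group coefficient); the LRT p is still well defined
    full <- suppressWarnings(
      cox_fit(dat, c("expr_high", covariates), strata = strata, ties = ties))
    if (length(covariates) == 0L) {
      full$lrt_p
    } else {
      reduced <- suppressWarnings(
        cox_fit(dat, covariates, strata = strata, ties = ties))
      lrt <- full$lrt_statistic - reduced$lrt_statistic
      stats::pchisq(max(lrt, 0), df = 1L, lower.tail = FALSE)
    }
  }
}

#' Minimal-p optimal expression cutpoint
#'
#' Dichotomizes a continuous expression covariate at the candidate cutoff
#' whose split has the smallest survival-association p-value.  Candidates
#' are the midpoints between consecutive distinct sorted expression values
#' whose induced low (`expr <= cutoff`) and high (`expr > cutoff`) groups
#' both contain at least `min_group_frac * n` patients.  The p-value per
#' candidate is, by default, the one-degree-of-freedom likelihood-ratio
#' test of the group indicator in a Cox model with the given covariates and
#' stratification (`p_source = "cox_lrt"`), or a plain log-rank test.  Ties
#' on the minimal p are broken toward the cutoff nearest the expression
#' median.
#'
#' The reported `p_at_cutoff` is the minimum over many looks and is
#' selection-biased; it is labelled descriptive in the result and must not
#' be read as a calibrated significance level.
#'
#' @param cohort Cohort data frame with an `expr` column.
#' @param min_group_frac Minimum fraction of patients on each side of the
#'   split (default 0.05).
#' @param p_source `"cox_lrt"` (default) or `"logrank"`.
#' @param covariates Adjustment covariates for the Cox source (default
#'   `"age"`; ignored for log-rank).
#' @param strata Stratum column for the Cox source (default `"stratum"`;
#'   ignored for log-rank), or `NULL`.
#' @param ties Cox tie handling.
#' @return An object of class `cutpoint_result`: list with `cutoff`,
#'   `percentile` (percent of patients at or below the cutoff), `p_at_cutoff`,
#'   `p_note`, `group_sizes` (`low`, `high`), `labels` (per patient),
#'   `candidates` (data frame of every candidate cutoff and its p).
#' @export
optimal_cutoff <- function(cohort, min_group_frac = 0.05,
                           p_source = c("cox_lrt", "logrank"),
                           covariates = "age", strata = "stratum",
                           ties = c("breslow", "efron")) {
  p_source <- match.arg(p_source)
  ties <- match.arg(ties)
  cohort <- validate_cohort(cohort)
  expr <- cohort$expr
  n <- length(expr)
  vals <- sort(unique(expr))
  if (length(vals) < 2L) stop_plagekit("need at least 2 distinct expression values")
  mids <- (vals[-length(vals)] + vals[-1L]) / 2
  min_n <- min_group_frac * n
  feasible <- vapply(mids, function(cc) {
    n_low <- sum(expr <= cc)
    n_low >= min_n && (n - n_low) >= min_n
  }, logical(1L))
  mids <- mids[feasible]
  if (length(mids) == 0L) stop_plagekit("no feasible candidate cutoff")
  if (p_source == "logrank") covariates <- character()
  if (p_source == "logrank") strata <- NULL
  ps <- vapply(mids, function(cc) {
    cutoff_p(cohort, expr <= cc, p_source, covariates, strata, ties)
  }, numeric(1L))
  best <- which(ps <= min(ps))
  if (length(best) > 1L) {
    med <- stats::median(expr)
    best <- best[which.min(abs(mids[best] - med))]
  }
  cutoff <- mids[best]
  low <- expr <= cutoff
  structure(list(cutoff = cutoff,
                 percentile = 100 * mean(low),
                 p_at_cutoff = ps[best],
                 p_note = "minimal-p over candidate splits: selection-biased, descriptive",
                 group_sizes = c(low = sum(low), high = sum(!low)),
                 labels = ifelse(low, "low", "high"),
                 candidates = data.frame(cutoff = mids, p = ps)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("cutpoint_result: cutoff = %.6g (percentile %.1f), low/high = %d/%d\n",
              x$cutoff, x$percentile, x$group_sizes[["low"]],
              x$group_sizes[["high"]]))
  cat(sprintf("p at cutoff = %.4g (%s)\n", x$p_at_cutoff, x$p_note))
  invisible(x)
}

#' Mean-cutoff expression classification
#'
#' Labels a sample `high` when its expression strictly exceeds the cohort
#' mean, `low` otherwise; the convention used for relapse cohorts where no
#' cutpoint search is performed.  All-equal input yields all-`low` with a
#' warning.
#'
#' @param expr Numeric expression values (at least 2).
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
classify_mean_cutoff <- function(expr) {
  if (length(expr) < 2L) stop_plagekit("need at least 2 values")
  m <- mean(expr)
  if (all(expr == expr[1L])) {
    warning("all expression values equal; every sample labelled 'low'",
            call. = FALSE)
    return(rep("low", length(expr)))
  }
  ifelse(expr > m, "high", "low")
}

#' Paired two-tailed t-test convenience wrapper
#'
#' Routine paired comparison (for example diagnosis versus relapse
#' expression in matched patients); delegates to [stats::t.test()].
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List with `t_statistic`, `df`, `p_value`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t_statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_difference = unname(ht$estimate))
}
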