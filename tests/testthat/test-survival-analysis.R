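exclusion_fixture <- function() {
  data.frame(
    id = sprintf("p%02d", 1:10),
    time = c(15.9, 16.0, 100, 200, 300, 400, 10, 500, 600, 700),
    event = c(1, 1, 0, 1, 1, 0, 1, 1, 0, 1),
    expr = rnorm(10),
    age = c(50, 60, 17, 70, NA, 40, 55, 45, 30, 80),
    stratum = c("a", "a", "b", NA, "b", "a", "b", "a", "b", "a"),
    stringsAsFactors = FALSE)
}

test_that("exclusion rules are strict and reported per reason", {
  set.seed(1)
  cohort <- exclusion_fixture()
  out <- apply_exclusions(cohort)
  # p01 short OS (15.9 < 16), p02 exactly 16 kept, p03 under-age,
  # p04 unknown stratum, p05 unknown age, p07 short OS
  expect_setequal(out$id, c("p02", "p06", "p08", "p09", "p10"))
  rep <- attr(out, "exclusion_report")
  expect_equal(rep$n_input, 10)
  expect_equal(rep$n_kept, 5)
  expect_equal(rep$n_short_os, 2)
  expect_equal(rep$n_young, 1)
  expect_equal(rep$n_unknown_age, 1)
  expect_equal(rep$n_unknown_stratum, 1)
  expect_error(apply_exclusions(cohort, min_os_days = 1e6), "no patients")
})

test_that("Kaplan-Meier steps match hand-computed product limits", {
  # all events, distinct times
  km1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))
  # tied event times collapse to one step with multiplicity
  km2 <- km_curve(c(2, 2, 5), c(1, 1, 1))
  expect_equal(km2$surv[km2$time == 2], 1 / 3)
  expect_equal(km2$surv[km2$time == 5], 0)
  expect_equal(km2$n_event[km2$time == 2], 2)
  # all censored: survival stays at 1
  km3 <- km_curve(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km3$surv == 1))
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier equals the independent product-limit oracle", {
  set.seed(12)
  for (i in 1:10) {
    time <- round(rexp(40, 0.01), 1) + 0.1
    event <- rbinom(40, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    got <- km_curve(time, event)
    want <- oracle_km(time, event)
    expect_equal(got$surv[got$n_event > 0], want$surv, tolerance = 1e-12)
  }
  # no censoring: KM equals the empirical survival function
  time <- sort(sample(1:100, 20))
  got <- km_curve(time, rep(1, 20))
  expect_equal(got$surv, 1 - seq_len(20) / 20)
})

test_that("log-rank matches the O-E-V oracle and is label-symmetric", {
  set.seed(21)
  for (i in 1:10) {
    time <- round(rexp(30, 0.02), 1) + 0.1
    event <- rbinom(30, 1, 0.8)
    if (sum(event) == 0) event[1] <- 1
    grp <- rep(c("x", "y"), 15)
    got <- logrank_test(time, event, grp)
    want <- oracle_logrank(time, event, grp)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-8)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-8)
    swapped <- logrank_test(time, event, ifelse(grp == "x", "y", "x"))
    expect_equal(got$statistic, swapped$statistic, tolerance = 1e-12)
  }
})

test_that("log-rank degenerate and separation cases behave as declared", {
  # the same patients duplicated into both groups: no difference
  time <- c(5, 10, 15, 5, 10, 15)
  event <- c(1, 1, 0, 1, 1, 0)
  grp <- rep(c("a", "b"), each = 3)
  got <- logrank_test(time, event, grp)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1, tolerance = 1e-12)
  # strong separation is significant
  sep <- logrank_test(c(1:10, 101:110), rep(1, 20),
                      rep(c("early", "late"), each = 10))
  expect_lt(sep$p_value, 0.05)
  expect_error(logrank_test(1:3, c(1, 1, 1), rep("a", 3)), "two groups")
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "event")
})

test_that("Cox fit matches the independent partial-likelihood maximizer", {
  # 8 patients, one binary covariate, no ties
  cohort <- data.frame(
    time = c(3, 5, 7, 11, 13, 17, 19, 23),
    event = c(1, 1, 0, 1, 1, 0, 1, 1),
    expr = c(1, 1, 1, 0, 1, 0, 0, 0))
  fit <- cox_fit(cohort, "expr")
  beta_oracle <- oracle_cox_beta(cohort$time, cohort$event, cohort$expr)
  expect_equal(unname(fit$coefficients), beta_oracle, tolerance = 1e-6)
  expect_gte(fit$lrt_statistic, 0)
  expect_equal(fit$lrt_statistic,
               2 * (oracle_cox_loglik(beta_oracle, cohort$time, cohort$event,
                                      cohort$expr) -
                    oracle_cox_loglik(0, cohort$time, cohort$event,
                                      cohort$expr)),
               tolerance = 1e-6)
  # continuous covariate, random no-ties fixtures
  set.seed(33)
  for (i in 1:5) {
    n <- 30
    x <- rnorm(n)
    time <- rexp(n, 0.01 * exp(0.5 * x))
    event <- rbinom(n, 1, 0.8)
    if (sum(event) < 2) event[1:2] <- 1
    dat <- data.frame(time = time, event = event, expr = x)
    fit <- cox_fit(dat, "expr")
    expect_equal(unname(fit$coefficients),
                 oracle_cox_beta(time, event, x), tolerance = 1e-6)
  }
})

test_that("Cox errors on non-identifiable or event-free input", {
  dat <- data.frame(time = 1:5 + 0.5, event = c(1, 1, 0, 1, 0),
                    expr = rep(0, 5))
  expect_error(cox_fit(dat, "expr"), "constant")
  dat2 <- data.frame(time = 1:5 + 0.5, event = rep(0, 5), expr = rnorm(5))
  expect_error(cox_fit(dat2, "expr"), "no events")
})

test_that("stratified age-adjusted Cox recovers the planted hazard ratio", {
  hits <- 0
  for (s in 1:20) {
    sim <- simulate_cohort(n = 300, true_beta = 1, seed = 100 + s)
    fit <- cox_fit(sim$cohort, c("expr", "age"), strata = "stratum")
    b <- fit$coefficients[["expr"]]
    se <- fit$se[["expr"]]
    if (abs(b - 1) <= 2 * se) hits <- hits + 1
  }
  expect_gte(hits, 18)  # ~95% coverage of the 2-SE interval
})

test_that("optimal cutoff equals the exhaustive independent search", {
  for (s in 1:5) {
    sim <- simulate_cohort(n = 50, true_beta = 1, seed = 200 + s)
    got <- optimal_cutoff(sim$cohort)
    want <- oracle_optimal_cutoff(sim$cohort)
    expect_equal(got$cutoff, want$cutoff, tolerance = 1e-12)
    expect_equal(got$p_at_cutoff, want$p, tolerance = 1e-10)
    expect_equal(got$percentile,
                 100 * mean(sim$cohort$expr <= got$cutoff))
    expect_setequal(names(got$group_sizes), c("low", "high"))
    expect_match(got$p_note, "selection-biased")
  }
})

test_that("cutoff search respects the group-size floor and block structure", {
  # perfectly ordered: low-expression block dies first, far earlier
  cohort <- data.frame(
    time = c(1, 2, 3, 4, 5, 100, 110, 120, 130, 140),
    event = rep(1, 10),
    expr = c(1:5, 101:105),
    age = rep(50, 10),
    stratum = rep("s", 10))
  got <- suppressWarnings(
    optimal_cutoff(cohort, covariates = character(), strata = NULL))
  expect_gt(got$cutoff, 5)
  expect_lt(got$cutoff, 101)
  # min_group_frac = 0.5 leaves only the median split
  got2 <- suppressWarnings(
    optimal_cutoff(cohort, min_group_frac = 0.5,
                   covariates = character(), strata = NULL))
  expect_equal(nrow(got2$candidates), 1)
  expect_equal(got2$group_sizes[["low"]], 5)
  # log-rank source agrees with a direct log-rank at the chosen cutoff
  lr <- optimal_cutoff(cohort, p_source = "logrank")
  direct <- logrank_test(cohort$time, cohort$event,
                         ifelse(cohort$expr <= lr$cutoff, "low", "high"))
  expect_equal(lr$p_at_cutoff, direct$p_value, tolerance = 1e-12)
})

test_that("mean-cutoff classification is a strict comparison to the mean", {
  expect_identical(classify_mean_cutoff(c(1, 3)), c("low", "high"))
  expect_warning(lab <- classify_mean_cutoff(c(2, 2, 2)), "equal")
  expect_identical(lab, rep("low", 3))
  set.seed(44)
  x <- rnorm(100)
  expect_identical(classify_mean_cutoff(x),
                   ifelse(x > mean(x), "high", "low"))
  expect_error(classify_mean_cutoff(1), "at least 2")
})

test_that("cohort CSV round-trips through the exchange header", {
  sim <- simulate_cohort(n = 20, seed = 77)
  dir <- withr::local_tempdir()
  write_simulated(sim, dir)
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(back$time, sim$cohort$time, tolerance = 1e-12)
  expect_equal(back$expr, sim$cohort$expr, tolerance = 1e-12)
  expect_identical(back$stratum, sim$cohort$stratum)
})
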