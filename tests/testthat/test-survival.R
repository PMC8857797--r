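test_that("median split sends ties to the high group", {
  s1 <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s1), c("low", "low", "high", "high"))
  s2 <- median_split(c(1, 2, 2, 5))   # median 2: the two 2's go high
  expect_equal(as.character(s2), c("low", "high", "high", "high"))
  set.seed(1)
  s3 <- median_split(rnorm(260))
  expect_equal(unname(table(s3)), c(130L, 130L), ignore_attr = TRUE)
  expect_error(median_split(rep(3, 10)), "identical")
  expect_error(median_split(1:3), "at least 4")
})

test_that("Kaplan-Meier product-limit estimates match hand calculation", {
  # times 2+, 3, 5+: one event at 3 with 2 at risk -> S drops to 0.5
  km <- km_estimate(c(2, 3, 5), c(0, 1, 0))
  expect_equal(km$time, 3)
  expect_equal(km$n_risk, 2)
  expect_equal(km$surv, 0.5)
  # all events, distinct times: the empirical survival function
  km4 <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km4$surv, c(0.75, 0.5, 0.25, 0))
  expect_true(all(diff(km4$surv) < 0))
  # no events: S stays 1 (no event rows emitted)
  expect_equal(nrow(km_estimate(c(1, 2, 3), c(0, 0, 0))), 0L)
  # grouped estimate agrees with survival::survfit
  set.seed(2)
  tt <- rexp(60, 0.1); ev <- rbinom(60, 1, 0.7); g <- rep(c("a", "b"), 30)
  km2 <- km_estimate(tt, ev, g)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ g)
  ours <- km2$surv[km2$group == "a"]
  theirs <- sf$surv[seq_len(sf$strata[1])][sf$n.event[seq_len(sf$strata[1])] > 0]
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("log-rank test is calibrated, powered, and matches hand algebra", {
  # single event in group 1 with equal risk sets: chi2 = 0.25/0.25 = 1
  lr1 <- logrank_test(c(5, 10, 10, 10), c(1, 0, 0, 0),
                      c("a", "a", "b", "b"))
  expect_equal(lr1$chi2, 1)
  # null calibration: 300 reps at n = 200
  set.seed(3)
  rej <- mean(vapply(1:300, function(i) {
    tt <- rexp(200, 0.1)
    ev <- as.integer(tt < quantile(tt, 0.8))
    logrank_test(pmin(tt, quantile(tt, 0.8)), ev,
                 rep(c("a", "b"), 100))$p < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
  # power at hazard ratio 3, n = 200
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    g <- rep(0:1, 100)
    tt <- rexp(200, 0.05 * 3^g)
    logrank_test(tt, rep(1L, 200), g)$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 18L)
  expect_error(logrank_test(1:4, c(1, 1, 1, 1), rep("a", 4)), "two groups")
})

test_that("Cox regression recovers planted hazards and matches coxph", {
  # null recovery
  set.seed(4)
  x <- rnorm(500)
  fit0 <- cox_univariate(rexp(500, 0.1), rep(1L, 500), x)
  expect_lt(abs(fit0$beta), 0.1)
  # machine-precision agreement with the survival package (Breslow and
  # Efron) as independent oracle
  set.seed(5)
  n <- 120
  xb <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(0.7 * xb)) + runif(n, 0, 1e-4)
  ev <- rbinom(n, 1, 0.8)
  fit <- cox_univariate(tt, ev, xb)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ xb, ties = "breslow")
  expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-8)
  fit_e <- cox_univariate(round(tt), ev, xb, ties = "efron")
  ref_e <- survival::coxph(survival::Surv(round(tt), ev) ~ xb,
                           ties = "efron")
  expect_equal(fit_e$beta, unname(coef(ref_e)), tolerance = 1e-8)
  # HR and CI structure
  expect_equal(fit$hr, exp(fit$beta))
  expect_lte(fit$ci_low, fit$hr)
  expect_gte(fit$ci_high, fit$hr)
})

test_that("planted log hazard ratio is recovered through the generator", {
  fits <- t(vapply(1:10, function(s) {
    ds <- simulate_multiomics(survival_config(seed = s,
                                              prognostic_lnc_loghr = 0.5))
    tum <- ds$sample_table$sample_id[ds$sample_table$condition == "tumor"]
    expr <- log2(cpm_normalize(ds$counts$lncrna)[
      ds$truth$prognostic_lnc, tum] + 1)
    fit <- cox_univariate(ds$clinical$pfs_time, ds$clinical$event,
                          as.vector(scale(expr)))
    c(fit$beta, fit$ci_low <= exp(0.5) && exp(0.5) <= fit$ci_high)
  }, numeric(2)))
  expect_lt(abs(mean(fits[, 1]) - 0.5), 0.15)
  expect_gte(sum(fits[, 2]), 8)
  # null: no planted effect
  ds0 <- simulate_multiomics(survival_config(seed = 99,
                                             prognostic_lnc_loghr = 0))
  tum <- ds0$sample_table$sample_id[ds0$sample_table$condition == "tumor"]
  e0 <- log2(cpm_normalize(ds0$counts$lncrna)[
    ds0$truth$prognostic_lnc, tum] + 1)
  f0 <- cox_univariate(ds0$clinical$pfs_time, ds0$clinical$event,
                       as.vector(scale(e0)))
  expect_lt(abs(f0$beta), 0.2)
})

test_that("log-rank chi-squared equals the Cox score test for binary covariates", {
  set.seed(6)
  n <- 150
  g <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.08 * exp(0.5 * g)) + runif(n, 0, 1e-6)  # no ties
  ev <- rbinom(n, 1, 0.75)
  lr <- logrank_test(tt, ev, g)
  cx <- cox_univariate(tt, ev, g)
  expect_equal(lr$chi2, cx$score_chi2, tolerance = 1e-6)
})

test_that("covariate rescaling rescales beta and Newton steps never drop the likelihood", {
  set.seed(7)
  n <- 100
  x <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(0.4 * x))
  ev <- rbinom(n, 1, 0.8)
  f1 <- cox_univariate(tt, ev, x)
  f2 <- cox_univariate(tt, ev, 10 * x)
  expect_equal(f2$beta, f1$beta / 10, tolerance = 1e-6)
  expect_true(f1$converged)
  # the maximized partial likelihood is no worse than at beta = 0
  expect_gte(f1$loglik,
             ceRNAseeker:::cox_partial_deriv(0, tt, ev, x, "breslow")$loglik)
})

test_that("complete separation is flagged with an unbounded interval", {
  # covariate perfectly orders all event times: monotone likelihood
  tt <- 1:20
  x <- 20:1
  fit <- suppressWarnings(cox_univariate(tt, rep(1L, 20), x))
  expect_true(fit$separation || fit$beta > 2)
  if (fit$separation) expect_equal(fit$ci_high, Inf)
})
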