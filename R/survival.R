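#' Median split of a per-subject expression vector
#'
#' Subjects at or above the median go to the `"high"` group, the rest to
#' `"low"`. The median is the midpoint of the two central order
#' statistics for even n, so ties at the median go high (documented tie
#' rule). The split is scale-free, so any expression unit (FPKM, CPM)
#' works.
#'
#' @param values Named or unnamed numeric vector, length >= 4.
#' @return A factor with levels `c("low", "high")`.
#' @export
median_split <- function(values) {
  if (length(values) < 4) stop("need at least 4 subjects")
  if (length(unique(values)) == 1L)
    stop("all values identical: median split impossible")
  med <- stats::median(values)
  factor(ifelse(values >= med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times,
#' with censored subjects leaving the risk set after their time, and
#' Greenwood standard errors
#' `se(t) = S(t) * sqrt(sum d_i / (n_i (n_i - d_i)))`.
#'
#' @param time Positive follow-up times.
#' @param event 1 = event observed, 0 = censored.
#' @param group Optional group labels; the estimate is computed per
#'   group.
#' @return A data.frame `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `se` with one row per distinct event time (class `km_curve`).
#' @export
km_estimate <- function(time, event, group = NULL) {
  if (is.null(group)) group <- rep("all", length(time))
  stopifnot(length(time) == length(event), length(time) == length(group))
  out <- lapply(split(seq_along(time), group), function(idx) {
    tt <- time[idx]; ev <- event[idx]
    et <- sort(unique(tt[ev == 1]))
    if (!length(et))
      return(data.frame(group = character(0), time = numeric(0),
                        n_risk = numeric(0), n_event = numeric(0),
                        surv = numeric(0), se = numeric(0),
                        stringsAsFactors = FALSE))
    n_risk <- vapply(et, function(t) sum(tt >= t), numeric(1))
    n_event <- vapply(et, function(t) sum(tt == t & ev == 1), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    gw <- cumsum(n_event / (n_risk * pmax(n_risk - n_event, 1e-300)))
    data.frame(group = unname(group[idx[1]]), time = unname(et),
               n_risk = unname(n_risk), n_event = unname(n_event),
               surv = unname(surv), se = unname(surv * sqrt(gw)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("km_curve", "data.frame")
  res
}

#' Two-group log-rank test
#'
#' At each distinct event time, compares the observed number of events in
#' group 1 with its hypergeometric expectation given the risk sets;
#' `chi2 = (sum O - sum E)^2 / sum V`, with a chi-squared(1) p-value.
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @param group Two-level group labels.
#' @return A list with `chi2`, `p`, `observed`, `expected` (group-1
#'   totals).
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("log-rank test needs exactly two groups")
  if (any(table(group) == 0L)) stop("one group is empty")
  if (sum(event) < 1) stop("need at least one event")
  g1 <- group == levels(group)[1]
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Univariate Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood (Breslow tie handling by default,
#' Efron available) by Newton-Raphson from `beta = 0` with step-halving,
#' declaring convergence when the score falls below 1e-8 or the step
#' below 1e-10 (at most 50 iterations). The standard error comes from the
#' inverse observed information; `HR = exp(beta)` with a 95% CI
#' `exp(beta +/- 1.959964 se)` and a two-sided normal Wald p-value. The
#' score test at `beta = 0` is also reported; for a binary covariate
#' without tied event times it equals the log-rank chi-squared. Monotone
#' likelihood (complete separation) is flagged and the CI reported as
#' unbounded.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (0/1).
#' @param covariate Numeric covariate (expression or group indicator).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A list of class `cox_result`: `beta`, `se`, `hr`, `ci_low`,
#'   `ci_high`, `wald_p`, `score_chi2`, `score_p`, `loglik`, `n`,
#'   `n_events`, `converged`, `separation`.
#' @export
cox_univariate <- function(time, event, covariate,
                           ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(event),
            length(time) == length(covariate))
  if (length(time) < 10 || sum(event) < 5)
    warning("fewer than 10 subjects or 5 events: estimates are unstable")

  deriv <- function(beta) cox_partial_deriv(beta, time, event, covariate, ties)
  d0 <- deriv(0)
  score_chi2 <- if (d0$info > 0) d0$score^2 / d0$info else NA_real_

  beta <- 0
  ll <- d0$loglik
  converged <- FALSE
  for (it in seq_len(50L)) {
    d <- deriv(beta)
    if (abs(d$score) < 1e-8) { converged <- TRUE; ll <- d$loglik; break }
    if (d$info <= 0) break
    step <- d$score / d$info
    # step-halving: never decrease the partial log-likelihood
    for (h in 0:20) {
      cand <- beta + step / 2^h
      if (deriv(cand)$loglik >= d$loglik - 1e-12) break
    }
    if (abs(cand - beta) < 1e-10) {
      beta <- cand; converged <- TRUE; ll <- deriv(beta)$loglik; break
    }
    beta <- cand
    ll <- deriv(beta)$loglik
  }
  dfin <- deriv(beta)
  separation <- !converged && abs(beta) > 15
  se <- if (dfin$info > 0) sqrt(1 / dfin$info) else NA_real_
  zq <- 1.959964
  if (separation || !is.finite(se)) {
    ci <- c(0, Inf)
    wald_p <- NA_real_
  } else {
    ci <- exp(beta + c(-1, 1) * zq * se)
    wald_p <- 2 * stats::pnorm(-abs(beta / se))
  }
  structure(list(beta = beta, se = se, hr = exp(beta), ci_low = ci[1],
                 ci_high = ci[2], wald_p = wald_p,
                 score_chi2 = score_chi2,
                 score_p = stats::pchisq(score_chi2, 1, lower.tail = FALSE),
                 loglik = ll, n = length(time), n_events = sum(event),
                 converged = converged, separation = separation,
                 ties = ties), class = "cox_result")
}

# Partial log-likelihood, score and information at beta (single covariate).
cox_partial_deriv <- function(beta, time, event, x, ties) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ex <- exp(beta * x)
  # reverse-cumulative risk-set sums
  s0 <- rev(cumsum(rev(ex)))
  s1 <- rev(cumsum(rev(x * ex)))
  s2 <- rev(cumsum(rev(x^2 * ex)))
  first <- match(time, time)    # index of first subject with each time
  loglik <- score <- info <- 0
  et <- unique(time[event == 1])
  for (t in et) {
    at <- which(time == t & event == 1)
    d <- length(at)
    i0 <- first[at[1]]
    S0 <- s0[i0]; S1 <- s1[i0]; S2 <- s2[i0]
    xsum <- sum(x[at])
    if (ties == "breslow" || d == 1L) {
      loglik <- loglik + beta * xsum - d * log(S0)
      score <- score + xsum - d * S1 / S0
      info <- info + d * (S2 / S0 - (S1 / S0)^2)
    } else {
      D0 <- sum(exp(beta * x[at]))
      D1 <- sum(x[at] * exp(beta * x[at]))
      D2 <- sum(x[at]^2 * exp(beta * x[at]))
      loglik <- loglik + beta * xsum
      for (j in seq_len(d) - 1L) {
        f <- j / d
        E0 <- S0 - f * D0; E1 <- S1 - f * D1; E2 <- S2 - f * D2
        loglik <- loglik - log(E0)
        score <- score + xsum / d - E1 / E0
        info <- info + E2 / E0 - (E1 / E0)^2
      }
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Median-split prognostic evaluation of one feature
#'
#' Convenience wrapper reproducing the standard prognostic workflow:
#' median split of the expression vector, Kaplan-Meier curves per group,
#' log-rank test between groups, and univariate Cox regression on the
#' standardized continuous expression.
#'
#' @param time,event Survival outcome per subject.
#' @param expression Per-subject expression of the feature.
#' @return A list with `group`, `km` ([km_estimate()]), `logrank`
#'   ([logrank_test()]) and `cox` ([cox_univariate()] on the
#'   standardized expression).
#' @export
evaluate_prognostic <- function(time, event, expression) {
  group <- median_split(expression)
  z <- as.vector(scale(expression))
  list(group = group,
       km = km_estimate(time, event, group),
       logrank = logrank_test(time, event, group),
       cox = cox_univariate(time, event, z))
}
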