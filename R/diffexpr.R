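#' Counts-per-million normalization
#'
#' Scales each sample column to counts per million mapped reads:
#' `cpm(f, s) = count(f, s) / libsize(s) * 1e6`, where the library size is
#' the column sum. Every column of the result sums to 1e6.
#'
#' @param counts Nonnegative integer feature-by-sample matrix.
#' @param log2 If `TRUE`, return `log2(CPM + 1)` instead of raw CPM.
#' @return A numeric matrix with the same dimnames as `counts`.
#' @export
cpm_normalize <- function(counts, log2 = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  libsize <- colSums(counts)
  zero <- libsize == 0
  if (any(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  cpm <- sweep(counts, 2, libsize, "/") * 1e6
  if (log2) base::log2(cpm + 1) else cpm
}

#' Median-of-ratios size factors
#'
#' Robust per-sample normalization factors: the median across features of
#' the ratio of a sample's counts to the per-feature geometric mean
#' (features with a zero count in any sample are excluded from the
#' reference). Unlike raw column totals, these are insensitive to
#' composition bias from strongly asymmetric differential expression.
#' Falls back to total-count factors if fewer than 10 features are
#' usable. Factors are scaled to mean 1.
#'
#' @param counts Feature-by-sample count matrix.
#' @return Named per-sample size-factor vector (mean 1).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) >= 10) {
    logref <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2, function(y)
      exp(stats::median(log(y) - logref)))
  } else {
    sf <- colSums(counts)
  }
  sf / mean(sf)
}

#' Method-of-moments negative-binomial dispersion with trend shrinkage
#'
#' For each feature, computes the moment estimator
#' `d = max(0, (s^2 - mu) / mu^2)` on library-size-normalized counts
#' pooled within condition, then shrinks it 50/50 toward a fitted
#' mean-dispersion trend `d(mu) = a + b / mu`. Estimates are never
#' negative.
#'
#' @param counts Feature-by-sample count matrix.
#' @param condition Per-sample condition labels (two or more levels, each
#'   with at least 2 samples).
#' @return Named per-feature dispersion vector.
#' @export
estimate_dispersion <- function(counts, condition) {
  counts <- as.matrix(counts)
  condition <- as.factor(condition)
  if (length(condition) != ncol(counts))
    stop("condition length must equal the number of samples")
  if (any(table(condition) < 2L))
    stop("each condition needs at least 2 samples")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")

  d_raw <- rep(0, nrow(counts))
  mu_all <- rep(0, nrow(counts))
  wsum <- 0
  for (lev in levels(condition)) {
    x <- norm[, condition == lev, drop = FALSE]
    mu <- rowMeans(x)
    s2 <- apply(x, 1, stats::var)
    w <- ncol(x) - 1L
    d_lev <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
    d_raw <- d_raw + w * d_lev
    mu_all <- mu_all + w * mu
    wsum <- wsum + w
  }
  d_raw <- d_raw / wsum
  mu_all <- mu_all / wsum

  # mean-dispersion trend: d(mu) = a + b/mu, fitted on informative features
  use <- mu_all > 1
  d_trend <- rep(mean(d_raw[use]), nrow(counts))
  if (sum(use) >= 10L) {
    fit <- stats::lm.fit(cbind(1, 1 / mu_all[use]), d_raw[use])
    pred <- cbind(1, 1 / mu_all) %*% fit$coefficients
    d_trend <- pmax(0, as.vector(pred))
  }
  stats::setNames(pmax(0, 0.5 * d_raw + 0.5 * d_trend), rownames(counts))
}

#' Negative-binomial Wald test for paired tumor/normal designs
#'
#' Fits, per feature, a negative-binomial log-linear model with a
#' condition effect and log-library-size offsets by iteratively
#' reweighted least squares, and tests the condition coefficient with a
#' Wald statistic (`beta / se`, two-sided normal p-value). The log2 fold
#' change is `beta / ln 2` (tumor over normal). Dispersions default to
#' [estimate_dispersion()]. Benjamini-Hochberg adjusted p-values are
#' computed across features and results are sorted by p-value.
#'
#' With `subject` supplied, subject fixed effects are added (a blocked
#' paired analysis) and each feature is fit individually.
#'
#' @param counts Feature-by-sample count matrix.
#' @param condition Per-sample labels; must contain `"tumor"` and
#'   `"normal"` (tumor is the numerator of the fold change).
#' @param subject Optional per-sample subject ids for a subject-blocked
#'   fit (off by default).
#' @param dispersion Optional per-feature dispersion vector.
#' @param lfc_cut,p_cut Gate used to annotate the `direction` column
#'   (see [filter_de()]).
#' @param max_iter IRLS iteration cap; non-converged features are flagged
#'   and given p = 1 with a warning.
#' @return A data.frame with columns `feature_id`, `base_mean`, `log2fc`,
#'   `p_value`, `padj`, `direction`, `converged`, sorted by `p_value`.
#' @export
nb_wald_test <- function(counts, condition, subject = NULL,
                         dispersion = NULL, lfc_cut = 1, p_cut = 0.05,
                         max_iter = 50L) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (!all(c("tumor", "normal") %in% condition))
    stop("condition must contain both 'tumor' and 'normal'")
  if (is.null(dispersion)) dispersion <- estimate_dispersion(counts, condition)
  d <- dispersion[rownames(counts)]
  d[is.na(d)] <- 0

  sf <- size_factors(counts)
  off <- matrix(log(sf), nrow(counts), ncol(counts), byrow = TRUE)
  x <- as.numeric(condition == "tumor")

  if (!is.null(subject)) {
    res <- nb_wald_blocked(counts, x, subject, off, d, max_iter)
  } else {
    res <- nb_wald_vectorized(counts, x, off, d, max_iter)
  }
  if (any(!res$converged))
    warning(sum(!res$converged), " feature(s) did not converge; p set to 1")

  base_mean <- rowMeans(sweep(counts, 2, sf, "/"))
  out <- data.frame(feature_id = rownames(counts), base_mean = base_mean,
                    log2fc = res$beta / log(2), p_value = res$p,
                    padj = stats::p.adjust(res$p, "BH"),
                    converged = res$converged, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$direction <- ifelse(out$p_value <= p_cut & out$log2fc >= lfc_cut, "up",
                   ifelse(out$p_value <= p_cut & out$log2fc <= -lfc_cut,
                          "down", "none"))
  out[order(out$p_value), , drop = FALSE]
}

# IRLS across all features simultaneously for the two-group design.
nb_wald_vectorized <- function(counts, x, off, d, max_iter) {
  n_f <- nrow(counts)
  xm <- matrix(x, n_f, ncol(counts), byrow = TRUE)
  lib <- exp(off)
  mean_t <- rowSums(counts[, x == 1, drop = FALSE]) /
    rowSums(lib[, x == 1, drop = FALSE])
  mean_n <- rowSums(counts[, x == 0, drop = FALSE]) /
    rowSums(lib[, x == 0, drop = FALSE])
  eps <- 1e-8
  b0 <- log(pmax(mean_n, eps))
  b1 <- log(pmax(mean_t, eps)) - b0
  converged <- rep(FALSE, n_f)
  active <- rowSums(counts) > 0

  for (iter in seq_len(max_iter)) {
    eta <- b0 + b1 * xm
    mu <- pmax(exp(eta + off), 1e-10)
    w <- mu / (1 + d * mu)
    z <- eta + (counts - mu) / mu
    sw <- rowSums(w)
    swx <- rowSums(w * xm)
    swz <- rowSums(w * z)
    swxz <- rowSums(w * z * xm)
    det <- sw * swx - swx^2          # x binary: sum w x^2 = sum w x
    det[det <= 0] <- NA
    b1_new <- (sw * swxz - swx * swz) / det
    b0_new <- (swz - swx * b1_new) / sw
    step <- pmax(abs(b1_new - b1), abs(b0_new - b0))
    upd <- active & !converged & is.finite(b1_new) & is.finite(b0_new)
    b0[upd] <- b0_new[upd]
    b1[upd] <- b1_new[upd]
    converged <- converged | (is.finite(step) & step < 1e-8)
    if (all(converged[active])) break
  }
  eta <- b0 + b1 * xm
  mu <- pmax(exp(eta + off), 1e-10)
  w <- mu / (1 + d * mu)
  sw <- rowSums(w)
  swx <- rowSums(w * xm)
  det <- sw * swx - swx^2
  se <- sqrt(sw / pmax(det, 1e-300))
  zstat <- b1 / se
  p <- 2 * stats::pnorm(-abs(zstat))
  p[!active] <- 1
  b1[!active] <- 0
  converged[!active] <- TRUE
  p[!converged] <- 1
  list(beta = b1, p = p, converged = converged)
}

# Per-feature IRLS with subject fixed effects (paired/blocked analysis).
nb_wald_blocked <- function(counts, x, subject, off, d, max_iter) {
  subject <- as.factor(subject)
  X <- stats::model.matrix(~ x + subject)
  j <- 2L  # condition coefficient
  n_f <- nrow(counts)
  beta_out <- numeric(n_f); p_out <- rep(1, n_f)
  conv <- logical(n_f)
  for (f in seq_len(n_f)) {
    y <- counts[f, ]
    if (all(y == 0)) { conv[f] <- TRUE; next }
    o <- off[f, ]
    eta <- log(pmax(y, 0.5)) - o
    beta <- tryCatch(stats::lm.fit(X, eta)$coefficients, error = function(e) NULL)
    if (is.null(beta)) next
    beta[is.na(beta)] <- 0
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- as.vector(X %*% beta)
      mu <- pmax(exp(eta + o), 1e-10)
      w <- mu / (1 + d[f] * mu)
      z <- eta + (y - mu) / mu
      fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
      if (is.null(fit)) break
      nb <- fit$coefficients
      nb[is.na(nb)] <- 0
      if (max(abs(nb - beta)) < 1e-8) { beta <- nb; ok <- TRUE; break }
      beta <- nb
    }
    if (!ok) next
    eta <- as.vector(X %*% beta)
    mu <- pmax(exp(eta + o), 1e-10)
    w <- mu / (1 + d[f] * mu)
    XtWX <- crossprod(X * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) next
    se <- sqrt(cov[j, j])
    beta_out[f] <- beta[j]
    p_out[f] <- 2 * stats::pnorm(-abs(beta[j] / se))
    conv[f] <- TRUE
  }
  list(beta = beta_out, p = p_out, converged = conv)
}

#' Partition DE results into up- and down-regulated sets
#'
#' A feature passes the gate iff `|log2fc| >= lfc_cut` and
#' `p <= p_cut` (both thresholds inclusive). The raw p-value drives the
#' gate by default; set `use_adjusted = TRUE` to gate on the
#' Benjamini-Hochberg adjusted p-value instead.
#'
#' @param results Data.frame from [nb_wald_test()].
#' @param lfc_cut Absolute log2 fold-change threshold (default 1).
#' @param p_cut P-value threshold (default 0.05).
#' @param use_adjusted Gate on `padj` instead of `p_value`.
#' @return A list with character vectors `up` and `down`.
#' @export
filter_de <- function(results, lfc_cut = 1, p_cut = 0.05,
                      use_adjusted = FALSE) {
  p <- if (use_adjusted) results$padj else results$p_value
  pass <- p <= p_cut & abs(results$log2fc) >= lfc_cut
  list(up = results$feature_id[pass & results$log2fc >= lfc_cut],
       down = results$feature_id[pass & results$log2fc <= -lfc_cut])
}
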