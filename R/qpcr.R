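#' Relative quantification of qPCR Ct tables by the 2^-ddCt method
#'
#' Technical replicates are first averaged on the Ct scale. Per subject
#' and group, `dCt = Ct_target - Ct_reference`; per subject,
#' `ddCt = dCt_tumor - dCt_normal` and the fold change is `2^-ddCt`.
#' Because dCt subtracts the reference within each (subject, group), any
#' additive plate offset shared by all genes cancels. Significance of the
#' tumor/normal shift is assessed by a two-sided paired Wilcoxon
#' signed-rank test on the per-subject dCt values (exact distribution for
#' n <= 25, normal approximation with continuity correction above); a
#' paired t-test is available behind `test = "t"`.
#'
#' @param ct_table Data.frame with columns `subject_id`, `group`
#'   (`"tumor"`/`"normal"`), `gene_id`, `ct`.
#' @param target Target gene id.
#' @param reference Reference gene id (e.g. GAPDH for genes, U6 for
#'   miRNAs).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return A list with `per_subject` (subject, dct_normal, dct_tumor,
#'   ddct, fold), `mean_fold` (geometric mean), `p_value`, `n`, `test`.
#' @export
ddct_fold_change <- function(ct_table, target, reference,
                             test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  needed <- c("subject_id", "group", "gene_id", "ct")
  missing <- setdiff(needed, names(ct_table))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  tab <- ct_table[ct_table$gene_id %in% c(target, reference), , drop = FALSE]
  # average technical replicates on the Ct scale
  agg <- stats::aggregate(ct ~ subject_id + group + gene_id, data = tab,
                          FUN = mean)
  get_ct <- function(gene, grp) {
    sub <- agg[agg$gene_id == gene & agg$group == grp, ]
    stats::setNames(sub$ct, sub$subject_id)
  }
  tt <- get_ct(target, "tumor"); tn <- get_ct(target, "normal")
  rt <- get_ct(reference, "tumor"); rn <- get_ct(reference, "normal")
  subjects <- Reduce(intersect, list(names(tt), names(tn), names(rt),
                                     names(rn)))
  dropped <- setdiff(unique(agg$subject_id), subjects)
  if (length(dropped))
    warning("subject(s) dropped for missing measurements: ",
            paste(dropped, collapse = ", "))
  if (!length(subjects)) stop("no subject with complete measurements")
  dct_t <- tt[subjects] - rt[subjects]
  dct_n <- tn[subjects] - rn[subjects]
  ddct <- dct_t - dct_n
  fold <- 2^(-ddct)
  n <- length(subjects)
  p <- if (n < 2) NA_real_ else if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(dct_t, dct_n, paired = TRUE,
                                        exact = n <= 25,
                                        correct = TRUE))$p.value
  } else {
    stats::t.test(dct_t, dct_n, paired = TRUE)$p.value
  }
  list(per_subject = data.frame(subject_id = subjects,
                                dct_normal = unname(dct_n),
                                dct_tumor = unname(dct_t),
                                ddct = unname(ddct), fold = unname(fold),
                                stringsAsFactors = FALSE),
       mean_fold = 2^(-mean(ddct)), p_value = p, n = n, test = test)
}
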