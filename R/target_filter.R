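#' Filter predicted miRNA-target interactions by score and binding energy
#'
#' Keeps rows with prediction `score >= min_score` and binding free
#' `energy <= max_energy` (both thresholds inclusive), then collapses
#' duplicate (miRNA, target) rows keeping the best-supported one (highest
#' score, ties broken by lowest energy). Filtering is idempotent.
#'
#' @param table Interaction data.frame with columns `mirna_id`,
#'   `target_id`, `target_class`, `score`, `energy`.
#' @param min_score Minimum prediction score (default 150).
#' @param max_energy Maximum binding free energy in kcal/mol
#'   (default -20; more negative is more stable).
#' @return The filtered, deduplicated data.frame.
#' @export
filter_interactions <- function(table, min_score = 150, max_energy = -20) {
  needed <- c("mirna_id", "target_id", "score", "energy")
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  keep <- table$score >= min_score & table$energy <= max_energy
  out <- table[keep, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(-out$score, out$energy), , drop = FALSE]
    out <- out[!duplicated(paste(out$mirna_id, out$target_id)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Build bipartite miRNA-targeting maps restricted to DE features
#'
#' From a filtered interaction table, retains only interactions whose
#' miRNA and target are both differentially expressed, and returns the
#' per-lncRNA and per-mRNA sets of targeting miRNAs together with the
#' miRNA universe used by the downstream shared-miRNA hypergeometric
#' test. By default the universe is the set of DE miRNAs with at least
#' one surviving interaction; pass `universe` to override.
#'
#' @param filtered Output of [filter_interactions()].
#' @param de_mirna,de_lnc,de_mrna Character vectors of DE feature ids.
#' @param universe Optional explicit miRNA universe.
#' @return A list of class `bipartite_targeting` with `mirna_universe`,
#'   `lnc_targets` (named list: lncRNA id -> miRNA id set) and
#'   `mrna_targets`.
#' @export
build_bipartite <- function(filtered, de_mirna, de_lnc, de_mrna,
                            universe = NULL) {
  keep <- filtered$mirna_id %in% de_mirna &
    ((filtered$target_class == "lncRNA" & filtered$target_id %in% de_lnc) |
     (filtered$target_class == "mRNA" & filtered$target_id %in% de_mrna))
  surv <- filtered[keep, , drop = FALSE]
  split_targets <- function(class) {
    sub <- surv[surv$target_class == class, , drop = FALSE]
    if (!nrow(sub)) return(list())
    lapply(split(sub$mirna_id, sub$target_id), unique)
  }
  if (is.null(universe)) universe <- sort(unique(surv$mirna_id))
  structure(list(mirna_universe = universe,
                 lnc_targets = split_targets("lncRNA"),
                 mrna_targets = split_targets("mRNA")),
            class = "bipartite_targeting")
}
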