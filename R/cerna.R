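#' Hypergeometric shared-miRNA test for a candidate ceRNA pair
#'
#' Under the ceRNA hypothesis, a lncRNA and an mRNA that share more
#' targeting miRNAs than chance expects are candidate competitors. With
#' `K` miRNAs targeting the lncRNA, `n` targeting the mRNA, and a
#' universe of `N` miRNAs, the number of shared miRNAs under independence
#' is hypergeometric; the reported p-value is the upper tail
#' `P(X >= k)` at the observed overlap `k` (1 when `k = 0`), evaluated by
#' a log-space-stable CDF.
#'
#' @param lnc_set miRNA ids targeting the lncRNA.
#' @param mrna_set miRNA ids targeting the mRNA.
#' @param universe miRNA id universe; both sets must be contained in it.
#' @return A list with `k`, `K`, `n`, `N`, `hyper_p`.
#' @export
shared_mirna_test <- function(lnc_set, mrna_set, universe) {
  universe <- unique(universe)
  lnc_set <- unique(lnc_set)
  mrna_set <- unique(mrna_set)
  if (!length(universe)) stop("universe must be nonempty")
  if (!all(lnc_set %in% universe) || !all(mrna_set %in% universe))
    stop("lnc_set and mrna_set must be subsets of the universe")
  k <- length(intersect(lnc_set, mrna_set))
  K <- length(lnc_set)
  n <- length(mrna_set)
  N <- length(universe)
  list(k = k, K = K, n = n, N = N,
       hyper_p = hyper_upper_tail(k, K, n, N))
}

# P(X >= k), X ~ Hypergeometric(N, K, n).
hyper_upper_tail <- function(k, K, n, N) {
  ifelse(k <= 0, 1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' Computes Pearson's r between two expression vectors and the two-sided
#' p-value from `t = r * sqrt((m-2) / (1-r^2))` with `m - 2` degrees of
#' freedom. Zero-variance input returns `r = 0, p = 1` with a warning.
#'
#' @param x,y Numeric vectors of equal length `m >= 3` with finite values.
#' @return A list with `r` and `p`.
#' @export
pair_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  m <- length(x)
  if (m < 3) stop("need at least 3 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input; returning r = 0, p = 1")
    return(list(r = 0, p = 1))
  }
  r <- stats::cor(x, y)
  p <- cor_pvalue(r, m)
  list(r = r, p = p)
}

cor_pvalue <- function(r, m) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), m - 2)
  p[abs(r) >= 1] <- 0
  p
}

#' Call ceRNA triplets and assemble the lncRNA-miRNA-mRNA network
#'
#' Scores every lncRNA-mRNA pair with at least one shared targeting miRNA
#' by (i) the upper-tail hypergeometric shared-miRNA test and (ii) the
#' Pearson correlation of their log2(CPM+1) profiles over the supplied
#' samples. A pair is accepted iff `r > r_cut` (strictly positive
#' correlation only), `cor_p < p_cut` and `hyper_p < hyper_p_cut`;
#' accepted pairs expand into one triplet per shared miRNA. The full
#' scored pair table is retained for audit, with Benjamini-Hochberg
#' columns for both p-values.
#'
#' @param targeting A [build_bipartite()] object.
#' @param expr_lnc,expr_mrna CPM matrices (features x samples) covering
#'   the targeted features; log2(CPM+1) is taken internally.
#' @param samples Optional sample ids to correlate over (typically the
#'   tumor samples); default all columns.
#' @param r_cut Correlation threshold (strict, default 0.5).
#' @param p_cut Correlation p-value threshold (strict, default 0.05).
#' @param hyper_p_cut Hypergeometric p-value threshold (strict, default
#'   `p_cut`).
#' @return A list of class `cerna_network`: `pairs` (audit table),
#'   `triplets`, `nodes`, `edges`, and `n_skipped` (pairs dropped for
#'   missing expression).
#' @export
build_cerna_network <- function(targeting, expr_lnc, expr_mrna,
                                samples = NULL, r_cut = 0.5, p_cut = 0.05,
                                hyper_p_cut = p_cut) {
  stopifnot(inherits(targeting, "bipartite_targeting"))
  empty <- empty_cerna_network()
  lt <- targeting$lnc_targets
  mt <- targeting$mrna_targets
  if (!length(lt) || !length(mt)) return(empty)
  universe <- targeting$mirna_universe
  N <- length(universe)

  # incidence matrices over the universe; overlap counts by crossproduct
  inc <- function(targets) {
    m <- matrix(0L, length(targets), N,
                dimnames = list(names(targets), universe))
    for (i in seq_along(targets))
      m[i, match(intersect(targets[[i]], universe), universe)] <- 1L
    m
  }
  L <- inc(lt)
  M <- inc(mt)
  kmat <- tcrossprod(L, M)
  Kv <- rowSums(L)
  nv <- rowSums(M)

  cand <- which(kmat >= 1L, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  pairs <- data.frame(lncrna = rownames(L)[cand[, 1]],
                      mrna = rownames(M)[cand[, 2]],
                      k = kmat[cand], K = Kv[cand[, 1]], n = nv[cand[, 2]],
                      N = N, stringsAsFactors = FALSE)
  pairs$hyper_p <- hyper_upper_tail(pairs$k, pairs$K, pairs$n, pairs$N)

  if (is.null(samples)) samples <- colnames(expr_lnc)
  n_skipped <- sum(!(pairs$lncrna %in% rownames(expr_lnc)) |
                     !(pairs$mrna %in% rownames(expr_mrna)))
  if (n_skipped > 0)
    warning(n_skipped, " pair(s) skipped: expression missing")
  pairs <- pairs[pairs$lncrna %in% rownames(expr_lnc) &
                   pairs$mrna %in% rownames(expr_mrna), , drop = FALSE]
  if (!nrow(pairs)) return(empty)

  m <- length(samples)
  le <- log2(expr_lnc[unique(pairs$lncrna), samples, drop = FALSE] + 1)
  me <- log2(expr_mrna[unique(pairs$mrna), samples, drop = FALSE] + 1)
  rmat <- suppressWarnings(stats::cor(t(le), t(me)))
  rmat[is.na(rmat)] <- 0  # zero-variance profiles: r = 0 (p becomes 1)
  pairs$pearson_r <- rmat[cbind(match(pairs$lncrna, rownames(rmat)),
                                match(pairs$mrna, colnames(rmat)))]
  pairs$cor_p <- cor_pvalue(pairs$pearson_r, m)
  pairs$hyper_padj <- stats::p.adjust(pairs$hyper_p, "BH")
  pairs$cor_padj <- stats::p.adjust(pairs$cor_p, "BH")
  pairs$accepted <- pairs$pearson_r > r_cut & pairs$cor_p < p_cut &
    pairs$hyper_p < hyper_p_cut
  pairs <- pairs[order(pairs$hyper_p, pairs$lncrna, pairs$mrna), , drop = FALSE]
  rownames(pairs) <- NULL

  acc <- pairs[pairs$accepted, , drop = FALSE]
  triplets <- if (nrow(acc)) do.call(rbind, lapply(seq_len(nrow(acc)),
    function(i) {
      shared <- intersect(lt[[acc$lncrna[i]]], mt[[acc$mrna[i]]])
      data.frame(lncrna = acc$lncrna[i], mirna = sort(shared),
                 mrna = acc$mrna[i], pearson_r = acc$pearson_r[i],
                 hyper_p = acc$hyper_p[i], stringsAsFactors = FALSE)
    })) else data.frame(lncrna = character(0), mirna = character(0),
                        mrna = character(0), pearson_r = numeric(0),
                        hyper_p = numeric(0))
  rownames(triplets) <- NULL
  net <- structure(list(pairs = pairs, triplets = triplets,
                        nodes = NULL, edges = NULL, n_skipped = n_skipped),
                   class = "cerna_network")
  net[c("nodes", "edges")] <- assemble_graph(triplets)
  net
}

empty_cerna_network <- function() {
  structure(list(
    pairs = data.frame(lncrna = character(0), mrna = character(0),
                       k = integer(0), K = numeric(0), n = numeric(0),
                       N = integer(0), hyper_p = numeric(0),
                       pearson_r = numeric(0), cor_p = numeric(0),
                       hyper_padj = numeric(0), cor_padj = numeric(0),
                       accepted = logical(0)),
    triplets = data.frame(lncrna = character(0), mirna = character(0),
                          mrna = character(0), pearson_r = numeric(0),
                          hyper_p = numeric(0)),
    nodes = data.frame(id = character(0), type = character(0)),
    edges = data.frame(source = character(0), target = character(0),
                       edge_type = character(0), pearson_r = numeric(0),
                       hyper_p = numeric(0)),
    n_skipped = 0L), class = "cerna_network")
}

assemble_graph <- function(triplets) {
  if (!nrow(triplets))
    return(list(nodes = data.frame(id = character(0), type = character(0)),
                edges = data.frame(source = character(0),
                                   target = character(0),
                                   edge_type = character(0),
                                   pearson_r = numeric(0),
                                   hyper_p = numeric(0))))
  nodes <- unique(rbind(
    data.frame(id = triplets$lncrna, type = "lncRNA"),
    data.frame(id = triplets$mirna, type = "miRNA"),
    data.frame(id = triplets$mrna, type = "mRNA")))
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- rbind(
    data.frame(source = triplets$lncrna, target = triplets$mirna,
               edge_type = "lncRNA-miRNA", pearson_r = NA_real_,
               hyper_p = NA_real_),
    data.frame(source = triplets$mirna, target = triplets$mrna,
               edge_type = "miRNA-mRNA", pearson_r = NA_real_,
               hyper_p = NA_real_),
    data.frame(source = triplets$lncrna, target = triplets$mrna,
               edge_type = "lncRNA-mRNA", pearson_r = triplets$pearson_r,
               hyper_p = triplets$hyper_p))
  edges <- unique(edges)
  edges <- edges[order(edges$edge_type, edges$source, edges$target), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}

#' Extract the subnetwork induced by a set of lncRNAs
#'
#' Keeps only triplets whose lncRNA is in `lnc_ids`, rebuilds nodes and
#' edges, and reports the number of distinct regulatory relations
#' (triplets) per lncRNA.
#'
#' @param net A `cerna_network`.
#' @param lnc_ids Character vector of lncRNA ids.
#' @return A `cerna_network` with an extra `relation_counts` table.
#' @export
extract_subnetwork <- function(net, lnc_ids) {
  stopifnot(inherits(net, "cerna_network"))
  unknown <- setdiff(lnc_ids, net$triplets$lncrna)
  if (length(unknown))
    warning("lncRNA id(s) absent from the network: ",
            paste(unknown, collapse = ", "))
  triplets <- net$triplets[net$triplets$lncrna %in% lnc_ids, , drop = FALSE]
  rownames(triplets) <- NULL
  pairs <- net$pairs[net$pairs$lncrna %in% lnc_ids & net$pairs$accepted, ,
                     drop = FALSE]
  rownames(pairs) <- NULL
  tb <- table(triplets$lncrna)
  counts <- data.frame(lncrna = names(tb), n_relations = as.integer(tb),
                       stringsAsFactors = FALSE)
  sub <- structure(list(pairs = pairs, triplets = triplets, nodes = NULL,
                        edges = NULL, n_skipped = 0L,
                        relation_counts = counts),
                   class = "cerna_network")
  sub[c("nodes", "edges")] <- assemble_graph(triplets)
  sub
}

#' Export a ceRNA network as node and edge TSV tables
#'
#' Writes `<prefix>_nodes.tsv` (id, type) and `<prefix>_edges.tsv`
#' (source, target, edge_type, pearson_r, hyper_p) in deterministic
#' sorted order, a format loadable by standard network viewers.
#'
#' @param net A `cerna_network`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(net, prefix) {
  stopifnot(inherits(net, "cerna_network"))
  paths <- c(nodes = paste0(prefix, "_nodes.tsv"),
             edges = paste0(prefix, "_edges.tsv"))
  write_tsv(net$nodes, paths["nodes"])
  write_tsv(net$edges, paths["edges"])
  invisible(paths)
}
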