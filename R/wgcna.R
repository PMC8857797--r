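#' Scan soft-thresholding powers for scale-free topology
#'
#' For each candidate power `beta`, builds the unsigned weighted adjacency
#' `a_ij = |cor(i, j)|^beta`, computes the connectivity
#' `k_i = sum_{j != i} a_ij`, bins `k` into equal-width bins, and fits
#' `log10 p(k)` against `log10 mean(k)` per bin (empty bins dropped). The
#' signed scale-free fit index is `-sign(slope) * R^2`, positive when the
#' connectivity distribution decays as scale-free topology predicts. The
#' recommended power is the smallest one reaching `rsq_target`, else the
#' argmax of the scan with a warning.
#'
#' @param expr Samples-by-genes numeric matrix (at least 8 samples, no
#'   zero-variance gene).
#' @param powers Candidate powers (default 1:20).
#' @param n_bins Connectivity histogram bins (default 10).
#' @param rsq_target Signed R^2 considered a scale-free fit (default
#'   0.85).
#' @return A list of class `soft_threshold_scan` with `table` (power,
#'   signed_r2, mean_connectivity) and `power` (the recommendation).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, n_bins = 10,
                                rsq_target = 0.85) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 8) stop("need at least 8 samples")
  sds <- apply(expr, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance gene(s) present; remove them first")
  ac <- abs(stats::cor(expr))
  diag(ac) <- 0
  tab <- data.frame(power = powers, signed_r2 = NA_real_,
                    mean_connectivity = NA_real_)
  for (i in seq_along(powers)) {
    a <- ac^powers[i]
    k <- colSums(a)
    tab$mean_connectivity[i] <- mean(k)
    tab$signed_r2[i] <- scale_free_fit(k, n_bins)
  }
  hit <- which(tab$signed_r2 >= rsq_target)
  if (length(hit)) {
    power <- powers[hit[1]]
  } else {
    power <- powers[which.max(tab$signed_r2)]
    warning("no power reached signed R^2 >= ", rsq_target,
            "; using the scan argmax (", power, ")")
  }
  structure(list(table = tab, power = power, rsq_target = rsq_target),
            class = "soft_threshold_scan")
}

# Signed scale-free topology fit index from a connectivity vector.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  p_k <- tapply(k, bin, length) / length(k)
  dk <- tapply(k, bin, mean)
  keep <- !is.na(p_k) & p_k > 0 & !is.na(dk) & dk > 0
  if (sum(keep) < 3) return(NA_real_)
  x <- log10(dk[keep])
  y <- log10(p_k[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Unsigned weighted adjacency matrix
#'
#' @param expr Samples-by-genes matrix.
#' @param power Soft-thresholding power.
#' @return Genes-by-genes adjacency `|cor|^power` with unit diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  a <- abs(stats::cor(as.matrix(expr)))^power
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`,
#' where `l_ij = sum_{u != i,j} a_iu * a_uj` and
#' `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. The clustering dissimilarity
#' is `1 - TOM`.
#'
#' @param adjacency Symmetric matrix with entries in [0, 1] and unit
#'   diagonal.
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a) || max(abs(a - t(a))) > 1e-12)
    stop("adjacency must be square and symmetric")
  if (min(a) < -1e-12 || max(a) > 1 + 1e-12)
    stop("adjacency entries must lie in [0, 1]")
  a0 <- a
  diag(a0) <- 0
  l <- a0 %*% a0            # diag(a0) = 0 excludes u = i and u = j
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules by static-cut tree pruning
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity,
#' followed by a simplified dynamic pruning: a static cut at the
#' `cut_quantile` of the dendrogram merge heights, dissolution of
#' clusters smaller than `min_size` to the unassigned ("grey", label 0)
#' pool, and one reassignment pass that attaches an unassigned gene to
#' the module whose eigengene correlates with it above `reattach_cor`.
#' Labels are relabeled contiguously by decreasing module size. The
#' procedure is deterministic given its input.
#'
#' @param dissimilarity Square symmetric dissimilarity matrix (1 - TOM).
#' @param expr Samples-by-genes matrix (used for the reattachment pass).
#' @param min_size Minimum module size (default 30).
#' @param cut_quantile Quantile of merge heights for the static cut
#'   (default 0.99).
#' @param reattach_cor Eigengene correlation needed to rescue an
#'   unassigned gene (default 0.3).
#' @return A list of class `module_assignment` with `labels` (named
#'   integer vector, 0 = unassigned), `dendrogram` (hclust), and
#'   `params`.
#' @export
cluster_modules <- function(dissimilarity, expr, min_size = 30,
                            cut_quantile = 0.99, reattach_cor = 0.3) {
  d <- as.matrix(dissimilarity)
  if (nrow(d) != ncol(d)) stop("dissimilarity must be square")
  genes <- colnames(d)
  if (is.null(genes)) genes <- colnames(expr)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  h <- stats::quantile(hc$height, cut_quantile)
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  labels <- ifelse(raw %in% as.integer(names(sizes)[sizes >= min_size]),
                   raw, 0L)
  labels <- relabel_by_size(labels)
  names(labels) <- genes

  if (any(labels > 0L) && any(labels == 0L)) {
    me <- module_eigengenes(expr, labels)$eigengenes
    grey <- names(labels)[labels == 0L]
    cors <- stats::cor(expr[, grey, drop = FALSE], me)
    best <- max.col(cors, ties.method = "first")
    rescue <- cors[cbind(seq_along(grey), best)] > reattach_cor
    labels[grey[rescue]] <- as.integer(sub("^ME", "", colnames(me)))[
      best[rescue]]
    labels <- relabel_by_size(labels)
    names(labels) <- genes
  }
  structure(list(labels = labels, dendrogram = hc,
                 params = list(min_size = min_size,
                               cut_quantile = cut_quantile,
                               reattach_cor = reattach_cor)),
            class = "module_assignment")
}

relabel_by_size <- function(labels) {
  mods <- setdiff(unique(labels), 0L)
  if (!length(mods)) return(as.integer(labels))
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  ord <- mods[order(-sizes, mods)]
  out <- integer(length(labels))
  for (i in seq_along(ord)) out[labels == ord[i]] <- i
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' per-gene z-scored module expression across samples (unit-norm left
#' singular vector), sign-oriented so that its correlation with the
#' module's mean standardized profile is nonnegative. The fraction of
#' variance explained by the first component is reported.
#'
#' @param expr Samples-by-genes matrix.
#' @param labels Named integer module labels (0 = unassigned), or a
#'   `module_assignment`.
#' @return A list of class `module_eigengenes` with `eigengenes`
#'   (samples x modules matrix, columns `ME1`, `ME2`, ...) and
#'   `var_explained`.
#' @export
module_eigengenes <- function(expr, labels) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  mods <- sort(setdiff(unique(labels), 0L))
  if (!length(mods)) stop("no assigned module")
  expr <- as.matrix(expr)
  me <- matrix(NA_real_, nrow(expr), length(mods),
               dimnames = list(rownames(expr), paste0("ME", mods)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    x <- scale(expr[, genes, drop = FALSE])
    x[, attr(x, "scaled:scale") == 0] <- 0
    if (ncol(x) == 1L) {
      v <- as.vector(x)
      nrm <- sqrt(sum(v^2))
      me[, i] <- if (nrm > 0) v / nrm else v
      ve[i] <- 1
    } else {
      sv <- svd(x, nu = 1, nv = 0)
      u <- sv$u[, 1]
      if (stats::sd(rowMeans(x)) > 0 && stats::cor(u, rowMeans(x)) < 0)
        u <- -u
      me[, i] <- u
      ve[i] <- sv$d[1]^2 / sum(sv$d^2)
    }
  }
  structure(list(eigengenes = me, var_explained = ve),
            class = "module_eigengenes")
}

#' Merge modules with highly correlated eigengenes
#'
#' Clusters module eigengenes by average linkage on `1 - cor(ME)`, merges
#' every branch falling below `cut_height`, recomputes eigengenes, and
#' iterates until no merge occurs. With the default 0.25 cut, modules
#' whose eigengenes correlate above 0.75 are merged.
#'
#' @param expr Samples-by-genes matrix.
#' @param labels Named integer module labels or a `module_assignment`.
#' @param cut_height Eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @return A list with `labels` (relabeled contiguously by size) and
#'   `eigengenes` (recomputed [module_eigengenes()]).
#' @export
merge_close_modules <- function(expr, labels, cut_height = 0.25) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  genes <- names(labels)
  repeat {
    mods <- sort(setdiff(unique(labels), 0L))
    if (length(mods) < 2L) break
    me <- module_eigengenes(expr, labels)$eigengenes
    dme <- 1 - stats::cor(me)
    hc <- stats::hclust(stats::as.dist(dme), method = "average")
    grp <- stats::cutree(hc, h = cut_height)
    if (max(table(grp)) == 1L) break
    new_labels <- labels
    for (g in unique(grp)) {
      members <- mods[grp == g]
      if (length(members) > 1L)
        new_labels[labels %in% members] <- min(members)
    }
    labels <- stats::setNames(relabel_by_size(new_labels), genes)
  }
  list(labels = labels, eigengenes = module_eigengenes(expr, labels))
}

#' Correlate module eigengenes with clinical traits
#'
#' Pearson correlation and two-sided t-based p-value per (module, trait);
#' binary traits are encoded 0/1. A constant trait yields `NA` with a
#' warning.
#'
#' @param me A `module_eigengenes` object (or its eigengene matrix).
#' @param traits Per-sample data.frame of numeric or 0/1 traits, rows
#'   aligned with the eigengene samples.
#' @return A list of class `module_trait_cor` with matrices `cor` and
#'   `p`.
#' @export
module_trait_correlation <- function(me, traits) {
  if (inherits(me, "module_eigengenes")) me <- me$eigengenes
  traits <- as.data.frame(traits)
  if (nrow(traits) != nrow(me))
    stop("traits and eigengenes must cover the same samples")
  m <- nrow(me)
  cors <- matrix(NA_real_, ncol(me), ncol(traits),
                 dimnames = list(colnames(me), names(traits)))
  ps <- cors
  for (j in seq_along(traits)) {
    tr <- as.numeric(traits[[j]])
    if (stats::sd(tr) == 0) {
      warning("constant trait '", names(traits)[j], "': correlation undefined")
      next
    }
    cors[, j] <- stats::cor(me, tr)
    ps[, j] <- cor_pvalue(cors[, j], m)
  }
  structure(list(cor = cors, p = ps), class = "module_trait_cor")
}

#' Select hub genes by module membership and gene significance
#'
#' `MM(g)` is the correlation of gene `g` with its module's eigengene;
#' `GS(g)` its correlation with the trait. A gene passes iff
#' `|MM| > mm_cut` and `|GS| > gs_cut` (both strict). The table is sorted
#' by `|MM|` descending.
#'
#' @param expr Samples-by-genes matrix.
#' @param me A `module_eigengenes` object.
#' @param labels Named module labels or a `module_assignment`.
#' @param trait Per-sample numeric (or 0/1) trait vector.
#' @param module Module label (integer) to select hubs from.
#' @param mm_cut Module-membership threshold (default 0.8).
#' @param gs_cut Gene-significance threshold (default 0.4).
#' @return Data.frame `gene`, `module`, `MM`, `GS`, `passing`.
#' @export
hub_genes <- function(expr, me, labels, trait, module, mm_cut = 0.8,
                      gs_cut = 0.4) {
  if (inherits(labels, "module_assignment")) labels <- labels$labels
  if (inherits(me, "module_eigengenes")) me <- me$eigengenes
  col <- paste0("ME", module)
  if (!col %in% colnames(me)) stop("module ", module, " has no eigengene")
  genes <- names(labels)[labels == module]
  if (!length(genes)) stop("module ", module, " is empty")
  x <- as.matrix(expr)[, genes, drop = FALSE]
  mm <- as.vector(stats::cor(x, me[, col]))
  gs <- as.vector(stats::cor(x, as.numeric(trait)))
  out <- data.frame(gene = genes, module = module, MM = mm, GS = gs,
                    passing = abs(mm) > mm_cut & abs(gs) > gs_cut,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$MM)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
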