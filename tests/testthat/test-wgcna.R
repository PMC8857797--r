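test_that("soft-threshold scan behaves on degenerate and simulated input", {
  sim <- simulate_module_matrix(3, 50, 50, 0.7, seed = 11)
  scan <- pick_soft_threshold(sim$expr, 1:20)
  # some scanned power reaches a scale-free fit
  expect_gte(max(scan$table$signed_r2, na.rm = TRUE), 0.8)
  # mean connectivity strictly decreases with the power
  tab <- scan$table
  expect_gt(tab$mean_connectivity[tab$power == 1],
            tab$mean_connectivity[tab$power == 6])
  expect_true(all(diff(tab$mean_connectivity) < 0))
  # two perfectly correlated genes: adjacency 1 at every power
  x <- rnorm(20)
  expect_equal(adjacency_matrix(cbind(x, 2 * x), 7),
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_error(pick_soft_threshold(sim$expr[1:5, ]), "8 samples")
  expect_error(pick_soft_threshold(cbind(sim$expr, flat = rep(1, 50))),
               "zero-variance")
})

test_that("TOM matches hand calculations and the brute-force triple loop", {
  # 2 genes, a_12 = 0.5: l = 0, k = 0.5, TOM = 0.5/(0.5 + 1 - 0.5)
  a2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(tom_similarity(a2)[1, 2], 0.5)
  # identity adjacency maps to identity
  expect_equal(tom_similarity(diag(4)), diag(4))
  # all-ones (n=4): l = 2, k = 3, (2+1)/(3+1-1) = 1 everywhere
  expect_equal(tom_similarity(matrix(1, 4, 4)), matrix(1, 4, 4))
  # brute-force oracle on a random 20-gene adjacency
  set.seed(2)
  n <- 20
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  tm <- tom_similarity(a)
  bf <- diag(n)
  for (i in 1:n) for (j in seq_len(n)[-i]) {
    l <- sum(vapply(setdiff(1:n, c(i, j)), function(u) a[i, u] * a[u, j],
                    numeric(1)))
    bf[i, j] <- (l + a[i, j]) /
      (min(sum(a[i, -i]), sum(a[j, -j])) + 1 - a[i, j])
  }
  expect_lt(max(abs(tm - bf)), 1e-10)
  expect_true(isSymmetric(tm))
  expect_true(all(tm >= 0 & tm <= 1 + 1e-12))
  expect_error(tom_similarity(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("planted modules are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:3, function(s) {
    sim <- simulate_module_matrix(3, 50, 50, 0.7, seed = s)
    tom <- tom_similarity(adjacency_matrix(sim$expr, 6))
    asg <- cluster_modules(1 - tom, sim$expr, min_size = 30)
    mclust::adjustedRandIndex(asg$labels, sim$labels)
  }, numeric(1))
  expect_true(all(aris >= 0.8))
  # labels are permutation-invariant up to relabeling
  sim <- simulate_module_matrix(3, 40, 50, 0.7, seed = 9)
  tom <- tom_similarity(adjacency_matrix(sim$expr, 6))
  asg <- cluster_modules(1 - tom, sim$expr, min_size = 30)
  perm <- sample(ncol(sim$expr))
  asg_p <- cluster_modules((1 - tom)[perm, perm], sim$expr[, perm],
                           min_size = 30)
  expect_equal(mclust::adjustedRandIndex(asg$labels,
                                         asg_p$labels[names(asg$labels)]), 1)
  # min_size larger than the gene count: everything unassigned
  tiny <- simulate_module_matrix(1, 10, 20, 0.7, seed = 1)
  tom_t <- tom_similarity(adjacency_matrix(tiny$expr, 6))
  asg_t <- cluster_modules(1 - tom_t, tiny$expr, min_size = 50)
  expect_true(all(asg_t$labels == 0L))
})

test_that("eigengenes honor the variance-explained and orientation rules", {
  set.seed(4)
  prof <- rnorm(30)
  expr <- cbind(g1 = prof, g2 = prof, g3 = prof)
  me <- module_eigengenes(expr, c(g1 = 1L, g2 = 1L, g3 = 1L))
  expect_equal(unname(me$var_explained), 1)
  expect_gt(cor(me$eigengenes[, 1], prof), 0.999)
  # 2-gene module with exact sample correlation 0.8: VE = (1 + 0.8)/2
  a <- as.vector(scale(rnorm(30)))
  b <- as.vector(scale(resid(lm(rnorm(30) ~ a))))
  y <- 0.8 * a + sqrt(1 - 0.64) * b
  me2 <- module_eigengenes(cbind(g1 = a, g2 = y), c(g1 = 1L, g2 = 1L))
  expect_equal(unname(me2$var_explained), 0.9, tolerance = 1e-10)
  # flip consistency: negating the data negates the eigengene
  me_neg <- module_eigengenes(-expr, c(g1 = 1L, g2 = 1L, g3 = 1L))
  expect_equal(me_neg$eigengenes[, 1], -me$eigengenes[, 1],
               tolerance = 1e-10)
  # singleton module: the gene's z-scored profile (unit norm)
  me1 <- module_eigengenes(cbind(g1 = prof, g2 = rnorm(30)),
                           c(g1 = 1L, g2 = 0L))
  expect_equal(abs(cor(me1$eigengenes[, 1], prof)), 1, tolerance = 1e-12)
})

test_that("modules merge by eigengene correlation and merging is idempotent", {
  set.seed(5)
  f <- rnorm(40)
  mk <- function(base, k, noise) sapply(seq_len(k), function(i)
    base + rnorm(40, 0, noise))
  expr <- cbind(mk(f, 10, 0.3), mk(f, 10, 0.3), mk(rnorm(40), 10, 0.3))
  colnames(expr) <- sprintf("g%02d", 1:30)
  labels <- setNames(rep(1:3, each = 10L), colnames(expr))
  merged <- merge_close_modules(expr, labels, cut_height = 0.25)
  expect_equal(length(setdiff(unique(merged$labels), 0L)), 2L)
  # the two copies of the shared factor end up together
  expect_equal(unname(merged$labels[1]), unname(merged$labels[11]))
  # idempotence
  again <- merge_close_modules(expr, merged$labels, cut_height = 0.25)
  expect_identical(again$labels, merged$labels)
  # uncorrelated modules never merge
  expr2 <- cbind(mk(rnorm(40), 10, 0.3), mk(rnorm(40), 10, 0.3))
  colnames(expr2) <- sprintf("h%02d", 1:20)
  lab2 <- setNames(rep(1:2, each = 10L), colnames(expr2))
  expect_identical(sort(unique(merge_close_modules(expr2, lab2)$labels)),
                   1:2)
})

test_that("module-trait correlation finds the planted trait-linked module", {
  set.seed(6)
  hits <- vapply(1:5, function(s) {
    sim <- simulate_module_matrix(4, 30, 60, 0.7, seed = s)
    labels <- setNames(as.integer(sim$labels), names(sim$labels))
    me <- module_eigengenes(sim$expr, labels)
    trait <- as.vector(scale(me$eigengenes[, "ME2"])) + rnorm(60, 0, 0.5)
    mtc <- module_trait_correlation(me, data.frame(t = trait))
    which.max(abs(mtc$cor[, 1])) == 2L
  }, logical(1))
  expect_gte(sum(hits), 4L)
  # trait equal to an eigengene correlates perfectly
  sim <- simulate_module_matrix(2, 20, 40, 0.7, seed = 1)
  me <- module_eigengenes(sim$expr, sim$labels)
  mtc <- module_trait_correlation(me, data.frame(t = me$eigengenes[, 1]))
  expect_equal(unname(mtc$cor["ME1", "t"]), 1, tolerance = 1e-12)
  expect_warning(module_trait_correlation(me, data.frame(flat = rep(1, 40))),
                 "constant trait")
})

test_that("hub-gene selection applies strict MM and GS thresholds", {
  set.seed(7)
  latent <- rnorm(50)
  hub <- sapply(1:5, function(i) 0.95 * latent + sqrt(1 - 0.95^2) * rnorm(50))
  bulk <- matrix(rnorm(50 * 20), 50, 20)
  expr <- cbind(hub, bulk)
  colnames(expr) <- sprintf("g%02d", 1:25)
  labels <- setNames(c(rep(1L, 5), rep(0L, 20)), colnames(expr))
  me <- module_eigengenes(expr, labels)
  trait <- latent + rnorm(50, 0, 0.5)
  tab <- hub_genes(expr, me, labels, trait, module = 1)
  expect_true(all(tab$passing[tab$gene %in% sprintf("g%02d", 1:5)]))
  # strict inequality: mm_cut = 1 passes nothing
  none <- hub_genes(expr, me, labels, trait, module = 1, mm_cut = 1)
  expect_false(any(none$passing))
  # monotone in both cuts
  loose <- hub_genes(expr, me, labels, trait, module = 1,
                     mm_cut = 0.5, gs_cut = 0.2)
  expect_true(all(tab$gene[tab$passing] %in% loose$gene[loose$passing]))
  # sorted by |MM| descending
  expect_true(all(diff(abs(tab$MM)) <= 1e-12))
})
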