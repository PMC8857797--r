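test_that("shared-miRNA test matches direct combinatorics on worked examples", {
  # N=10, K=4, n=5, k=4: C(4,4)*C(6,1)/C(10,5) = 6/252
  res <- shared_mirna_test(paste0("m", 1:4),
                           paste0("m", c(1:4, 5)), paste0("m", 1:10))
  expect_equal(res$k, 4)
  expect_equal(res$hyper_p, 6 / 252, tolerance = 1e-12)
  # no overlap: upper tail at zero is 1
  res0 <- shared_mirna_test("m1", "m2", paste0("m", 1:5))
  expect_equal(res0$hyper_p, 1)
  # degenerate: both sets equal the universe, X = N surely
  resN <- shared_mirna_test(paste0("m", 1:6), paste0("m", 1:6),
                            paste0("m", 1:6))
  expect_equal(resN$hyper_p, 1)
  expect_error(shared_mirna_test("x", "m1", paste0("m", 1:4)), "subsets")
  expect_error(shared_mirna_test("m1", "m1", character(0)), "nonempty")
})

test_that("shared-miRNA test agrees with exhaustive enumeration for N <= 12", {
  # brute-force oracle: enumerate every n-subset of the universe
  max_err <- 0
  for (N in c(5, 8, 12)) {
    universe <- paste0("m", seq_len(N))
    for (K in c(1, ceiling(N / 2), N)) {
      for (n in c(1, ceiling(N / 3), N)) {
        for (k in 0:min(K, n)) {
          if (K + n - k > N) next
          lnc <- universe[seq_len(K)]
          mrna <- universe[c(seq_len(k),
                             if (n > k) K + seq_len(n - k))]
          got <- shared_mirna_test(lnc, mrna, universe)$hyper_p
          want <- enumerate_overlap_tail(k, K, n, N)
          max_err <- max(max_err, abs(got - want) / max(want, 1e-300))
        }
      }
    }
  }
  expect_lt(max_err, 1e-12)
})

test_that("hypergeometric tail is monotone nonincreasing in the overlap", {
  universe <- paste0("m", 1:30)
  p <- vapply(0:8, function(k) {
    mrna <- universe[c(seq_len(k), if (k < 10) 10 + seq_len(10 - k))]
    shared_mirna_test(universe[1:10], mrna, universe)$hyper_p
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-15))
})

test_that("pair correlation returns exact r and a calibrated t p-value", {
  x <- 1:10
  perf <- pair_correlation(x, 2 * x + 1)
  expect_equal(perf$r, 1)
  expect_lt(perf$p, 1e-12)
  # r = 0.5 at m = 20: p from independent numeric integration of the
  # t density with 18 df
  m <- 20
  tstat <- 0.5 * sqrt((m - 2) / (1 - 0.25))
  p_oracle <- 2 * integrate(function(u) dt(u, m - 2), tstat, Inf)$value
  set.seed(1)
  a <- as.vector(scale(rnorm(m)))
  b0 <- as.vector(scale(resid(lm(rnorm(m) ~ a))))
  y <- 0.5 * a + sqrt(1 - 0.25) * b0  # exact sample correlation 0.5
  got <- pair_correlation(a, y)
  expect_equal(got$r, 0.5, tolerance = 1e-10)
  expect_equal(got$p, p_oracle, tolerance = 1e-8)
  expect_equal(round(got$p, 4), 0.0248)
  # null calibration
  set.seed(2)
  ps <- vapply(1:1000, function(i)
    pair_correlation(rnorm(20), rnorm(20))$p, numeric(1))
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
  # degenerate input
  expect_warning(z <- pair_correlation(rep(1, 5), rnorm(5)), "zero-variance")
  expect_equal(z, list(r = 0, p = 1))
  expect_error(pair_correlation(1:4, 1:5), "equal length")
})

test_that("network acceptance follows the sign rule and threshold monotonicity", {
  set.seed(3)
  universe <- paste0("m", 1:20)
  tab <- rbind(
    data.frame(mirna_id = universe[1:6], target_id = "L1",
               target_class = "lncRNA", score = 160, energy = -25),
    data.frame(mirna_id = universe[1:6], target_id = "g1",
               target_class = "mRNA", score = 160, energy = -25),
    data.frame(mirna_id = universe[7:12], target_id = "g2",
               target_class = "mRNA", score = 160, energy = -25))
  bp <- build_bipartite(tab, universe, "L1", c("g1", "g2"),
                        universe = universe)
  m <- 20
  base <- rnorm(m)
  lnc_expr <- matrix(2^(base * 2 + 8), 1, m, dimnames = list("L1", NULL))
  # g1 perfectly anticorrelated with L1, g2 unrelated
  mrna_expr <- rbind(g1 = 2^(-base * 2 + 8), g2 = 2^(rnorm(m) + 8))
  colnames(lnc_expr) <- colnames(mrna_expr) <- sprintf("s%02d", 1:m)
  net <- build_cerna_network(bp, lnc_expr, mrna_expr)
  p1 <- net$pairs[net$pairs$mrna == "g1", ]
  expect_lt(p1$hyper_p, 1e-4)
  expect_lt(p1$pearson_r, -0.9)
  expect_false(p1$accepted)      # strong but negative: rejected
  expect_false("g2" %in% net$pairs$mrna)  # k = 0 pair never scored
  # relaxing thresholds never removes an accepted pair
  strict <- build_cerna_network(bp, lnc_expr, mrna_expr, r_cut = 0.8,
                                p_cut = 0.01)
  loose <- build_cerna_network(bp, lnc_expr, mrna_expr, r_cut = 0.1,
                               p_cut = 0.2)
  sk <- with(strict$pairs, paste(lncrna, mrna)[accepted])
  lk <- with(loose$pairs, paste(lncrna, mrna)[accepted])
  expect_true(all(sk %in% lk))
})

test_that("planted triplets are recovered on synthetic data", {
  ds <- simulate_multiomics(simulation_config(n_pairs = 20, seed = 5))
  chain <- run_cerna_chain(ds)
  expect_gte(mean(chain$true_keys %in% chain$accepted_keys), 0.8)
  # triplets expand one row per shared miRNA of each accepted true pair
  tri <- chain$net$triplets
  expect_true(all(paste(tri$lncrna, tri$mrna) %in%
                    with(chain$net$pairs, paste(lncrna, mrna)[accepted])))
})

test_that("subnetwork extraction induces exactly the requested lncRNAs", {
  tri <- data.frame(lncrna = rep("L1", 3), mirna = paste0("m", 1:3),
                    mrna = paste0("g", 1:3), pearson_r = 0.9,
                    hyper_p = 1e-4)
  net <- structure(list(pairs = data.frame(lncrna = "L1", mrna = "g1",
                                           accepted = TRUE),
                        triplets = tri, nodes = NULL, edges = NULL,
                        n_skipped = 0L), class = "cerna_network")
  sub <- extract_subnetwork(net, "L1")
  expect_equal(sub$relation_counts$n_relations, 3L)
  expect_equal(nrow(sub$triplets), 3L)
  empty <- extract_subnetwork(net, character(0))
  expect_equal(nrow(empty$triplets), 0L)
  expect_warning(extract_subnetwork(net, "ghost"), "ghost")
})

test_that("network export is deterministic and round-trips", {
  ds <- simulate_multiomics(small_config(seed = 2, n_pairs = 15))
  chain <- run_cerna_chain(ds)
  net <- chain$net
  # one triplet contributes a lnc-mi, mi-m and lnc-m edge
  if (nrow(net$triplets) > 0) {
    expect_setequal(unique(net$edges$edge_type),
                    c("lncRNA-miRNA", "miRNA-mRNA", "lncRNA-mRNA"))
    expect_true(all(c(net$edges$source, net$edges$target) %in% net$nodes$id))
  }
  d <- withr::local_tempdir()
  p1 <- export_network(net, file.path(d, "a"))
  # re-import and re-export: byte-identical
  reimported <- structure(list(pairs = net$pairs,
                               triplets = net$triplets,
                               nodes = read_tsv(p1["nodes"]),
                               edges = read_tsv(p1["edges"]),
                               n_skipped = 0L), class = "cerna_network")
  p2 <- export_network(reimported, file.path(d, "b"))
  expect_identical(readLines(p1["edges"]), readLines(p2["edges"]))
  expect_identical(readLines(p1["nodes"]), readLines(p2["nodes"]))
  # empty network: header-only files
  p0 <- export_network(build_cerna_network(
    build_bipartite(ds$interactions[0, ], character(0), character(0),
                    character(0)),
    cpm_normalize(ds$counts$lncrna), cpm_normalize(ds$counts$mrna)),
    file.path(d, "empty"))
  expect_length(readLines(p0["nodes"]), 1L)
})
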