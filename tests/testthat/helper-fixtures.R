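# Small configurations shared across tests. Feature counts are kept low
# so the whole suite stays fast; the planted structure is unchanged.

small_config <- function(seed = 1L, ...) {
  defaults <- list(n_pairs = 10L, n_mrna = 80L, n_mirna = 40L,
                   n_lncrna = 60L, n_triplets = 3L, n_shared_mirnas = 4L,
                   n_modules = 2L, module_size = 10L, n_decoys = 50L,
                   bg_lnc_degree = 3L, bg_mrna_degree = 3L, seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Configuration for survival-focused runs: many subjects, few features.
survival_config <- function(seed = 1L, ...) {
  defaults <- list(n_pairs = 300L, n_mrna = 20L, n_mirna = 20L,
                   n_lncrna = 20L, n_triplets = 1L, n_shared_mirnas = 2L,
                   n_modules = 1L, module_size = 5L, n_decoys = 20L,
                   seed = seed)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# Run the DE -> filter -> bipartite -> network chain on a dataset at the
# standard thresholds and return the network plus the truth pair keys.
run_cerna_chain <- function(ds) {
  cond <- ds$sample_table$condition
  de <- lapply(ds$counts, nb_wald_test, condition = cond)
  sets <- lapply(de, filter_de)
  filt <- filter_interactions(ds$interactions)
  bp <- build_bipartite(filt, unlist(sets$mirna, use.names = FALSE),
                        unlist(sets$lncrna, use.names = FALSE),
                        unlist(sets$mrna, use.names = FALSE))
  net <- build_cerna_network(
    bp, cpm_normalize(ds$counts$lncrna), cpm_normalize(ds$counts$mrna),
    samples = ds$sample_table$sample_id[cond == "tumor"])
  tt <- unique(ds$truth$true_triplets[c("lncrna", "mrna")])
  list(net = net, true_keys = paste(tt$lncrna, tt$mrna),
       accepted_keys = paste(net$pairs$lncrna,
                             net$pairs$mrna)[net$pairs$accepted])
}

# Exhaustive upper-tail overlap probability: enumerate all n-subsets of
# 1:N and count those sharing at least k elements with 1:K. Independent
# of any distribution function.
enumerate_overlap_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  if (n == 0) return(0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}
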