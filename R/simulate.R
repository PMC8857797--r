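#' Configuration for the synthetic multi-omics generator
#'
#' Bundles every knob of the planted-ground-truth simulation: the paired
#' tumor/normal design, negative-binomial count noise, differential
#' expression effects, the miRNA targeting graph with its score/energy
#' annotations, planted ceRNA sponge triplets, planted co-expression
#' modules tied to clinical traits, a prognostic lncRNA driving
#' progression-free survival, and qPCR cycle-threshold tables.
#'
#' @param n_pairs Number of tumor/normal subject pairs (each subject
#'   contributes one tumor and one normal sample).
#' @param n_mrna,n_mirna,n_lncrna Feature counts per RNA class.
#' @param frac_de Fraction of features per class that are differentially
#'   expressed between tumor and normal.
#' @param lfc_mean,lfc_sd Mean and sd of the |log2 fold change| drawn for
#'   DE features (sign assigned at random; planted sponge features are
#'   truncated below at 1.2 so they always clear the DE gate).
#' @param nb_dispersion Negative-binomial dispersion d, so that
#'   variance = mu + d * mu^2. Zero gives Poisson counts.
#' @param libsize_range Interval of multiplicative per-sample library-size
#'   factors (relative depth), drawn uniformly.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   per-feature baseline mean expression.
#' @param n_triplets Number of planted ceRNA sponge pairs; each pair is one
#'   lncRNA and one mRNA sharing `n_shared_mirnas` miRNAs.
#' @param n_shared_mirnas Shared miRNAs per planted sponge pair.
#' @param sponge_loading Magnitude of the per-tumor-sample latent factor
#'   loading (natural-log scale) that loads positively on the sponge
#'   lncRNA and mRNA means and negatively on the shared miRNA means.
#' @param sponge_base_mean Baseline mean expression for sponge features
#'   (high so count noise does not drown the planted correlation).
#' @param bg_lnc_degree,bg_mrna_degree Number of background (non-sponge)
#'   miRNA interactions drawn per lncRNA / mRNA; these pass the
#'   score/energy filter but carry no planted co-expression.
#' @param n_modules,module_size Planted co-expression modules among the
#'   lncRNAs and their size.
#' @param module_loading Loading (natural-log scale) of the per-sample
#'   module latent factor on module gene means.
#' @param prognostic_lnc_loghr Log hazard ratio per unit standardized
#'   tumor expression of the designated prognostic lncRNA.
#' @param censor_rate Target censoring fraction (independent uniform
#'   censoring, calibrated by bisection).
#' @param baseline_hazard Baseline exponential hazard (per month).
#' @param n_decoys Number of decoy interactions whose score/energy
#'   annotations violate the filter thresholds.
#' @param true_score_range,true_energy_range Annotation intervals for true
#'   interactions; must lie entirely at score >= 150 and energy <= -20.
#' @param decoy_score_range,decoy_energy_range Annotation intervals for
#'   decoys; must violate at least one threshold so the filter separates.
#' @param qpcr_n_subjects Number of paired subjects in the simulated qPCR
#'   assay.
#' @param qpcr_ddct Planted ddCt shift (tumor minus normal) for the qPCR
#'   target gene; positive means down-regulation in tumor (fold < 1).
#' @param qpcr_ct_noise_sd Gaussian technical noise sd on each Ct value.
#' @param seed Root random seed; per-component child seeds are derived
#'   from it so that adding components does not perturb existing draws.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_pairs = 10L,
                              n_mrna = 400L, n_mirna = 150L, n_lncrna = 150L,
                              frac_de = 0.4, lfc_mean = 2, lfc_sd = 0.5,
                              nb_dispersion = 0.1, libsize_range = c(0.7, 1.4),
                              base_mean_meanlog = log(100), base_mean_sdlog = 1,
                              n_triplets = 10L, n_shared_mirnas = 4L,
                              sponge_loading = 0.7, sponge_base_mean = 500,
                              bg_lnc_degree = 6L, bg_mrna_degree = 5L,
                              n_modules = 3L, module_size = 40L,
                              module_loading = 0.5,
                              prognostic_lnc_loghr = 0.5, censor_rate = 0.3,
                              baseline_hazard = log(2) / 24,
                              n_decoys = 300L,
                              true_score_range = c(150, 200),
                              decoy_score_range = c(60, 149),
                              true_energy_range = c(-40, -20),
                              decoy_energy_range = c(-19, -5),
                              qpcr_n_subjects = 26L, qpcr_ddct = 1.5,
                              qpcr_ct_noise_sd = 0.3,
                              seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
              n_lncrna = as.integer(n_lncrna),
              frac_de = frac_de, lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              nb_dispersion = nb_dispersion, libsize_range = libsize_range,
              base_mean_meanlog = base_mean_meanlog,
              base_mean_sdlog = base_mean_sdlog,
              n_triplets = as.integer(n_triplets),
              n_shared_mirnas = as.integer(n_shared_mirnas),
              sponge_loading = sponge_loading,
              sponge_base_mean = sponge_base_mean,
              bg_lnc_degree = as.integer(bg_lnc_degree),
              bg_mrna_degree = as.integer(bg_mrna_degree),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_loading = module_loading,
              prognostic_lnc_loghr = prognostic_lnc_loghr,
              censor_rate = censor_rate, baseline_hazard = baseline_hazard,
              n_decoys = as.integer(n_decoys),
              true_score_range = true_score_range,
              decoy_score_range = decoy_score_range,
              true_energy_range = true_energy_range,
              decoy_energy_range = decoy_energy_range,
              qpcr_n_subjects = as.integer(qpcr_n_subjects),
              qpcr_ddct = qpcr_ddct, qpcr_ct_noise_sd = qpcr_ct_noise_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 1L, cfg$n_mrna >= 1L, cfg$n_mirna >= 1L,
            cfg$n_lncrna >= 1L)
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    stop("frac_de must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (cfg$n_modules > 0L &&
      cfg$n_modules * cfg$module_size > cfg$n_lncrna - cfg$n_triplets)
    stop("n_modules * module_size exceeds available lncRNA features")
  if (cfg$n_triplets > 0L) {
    if (cfg$n_triplets > min(cfg$n_lncrna, cfg$n_mrna))
      stop("n_triplets exceeds available feature combinations")
    n_de_mir <- round(cfg$frac_de * cfg$n_mirna)
    if (cfg$n_triplets * cfg$n_shared_mirnas > n_de_mir)
      stop("n_triplets * n_shared_mirnas exceeds the DE miRNA pool")
  }
  if (min(cfg$true_score_range) < 150 || max(cfg$true_energy_range) > -20)
    stop("true score/energy ranges must satisfy score >= 150 and energy <= -20")
  if (max(cfg$decoy_score_range) >= 150 && min(cfg$decoy_energy_range) <= -20)
    stop("decoy ranges overlap the filter region: filter would not separate")
  invisible(cfg)
}

# Child seed for a named component stream: stable, below 2^31.
child_seed <- function(seed, what) {
  offset <- c(counts = 101L, interactions = 202L, survival = 303L,
              qpcr = 404L, modules = 505L)[[what]]
  (as.integer(seed) %% 2000000000L) + offset
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a paired tumor/normal multi-omics dataset with planted truth
#'
#' Draws negative-binomial counts for mRNAs, miRNAs and lncRNAs over a
#' paired tumor/normal design, planting (i) differentially expressed
#' features with recorded direction, (ii) ceRNA sponge triplets in which a
#' per-tumor-sample latent factor loads positively on a lncRNA and an mRNA
#' and negatively on their shared miRNAs, (iii) lncRNA co-expression
#' modules tied to binary clinical traits, and (iv) progression-free
#' survival driven by a designated prognostic lncRNA. A miRNA-target
#' interaction table with separating score/energy annotations and the full
#' ground truth are attached.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `multiomics_dataset` with elements `counts`
#'   (list of feature-by-sample integer matrices `mrna`, `mirna`,
#'   `lncrna`), `sample_table`, `clinical`, `interactions`, and `truth`
#'   (class `ground_truth`).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(child_seed(cfg$seed, "counts"))

  n_s <- 2L * cfg$n_pairs
  subjects <- sprintf("S%03d", seq_len(cfg$n_pairs))
  sample_table <- data.frame(
    sample_id = c(paste0(subjects, "_T"), paste0(subjects, "_N")),
    subject_id = rep(subjects, 2L),
    condition = rep(c("tumor", "normal"), each = cfg$n_pairs),
    stringsAsFactors = FALSE)
  tumor_idx <- seq_len(cfg$n_pairs)
  ids <- list(mrna = sprintf("mRNA_%04d", seq_len(cfg$n_mrna)),
              mirna = sprintf("miR_%04d", seq_len(cfg$n_mirna)),
              lncrna = sprintf("lnc_%04d", seq_len(cfg$n_lncrna)))

  # --- differential expression assignment -------------------------------
  de <- lapply(ids, function(v) sort(sample(v, round(cfg$frac_de * length(v)))))

  # planted sponge triplets: lncRNA and mRNA up, shared miRNAs down
  trip <- NULL
  if (cfg$n_triplets > 0L) {
    t_lnc <- if (length(de$lncrna)) sample(de$lncrna, cfg$n_triplets) else
      sample(ids$lncrna, cfg$n_triplets)
    t_mrna <- if (length(de$mrna)) sample(de$mrna, cfg$n_triplets) else
      sample(ids$mrna, cfg$n_triplets)
    t_mir <- sample(de$mirna, cfg$n_triplets * cfg$n_shared_mirnas)
    trip <- list(lnc = t_lnc, mrna = t_mrna,
                 mir = split(t_mir, rep(seq_len(cfg$n_triplets),
                                        each = cfg$n_shared_mirnas)))
    de$lncrna <- union(de$lncrna, t_lnc)
    de$mrna <- union(de$mrna, t_mrna)
  }

  draw_lfc <- function(fids) {
    if (!length(fids)) return(numeric(0))
    mag <- abs(stats::rnorm(length(fids), cfg$lfc_mean, cfg$lfc_sd))
    sgn <- sample(c(-1, 1), length(fids), replace = TRUE)
    stats::setNames(mag * sgn, fids)
  }
  lfc <- lapply(de, draw_lfc)
  if (!is.null(trip)) {
    # sponge features must clear the |log2FC| >= 1 gate by construction
    force_lfc <- function(v, fids, sign) {
      v[fids] <- sign * pmax(abs(v[fids]), 1.2)
      v
    }
    lfc$lncrna <- force_lfc(lfc$lncrna, trip$lnc, +1)
    lfc$mrna <- force_lfc(lfc$mrna, trip$mrna, +1)
    lfc$mirna <- force_lfc(lfc$mirna, unlist(trip$mir), -1)
  }

  # planted lncRNA co-expression modules (disjoint from sponge lncRNAs)
  module_membership <- character(0)
  module_latent <- NULL
  if (cfg$n_modules > 0L) {
    pool <- setdiff(ids$lncrna, if (is.null(trip)) character(0) else trip$lnc)
    mod_genes <- sample(pool, cfg$n_modules * cfg$module_size)
    module_membership <- stats::setNames(
      rep(sprintf("M%d", seq_len(cfg$n_modules)), each = cfg$module_size),
      mod_genes)
    module_latent <- matrix(stats::rnorm(cfg$n_modules * n_s),
                            cfg$n_modules, n_s)
  }

  # --- mean matrices and counts -----------------------------------------
  lib <- stats::runif(n_s, cfg$libsize_range[1], cfg$libsize_range[2])
  sponge_factor <- if (!is.null(trip))
    matrix(stats::rnorm(cfg$n_triplets * cfg$n_pairs),
           cfg$n_triplets, cfg$n_pairs) else NULL

  make_counts <- function(class) {
    fids <- ids[[class]]
    n_f <- length(fids)
    base <- stats::rlnorm(n_f, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
    names(base) <- fids
    if (!is.null(trip)) {
      sponge_ids <- switch(class, lncrna = trip$lnc, mrna = trip$mrna,
                           mirna = unlist(trip$mir))
      base[sponge_ids] <- cfg$sponge_base_mean
    }
    mu <- matrix(base, n_f, n_s, dimnames = list(fids, sample_table$sample_id))
    fl <- lfc[[class]]
    if (length(fl)) mu[names(fl), tumor_idx] <-
      mu[names(fl), tumor_idx, drop = FALSE] * 2^fl
    if (!is.null(trip)) {
      for (t in seq_len(cfg$n_triplets)) {
        # mean-centered multiplier: E[exp(L f - L^2/2)] = 1, so the planted
        # log2FC stays the true expected fold change
        f_pos <- exp(cfg$sponge_loading * sponge_factor[t, ] -
                       cfg$sponge_loading^2 / 2)
        f_neg <- exp(-cfg$sponge_loading * sponge_factor[t, ] -
                       cfg$sponge_loading^2 / 2)
        if (class == "lncrna") mu[trip$lnc[t], tumor_idx] <-
            mu[trip$lnc[t], tumor_idx] * f_pos
        if (class == "mrna") mu[trip$mrna[t], tumor_idx] <-
            mu[trip$mrna[t], tumor_idx] * f_pos
        if (class == "mirna") mu[trip$mir[[t]], tumor_idx] <-
            sweep(mu[trip$mir[[t]], tumor_idx, drop = FALSE], 2, f_neg, "*")
      }
    }
    if (class == "lncrna" && length(module_membership)) {
      for (m in seq_len(cfg$n_modules)) {
        genes <- names(module_membership)[module_membership ==
                                            sprintf("M%d", m)]
        mu[genes, ] <- sweep(mu[genes, , drop = FALSE], 2,
                             exp(cfg$module_loading * module_latent[m, ] -
                                   cfg$module_loading^2 / 2), "*")
      }
    }
    mu <- sweep(mu, 2, lib, "*")
    cnt <- matrix(rnb(length(mu), as.vector(mu), cfg$nb_dispersion),
                  n_f, n_s, dimnames = dimnames(mu))
    storage.mode(cnt) <- "integer"
    cnt
  }
  counts <- list(mrna = make_counts("mrna"), mirna = make_counts("mirna"),
                 lncrna = make_counts("lncrna"))

  # --- ground truth ------------------------------------------------------
  de_features <- do.call(rbind, lapply(names(lfc), function(class) {
    if (!length(lfc[[class]])) return(NULL)
    data.frame(feature_id = names(lfc[[class]]), class = class,
               log2fc = unname(lfc[[class]]),
               direction = ifelse(lfc[[class]] > 0, "up", "down"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(de_features))
    de_features <- data.frame(feature_id = character(0), class = character(0),
                              log2fc = numeric(0), direction = character(0))
  true_triplets <- if (!is.null(trip))
    do.call(rbind, lapply(seq_len(cfg$n_triplets), function(t)
      data.frame(lncrna = trip$lnc[t], mirna = trip$mir[[t]],
                 mrna = trip$mrna[t], stringsAsFactors = FALSE))) else
    data.frame(lncrna = character(0), mirna = character(0),
               mrna = character(0))
  prognostic_lnc <- if (!is.null(trip)) trip$lnc[1] else ids$lncrna[1]

  truth <- structure(list(de_features = de_features,
                          true_triplets = true_triplets,
                          module_membership = module_membership,
                          prognostic_lnc = prognostic_lnc,
                          true_interactions = NULL),
                     class = "ground_truth")

  dataset <- structure(list(counts = counts, sample_table = sample_table,
                            clinical = NULL, interactions = NULL,
                            truth = truth, config = cfg),
                       class = "multiomics_dataset")
  dataset$interactions <- simulate_interactions(cfg, dataset)
  dataset$truth$true_interactions <-
    dataset$interactions[dataset$interactions$is_true,
                         c("mirna_id", "target_id", "target_class")]
  rownames(dataset$truth$true_interactions) <- NULL
  dataset$clinical <- simulate_survival(cfg, dataset,
                                        module_latent = module_latent)
  dataset
}

#' Simulate a miRNA-target interaction table with separating annotations
#'
#' True interactions (planted sponge edges plus random background edges)
#' receive prediction scores and binding free energies inside the
#' configured true ranges, so they survive the score >= 150 / energy <=
#' -20 filter; decoys receive annotations violating at least one
#' threshold, so the filter removes exactly them.
#'
#' @param config A [simulation_config()].
#' @param dataset A partially built `multiomics_dataset` (truth populated).
#' @return A data.frame with columns `mirna_id`, `target_id`,
#'   `target_class`, `score`, `energy`, `is_true`.
#' @export
simulate_interactions <- function(config, dataset) {
  cfg <- config
  set.seed(child_seed(cfg$seed, "interactions"))
  mir_ids <- rownames(dataset$counts$mirna)
  lnc_ids <- rownames(dataset$counts$lncrna)
  mrna_ids <- rownames(dataset$counts$mrna)

  edges <- list()
  tt <- dataset$truth$true_triplets
  if (nrow(tt)) {
    edges[[1]] <- data.frame(mirna_id = tt$mirna, target_id = tt$lncrna,
                             target_class = "lncRNA", stringsAsFactors = FALSE)
    edges[[2]] <- data.frame(mirna_id = tt$mirna, target_id = tt$mrna,
                             target_class = "mRNA", stringsAsFactors = FALSE)
  }
  bg <- function(targets, class, degree) {
    if (degree <= 0L) return(NULL)
    data.frame(mirna_id = as.vector(vapply(targets, function(t)
                 sample(mir_ids, degree), character(degree))),
               target_id = rep(targets, each = degree),
               target_class = class, stringsAsFactors = FALSE)
  }
  edges[[3]] <- bg(lnc_ids, "lncRNA", cfg$bg_lnc_degree)
  edges[[4]] <- bg(mrna_ids, "mRNA", cfg$bg_mrna_degree)
  true_tab <- unique(do.call(rbind, edges))

  n_true <- nrow(true_tab)
  true_tab$score <- stats::runif(n_true, cfg$true_score_range[1],
                                 cfg$true_score_range[2])
  true_tab$energy <- stats::runif(n_true, cfg$true_energy_range[1],
                                  cfg$true_energy_range[2])
  true_tab$is_true <- TRUE

  decoys <- NULL
  if (cfg$n_decoys > 0L) {
    all_targets <- c(lnc_ids, mrna_ids)
    tclass <- rep(c("lncRNA", "mRNA"), c(length(lnc_ids), length(mrna_ids)))
    idx <- sample(length(all_targets), cfg$n_decoys, replace = TRUE)
    decoys <- data.frame(mirna_id = sample(mir_ids, cfg$n_decoys,
                                           replace = TRUE),
                         target_id = all_targets[idx],
                         target_class = tclass[idx], stringsAsFactors = FALSE)
    key_true <- paste(true_tab$mirna_id, true_tab$target_id)
    decoys <- decoys[!duplicated(paste(decoys$mirna_id, decoys$target_id)) &
                       !(paste(decoys$mirna_id, decoys$target_id) %in%
                           key_true), , drop = FALSE]
    decoys$score <- stats::runif(nrow(decoys), cfg$decoy_score_range[1],
                                 cfg$decoy_score_range[2])
    decoys$energy <- stats::runif(nrow(decoys), cfg$decoy_energy_range[1],
                                  cfg$decoy_energy_range[2])
    decoys$is_true <- FALSE
  }
  out <- rbind(true_tab, decoys)
  rownames(out) <- NULL
  out
}

#' Simulate progression-free survival driven by a prognostic lncRNA
#'
#' Event times are exponential with hazard `h0 * exp(beta * z)` where `z`
#' is the standardized tumor-sample log2(CPM+1) expression of the
#' designated prognostic lncRNA and `beta` the configured log hazard
#' ratio. Censoring is independent uniform, with its upper bound
#' calibrated by bisection so the expected censoring fraction matches the
#' target. Binary traits (recurrence, metastasis) are tied to the planted
#' module latent factors when modules exist.
#'
#' @param config A [simulation_config()].
#' @param dataset A `multiomics_dataset` with counts and truth available.
#' @param module_latent Internal: module-by-sample latent factor matrix.
#' @return A clinical data.frame: `subject_id`, `pfs_time` (months),
#'   `event`, `recurrence`, `metastasis`.
#' @export
simulate_survival <- function(config, dataset, module_latent = NULL) {
  cfg <- config
  set.seed(child_seed(cfg$seed, "survival"))
  st <- dataset$sample_table
  tumor <- st$sample_id[st$condition == "tumor"]
  subjects <- st$subject_id[st$condition == "tumor"]
  n <- length(tumor)

  expr <- log2(cpm_normalize(dataset$counts$lncrna)[
    dataset$truth$prognostic_lnc, tumor] + 1)
  z <- if (stats::sd(expr) > 0) as.vector(scale(expr)) else rep(0, n)
  rate <- cfg$baseline_hazard * exp(cfg$prognostic_lnc_loghr * z)
  t_event <- stats::rexp(n, rate)

  if (cfg$censor_rate <= 0) {
    pfs_time <- t_event
    event <- rep(1L, n)
  } else {
    # P(censored | rate, cmax) for C ~ U(0, cmax): (1 - exp(-r*cmax))/(r*cmax)
    cens_frac <- function(cmax) mean((1 - exp(-rate * cmax)) / (rate * cmax))
    lo <- 1e-6; hi <- 1e6
    for (i in 1:60) {
      mid <- sqrt(lo * hi)
      if (cens_frac(mid) > cfg$censor_rate) lo <- mid else hi <- mid
    }
    cmax <- sqrt(lo * hi)
    t_cens <- stats::runif(n, 0, cmax)
    pfs_time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  pfs_time <- pmax(pfs_time, 1e-6)

  trait_from_latent <- function(m) {
    if (!is.null(module_latent) && nrow(module_latent) >= m) {
      g <- module_latent[m, match(tumor, st$sample_id)]
      as.integer(g + stats::rnorm(n, 0, 0.5) > 0)
    } else stats::rbinom(n, 1L, 0.5)
  }
  data.frame(subject_id = subjects, pfs_time = pfs_time, event = event,
             recurrence = trait_from_latent(1L),
             metastasis = trait_from_latent(2L),
             stringsAsFactors = FALSE)
}

#' Simulate a qPCR cycle-threshold table with a planted ddCt shift
#'
#' Per subject and group (tumor/normal), draws Ct values for a target gene
#' and a reference gene with Gaussian technical noise and a shared
#' per-(subject, group) plate offset; the target's tumor Ct carries the
#' planted ddCt shift, so the expected fold change is `2^-ddct`.
#'
#' @param config A [simulation_config()].
#' @param target_id,reference_id Gene labels used in the table.
#' @return A list with `ct_table` (columns `subject_id`, `group`,
#'   `gene_id`, `ct`, `is_reference`) and `truth` (the planted ddCt).
#' @export
simulate_ct_table <- function(config, target_id = "TARGET1",
                              reference_id = "REF1") {
  cfg <- config
  set.seed(child_seed(cfg$seed, "qpcr"))
  n <- cfg$qpcr_n_subjects
  subjects <- sprintf("Q%03d", seq_len(n))
  grid <- expand.grid(subject_id = subjects, group = c("tumor", "normal"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  plate <- stats::rnorm(nrow(grid), 0, 0.5)
  noise <- function() stats::rnorm(nrow(grid), 0, cfg$qpcr_ct_noise_sd)
  ct_ref <- 15 + plate + noise()
  shift <- ifelse(grid$group == "tumor", cfg$qpcr_ddct, 0)
  ct_tgt <- 20 + shift + plate + noise()
  ct_table <- rbind(
    data.frame(grid, gene_id = reference_id, ct = ct_ref,
               is_reference = TRUE, stringsAsFactors = FALSE),
    data.frame(grid, gene_id = target_id, ct = ct_tgt,
               is_reference = FALSE, stringsAsFactors = FALSE))
  rownames(ct_table) <- NULL
  list(ct_table = ct_table, truth = list(ddct = cfg$qpcr_ddct,
                                         target_id = target_id))
}

#' Simulate a Gaussian expression matrix with planted co-expression modules
#'
#' Each module gene is `sqrt(rho) * f_m + sqrt(1-rho) * e` for a shared
#' per-module latent factor `f_m`, giving within-module correlation `rho`
#' and zero expected between-module correlation. Optional unstructured
#' noise genes can be appended.
#'
#' @param n_modules Number of modules.
#' @param module_size Genes per module.
#' @param n_samples Number of samples (rows).
#' @param within_cor Within-module correlation `rho`.
#' @param n_noise Additional independent noise genes.
#' @param seed Random seed.
#' @return A list with `expr` (samples x genes matrix) and `labels`
#'   (named integer vector; 0 marks noise genes).
#' @export
simulate_module_matrix <- function(n_modules = 3L, module_size = 50L,
                                   n_samples = 50L, within_cor = 0.7,
                                   n_noise = 0L, seed = 1L) {
  stopifnot(within_cor >= 0, within_cor < 1)
  set.seed(child_seed(seed, "modules"))
  n_genes <- n_modules * module_size + n_noise
  f <- matrix(stats::rnorm(n_samples * n_modules), n_samples, n_modules)
  expr <- matrix(stats::rnorm(n_samples * n_genes), n_samples, n_genes)
  labels <- integer(n_genes)
  for (m in seq_len(n_modules)) {
    idx <- (m - 1L) * module_size + seq_len(module_size)
    expr[, idx] <- sqrt(within_cor) * f[, m] +
      sqrt(1 - within_cor) * expr[, idx]
    labels[idx] <- m
  }
  colnames(expr) <- sprintf("g%04d", seq_len(n_genes))
  names(labels) <- colnames(expr)
  list(expr = expr, labels = labels)
}
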