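#' Analysis thresholds for the full ceRNA pipeline
#'
#' Defaults encode the study-standard cut-offs of every stage:
#' differential expression at |log2FC| >= 1 and P <= 0.05, interaction
#' filtering at score >= 150 and energy <= -20, triplet calling at
#' Pearson r > 0.5 with both p-values < 0.05, co-expression modules with
#' automatic soft-power selection at scale-free R^2 = 0.85, minimum
#' module size 30, eigengene merge height 0.25, and hub selection at
#' MM > 0.8, GS > 0.4.
#'
#' @param lfc_cut,p_cut,use_adjusted DE gate (see [filter_de()]).
#' @param min_score,max_energy Interaction filter.
#' @param r_cut,cor_p_cut,hyper_p_cut Triplet acceptance.
#' @param power Soft-thresholding power; 0 means scan automatically.
#' @param powers Candidate powers for the scan.
#' @param rsq_target Scale-free fit target for the scan.
#' @param min_module_size,merge_height,mm_cut,gs_cut Module detection and
#'   hub selection.
#' @return A list of class `pipeline_params`.
#' @export
pipeline_params <- function(lfc_cut = 1, p_cut = 0.05, use_adjusted = FALSE,
                            min_score = 150, max_energy = -20,
                            r_cut = 0.5, cor_p_cut = 0.05,
                            hyper_p_cut = 0.05,
                            power = 0, powers = c(1:10, 12, 14, 16, 18, 20),
                            rsq_target = 0.85,
                            min_module_size = 30, merge_height = 0.25,
                            mm_cut = 0.8, gs_cut = 0.4) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full ceRNA discovery pipeline on a synthetic dataset
#'
#' Executes, in dependency order: data simulation, per-class differential
#' expression, interaction filtering, bipartite map construction, ceRNA
#' triplet calling, co-expression module detection with trait
#' correlation and hub selection, median-split survival analysis of the
#' prognostic lncRNA, and qPCR relative quantification. Every output is
#' written as TSV/JSON under `outdir` and a reproducibility manifest
#' (stage list, parameters, config hash, output MD5 checksums, wall
#' times) is recorded; rerunning with the same configuration reproduces
#' identical checksums.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @param params A [pipeline_params()].
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "de", "filter_targets", "cerna", "wgcna",
#'   "survival", "qpcr")`. Later stages require the earlier ones.
#' @param survival_feature Feature id for the survival stage; defaults to
#'   the dataset's planted prognostic lncRNA.
#' @return Invisibly, a list with the in-memory results of every stage
#'   and the manifest.
#' @export
run_pipeline <- function(config = simulation_config(), outdir,
                         params = pipeline_params(),
                         stages = c("simulate", "de", "filter_targets",
                                    "cerna", "wgcna", "survival", "qpcr"),
                         survival_feature = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), stages = list())
  results <- list()
  written <- character(0)
  out <- function(name) file.path(outdir, name)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(
      wall_time = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = setdiff(list.files(outdir), written))
    written <<- list.files(outdir)
    res
  }

  if (!"simulate" %in% stages)
    stop("the synthetic pipeline requires the 'simulate' stage")
  ds <- run_stage("simulate", function() {
    d <- simulate_multiomics(config)
    for (cl in names(d$counts))
      write_count_matrix(d$counts[[cl]], out(paste0("counts_", cl, ".tsv")))
    write_tsv(d$sample_table, out("sample_table.tsv"))
    write_tsv(d$clinical, out("clinical.tsv"))
    write_tsv(d$interactions, out("interactions.tsv"))
    jsonlite::write_json(list(
      de_features = d$truth$de_features,
      true_triplets = d$truth$true_triplets,
      true_interactions = d$truth$true_interactions,
      module_membership = as.list(d$truth$module_membership),
      prognostic_lnc = d$truth$prognostic_lnc),
      out("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    d
  })
  results$dataset <- ds
  cond <- ds$sample_table$condition
  tumor_samples <- ds$sample_table$sample_id[cond == "tumor"]

  de_sets <- NULL
  if ("de" %in% stages) {
    results$de <- run_stage("de", function() {
      lapply(stats::setNames(nm = names(ds$counts)), function(cl) {
        res <- nb_wald_test(ds$counts[[cl]], cond,
                            lfc_cut = params$lfc_cut, p_cut = params$p_cut)
        write_tsv(res, out(paste0("de_", cl, ".tsv")))
        res
      })
    })
    de_sets <- lapply(results$de, filter_de, lfc_cut = params$lfc_cut,
                      p_cut = params$p_cut,
                      use_adjusted = params$use_adjusted)
  }

  targeting <- NULL
  if ("filter_targets" %in% stages) {
    if (is.null(de_sets)) stop("stage 'filter_targets' requires 'de'")
    results$filtered <- run_stage("filter_targets", function() {
      f <- filter_interactions(ds$interactions, params$min_score,
                               params$max_energy)
      write_tsv(f, out("interactions_filtered.tsv"))
      f
    })
    targeting <- build_bipartite(
      results$filtered,
      de_mirna = unlist(de_sets$mirna, use.names = FALSE),
      de_lnc = unlist(de_sets$lncrna, use.names = FALSE),
      de_mrna = unlist(de_sets$mrna, use.names = FALSE))
  }

  if ("cerna" %in% stages) {
    if (is.null(targeting)) stop("stage 'cerna' requires 'filter_targets'")
    results$cerna <- run_stage("cerna", function() {
      net <- build_cerna_network(
        targeting,
        expr_lnc = cpm_normalize(ds$counts$lncrna),
        expr_mrna = cpm_normalize(ds$counts$mrna),
        samples = tumor_samples, r_cut = params$r_cut,
        p_cut = params$cor_p_cut, hyper_p_cut = params$hyper_p_cut)
      write_tsv(net$pairs, out("cerna_pairs.tsv"))
      write_tsv(net$triplets, out("cerna_triplets.tsv"))
      export_network(net, out("cerna"))
      net
    })
  }

  if ("wgcna" %in% stages) {
    results$wgcna <- run_stage("wgcna", function() {
      expr <- t(log2(cpm_normalize(ds$counts$lncrna)[, tumor_samples] + 1))
      expr <- expr[, apply(expr, 2, stats::sd) > 0, drop = FALSE]
      power <- params$power
      scan <- NULL
      if (power == 0) {
        scan <- pick_soft_threshold(expr, params$powers,
                                    rsq_target = params$rsq_target)
        write_tsv(scan$table, out("wgcna_soft_threshold.tsv"))
        power <- scan$power
      }
      tom <- tom_similarity(adjacency_matrix(expr, power))
      assign <- cluster_modules(1 - tom, expr,
                                min_size = params$min_module_size)
      merged <- if (any(assign$labels > 0L))
        merge_close_modules(expr, assign$labels, params$merge_height) else
        list(labels = assign$labels, eigengenes = NULL)
      write_tsv(data.frame(gene = names(merged$labels),
                           module = unname(merged$labels)),
                out("wgcna_modules.tsv"))
      mtc <- hubs <- NULL
      if (!is.null(merged$eigengenes)) {
        me <- merged$eigengenes
        write_tsv(data.frame(sample_id = rownames(me$eigengenes),
                             me$eigengenes, check.names = FALSE),
                  out("wgcna_eigengenes.tsv"))
        traits <- ds$clinical[match(ds$sample_table$subject_id[
          match(tumor_samples, ds$sample_table$sample_id)],
          ds$clinical$subject_id), c("recurrence", "metastasis")]
        mtc <- module_trait_correlation(me, traits)
        write_tsv(data.frame(module = rownames(mtc$cor), cor = mtc$cor,
                             p = mtc$p, check.names = FALSE),
                  out("wgcna_module_trait.tsv"))
        best <- which(abs(mtc$cor) == max(abs(mtc$cor), na.rm = TRUE),
                      arr.ind = TRUE)[1, ]
        mod <- as.integer(sub("^ME", "", rownames(mtc$cor)[best[1]]))
        hubs <- hub_genes(expr, me, merged$labels,
                          traits[[best[2]]], mod,
                          mm_cut = params$mm_cut, gs_cut = params$gs_cut)
        write_tsv(hubs, out("wgcna_hub_genes.tsv"))
      }
      list(scan = scan, power = power, assignment = merged$labels,
           eigengenes = merged$eigengenes, module_trait = mtc, hubs = hubs)
    })
  }

  if ("survival" %in% stages) {
    results$survival <- run_stage("survival", function() {
      feature <- if (is.null(survival_feature))
        ds$truth$prognostic_lnc else survival_feature
      expr <- log2(cpm_normalize(ds$counts$lncrna)[feature, tumor_samples]
                   + 1)
      subj <- ds$sample_table$subject_id[match(tumor_samples,
                                               ds$sample_table$sample_id)]
      cl <- ds$clinical[match(subj, ds$clinical$subject_id), ]
      fit <- evaluate_prognostic(cl$pfs_time, cl$event, expr)
      write_tsv(fit$km, out("survival_km.tsv"))
      jsonlite::write_json(list(
        feature = feature, hr = fit$cox$hr, beta = fit$cox$beta,
        ci_low = fit$cox$ci_low, ci_high = fit$cox$ci_high,
        wald_p = fit$cox$wald_p, logrank_chi2 = fit$logrank$chi2,
        logrank_p = fit$logrank$p,
        reference_group = "low expression"),
        out("survival_summary.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
      fit
    })
  }

  if ("qpcr" %in% stages) {
    results$qpcr <- run_stage("qpcr", function() {
      sim <- simulate_ct_table(config)
      write_tsv(sim$ct_table, out("qpcr_ct.tsv"))
      fc <- ddct_fold_change(sim$ct_table, target = "TARGET1",
                             reference = "REF1")
      write_tsv(fc$per_subject, out("qpcr_fold_changes.tsv"))
      jsonlite::write_json(list(mean_fold = fc$mean_fold,
                                p_value = fc$p_value, n = fc$n,
                                test = fc$test),
                           out("qpcr_summary.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      fc
    })
  }

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest$parameters <- unclass(params)
  manifest$seed <- config$seed
  manifest$checksums <- as.list(tools::md5sum(file.path(outdir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a pipeline configuration from YAML
#'
#' The file may contain a `simulation:` block (arguments of
#' [simulation_config()]) and a `params:` block (arguments of
#' [pipeline_params()]); omitted entries keep their defaults.
#'
#' @param path YAML file path.
#' @return A list with `config` and `params`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  config <- do.call(simulation_config,
                    if (is.null(y$simulation)) list() else y$simulation)
  params <- do.call(pipeline_params,
                    if (is.null(y$params)) list() else y$params)
  list(config = config, params = params)
}
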