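#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]. Input
#' paths point at files in the dialects of the io readers; analysis
#' defaults are the study constants: alpha 0.05, cross-hybridization
#' threshold 40 with 3000 permutations, enrichment subsampling probability
#' 0.2, and a 1 Mb cis window for expression.
#'
#' @param beta_paths Character vector of per-cohort beta matrices; the
#'   first is the discovery cohort, the rest are replication cohorts.
#' @param covariate_paths Per-cohort covariate tables, same order.
#' @param annotation_path Probe annotation manifest.
#' @param out_dir Output directory.
#' @param allosome_path Optional FASTA of allosome reference sequences
#'   (enables the cross-hybridization screen).
#' @param blocklist_path Optional one-column file of known cross-reactive
#'   probe ids.
#' @param geneset_path Optional GMT of gene sets; a set named `imprinted`
#'   feeds the imprinted-gene analyses, every set is tested with the
#'   probe-count-weighted test, and sets other than `imprinted` also get
#'   the plain hypergeometric test.
#' @param expression_path,expression_genes_path Optional expression matrix
#'   (genes x samples, first column gene id) and gene coordinate table for
#'   the discovery cohort.
#' @param alpha Family-wise error rate.
#' @param crosshyb_threshold Exclusion threshold on h.
#' @param n_perm Permutations for the cross-hybridization association test.
#' @param subsample_prob Bernoulli thinning probability for the CGI
#'   enrichment.
#' @param expression_window Cis window in bp.
#' @param sig_rule Significance rule for expression pairs
#'   (see [significant_pairs()]).
#' @param seed Integer seed for the stochastic stages.
#' @return Config list of class `sma_pipeline_config`.
#' @export
pipeline_config <- function(beta_paths, covariate_paths, annotation_path,
                            out_dir,
                            allosome_path = NULL, blocklist_path = NULL,
                            geneset_path = NULL, expression_path = NULL,
                            expression_genes_path = NULL,
                            alpha = 0.05, crosshyb_threshold = 40,
                            n_perm = 3000, subsample_prob = 0.2,
                            expression_window = 1e6,
                            sig_rule = "both", seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$beta_paths) != length(cfg$covariate_paths))
    stop("need one covariate table per beta matrix")
  if (length(cfg$beta_paths) < 1) stop("need at least a discovery cohort")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must be in (0,1)")
  for (p in c(cfg$beta_paths, cfg$covariate_paths, cfg$annotation_path,
              cfg$allosome_path, cfg$blocklist_path, cfg$geneset_path,
              cfg$expression_path, cfg$expression_genes_path))
    if (!is.null(p) && !file.exists(p)) stop("input file does not exist: ", p)
  structure(cfg, class = "sma_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipeline_config()].
#' @return Config list of class `sma_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full sex-methylation association pipeline
#'
#' Orchestrates probe QC (blocklist, allosomal cross-hybridization screen),
#' the discovery association analysis, replication with Fisher-z
#' DerSimonian-Laird meta-analysis, sign-consistency and cross-study
#' correlation checks, CGI-context / imprinted-gene / weighted and plain
#' gene-set enrichment, and the cis expression linkage. Stage outputs are
#' written as TSV into `out_dir` together with a JSON run manifest that
#' records seeds, thresholds and the probe accounting at every filter
#' (probes in, removed by blocklist, removed by cross-hybridization,
#' analyzed).
#'
#' @param config A [pipeline_config()], a YAML path, or a plain list of
#'   [pipeline_config()] arguments.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "sma_pipeline_config"))
    config <- do.call(pipeline_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("smapipe")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, alpha = config$alpha)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## ---- inputs -----------------------------------------------------------
  annotation <- stage("read_annotation", read_probe_annotation(config$annotation_path))
  betas <- stage("read_beta", lapply(config$beta_paths, read_beta_matrix))
  covs <- stage("read_covariates", lapply(config$covariate_paths, read_covariate_table))
  n_cohorts <- length(betas)
  probes_in <- rownames(betas[[1]])
  manifest$counts <- list(probes_in = length(probes_in))

  ## ---- probe QC ---------------------------------------------------------
  kept <- probes_in
  if (!is.null(config$blocklist_path)) {
    kept <- stage("blocklist", apply_blocklist(kept, config$blocklist_path))
    manifest$counts$removed_blocklist <- attr(kept, "n_removed")
  } else manifest$counts$removed_blocklist <- 0L
  xhyb <- NULL
  if (!is.null(config$allosome_path)) {
    allosomes <- stage("read_allosomes", read_fasta(config$allosome_path))
    ann_kept <- annotation[annotation$probe_id %in% kept, , drop = FALSE]
    xhyb <- stage("crosshyb_score", crosshyb_table(ann_kept, allosomes))
    write_results_table(xhyb, file.path(config$out_dir, "crosshyb.tsv"))
  }

  ## ---- discovery SMA (pre-filter, for the accounting) -------------------
  disc <- stage("sma_discovery",
                sma_cohort(betas[[1]][kept, , drop = FALSE], covs[[1]]))
  m_disc_pre <- sum(!disc$degenerate)
  thr_pre <- bonferroni_threshold(config$alpha, m_disc_pre)
  sig_pre <- disc$probe_id[!disc$degenerate & disc$p < thr_pre]

  if (!is.null(xhyb)) {
    fx <- stage("crosshyb_filter",
                filter_crosshyb(xhyb, threshold = config$crosshyb_threshold,
                                significant_ids = sig_pre))
    manifest$counts$removed_crosshyb <- fx$summary$n_removed
    manifest$crosshyb <- fx$summary
    kept <- setdiff(kept, fx$removed)
    disc <- disc[disc$probe_id %in% kept, , drop = FALSE]
    perm <- stage("crosshyb_permutation", {
      xs <- xhyb[match(disc$probe_id, xhyb$probe_id), ]
      ok <- !is.na(disc$r) & !is.na(xs$h)
      permutation_association_test(disc$r[ok], xs$h[ok],
                                   n_perm = config$n_perm, seed = config$seed)
    })
    manifest$crosshyb$post_filter_permutation_p <- perm$p
  } else manifest$counts$removed_crosshyb <- 0L
  manifest$counts$analyzed <- length(kept)
  stopifnot(manifest$counts$probes_in ==
              manifest$counts$analyzed + manifest$counts$removed_blocklist +
              manifest$counts$removed_crosshyb)

  ## ---- discovery significance over the analyzed probes ------------------
  m_disc <- sum(!disc$degenerate)
  thr_disc <- bonferroni_threshold(config$alpha, m_disc)
  disc$significant <- !disc$degenerate & disc$p < thr_disc
  manifest$discovery <- list(m = m_disc, threshold = thr_disc,
                             n_significant = sum(disc$significant))
  write_results_table(disc, file.path(config$out_dir, "sma_discovery.tsv"))
  write_results_table(manhattan_table(disc, annotation),
                      file.path(config$out_dir, "manhattan.tsv"))
  disc_sig <- disc$probe_id[disc$significant]

  ## ---- replication and meta-analysis ------------------------------------
  meta <- NULL
  if (n_cohorts >= 2 && length(disc_sig) >= 2) {
    rep_tabs <- stage("sma_replication", lapply(2:n_cohorts, function(i)
      sma_cohort(betas[[i]][intersect(disc_sig, rownames(betas[[i]])), ,
                            drop = FALSE], covs[[i]])))
    names(rep_tabs) <- paste0("replication", seq_along(rep_tabs))
    meta <- stage("meta_analysis", meta_analyze(rep_tabs))
    meta <- replicate_probes(meta, alpha = config$alpha)
    manifest$replication <- list(
      m = nrow(meta), threshold = attr(meta, "threshold"),
      n_excluded = attr(meta, "n_excluded"),
      n_replicated = sum(meta$replicated))
    dd <- disc$direction[match(meta$probe_id, disc$probe_id)]
    sc <- stage("sign_consistency",
                sign_consistency_test(dd, sign(meta$theta)))
    manifest$replication$sign_consistency <- sc
    manifest$replication$cross_study_r <- vapply(rep_tabs, function(tb)
      cross_study_correlation(disc, tb, probe_subset = disc_sig), numeric(1))
    write_results_table(meta, file.path(config$out_dir, "meta.tsv"))
  }
  replicated <- if (!is.null(meta)) meta$probe_id[meta$replicated] else disc_sig

  ## ---- enrichment -------------------------------------------------------
  sub <- subsample_sites(kept, prob = config$subsample_prob,
                         seed = config$seed)
  ann_sub <- annotation[match(sub, annotation$probe_id), , drop = FALSE]
  cgi <- stage("cgi_enrichment",
               cgi_enrichment(ann_sub$cgi_relation, sub %in% replicated))
  cgi_noshore <- stage("cgi_enrichment_no_shore",
                       cgi_enrichment(ann_sub$cgi_relation, sub %in% replicated,
                                      exclude = "shore"))
  manifest$enrichment <- list(
    n_subsampled = length(sub),
    n_subsampled_significant = sum(sub %in% replicated),
    shore = cgi[c("chi2", "df", "p", "framing")],
    no_shore = cgi_noshore[c("chi2", "df", "p", "framing")])

  gene_tab <- stage("best_cpg_per_gene", best_cpg_per_gene(disc, annotation))
  write_results_table(gene_tab, file.path(config$out_dir, "gene_level.tsv"))
  gene_sig <- gene_tab$gene[gene_tab$best_p < thr_disc]
  rep_genes <- unique(unlist(split_gene_names(
    annotation$gene_names[annotation$probe_id %in% replicated])))

  if (!is.null(config$geneset_path)) {
    sets <- stage("read_gene_sets", read_gmt(config$geneset_path))
    if ("imprinted" %in% names(sets)) {
      imp <- gene_tab$gene %in% sets$imprinted
      if (length(unique(imp)) == 2) {
        manifest$enrichment$imprinted_spearman <-
          imprinted_spearman(gene_tab$best_p, imp)
        manifest$enrichment$imprinted_hypergeom <- geneset_enrichment(
          sets$imprinted, gene_sig, universe = gene_tab$gene)
      }
    }
    pwf_ok <- length(rep_genes) > 0 && length(rep_genes) < nrow(gene_tab)
    if (pwf_ok) {
      pwf <- stage("fit_pwf", fit_pwf(gene_tab$gene %in% rep_genes,
                                      gene_tab$n_probes_of_gene,
                                      genes = gene_tab$gene))
      wres <- lapply(sets, function(s)
        weighted_category_test(s, rep_genes, pwf))
      manifest$enrichment$weighted_genesets <- lapply(wres, `[`,
        c("k", "n_category", "odds", "p"))
    }
    plain <- setdiff(names(sets), "imprinted")
    if (length(plain) > 0)
      manifest$enrichment$plain_genesets <- lapply(sets[plain], function(s)
        geneset_enrichment(s, rep_genes, universe = gene_tab$gene))
  }

  ## ---- expression linkage ------------------------------------------------
  if (!is.null(config$expression_path) && length(replicated) > 0) {
    exprs <- stage("read_expression", {
      df <- utils::read.table(config$expression_path, header = TRUE, sep = "\t",
                              check.names = FALSE)
      m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]; m
    })
    gcoords <- stage("read_expression_genes",
                     utils::read.table(config$expression_genes_path,
                                       header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
    cpg_pos <- annotation[annotation$probe_id %in% replicated,
                          c("probe_id", "chromosome", "position")]
    gcoords$chromosome <- as.character(gcoords$chromosome)
    pairs <- stage("pair_cpg_genes",
                   pair_cpg_genes(cpg_pos, gcoords,
                                  window = config$expression_window))
    recs <- stage("expression_models",
                  expression_link_models(pairs, exprs, betas[[1]], covs[[1]]))
    sig <- significant_pairs(recs, alpha = config$alpha, n_pairs = nrow(recs),
                             rule = config$sig_rule)
    manifest$expression <- list(n_pairs = nrow(recs),
                                threshold = attr(sig, "threshold"),
                                n_significant = nrow(sig),
                                rule = config$sig_rule)
    write_results_table(recs, file.path(config$out_dir, "expression_pairs.tsv"))
    write_results_table(sig, file.path(config$out_dir, "expression_significant.tsv"))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a dataset and run the pipeline on it (smoke test)
#'
#' Generates a synthetic multi-cohort dataset, writes it to disk, runs
#' [run_pipeline()] on the files and returns the manifest together with
#' the simulation truth for recovery scoring.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @param sim_config Optional [simulation_config()] (its seed is overridden
#'   by `seed`).
#' @param with_expression Also simulate and analyze expression.
#' @return List with `manifest`, `truth`, `dir`.
#' @export
simulate_and_run <- function(seed, out_dir,
                             sim_config = simulation_config(),
                             with_expression = TRUE) {
  sim_config$seed <- seed
  sim <- generate_cohorts(sim_config)
  expr <- if (with_expression) generate_expression(sim) else NULL
  data_dir <- file.path(out_dir, "data")
  simulate_to_dir(sim, data_dir, expression = expr)
  k <- length(sim$cohorts)
  cfg <- pipeline_config(
    beta_paths = file.path(data_dir, sprintf("beta_cohort%d.tsv", seq_len(k))),
    covariate_paths = file.path(data_dir, sprintf("covariates_cohort%d.tsv", seq_len(k))),
    annotation_path = file.path(data_dir, "annotation.csv"),
    allosome_path = file.path(data_dir, "allosomes.fa"),
    geneset_path = file.path(data_dir, "genesets.gmt"),
    expression_path = if (with_expression) file.path(data_dir, "expression.tsv"),
    expression_genes_path = if (with_expression) file.path(data_dir, "expression_genes.tsv"),
    out_dir = file.path(out_dir, "results"),
    seed = seed)
  manifest <- run_pipeline(cfg)
  list(manifest = manifest, truth = sim$truth, dir = out_dir)
}
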