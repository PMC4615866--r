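#' Simulation configuration for multi-cohort synthetic datasets
#'
#' Builds and validates the configuration of the synthetic-data generator.
#' Defaults emulate the structure of a blood-based 450k sex-methylation
#' study: three cohorts of 300 adults, 20,000 autosomal CpGs of which 5%
#' carry a sex effect with target correlation |r| drawn uniformly from
#' 0.2-0.5, CGI-region shares of island 0.332 / shore 0.240 / shelf 0.091 /
#' open sea 0.336 (renormalized to sum to 1), a 3-fold excess of planted
#' effects in shores and in imprinted genes, 100 cross-hybridizing probes
#' whose signal mixes in an allosomal, sex-dependent component with weight
#' lambda = 0.7 and whose sequences are copied from the decoy allosomes
#' with 5 mismatches, and cis-linked expression with negative sex and
#' methylation effects.
#'
#' @param n_probes Number of autosomal CpG probes.
#' @param n_samples Samples per cohort (scalar or vector of `n_cohorts`).
#' @param n_cohorts Number of cohorts (first = discovery).
#' @param fraction_sex_associated Fraction of probes with a true sex effect.
#' @param effect_size_r Range (length 2) of target |Pearson r| for planted
#'   effects.
#' @param noise_sd Residual sd on the logit scale.
#' @param covariate_effect_sd Per-probe sd of covariate coefficients
#'   (logit scale).
#' @param block_size Number of adjacent probes per correlation block.
#' @param block_rho Within-block correlation of the logit noise.
#' @param cgi_proportions Named length-4 vector of region probabilities
#'   (island, shore, shelf, open_sea); renormalized to sum to 1.
#' @param shore_enrichment_multiplier Relative odds of planting an effect at
#'   a shore probe.
#' @param n_genes Number of annotated genes.
#' @param imprinted_gene_count Number of genes flagged imprinted.
#' @param imprinted_enrichment_multiplier Relative odds of planting an
#'   effect at a probe of an imprinted gene.
#' @param n_crosshyb_probes Number of allosome-contaminated probes.
#' @param contamination_lambda Mixture weight of the allosomal component,
#'   in \[0,1\].
#' @param crosshyb_mismatches Substitutions introduced when copying
#'   contaminated probe sequences from the allosomes.
#' @param allosome_length Length (bp) of each decoy allosome sequence.
#' @param allosome_sex_shift Logit shift between sexes of the allosomal
#'   methylation component.
#' @param cohort_effect_jitter_sd Sd of the per-cohort multiplicative
#'   jitter on effect sizes (gives the meta-analysis a nonzero tau^2
#'   regime).
#' @param expression List: `n_genes`, `n_linked`, `cis_window`, `b1` (sex
#'   effect), `b2` (methylation effect), `noise_sd`.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Validated config list of class `sma_sim_config`.
#' @export
simulation_config <- function(n_probes = 20000,
                              n_samples = 300,
                              n_cohorts = 3,
                              fraction_sex_associated = 0.05,
                              effect_size_r = c(0.2, 0.5),
                              noise_sd = 0.5,
                              covariate_effect_sd = 0.05,
                              block_size = 10,
                              block_rho = 0.3,
                              cgi_proportions = c(island = 0.332, shore = 0.240,
                                                  shelf = 0.091, open_sea = 0.336),
                              shore_enrichment_multiplier = 3,
                              n_genes = 2000,
                              imprinted_gene_count = 50,
                              imprinted_enrichment_multiplier = 3,
                              n_crosshyb_probes = 100,
                              contamination_lambda = 0.7,
                              crosshyb_mismatches = 5,
                              allosome_length = 2000,
                              allosome_sex_shift = 3,
                              cohort_effect_jitter_sd = 0.15,
                              expression = list(n_genes = 500, n_linked = 50,
                                                cis_window = 1e6, b1 = -0.5,
                                                b2 = -0.8, noise_sd = 0.5),
                              seed = 1) {
  cfg <- as.list(environment())
  if (length(cfg$n_samples) == 1)
    cfg$n_samples <- rep(cfg$n_samples, cfg$n_cohorts)
  if (length(cfg$n_samples) != cfg$n_cohorts)
    stop("n_samples must have length 1 or n_cohorts")
  if (length(cfg$effect_size_r) == 1)
    cfg$effect_size_r <- rep(cfg$effect_size_r, 2)
  stopifnot(cfg$n_probes >= 1, all(cfg$n_samples >= 8), cfg$n_cohorts >= 1)
  if (cfg$fraction_sex_associated < 0 || cfg$fraction_sex_associated > 1)
    stop("fraction_sex_associated must be in [0,1]")
  if (cfg$contamination_lambda < 0 || cfg$contamination_lambda > 1)
    stop("contamination_lambda must be in [0,1]")
  if (any(cfg$effect_size_r < 0) || any(cfg$effect_size_r >= 1))
    stop("effect_size_r must be in [0,1)")
  if (!setequal(names(cfg$cgi_proportions),
                c("island", "shore", "shelf", "open_sea")))
    stop("cgi_proportions must name island, shore, shelf, open_sea")
  if (any(cfg$cgi_proportions < 0)) stop("cgi_proportions must be >= 0")
  cfg$cgi_proportions <- cfg$cgi_proportions / sum(cfg$cgi_proportions)
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) stop("block_rho must be in [0,1)")
  structure(cfg, class = "sma_sim_config")
}

# target Pearson r (of sex with residualized beta) -> logit-scale sex shift,
# via the delta method: on the logit scale r = d*s / sqrt(d^2 s^2 + sigma^2)
# with s = sd(sex) = 0.5 for balanced sexes, so d = r/sqrt(1-r^2) * sigma/s.
# The inverse-logit is locally linear, so r carries over to the beta scale
# up to a small curvature attenuation (documented in the methods vignette).
.r_to_logit_shift <- function(r, sigma, s = 0.5) {
  sign(r) * abs(r) / sqrt(1 - r^2) * sigma / s
}

.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

.mutate_seq <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  pos <- sample(length(x), k)
  for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
  paste(x, collapse = "")
}

# covariate table emulating an adult population cohort (Table-1-like ranges)
.simulate_covariates <- function(n, cohort, plate_size = 96) {
  cell <- matrix(stats::rgamma(n * 5, shape = c(8, 4, 2, 1.5, 1)), nrow = n,
                 byrow = TRUE)
  cell <- cell / rowSums(cell)
  # reference-based deconvolution estimates carry per-type noise and do not
  # sum exactly to one; without it the proportions would be collinear with
  # the intercept
  cell <- pmin(cell * matrix(exp(stats::rnorm(n * 5, 0, 0.05)), n, 5), 1)
  data.frame(
    sample_id = sprintf("C%d_S%03d", cohort, seq_len(n)),
    sex = sample(rep(0:1, length.out = n)),
    age = round(stats::rnorm(n, 60, 9), 1),
    bmi = round(stats::rnorm(n, 28.2, 4.8), 1),
    smoking = stats::rbinom(n, 1, 0.15),
    alcohol = round(stats::rexp(n, 1 / 15.5), 1),
    triglycerides = round(stats::rlnorm(n, log(1.4), 0.5), 2),
    cholesterol = round(stats::rnorm(n, 5.7, 1.0), 2),
    hdl = round(stats::rnorm(n, 1.46, 0.38), 2),
    ldl = round(stats::rnorm(n, 3.6, 0.9), 2),
    leukocytes = round(stats::rnorm(n, 6, 1.5), 2),
    cd4t = cell[, 2], cd8t = cell[, 3], bcell = cell[, 4], mono = cell[, 5],
    gran = cell[, 1],
    physical_activity = factor(sample(c("no", "low", "medium", "high"), n,
                                      replace = TRUE,
                                      prob = c(0.3, 0.2, 0.3, 0.2))),
    diabetes = stats::rbinom(n, 1, 0.09),
    mi = stats::rbinom(n, 1, 0.035),
    plate = factor(paste0("plate", ceiling(seq_len(n) / plate_size))),
    stringsAsFactors = FALSE)
}

#' Generate multi-cohort synthetic methylation data with ground truth
#'
#' Produces, for each cohort, a beta-value matrix and covariate table, plus
#' a shared probe annotation, decoy allosome sequences and a truth table.
#' Betas are the inverse logit of (probe baseline + covariate effects +
#' sex effect x sex + block-correlated Gaussian noise), hence strictly in
#' (0,1). Cross-hybridizing probes mix in an allosomal component that
#' differs between sexes with weight lambda, and their probe sequences are
#' copied (with mismatches) from the decoy allosomes so the
#' cross-hybridization screen can find them.
#'
#' @param config A [simulation_config()].
#' @return List with `cohorts` (each `beta`, `covariates`), `annotation`,
#'   `truth`, `allosomes`, `config`.
#' @export
generate_cohorts <- function(config) {
  if (!inherits(config, "sma_sim_config")) config <- do.call(simulation_config, config)
  set.seed(config$seed)
  P <- config$n_probes

  ## -- annotation ---------------------------------------------------------
  chr <- sort(sample(1:22, P, replace = TRUE,
                     prob = 23 - (1:22)))          # larger chromosomes get more probes
  pos <- unlist(lapply(split(seq_len(P), chr), function(ix)
    cumsum(sample(500:5000, length(ix), replace = TRUE))), use.names = FALSE)
  probe_id <- sprintf("cg%08d", seq_len(P))
  region4 <- sample(names(config$cgi_proportions), P, replace = TRUE,
                    prob = config$cgi_proportions)
  side <- sample(c("north", "south"), P, replace = TRUE)
  cgi <- ifelse(region4 %in% c("shore", "shelf"),
                paste(region4, side, sep = "_"), region4)

  ## genes as contiguous probe segments per chromosome (probe-count bias by
  ## construction: segment lengths vary); ~25% of segments are intergenic
  gene_sizes <- pmax(1, stats::rpois(ceiling(P / 4), lambda = 4))
  seg <- rep(seq_along(gene_sizes), gene_sizes)[seq_len(P)]
  seg[is.na(seg)] <- max(seg, na.rm = TRUE)
  n_seg <- length(unique(seg))
  seg_gene <- ifelse(stats::runif(n_seg) < 0.75,
                     sprintf("GENE%05d", seq_len(n_seg)), "")
  gene <- seg_gene[seg]

  annotation <- data.frame(probe_id = probe_id, chromosome = as.character(chr),
                           position = pos, gene_names = gene,
                           cgi_relation = factor(cgi, levels = .cgi_levels),
                           probe_sequence = NA_character_,
                           stringsAsFactors = FALSE)

  ## -- imprinted genes and planted sex effects ----------------------------
  all_genes <- unique(gene[gene != ""])
  imprinted <- sample(all_genes, min(config$imprinted_gene_count, length(all_genes)))
  is_imprinted <- gene %in% imprinted
  is_shore <- region4 == "shore"
  w <- ifelse(is_shore, config$shore_enrichment_multiplier, 1) *
    ifelse(is_imprinted, config$imprinted_enrichment_multiplier, 1)
  n_assoc <- round(config$fraction_sex_associated * P)
  assoc_idx <- if (n_assoc > 0) sample(P, n_assoc, prob = w) else integer(0)
  target_r <- numeric(P)
  if (n_assoc > 0)
    target_r[assoc_idx] <- sample(c(-1, 1), n_assoc, replace = TRUE) *
      stats::runif(n_assoc, config$effect_size_r[1], config$effect_size_r[2])

  ## per-probe baselines: bimodal (hypo- and hyper-methylated modes plus an
  ## intermediate fraction), typical of array beta distributions
  mode <- sample(1:3, P, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  mu0 <- c(stats::rnorm(P, -1.8, 0.6), stats::rnorm(P, 1.8, 0.6),
           stats::rnorm(P, 0, 0.8))[seq_len(P) + (mode - 1) * P]

  ## logit shift for the target r (delta method), with a second-order
  ## curvature correction: the inverse-logit compresses the signal more at
  ## extreme baselines, attenuating the realized beta-scale correlation by
  ## about 1/sqrt(1 + (1-2*p0)^2 * var(logit)/2)
  d0 <- .r_to_logit_shift(target_r, config$noise_sd)
  curv <- (1 - 2 * stats::plogis(mu0))^2 *
    (config$noise_sd^2 + (d0 * 0.5)^2) / 2
  d <- d0 * sqrt(1 + curv)

  ## -- cross-hybridizing probes and sequences -----------------------------
  allosomes <- c(chrX = .random_dna(1, config$allosome_length),
                 chrY = .random_dna(1, config$allosome_length))
  xhyb_idx <- sample(setdiff(seq_len(P), assoc_idx),
                     min(config$n_crosshyb_probes, P - n_assoc))
  seqs <- .random_dna(P, 50)
  for (i in xhyb_idx) {
    src <- allosomes[[sample(2, 1)]]
    start <- sample(nchar(src) - 49, 1)
    sub <- substr(src, start, start + 49)
    if (stats::runif(1) < 0.5) sub <- .revcomp(sub)
    seqs[i] <- .mutate_seq(sub, config$crosshyb_mismatches)
  }
  annotation$probe_sequence <- seqs

  ## -- truth table --------------------------------------------------------
  truth <- data.frame(probe_id = probe_id, chromosome = as.character(chr),
                      position = pos, gene = gene,
                      cgi_relation = factor(cgi, levels = .cgi_levels),
                      is_sex_associated = seq_len(P) %in% assoc_idx,
                      target_r = target_r, effect_logit = d,
                      is_imprinted_gene = is_imprinted,
                      is_crosshyb = seq_len(P) %in% xhyb_idx,
                      lambda = ifelse(seq_len(P) %in% xhyb_idx,
                                      config$contamination_lambda, 0),
                      stringsAsFactors = FALSE)

  ## -- covariate coefficients and correlation blocks ----------------------
  B <- matrix(stats::rnorm(P * 3, 0, config$covariate_effect_sd), P, 3)
  mu_allo <- stats::rnorm(P, 0, 1)
  n_blocks <- ceiling(P / config$block_size)
  block <- rep(seq_len(n_blocks), each = config$block_size)[seq_len(P)]

  ## -- cohorts ------------------------------------------------------------
  cohorts <- vector("list", config$n_cohorts)
  for (co in seq_len(config$n_cohorts)) {
    n <- config$n_samples[co]
    cov <- .simulate_covariates(n, co)
    sex <- cov$sex
    Xstd <- scale(as.matrix(cov[, c("age", "bmi", "cd4t")]))
    jitter <- matrix(stats::rnorm(P, 1, config$cohort_effect_jitter_sd), P, 1)
    z_block <- matrix(stats::rnorm(n_blocks * n), n_blocks, n)
    noise <- config$noise_sd *
      (sqrt(config$block_rho) * z_block[block, , drop = FALSE] +
         sqrt(1 - config$block_rho) * matrix(stats::rnorm(P * n), P, n))
    Y <- mu0 + B %*% t(Xstd) + (d * jitter[, 1]) %*% t(sex) + noise
    beta <- stats::plogis(Y)
    if (length(xhyb_idx) > 0 && config$contamination_lambda > 0) {
      k <- length(xhyb_idx)
      allo <- stats::plogis(matrix(mu_allo[xhyb_idx], k, n) +
                              config$allosome_sex_shift *
                                matrix(sex, k, n, byrow = TRUE) +
                              matrix(stats::rnorm(k * n, 0, 0.3), k, n))
      beta[xhyb_idx, ] <- (1 - config$contamination_lambda) * beta[xhyb_idx, ] +
        config$contamination_lambda * allo
    }
    dimnames(beta) <- list(probe_id, cov$sample_id)
    cohorts[[co]] <- list(beta = beta, covariates = cov)
  }
  names(cohorts) <- paste0("cohort", seq_len(config$n_cohorts))
  list(cohorts = cohorts, annotation = annotation, truth = truth,
       allosomes = allosomes, config = config)
}

#' Generate cis-linked expression data for the discovery cohort
#'
#' Picks sex-associated CpGs from the truth table and links each to one
#' expression gene placed within the cis window on the same chromosome;
#' linked genes follow `expression = b0 + b1*sex + b2*methylation + e`,
#' unlinked genes are baseline plus noise. A handful of decoy genes are
#' placed just beyond the window around linked CpGs to exercise the window
#' boundary.
#'
#' @param sim Output of [generate_cohorts()].
#' @param cohort Which cohort carries expression (default 1, discovery).
#' @return List with `expression` (genes x samples), `gene_coordinates`
#'   (`gene`, `chromosome`, `start`, `end`, `strand`) and `truth`
#'   (`gene`, `linked`, `cpg_id`, `b1`, `b2`).
#' @export
generate_expression <- function(sim, cohort = 1) {
  config <- sim$config
  ex <- config$expression
  set.seed(config$seed + 104729L)    # distinct stream from the cohort draw
  truth <- sim$truth
  beta <- sim$cohorts[[cohort]]$beta
  cov <- sim$cohorts[[cohort]]$covariates
  sex <- cov$sex
  n <- length(sex)

  cand <- truth$probe_id[truth$is_sex_associated & !truth$is_crosshyb]
  n_linked <- min(ex$n_linked, length(cand))
  linked_cpg <- sample(cand, n_linked)
  gene_ids <- sprintf("EXPR%05d", seq_len(ex$n_genes))
  linked <- seq_len(n_linked)

  coords <- data.frame(gene = gene_ids, chromosome = NA_character_,
                       start = NA_real_, end = NA_real_,
                       strand = sample(c("+", "-"), ex$n_genes, replace = TRUE),
                       stringsAsFactors = FALSE)
  tmap <- match(linked_cpg, truth$probe_id)
  offs <- sample(1000:500000, n_linked, replace = TRUE)
  coords$chromosome[linked] <- truth$chromosome[tmap]
  coords$start[linked] <- truth$position[tmap] + offs
  coords$end[linked] <- coords$start[linked] + sample(5000:100000, n_linked,
                                                      replace = TRUE)
  ## a few decoys just beyond the window near linked CpGs
  n_decoy <- min(10, ex$n_genes - n_linked)
  decoy <- n_linked + seq_len(n_decoy)
  dm <- tmap[seq_len(n_decoy)]
  coords$chromosome[decoy] <- truth$chromosome[dm]
  coords$start[decoy] <- truth$position[dm] + ex$cis_window +
    sample(1:100000, n_decoy, replace = TRUE)
  coords$end[decoy] <- coords$start[decoy] + 20000
  rest <- which(is.na(coords$chromosome))
  coords$chromosome[rest] <- as.character(sample(1:22, length(rest), replace = TRUE))
  coords$start[rest] <- sample(1e6:5e7, length(rest), replace = TRUE)
  coords$end[rest] <- coords$start[rest] + sample(5000:100000, length(rest),
                                                  replace = TRUE)

  b0 <- stats::rnorm(ex$n_genes, 7, 1)
  E <- matrix(stats::rnorm(ex$n_genes * n, 0, ex$noise_sd), ex$n_genes, n) + b0
  E[linked, ] <- E[linked, ] + ex$b1 * matrix(sex, n_linked, n, byrow = TRUE) +
    ex$b2 * beta[linked_cpg, , drop = FALSE]
  dimnames(E) <- list(gene_ids, cov$sample_id)

  etruth <- data.frame(gene = gene_ids,
                       linked = seq_len(ex$n_genes) %in% linked,
                       cpg_id = NA_character_, b1 = 0, b2 = 0,
                       stringsAsFactors = FALSE)
  etruth$cpg_id[linked] <- linked_cpg
  etruth$b1[linked] <- ex$b1
  etruth$b2[linked] <- ex$b2
  list(expression = E, gene_coordinates = coords, truth = etruth)
}

#' Write a synthetic dataset to a directory in pipeline dialects
#'
#' Emits per-cohort beta and covariate tables, the annotation manifest,
#' decoy allosome FASTA, truth table, an imprinted-gene GMT, and (when
#' given) expression matrix and gene coordinates.
#'
#' @param sim Output of [generate_cohorts()].
#' @param dir Output directory (created if needed).
#' @param expression Optional output of [generate_expression()].
#' @return The directory path, invisibly.
#' @export
simulate_to_dir <- function(sim, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in names(sim$cohorts)) {
    write_beta_matrix(sim$cohorts[[co]]$beta,
                      file.path(dir, paste0("beta_", co, ".tsv")))
    utils::write.table(sim$cohorts[[co]]$covariates,
                       file.path(dir, paste0("covariates_", co, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_probe_annotation(sim$annotation, file.path(dir, "annotation.csv"))
  write_fasta(sim$allosomes, file.path(dir, "allosomes.fa"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  imprinted <- unique(sim$truth$gene[sim$truth$is_imprinted_gene & sim$truth$gene != ""])
  sets <- list(imprinted = imprinted)
  other <- setdiff(unique(sim$truth$gene[sim$truth$gene != ""]), imprinted)
  if (length(other) >= 20) sets$hormone_related <- sort(sample(other, 20))
  write_gmt(sets, file.path(dir, "genesets.gmt"))
  if (!is.null(expression)) {
    df <- data.frame(gene = rownames(expression$expression),
                     expression$expression, check.names = FALSE)
    utils::write.table(df, file.path(dir, "expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expression$gene_coordinates,
                       file.path(dir, "expression_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expression$truth,
                       file.path(dir, "expression_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
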