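# shared fixture builders; everything is generated in code at test time

tiny_annotation <- function() {
  data.frame(
    probe_id = sprintf("cg%08d", 1:5),
    chromosome = c("1", "1", "2", "2", "3"),
    position = c(100L, 2000L, 500L, 800L, 42L),
    gene_names = c("TP53;TP53;EGFR", "TP53", "", "BRCA2", "EGFR"),
    cgi_relation = factor(c("island", "shore_north", "open_sea",
                            "shelf_south", "open_sea"),
                          levels = c("island", "shore_north", "shore_south",
                                     "shelf_north", "shelf_south", "open_sea")),
    probe_sequence = NA_character_,
    stringsAsFactors = FALSE)
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent brute-force cross-hybridization oracle: all offsets with full
# overlap, both probe orientations, every reference
oracle_crosshyb <- function(probe, refs) {
  count_best <- function(p, r) {
    pv <- strsplit(p, "")[[1]]; rv <- strsplit(r, "")[[1]]
    if (length(rv) < length(pv)) { tmp <- pv; pv <- rv; rv <- tmp }
    m <- length(pv)
    best <- 0L
    for (o in 0:(length(rv) - m))
      best <- max(best, sum(pv == rv[(o + 1):(o + m)]))
    best
  }
  best <- 0L
  for (r in refs)
    best <- max(best, count_best(probe, r), count_best(revcomp(probe), r))
  best
}

# exhaustive hypergeometric tail oracle by direct combinatorial summation
oracle_hyper_tail <- function(N, K, n, k, convention = "ge") {
  lo <- if (convention == "ge") k else k + 1
  hi <- min(K, n)
  if (lo > hi) return(0)
  sum(vapply(lo:hi, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1)))
}

# small cohort with known structure for unit tests
small_sim <- function(seed = 42, ...) {
  generate_cohorts(simulation_config(
    n_probes = 1500, n_samples = 150, n_cohorts = 2, n_genes = 250,
    imprinted_gene_count = 15, n_crosshyb_probes = 25,
    allosome_length = 600,
    expression = list(n_genes = 80, n_linked = 15, cis_window = 1e6,
                      b1 = -0.5, b2 = -0.8, noise_sd = 0.5),
    seed = seed, ...))
}
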