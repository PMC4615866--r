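#' Random thinning of probes for enrichment testing
#'
#' Neighbouring CpGs are locally correlated, which inflates enrichment
#' p-values; the analysis therefore thins the probe set by independent
#' Bernoulli selection (default probability 0.2) before testing.
#'
#' @param probe_ids Character vector of probe ids.
#' @param prob Selection probability in (0, 1].
#' @param seed Optional integer seed.
#' @return Character vector subset of `probe_ids`.
#' @export
subsample_sites <- function(probe_ids, prob = 0.2, seed = NULL) {
  if (!(prob > 0 && prob <= 1)) stop("prob must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  probe_ids[stats::runif(length(probe_ids)) < prob]
}

#' Collapse the six CGI relation labels to four regions
#'
#' North and south shores (and shelves) are combined, giving
#' island / shore / shelf / open_sea.
#'
#' @param cgi_relation Factor or character vector over the six labels.
#' @return Factor with levels island, shore, shelf, open_sea.
#' @export
collapse_cgi <- function(cgi_relation) {
  x <- as.character(cgi_relation)
  x[x %in% c("shore_north", "shore_south")] <- "shore"
  x[x %in% c("shelf_north", "shelf_south")] <- "shelf"
  factor(x, levels = c("island", "shore", "shelf", "open_sea"))
}

#' CGI-context enrichment test from per-category counts
#'
#' Core contingency machinery for the shore-enrichment analysis. The default
#' framing tests overrepresentation of significant sites in CGI shores as a
#' 2x2 Pearson chi-square (shore vs all other regions, significant vs not)
#' without continuity correction. With `exclude = "shore"` the remaining
#' three categories are tested in a 2x3 contingency chi-square (is any
#' residual region enriched once shores are removed?). `omnibus = TRUE`
#' runs the full 2x4 test instead.
#'
#' @param total_counts Named vector of probe counts per region
#'   (island, shore, shelf, open_sea).
#' @param significant_counts Named vector of significant-site counts per
#'   region, same names.
#' @param exclude Optional region name dropped before testing.
#' @param omnibus Test all remaining categories jointly instead of
#'   shore-vs-rest.
#' @return List (`observed`, `expected`, `chi2`, `df`, `p`, `framing`).
#' @export
cgi_enrichment_counts <- function(total_counts, significant_counts,
                                  exclude = NULL, omnibus = FALSE) {
  cats <- names(total_counts)
  if (is.null(cats) || !setequal(names(significant_counts), cats))
    stop("total and significant counts must share category names")
  significant_counts <- significant_counts[cats]
  if (any(significant_counts > total_counts))
    stop("significant counts exceed totals")
  if (!is.null(exclude)) {
    if (!exclude %in% cats) stop("unknown category to exclude: ", exclude)
    keep <- setdiff(cats, exclude)
    total_counts <- total_counts[keep]
    significant_counts <- significant_counts[keep]
    cats <- keep
    omnibus <- TRUE   # without the focal category the test is a contingency omnibus
  }
  if (omnibus) {
    tab <- rbind(significant = significant_counts,
                 not_significant = total_counts - significant_counts)
    framing <- paste0("omnibus_2x", length(cats))
  } else {
    if (!"shore" %in% cats) stop("shore category absent; categories: ",
                                 paste(cats, collapse = ", "))
    sig_shore <- significant_counts[["shore"]]
    sig_rest <- sum(significant_counts) - sig_shore
    tot_shore <- total_counts[["shore"]]
    tot_rest <- sum(total_counts) - tot_shore
    tab <- cbind(shore = c(sig_shore, tot_shore - sig_shore),
                 rest = c(sig_rest, tot_rest - sig_rest))
    rownames(tab) <- c("significant", "not_significant")
    framing <- "shore_vs_rest_2x2"
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(observed = ht$observed, expected = ht$expected,
       chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, framing = framing)
}

#' CGI-context enrichment test from per-probe labels
#'
#' @param cgi_relation Per-probe CGI relation (six labels, collapsed
#'   internally) for the analysis subset.
#' @param significant Logical vector flagging significant sites.
#' @param ... Passed to [cgi_enrichment_counts()].
#' @return See [cgi_enrichment_counts()].
#' @export
cgi_enrichment <- function(cgi_relation, significant, ...) {
  if (length(cgi_relation) != length(significant)) stop("inputs must be paired")
  cat4 <- collapse_cgi(cgi_relation)
  missing_cats <- levels(cat4)[tabulate(cat4, 4) == 0]
  if (length(missing_cats) > 0)
    stop("category absent from subset: ", paste(missing_cats, collapse = ", "))
  total <- table(cat4)
  sig <- table(cat4[significant])
  cgi_enrichment_counts(
    stats::setNames(as.numeric(total), names(total)),
    stats::setNames(as.numeric(sig[names(total)]), names(total)), ...)
}

#' Exact hypergeometric tail probability
#'
#' P(X >= k) (convention `"ge"`) or P(X > k) (`"gt"`) for X hypergeometric:
#' `k` marked items in a sample of `n` from a universe of `N` containing
#' `K` marked items. Computed through the log-gamma machinery of
#' `stats::phyper`.
#'
#' @param N Universe size.
#' @param K Number of marked items.
#' @param n Sample size.
#' @param k Observed marked items in the sample.
#' @param convention `"ge"` (default) or `"gt"`.
#' @return Tail probability.
#' @export
hypergeometric_tail <- function(N, K, n, k, convention = c("ge", "gt")) {
  convention <- match.arg(convention)
  if (K > N || n > N || k > min(K, n) || k < 0 || k < n - (N - K))
    stop("inconsistent hypergeometric counts (N=", N, ", K=", K,
         ", n=", n, ", k=", k, ")")
  q <- if (convention == "ge") k - 1 else k
  stats::phyper(q, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Spearman rank test for imprinted-gene enrichment
#'
#' Correlates per-gene significance (`-log10` of the best-CpG p-value,
#' midrank-tied) with a binary imprinted-gene flag. Positive rho means
#' imprinted genes carry more significant sex associations. The p-value
#' uses the t approximation with n-2 degrees of freedom.
#'
#' @param p_values Per-gene p-values (best CpG per gene).
#' @param imprinted_flags Logical/0-1 vector, same length.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List (`rho`, `t`, `p`, `n`).
#' @export
imprinted_spearman <- function(p_values, imprinted_flags,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(p_values) != length(imprinted_flags)) stop("inputs must be paired")
  f <- as.numeric(imprinted_flags)
  if (length(unique(f)) < 2) stop("imprinted flags are constant; no contrast")
  n <- length(p_values)
  rho <- stats::cor(rank(-log10(p_values)), rank(f))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(t), df = n - 2),
              greater = stats::pt(t, df = n - 2, lower.tail = FALSE),
              less = stats::pt(t, df = n - 2))
  list(rho = rho, t = t, p = p, n = n)
}

#' Fit a probability weighting function (PWF) for probe-count bias
#'
#' Genes covered by more CpG probes have more chances to contain a
#' significant site, biasing category enrichment. The PWF estimates
#' P(gene significant | probe count) by a monotone fit: genes are binned
#' into `n_bins` equal-count groups by probe count, bin-wise significant
#' fractions are made monotone non-decreasing by isotonic regression, and
#' the fit is rescaled so the mean weight equals the overall significant
#' fraction.
#'
#' @param significant Logical vector: gene called significant.
#' @param probe_counts Integer vector of probes per gene, same length.
#' @param genes Optional gene names (used to name the weights).
#' @param n_bins Number of equal-count bins (default 10, reduced if there
#'   are fewer distinct counts).
#' @return Object of class `pwf`: list with `weights` (per gene, in (0,1)),
#'   `bin_counts`, `bin_rates`, `target_rate`.
#' @export
fit_pwf <- function(significant, probe_counts, genes = NULL, n_bins = 10) {
  significant <- as.logical(significant)
  if (length(significant) != length(probe_counts)) stop("inputs must be paired")
  if (all(significant) || !any(significant))
    stop("all genes significant or none: no contrast to fit")
  if (length(unique(probe_counts)) < 2)
    stop("need at least 2 distinct probe counts")
  n <- length(significant)
  n_bins <- max(1, min(n_bins, length(unique(probe_counts))))
  ord <- order(probe_counts)
  bin <- integer(n)
  bin[ord] <- ceiling(seq_len(n) / (n / n_bins))
  bin_x <- tapply(probe_counts, bin, mean)
  bin_y <- tapply(as.numeric(significant), bin, mean)
  iso <- stats::isoreg(bin_x, bin_y)
  fitted_bin <- iso$yf[order(order(bin_x))]
  w <- fitted_bin[bin]
  target <- mean(significant)
  if (mean(w) > 0) w <- w * target / mean(w)
  eps <- 1e-8
  w <- pmin(1 - eps, pmax(eps, w))
  if (!is.null(genes)) names(w) <- genes
  structure(list(weights = w, bin_counts = as.numeric(bin_x),
                 bin_rates = as.numeric(fitted_bin), target_rate = target),
            class = "pwf")
}

#' Wallenius noncentral hypergeometric distribution
#'
#' Distribution of the number of "marked" items among `n` items drawn
#' sequentially without replacement from a universe of `m1` marked and `m2`
#' unmarked items, marked items having sampling odds `odds` relative to
#' unmarked. `wallenius_pmf` computes the full probability mass function by
#' exact dynamic programming over the draw sequence (each step removes one
#' item, with marked-draw probability
#' `odds*(m1-x) / (odds*(m1-x) + (m2-(j-x)))`), which keeps every
#' intermediate value in \[0,1\] and so is numerically stable at any size.
#'
#' @param m1,m2 Marked/unmarked universe sizes.
#' @param n Number of draws (`0 <= n <= m1 + m2`).
#' @param odds Odds ratio (> 0) favouring marked items.
#' @return `wallenius_pmf`: numeric vector of P(X = x) for x = 0..min(m1,n)
#'   (named by x).
#' @export
wallenius_pmf <- function(m1, m2, n, odds) {
  if (odds <= 0) stop("odds must be positive")
  if (n < 0 || n > m1 + m2) stop("n must be in [0, m1+m2]")
  hi <- min(m1, n)
  f <- c(1, numeric(hi))            # f[x+1] = P(X_j = x)
  if (n > 0) for (j in 0:(n - 1)) {
    x <- max(0, j - m2):min(m1, j)   # reachable states after j draws
    marked_left <- m1 - x
    unmarked_left <- m2 - (j - x)
    pm <- odds * marked_left / (odds * marked_left + unmarked_left)
    fj <- f[x + 1]
    f[] <- 0
    f[x + 1] <- fj * (1 - pm)
    f[x + 2] <- f[x + 2] + fj * pm
    f <- f[seq_len(hi + 1)]
  }
  stats::setNames(f, 0:hi)
}

#' @rdname wallenius_pmf
#' @param x Number of marked items drawn.
#' @return `dwallenius`: probability mass P(X = x).
#' @export
dwallenius <- function(x, m1, m2, n, odds) {
  if (x < max(0, n - m2) || x > min(m1, n)) return(0)
  unname(wallenius_pmf(m1, m2, n, odds)[x + 1])
}

#' @rdname wallenius_pmf
#' @param k Lower bound of the upper tail.
#' @return `wallenius_tail`: P(X >= k).
#' @export
wallenius_tail <- function(k, m1, m2, n, odds) {
  hi <- min(m1, n)
  if (k > hi) return(0)
  if (abs(odds - 1) < 1e-12)
    return(hypergeometric_tail(N = m1 + m2, K = m1, n = n,
                               k = max(k, max(0, n - m2)), convention = "ge"))
  pmf <- wallenius_pmf(m1, m2, n, odds)
  min(1, max(0, sum(pmf[(max(k, 0) + 1):(hi + 1)])))
}

#' Probe-count-bias-corrected category enrichment test
#'
#' Tests whether significant genes are overrepresented in a category while
#' correcting for probe-count bias through a PWF (the approach of
#' weighting-based ontology enrichment for tag-count data, reimplemented).
#' The analytic method computes the Wallenius noncentral hypergeometric
#' upper-tail probability of the observed number of significant genes in
#' the category, with odds given by the ratio of mean-weight odds inside
#' versus outside the category. The `"sampling"` method instead draws
#' significant-gene sets of the observed size sequentially without
#' replacement with per-gene urn weights `w/(1-w)` (the odds implied by
#' the PWF, matching the analytic odds parameter) and reports the
#' empirical tail (add-one estimator).
#'
#' @param category_members Character vector of gene names in the category.
#' @param significant_genes Character vector of significant gene names.
#' @param pwf A [fit_pwf()] object with named weights covering the universe.
#' @param method `"wallenius"` (default) or `"sampling"`.
#' @param n_draws Draws for the sampling method (default 10000).
#' @param seed Optional seed for the sampling method.
#' @return List (`k`, `n_category`, `n_significant`, `n_universe`, `odds`,
#'   `p`, `method`).
#' @export
weighted_category_test <- function(category_members, significant_genes, pwf,
                                   method = c("wallenius", "sampling"),
                                   n_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  w <- pwf$weights
  if (is.null(names(w))) stop("pwf weights must be named by gene")
  universe <- names(w)
  category <- intersect(unique(category_members), universe)
  sig <- intersect(unique(significant_genes), universe)
  if (length(category) == 0) {
    warning("category has no members in the universe; p = 1")
    return(list(k = 0L, n_category = 0L, n_significant = length(sig),
                n_universe = length(universe), odds = NA_real_, p = 1,
                method = method))
  }
  k <- length(intersect(category, sig))
  m1 <- length(category); m2 <- length(universe) - m1; n <- length(sig)
  in_cat <- universe %in% category
  mw_in <- mean(w[in_cat]); mw_out <- mean(w[!in_cat])
  odds <- (mw_in / (1 - mw_in)) / (mw_out / (1 - mw_out))
  if (method == "wallenius") {
    p <- wallenius_tail(k, m1 = m1, m2 = m2, n = n, odds = odds)
  } else {
    if (!is.null(seed)) set.seed(seed)
    urn <- w / (1 - w)
    hits <- vapply(seq_len(n_draws), function(b)
      sum(sample(universe, n, prob = urn) %in% category), integer(1))
    p <- (1 + sum(hits >= k)) / (n_draws + 1)
  }
  list(k = k, n_category = m1, n_significant = n,
       n_universe = length(universe), odds = odds, p = p, method = method)
}

#' Plain gene-set enrichment (hypergeometric)
#'
#' Unweighted hypergeometric enrichment of significant genes in a gene set,
#' over a stated gene universe (allosomal genes are expected to be excluded
#' upstream; the analysis is autosomal throughout).
#'
#' @param gene_set Character vector of set members.
#' @param significant_genes Character vector of significant genes.
#' @param universe Character vector of all analyzed genes.
#' @param convention Tail convention, see [hypergeometric_tail()].
#' @return List (`k`, `n_set`, `n_significant`, `n_universe`, `p`).
#' @export
geneset_enrichment <- function(gene_set, significant_genes, universe,
                               convention = "ge") {
  universe <- unique(universe)
  set_in <- intersect(unique(gene_set), universe)
  if (length(set_in) == 0) stop("gene set does not intersect the universe")
  sig <- intersect(unique(significant_genes), universe)
  k <- length(intersect(set_in, sig))
  p <- hypergeometric_tail(N = length(universe), K = length(set_in),
                           n = length(sig), k = k, convention = convention)
  list(k = k, n_set = length(set_in), n_significant = length(sig),
       n_universe = length(universe), p = p)
}
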