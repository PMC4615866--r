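#' DerSimonian-Laird random-effects meta-analysis of correlations
#'
#' Pools per-cohort Pearson correlations on the Fisher-z scale with the
#' DerSimonian-Laird moment estimator of the between-study variance tau^2
#' (the default of the classical `metacor` routine): z_i = atanh(r_i),
#' v_i = 1/(n_i - 3), fixed-effect weights w_i = 1/v_i,
#' Q = sum w_i (z_i - z_FE)^2, tau^2 = max(0, (Q - (k-1)) / (sum w - sum
#' w^2 / sum w)), random-effects weights 1/(v_i + tau^2). The pooled
#' correlation theta is the back-transformed pooled z; the p-value is
#' two-sided from the normal reference on the z scale.
#'
#' @param r_list Numeric vector of per-study correlations, all |r| < 1.
#' @param n_list Integer vector of per-study sample sizes, all >= 4.
#' @return List with `k`, `z`, `v`, `Q`, `tau2`, `pooled_z`, `se_z`,
#'   `theta`, `p_meta`.
#' @export
dl_meta <- function(r_list, n_list) {
  k <- length(r_list)
  if (k == 0) stop("need at least one study")
  if (length(n_list) != k) stop("r_list and n_list lengths differ")
  if (any(n_list <= 3)) stop("all n_i must be >= 4 (variance 1/(n-3) undefined)")
  if (any(abs(r_list) >= 1)) stop("all |r_i| must be < 1 for the z-transform")
  z <- atanh(r_list)
  v <- 1 / (n_list - 3)
  w <- 1 / v
  z_fe <- sum(w * z) / sum(w)
  Q <- sum(w * (z - z_fe)^2)
  tau2 <- if (k == 1) 0 else {
    c_dl <- sum(w) - sum(w^2) / sum(w)
    max(0, (Q - (k - 1)) / c_dl)
  }
  w_re <- 1 / (v + tau2)
  pooled_z <- sum(w_re * z) / sum(w_re)
  se_z <- 1 / sqrt(sum(w_re))
  p <- 2 * stats::pnorm(-abs(pooled_z) / se_z)
  list(k = k, z = z, v = v, Q = Q, tau2 = tau2, pooled_z = pooled_z,
       se_z = se_z, theta = tanh(pooled_z), p_meta = max(p, .Machine$double.xmin))
}

#' Meta-analyze association tables across replication cohorts
#'
#' Runs [dl_meta()] per probe over the probes present (and non-degenerate)
#' in every cohort, vectorized. Probes missing from any cohort are excluded
#' and reported via the `n_excluded` attribute, so the number of rows is the
#' correct Bonferroni denominator for the replication step.
#'
#' @param sma_tables Named list of per-cohort association tables from
#'   [sma_cohort()].
#' @return Data.frame (`probe_id`, `k`, `Q`, `tau2`, `pooled_z`, `se_z`,
#'   `theta`, `p_meta`) with attribute `n_excluded`.
#' @export
meta_analyze <- function(sma_tables) {
  if (length(sma_tables) == 0) stop("need at least one cohort")
  usable <- lapply(sma_tables, function(tb)
    tb[!tb$degenerate & !is.na(tb$r) & abs(tb$r) < 1 & tb$n > 3, , drop = FALSE])
  shared <- Reduce(intersect, lapply(usable, `[[`, "probe_id"))
  all_ids <- Reduce(union, lapply(sma_tables, `[[`, "probe_id"))
  if (length(shared) == 0) stop("no probes shared across all cohorts")
  k <- length(usable)
  Z <- sapply(usable, function(tb) atanh(tb$r[match(shared, tb$probe_id)]))
  V <- sapply(usable, function(tb) 1 / (tb$n[match(shared, tb$probe_id)] - 3))
  Z <- matrix(Z, ncol = k); V <- matrix(V, ncol = k)
  W <- 1 / V
  sw <- rowSums(W)
  z_fe <- rowSums(W * Z) / sw
  Q <- rowSums(W * (Z - z_fe)^2)
  tau2 <- if (k == 1) rep(0, length(shared)) else {
    c_dl <- sw - rowSums(W^2) / sw
    pmax(0, (Q - (k - 1)) / c_dl)
  }
  Wre <- 1 / (V + tau2)
  swre <- rowSums(Wre)
  pooled_z <- rowSums(Wre * Z) / swre
  se_z <- 1 / sqrt(swre)
  p <- pmax(2 * stats::pnorm(-abs(pooled_z) / se_z), .Machine$double.xmin)
  out <- data.frame(probe_id = shared, k = k, Q = Q, tau2 = tau2,
                    pooled_z = pooled_z, se_z = se_z, theta = tanh(pooled_z),
                    p_meta = p, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- length(all_ids) - length(shared)
  out
}

#' Flag replicated probes at the Bonferroni threshold
#'
#' @param meta_table Output of [meta_analyze()].
#' @param alpha Family-wise error rate (default 0.05).
#' @param m Number of tests; defaults to `nrow(meta_table)`, the number of
#'   probes analyzed in all replication cohorts.
#' @return `meta_table` with logical column `replicated`
#'   (`p_meta < alpha/m`, strict) and attribute `threshold`.
#' @export
replicate_probes <- function(meta_table, alpha = 0.05, m = nrow(meta_table)) {
  if (nrow(meta_table) == 0) stop("empty meta table")
  thr <- bonferroni_threshold(alpha, m)
  meta_table$replicated <- meta_table$p_meta < thr
  attr(meta_table, "threshold") <- thr
  meta_table
}

#' Sign-consistency binomial test between discovery and replication
#'
#' Counts probes whose effect direction agrees between the discovery and
#' replication analyses and tests the count against a fair coin with a
#' one-sided exact binomial tail, computed in log space so that extreme
#' p-values (e.g. all 700 of 700 consistent) do not underflow to zero.
#'
#' @param discovery_directions,replication_directions Paired vectors of
#'   -1/0/+1 directions; pairs with a zero direction are dropped.
#' @return List with `k_consistent`, `n`, `p` and `log10_p`.
#' @export
sign_consistency_test <- function(discovery_directions, replication_directions) {
  if (length(discovery_directions) != length(replication_directions))
    stop("direction vectors must be paired")
  ok <- discovery_directions != 0 & replication_directions != 0 &
    !is.na(discovery_directions) & !is.na(replication_directions)
  n <- sum(ok)
  if (n == 0) stop("no non-degenerate direction pairs")
  k <- sum(sign(discovery_directions[ok]) == sign(replication_directions[ok]))
  # P(X >= k), X ~ Binomial(n, 1/2); log-space tail for extreme counts
  logp <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE, log.p = TRUE)
  list(k_consistent = k, n = n, p = exp(logp), log10_p = logp / log(10))
}

#' Correlation of association estimates between two cohorts
#'
#' Pearson correlation of the per-probe correlation estimates of two
#' cohorts over a shared probe subset (typically the probes taken to
#' replication).
#'
#' @param sma_a,sma_b Association tables.
#' @param probe_subset Optional probe ids restricting the comparison.
#' @return Pearson correlation (scalar).
#' @export
cross_study_correlation <- function(sma_a, sma_b, probe_subset = NULL) {
  shared <- intersect(sma_a$probe_id, sma_b$probe_id)
  if (!is.null(probe_subset)) shared <- intersect(shared, probe_subset)
  ra <- sma_a$r[match(shared, sma_a$probe_id)]
  rb <- sma_b$r[match(shared, sma_b$probe_id)]
  ok <- !is.na(ra) & !is.na(rb)
  if (sum(ok) < 3) stop("need at least 3 shared probes with estimates")
  stats::cor(ra[ok], rb[ok])
}

#' Hypergeometric overlap test between two significant sets
#'
#' Upper-tail hypergeometric probability of observing at least (convention
#' `"ge"`, default) or more than (`"gt"`) the observed overlap between two
#' significant probe sets drawn from a common universe.
#'
#' @param set_a,set_b Character vectors of significant ids.
#' @param universe Character vector containing both sets.
#' @param convention `"ge"` for P(X >= k) or `"gt"` for P(X > k).
#' @return List with `overlap`, `n_a`, `n_b`, `n_universe`, `p`,
#'   `convention`.
#' @export
overlap_test <- function(set_a, set_b, universe, convention = c("ge", "gt")) {
  convention <- match.arg(convention)
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  if (!all(set_a %in% universe)) stop("set_a is not a subset of the universe")
  if (!all(set_b %in% universe)) stop("set_b is not a subset of the universe")
  k <- length(intersect(set_a, set_b))
  p <- hypergeometric_tail(N = length(universe), K = length(set_a),
                           n = length(set_b), k = k, convention = convention)
  list(overlap = k, n_a = length(set_a), n_b = length(set_b),
       n_universe = length(universe), p = p, convention = convention)
}
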