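#' Pair CpGs with genes within a cis window
#'
#' Pairs each CpG with every gene on the same chromosome whose distance is
#' at most `window` base pairs (inclusive). Distance is 0 when the CpG lies
#' inside the gene body, otherwise the smaller of the absolute distances to
#' the gene start and end; strand is ignored (unsigned coordinates).
#' The total number of pairs is the multiplicity denominator for the
#' expression analysis.
#'
#' @param cpg_positions Data.frame with `probe_id`, `chromosome`,
#'   `position`.
#' @param gene_coordinates Data.frame with `gene`, `chromosome`, `start`,
#'   `end` (and optionally `strand`, unused).
#' @param window Maximum distance in bp (default 1e6).
#' @return Data.frame (`cpg_id`, `gene`, `chromosome`, `distance_bp`);
#'   `nrow` is the pair count.
#' @export
pair_cpg_genes <- function(cpg_positions, gene_coordinates, window = 1e6) {
  if (window <= 0) stop("window must be positive")
  out <- vector("list", 0)
  for (chr in intersect(unique(cpg_positions$chromosome),
                        unique(gene_coordinates$chromosome))) {
    cp <- cpg_positions[cpg_positions$chromosome == chr, , drop = FALSE]
    gn <- gene_coordinates[gene_coordinates$chromosome == chr, , drop = FALSE]
    if (nrow(cp) == 0 || nrow(gn) == 0) next
    pos <- matrix(cp$position, nrow(cp), nrow(gn))
    st <- matrix(gn$start, nrow(cp), nrow(gn), byrow = TRUE)
    en <- matrix(gn$end, nrow(cp), nrow(gn), byrow = TRUE)
    inside <- pos >= pmin(st, en) & pos <= pmax(st, en)
    d <- pmin(abs(pos - st), abs(pos - en))
    d[inside] <- 0
    hit <- which(d <= window, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[length(out) + 1]] <- data.frame(
      cpg_id = cp$probe_id[hit[, 1]], gene = gn$gene[hit[, 2]],
      chromosome = chr, distance_bp = d[hit],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(cpg_id = character(), gene = character(),
                      chromosome = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint sex + methylation expression model for one CpG-gene pair
#'
#' Fits `expression = b0 + b1*sex + b2*methylation (+ covariates) + e` by
#' OLS and reports the estimates with two-sided t-test p-values for the sex
#' and methylation coefficients.
#'
#' @param expression Numeric expression vector for one gene.
#' @param sex 0/1 vector (0 = female, 1 = male).
#' @param methylation Beta-values of the paired CpG.
#' @param covariate_design Optional additional covariate design (no
#'   intercept column; one is added).
#' @return List (`b0`, `b1`, `b2`, `se_b1`, `se_b2`, `p_b1`, `p_b2`, `n`).
#' @export
expression_model <- function(expression, sex, methylation,
                             covariate_design = NULL) {
  X <- cbind(`(Intercept)` = 1, sex = sex, methylation = methylation)
  if (!is.null(covariate_design)) {
    cd <- as.matrix(covariate_design)
    cd <- cd[, colnames(cd) != "(Intercept)", drop = FALSE]
    X <- cbind(X, cd)
  }
  ok <- stats::complete.cases(cbind(expression, X))
  X <- X[ok, , drop = FALSE]; y <- expression[ok]
  n <- length(y)
  if (n <= ncol(X)) stop("need more samples than model columns")
  .check_full_rank(X)
  fit <- stats::lm.fit(X, y)
  df <- n - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(sigma2 * diag(XtXinv))
  names(se) <- colnames(X)
  tt <- fit$coefficients / se
  p <- 2 * stats::pt(-abs(tt), df = df)
  list(b0 = unname(fit$coefficients[1]),
       b1 = unname(fit$coefficients["sex"]),
       b2 = unname(fit$coefficients["methylation"]),
       se_b1 = unname(se["sex"]), se_b2 = unname(se["methylation"]),
       p_b1 = unname(p["sex"]), p_b2 = unname(p["methylation"]), n = n)
}

#' Fit the expression model over all cis CpG-gene pairs
#'
#' @param pairs Output of [pair_cpg_genes()].
#' @param expression Expression matrix (genes x samples).
#' @param beta Beta-value matrix (CpGs x samples), same sample order as
#'   `expression` after matching on column names.
#' @param covariates Covariate table with `sample_id` and `sex`;
#'   remaining columns enter the model as in the main analysis.
#' @return Data.frame of ExpressionPairRecords: `cpg_id`, `gene`,
#'   `distance_bp`, `b0`, `b1`, `b2`, `p_b1`, `p_b2`, `n`.
#' @export
expression_link_models <- function(pairs, expression, beta, covariates) {
  samples <- intersect(colnames(expression), colnames(beta))
  samples <- intersect(samples, covariates$sample_id)
  if (length(samples) < 5) stop("too few shared samples across inputs")
  cov <- covariates[match(samples, covariates$sample_id), , drop = FALSE]
  sex <- as.numeric(cov$sex)
  design <- build_design(cov)
  recs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]; cg <- pairs$cpg_id[i]
    if (!g %in% rownames(expression) || !cg %in% rownames(beta)) next
    m <- expression_model(expression[g, samples], sex, beta[cg, samples],
                          covariate_design = design)
    recs[[i]] <- data.frame(cpg_id = cg, gene = g,
                            distance_bp = pairs$distance_bp[i],
                            b0 = m$b0, b1 = m$b1, b2 = m$b2,
                            p_b1 = m$p_b1, p_b2 = m$p_b2, n = m$n,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(cpg_id = character(), gene = character(),
                      distance_bp = numeric(), b0 = numeric(), b1 = numeric(),
                      b2 = numeric(), p_b1 = numeric(), p_b2 = numeric(),
                      n = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Select significant CpG-expression pairs
#'
#' A pair is significant when its coefficient p-values pass the Bonferroni
#' threshold `alpha / n_pairs` under the chosen rule: `"both"` (default;
#' sex and methylation both pass, i.e. expression is associated with both),
#' `"methylation_only"`, or `"either"`.
#'
#' @param records Output of [expression_link_models()].
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_pairs Total number of tested CpG-gene combinations (defaults to
#'   `nrow(records)`).
#' @param rule Significance rule.
#' @return Subset of `records`, with attribute `threshold`.
#' @export
significant_pairs <- function(records, alpha = 0.05, n_pairs = nrow(records),
                              rule = c("both", "methylation_only", "either")) {
  rule <- match.arg(rule)
  thr <- bonferroni_threshold(alpha, max(1, n_pairs))
  keep <- switch(rule,
                 both = records$p_b1 < thr & records$p_b2 < thr,
                 methylation_only = records$p_b2 < thr,
                 either = records$p_b1 < thr | records$p_b2 < thr)
  out <- records[keep, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}
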