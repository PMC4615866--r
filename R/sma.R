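#' Build a covariate design matrix
#'
#' Expands a covariate table into an OLS design matrix with intercept,
#' turning factor columns (smoking class, physical activity, plate, ...)
#' into dummy variables. Sex is deliberately excluded: methylation is
#' residualized on the covariates only, and then correlated with sex.
#'
#' @param covariates Covariate data.frame with a `sample_id` column.
#' @param exclude Columns to drop before building the design
#'   (default: `sample_id` and `sex`).
#' @return Numeric design matrix (rows = samples, first column intercept)
#'   with `rownames` set to sample ids.
#' @export
build_design <- function(covariates, exclude = c("sample_id", "sex")) {
  keep <- setdiff(colnames(covariates), exclude)
  if (length(keep) == 0) {
    X <- matrix(1, nrow(covariates), 1, dimnames = list(covariates$sample_id, "(Intercept)"))
    return(X)
  }
  X <- stats::model.matrix(~ ., data = covariates[, keep, drop = FALSE])
  rownames(X) <- covariates$sample_id
  .check_full_rank(X)
  X
}

.check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(q)
}

#' Residualize methylation on covariates
#'
#' Ordinary-least-squares residuals of each probe's beta-values on the
#' covariate design. Missing betas are handled by case-wise deletion per
#' probe. Residuals are orthogonal to every design column.
#'
#' @param beta Numeric vector (one probe) or matrix (probes x samples).
#' @param design Design matrix including an intercept, samples in rows.
#' @return Residuals with the shape of `beta` (NA where beta was missing).
#' @export
residualize <- function(beta, design) {
  vec <- is.null(dim(beta))
  Y <- if (vec) matrix(beta, nrow = 1) else beta
  if (ncol(Y) != nrow(design))
    stop("beta columns (", ncol(Y), ") must match design rows (", nrow(design), ")")
  q <- .check_full_rank(design)
  if (nrow(design) <= q$rank)
    stop("need more samples than design columns")
  if (!anyNA(Y)) {
    Q <- qr.Q(q)
    R <- Y - (Y %*% Q) %*% t(Q)
  } else {
    R <- Y
    complete <- !is.na(Y)
    for (i in seq_len(nrow(Y))) {
      ok <- complete[i, ]
      if (all(ok)) {
        Qi <- qr.Q(q)
        R[i, ] <- Y[i, ] - drop((Y[i, , drop = FALSE] %*% Qi) %*% t(Qi))
      } else {
        Xi <- design[ok, , drop = FALSE]
        if (sum(ok) <= qr(Xi)$rank)
          stop("probe ", i, ": too few non-missing samples for residualization")
        fit <- stats::lm.fit(Xi, Y[i, ok])
        R[i, ok] <- fit$residuals
        R[i, !ok] <- NA_real_
      }
    }
  }
  if (vec) drop(R) else R
}

#' Sex-methylation association for one probe
#'
#' Pearson correlation between sex (0 = female, 1 = male) and the
#' covariate-residualized beta-value; positive `r` means hypermethylated in
#' males. The p-value comes from the t reference distribution with n-2
#' degrees of freedom, two-sided.
#'
#' @param residuals Numeric vector of residualized beta-values.
#' @param sex Numeric 0/1 vector, same length.
#' @return List with `r`, `t`, `p`, `n`, `direction`, `degenerate`.
#' @export
sma <- function(residuals, sex) {
  ok <- !is.na(residuals) & !is.na(sex)
  x <- residuals[ok]; s <- sex[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations, got ", n)
  if (stats::sd(x) == 0 || stats::sd(s) == 0)
    return(list(r = NA_real_, t = NA_real_, p = NA_real_, n = n,
                direction = 0L, degenerate = TRUE))
  r <- stats::cor(x, s)
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(r = r, t = t, p = p, n = n, direction = as.integer(sign(r)),
       degenerate = FALSE)
}

#' Per-cohort sex-methylation association table
#'
#' Residualizes every probe on the covariates (sex excluded) and computes
#' the Pearson correlation of the residuals with sex, its t statistic,
#' two-sided p-value and direction. Probes with missing betas use case-wise
#' deletion, with the per-probe `n` recorded for downstream meta-analysis
#' variances.
#'
#' @param beta Beta-value matrix (probes x samples).
#' @param covariates Covariate table with `sample_id` and `sex` columns;
#'   samples are matched to `colnames(beta)` by id.
#' @param design Optional pre-built design matrix; by default
#'   `build_design(covariates)`.
#' @return Data.frame (`probe_id`, `r`, `t`, `p`, `n`, `direction`,
#'   `degenerate`), one row per probe.
#' @export
sma_cohort <- function(beta, covariates, design = NULL) {
  idx <- match(colnames(beta), covariates$sample_id)
  if (anyNA(idx))
    stop("samples missing from covariate table: ",
         paste(colnames(beta)[is.na(idx)][1:min(3, sum(is.na(idx)))], collapse = ", "))
  covariates <- covariates[idx, , drop = FALSE]
  if (!"sex" %in% colnames(covariates)) stop("covariate table must contain a 'sex' column")
  sex <- as.numeric(covariates$sex)
  if (!all(stats::na.omit(sex) %in% c(0, 1)))
    stop("sex must be coded 0 (female) / 1 (male)")
  if (is.null(design)) design <- build_design(covariates)
  R <- residualize(beta, design)
  n_all <- ncol(beta)
  if (!anyNA(R) && !anyNA(sex)) {
    sc <- sex - mean(sex)
    ss <- sqrt(sum(sc^2))
    num <- as.vector(R %*% sc)
    den <- sqrt(rowSums(R^2)) * ss
    r <- ifelse(den > 0, num / den, NA_real_)
    r <- pmin(1, pmax(-1, r))
    n <- rep(n_all, nrow(beta))
  } else {
    r <- numeric(nrow(beta)); n <- integer(nrow(beta))
    for (i in seq_len(nrow(beta))) {
      ok <- !is.na(R[i, ]) & !is.na(sex)
      n[i] <- sum(ok)
      ri <- R[i, ok]
      r[i] <- if (n[i] >= 4 && stats::sd(ri) > 0 && stats::sd(sex[ok]) > 0)
        stats::cor(ri, sex[ok]) else NA_real_
    }
  }
  degenerate <- is.na(r)
  t <- ifelse(abs(r) < 1, r * sqrt((n - 2) / (1 - r^2)), sign(r) * Inf)
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = n - 2), 0)
  p <- pmax(p, .Machine$double.xmin)
  p[degenerate] <- NA_real_
  data.frame(probe_id = rownames(beta), r = r, t = t, p = p, n = n,
             direction = as.integer(sign(ifelse(is.na(r), 0, r))),
             degenerate = degenerate, stringsAsFactors = FALSE, row.names = NULL)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0,1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  if (!(is.numeric(m) && m >= 1)) stop("m must be >= 1")
  alpha / m
}

#' Best (most significant) CpG per gene
#'
#' Reduces a probe-level association table to one record per annotated gene:
#' the probe with the smallest p-value, ties broken by lexicographic probe
#' id. Degenerate probes are ignored.
#'
#' @param sma_table Output of [sma_cohort()] (needs `probe_id`, `p`).
#' @param annotation Probe annotation with `probe_id` and `gene_names`.
#' @return Data.frame (`gene`, `best_probe_id`, `best_p`,
#'   `n_probes_of_gene`), one row per gene, ordered by gene.
#' @export
best_cpg_per_gene <- function(sma_table, annotation) {
  p <- sma_table$p[match(annotation$probe_id, sma_table$probe_id)]
  genes <- split_gene_names(annotation$gene_names)
  nrep <- lengths(genes)
  long <- data.frame(gene = unlist(genes),
                     probe_id = rep(annotation$probe_id, nrep),
                     p = rep(p, nrep), stringsAsFactors = FALSE)
  long <- long[!is.na(long$p), , drop = FALSE]
  # order by gene, then p, then probe id: first row per gene is the winner
  long <- long[order(long$gene, long$p, long$probe_id), , drop = FALSE]
  first <- !duplicated(long$gene)
  counts <- table(long$gene)
  out <- data.frame(gene = long$gene[first],
                    best_probe_id = long$probe_id[first],
                    best_p = long$p[first],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$n_probes_of_gene <- as.integer(counts[out$gene])
  out
}

#' Manhattan-plot-ready table
#'
#' Emits one row per probe with chromosome, position, -log10 p and a
#' hypermethylated-in-males flag (`direction > 0`), suitable for plotting.
#'
#' @param sma_table Association table.
#' @param annotation Probe annotation.
#' @return Data.frame (`probe_id`, `chromosome`, `position`, `neglog10_p`,
#'   `hypermethylated_male`).
#' @export
manhattan_table <- function(sma_table, annotation) {
  idx <- match(sma_table$probe_id, annotation$probe_id)
  data.frame(probe_id = sma_table$probe_id,
             chromosome = annotation$chromosome[idx],
             position = annotation$position[idx],
             neglog10_p = -log10(sma_table$p),
             hypermethylated_male = sma_table$direction > 0,
             stringsAsFactors = FALSE)
}
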