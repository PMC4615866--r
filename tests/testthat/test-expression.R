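test_that("cis pairing honours the inclusive 1 Mb window and gene bodies", {
  cpg <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4"),
                    chromosome = c("1", "1", "1", "2"),
                    position = c(5e6, 5e6, 5e6, 5e6),
                    stringsAsFactors = FALSE)
  genes <- data.frame(
    gene = c("inside", "at_window", "beyond", "upstream", "other_chr"),
    chromosome = c("1", "1", "1", "1", "2"),
    start = c(4.9e6, 6e6, 6000001, 4.0e6, 5.05e6),
    end = c(5.1e6, 6.1e6, 6100000, 4.2e6, 5.1e6),
    strand = "+", stringsAsFactors = FALSE)
  pairs <- pair_cpg_genes(cpg, genes, window = 1e6)
  got <- pairs[pairs$cpg_id == "cg1", ]
  expect_setequal(got$gene, c("inside", "at_window", "upstream"))
  expect_equal(got$distance_bp[got$gene == "inside"], 0)
  expect_equal(got$distance_bp[got$gene == "at_window"], 1e6)  # inclusive
  expect_false("beyond" %in% got$gene)                          # 1,000,001 bp
  expect_true(all(pairs$gene[pairs$cpg_id == "cg4"] == "other_chr"))
  # printed-style distances of the two reported loci both fall in-window
  expect_true(all(c(99832, 100699) <= 1e6))
})

test_that("expression model matches the normal-equations oracle", {
  set.seed(40)
  n <- 8
  sex <- rep(0:1, 4)
  meth <- runif(n)
  y <- 1 + 0.5 * sex - 2 * meth + rnorm(n, 0, 0.1)
  got <- expression_model(y, sex, meth)
  X <- cbind(1, sex, meth)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(c(got$b0, got$b1, got$b2), unname(drop(beta)), tolerance = 1e-10)
  s2 <- sum((y - X %*% beta)^2) / (n - 3)
  se <- sqrt(diag(s2 * solve(t(X) %*% X)))
  expect_equal(got$se_b2, unname(se[3]), tolerance = 1e-10)
  expect_error(expression_model(y, sex, meth, covariate_design = cbind(meth)),
               "collinear")
})

test_that("joint-model b2 equals the Frisch-Waugh partial coefficient", {
  set.seed(41)
  n <- 60
  sex <- rep(0:1, n / 2)
  Z <- cbind(1, sex, rnorm(n))
  meth <- runif(n)
  y <- rnorm(n)
  full <- expression_model(y, sex, meth, covariate_design = Z[, 3, drop = FALSE])
  ey <- stats::lm.fit(Z, y)$residuals
  em <- stats::lm.fit(Z, meth)$residuals
  expect_equal(full$b2, unname(stats::lm.fit(cbind(em), ey)$coefficients),
               tolerance = 1e-10)
})

test_that("null coefficients reject at the nominal rate", {
  set.seed(42)
  n <- 50
  hits <- replicate(400, {
    sex <- rep(0:1, n / 2)
    got <- expression_model(rnorm(n), sex, runif(n))
    c(got$p_b1 < 0.05, got$p_b2 < 0.05)
  })
  expect_gt(mean(hits[1, ]), 0.02); expect_lt(mean(hits[1, ]), 0.09)
  expect_gt(mean(hits[2, ]), 0.02); expect_lt(mean(hits[2, ]), 0.09)
})

test_that("significance rules and the printed threshold behave as stated", {
  expect_equal(signif(bonferroni_threshold(0.05, 585031), 3), 8.55e-08)
  recs <- data.frame(cpg_id = c("a", "b", "c"), gene = c("x", "y", "z"),
                     distance_bp = 0, b0 = 0, b1 = -1, b2 = -1,
                     p_b1 = c(1e-10, 1e-10, 0.5),
                     p_b2 = c(1e-10, 0.5, 1e-10), n = 100,
                     stringsAsFactors = FALSE)
  both <- significant_pairs(recs, alpha = 0.05, n_pairs = 100, rule = "both")
  expect_identical(both$cpg_id, "a")
  meth <- significant_pairs(recs, alpha = 0.05, n_pairs = 100,
                            rule = "methylation_only")
  expect_setequal(meth$cpg_id, c("a", "c"))
  either <- significant_pairs(recs, alpha = 0.05, n_pairs = 100, rule = "either")
  expect_equal(nrow(either), 3)
  none <- significant_pairs(transform(recs, p_b1 = 0.5, p_b2 = 0.5),
                            alpha = 0.05, n_pairs = 100)
  expect_equal(nrow(none), 0)
})

test_that("planted cis effects are recovered with correct signs", {
  sim <- small_sim(43)
  expr <- generate_expression(sim)
  linked <- expr$truth[expr$truth$linked, ]
  cov <- sim$cohorts[[1]]$covariates
  beta <- sim$cohorts[[1]]$beta
  sex <- cov$sex
  ok_b1 <- 0L; ok_b2 <- 0L; within_3se <- 0L
  for (i in seq_len(nrow(linked))) {
    got <- expression_model(expr$expression[linked$gene[i], ], sex,
                            beta[linked$cpg_id[i], ])
    ok_b1 <- ok_b1 + (got$b1 < 0)
    ok_b2 <- ok_b2 + (got$b2 < 0)
    within_3se <- within_3se + (abs(got$b2 - linked$b2[i]) < 3 * got$se_b2)
  }
  expect_gte(ok_b1 / nrow(linked), 0.95)
  expect_gte(within_3se / nrow(linked), 0.9)   # OLS recovery of the planted b2
  # unlinked genes show null coefficients
  unlinked <- expr$truth$gene[!expr$truth$linked][1:20]
  b1s <- vapply(unlinked, function(g)
    expression_model(expr$expression[g, ], sex,
                     beta[sample(rownames(beta), 1), ])$b1, numeric(1))
  expect_lt(abs(mean(b1s)), 0.1)
})

test_that("decoy genes beyond the window never pair with their CpG", {
  sim <- small_sim(44)
  expr <- generate_expression(sim)
  linked <- expr$truth[expr$truth$linked, ]
  cpg_pos <- sim$annotation[match(linked$cpg_id, sim$annotation$probe_id),
                            c("probe_id", "chromosome", "position")]
  pairs <- pair_cpg_genes(cpg_pos, expr$gene_coordinates, window = 1e6)
  # every linked gene is reachable from its CpG
  hit <- merge(linked, pairs, by.x = c("cpg_id", "gene"),
               by.y = c("cpg_id", "gene"))
  expect_equal(nrow(hit), nrow(linked))
  # decoy genes are placed beyond the window around the first linked CpGs:
  # none of them may pair with the CpG they were placed next to
  n_decoy <- min(10, sum(!expr$truth$linked))
  decoy_genes <- expr$gene_coordinates$gene[nrow(linked) + seq_len(n_decoy)]
  decoy_cpgs <- linked$cpg_id[seq_len(n_decoy)]
  bad <- mapply(function(g, cg) any(pairs$gene == g & pairs$cpg_id == cg),
                decoy_genes, decoy_cpgs)
  expect_false(any(bad))
})
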