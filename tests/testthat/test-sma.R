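test_that("residualization matches the normal-equations oracle", {
  set.seed(1)
  X <- cbind(1, rnorm(6), runif(6))
  colnames(X) <- c("(Intercept)", "age", "bmi")
  y <- rnorm(6)
  oracle <- y - X %*% solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, X), drop(oracle), tolerance = 1e-10)
  # orthogonality to every design column
  r <- residualize(y, X)
  expect_lt(max(abs(t(X) %*% r)), 1e-10)
  # intercept-only design is centering; constant beta gives zero residuals
  X0 <- matrix(1, 6, 1)
  expect_equal(residualize(y, X0), y - mean(y), tolerance = 1e-12)
  expect_equal(residualize(rep(0.4, 6), X), rep(0, 6), tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  X <- cbind(`(Intercept)` = 1, a = 1:6, twice_a = 2 * (1:6))
  expect_error(residualize(rnorm(6), X), "twice_a")
})

test_that("missing betas use case-wise deletion per probe", {
  set.seed(2)
  X <- cbind(1, rnorm(10))
  y <- rnorm(10); y[c(3, 7)] <- NA
  r <- residualize(y, X)
  expect_true(all(is.na(r[c(3, 7)])))
  ok <- !is.na(y)
  expect_equal(r[ok], stats::lm.fit(X[ok, ], y[ok])$residuals, tolerance = 1e-12)
})

test_that("sma reproduces the hand-computed correlation and handles extremes", {
  rec <- sma(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1))
  expect_equal(rec$r, 0.8944272, tolerance = 1e-6)
  expect_equal(rec$direction, 1L)
  perfect <- sma(c(0, 0, 1, 1, 0, 1), c(0, 0, 1, 1, 0, 1))
  expect_equal(perfect$r, 1)
  expect_gt(perfect$p, 0)          # no overflow / no exact zero
  neg <- sma(-c(0, 0, 1, 1, 0, 1), c(0, 0, 1, 1, 0, 1))
  expect_equal(neg$r, -1)
  deg <- sma(rep(0.5, 5), c(0, 1, 0, 1, 0))
  expect_true(deg$degenerate)
})

test_that("bonferroni thresholds reproduce the printed study constants", {
  expect_equal(signif(bonferroni_threshold(0.05, 10222), 3), 4.89e-06)
  expect_equal(signif(bonferroni_threshold(0.05, 585031), 3), 8.55e-08)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0))
  expect_error(bonferroni_threshold(1.2, 10))
})

test_that("residual-then-correlate relates to the partial correlation exactly", {
  # with sex left unresidualized, r equals the partial correlation scaled by
  # sd(sex residual)/sd(sex); when sex is orthogonal to the covariates in
  # sample the two coincide
  set.seed(3)
  n <- 40
  X <- cbind(1, rnorm(n))
  sex <- rep(0:1, n / 2)
  y <- rnorm(n)
  r_pkg <- sma(residualize(y, X), sex)$r
  ey <- stats::lm.fit(X, y)$residuals
  es <- stats::lm.fit(X, sex)$residuals
  partial <- stats::cor(ey, es)
  expect_equal(r_pkg, partial * stats::sd(es) / stats::sd(sex), tolerance = 1e-12)
  # orthogonal case: balanced sex against an orthogonalized covariate
  X2 <- cbind(1, residualize(rnorm(n), cbind(1, sex)))
  y2 <- rnorm(n)
  expect_equal(sma(residualize(y2, X2), sex)$r,
               stats::cor(stats::lm.fit(X2, y2)$residuals,
                          stats::lm.fit(X2, sex)$residuals),
               tolerance = 1e-10)
})

test_that("r is affine-invariant in beta and antisymmetric in sex labels", {
  set.seed(4)
  y <- runif(30); sex <- rep(0:1, 15)
  X <- matrix(1, 30, 1)
  r0 <- sma(residualize(y, X), sex)$r
  expect_equal(sma(residualize(0.2 + 3 * y, X), sex)$r, r0, tolerance = 1e-12)
  expect_equal(sma(residualize(y, X), 1 - sex)$r, -r0, tolerance = 1e-12)
})

test_that("sma_cohort fast path equals per-probe computation", {
  sim <- small_sim(5)
  beta <- sim$cohorts[[1]]$beta[1:40, ]
  cov <- sim$cohorts[[1]]$covariates
  tab <- sma_cohort(beta, cov)
  X <- build_design(cov)
  for (i in c(1, 17, 40)) {
    rec <- sma(residualize(beta[i, ], X), cov$sex)
    expect_equal(tab$r[i], rec$r, tolerance = 1e-10)
    expect_equal(tab$p[i], rec$p, tolerance = 1e-8)
  }
  expect_true(all(abs(tab$r) <= 1, na.rm = TRUE))
  expect_true(all(tab$p > 0 & tab$p <= 1, na.rm = TRUE))
})

test_that("power at the Bonferroni threshold matches the analytic oracle", {
  sim <- generate_cohorts(simulation_config(
    n_probes = 1000, n_samples = 500, n_cohorts = 1,
    fraction_sex_associated = 1, effect_size_r = c(0.3, 0.3),
    n_crosshyb_probes = 0, block_rho = 0, seed = 8))
  tab <- sma_cohort(sim$cohorts[[1]]$beta, sim$cohorts[[1]]$covariates)
  n <- 500; m <- 1000
  thr <- bonferroni_threshold(0.05, m)
  observed <- mean(tab$p < thr)
  # closed-form power of the correlation t-test via the Fisher-z normal
  # approximation
  tcrit <- stats::qt(1 - thr / 2, df = n - 2)
  rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
  power <- stats::pnorm((atanh(0.3) - atanh(rcrit)) * sqrt(n - 3))
  expect_lt(abs(observed - power), 0.05)
})

test_that("best CpG per gene picks minimum p with lexicographic ties", {
  ann <- data.frame(
    probe_id = sprintf("cg%02d", 1:8),
    chromosome = "1", position = 1:8 * 100,
    gene_names = c("A", "A", "B", "B;C", "C", "D", "D", "D"),
    cgi_relation = factor(rep("open_sea", 8), levels = levels(tiny_annotation()$cgi_relation)),
    probe_sequence = NA_character_, stringsAsFactors = FALSE)
  tab <- data.frame(probe_id = ann$probe_id,
                    p = c(0.01, 0.001, 0.5, 0.2, 0.2, 0.3, 0.3, 0.05),
                    stringsAsFactors = FALSE)
  out <- best_cpg_per_gene(tab, ann)
  expect_equal(out$best_probe_id[out$gene == "A"], "cg02")   # smaller p wins
  expect_equal(out$best_probe_id[out$gene == "B"], "cg04")
  # C: cg04 and cg05 tie at p = 0.2 -> lexicographically first probe
  expect_equal(out$best_probe_id[out$gene == "C"], "cg04")
  expect_equal(out$best_probe_id[out$gene == "D"], "cg08")
  expect_equal(out$n_probes_of_gene[order(out$gene)], c(2L, 2L, 2L, 3L))
})
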