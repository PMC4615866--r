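test_that("subsampling is Bernoulli, seed-reproducible, and identity at prob 1", {
  ids <- sprintf("cg%05d", 1:20000)
  expect_identical(subsample_sites(ids, prob = 1), ids)
  s1 <- subsample_sites(ids, prob = 0.2, seed = 30)
  s2 <- subsample_sites(ids, prob = 0.2, seed = 30)
  expect_identical(s1, s2)
  # binomial moments: 4000 +/- 4 * sqrt(20000 * 0.2 * 0.8)
  expect_lt(abs(length(s1) - 4000), 4 * sqrt(20000 * 0.16))
  expect_error(subsample_sites(ids, prob = 0), "prob")
})

test_that("CGI shore test reproduces the chi-square oracle on printed-style counts", {
  total <- c(island = 26159, shore = 18888, shelf = 7203, open_sea = 26484)
  sig <- c(island = 51, shore = 97, shelf = 19, open_sea = 64)
  res <- cgi_enrichment_counts(total, sig)
  # independent 2x2 chi-square oracle from first principles
  tab <- matrix(c(97, 18888 - 97, 231 - 97, 59846 - 134), 2, 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - E)^2 / E)
  expect_equal(res$chi2, chi2, tolerance = 1e-10)
  expect_lt(res$p, 1e-8)
  expect_gt(res$observed["significant", "shore"],
            res$expected["significant", "shore"])   # overrepresentation
  # expected counts reproduce the observed margins exactly
  expect_equal(rowSums(res$expected), rowSums(res$observed), tolerance = 1e-9)
  expect_equal(colSums(res$expected), colSums(res$observed), tolerance = 1e-9)
  # excluding shores drops the signal on these counts
  noshore <- cgi_enrichment_counts(total, sig, exclude = "shore")
  expect_equal(noshore$df, 2L)
  expect_gt(noshore$p, 0.05)
})

test_that("homogeneous significance rates give a null chi-square", {
  total <- c(island = 100, shore = 200, shelf = 50, open_sea = 150)
  sig <- total / 10
  res <- cgi_enrichment_counts(total, sig)
  expect_equal(res$chi2, 0, tolerance = 1e-10)
  expect_equal(res$p, 1, tolerance = 1e-10)
})

test_that("label interface collapses north/south and rejects missing categories", {
  set.seed(31)
  rel <- sample(c("island", "shore_north", "shore_south", "shelf_north",
                  "shelf_south", "open_sea"), 500, replace = TRUE)
  sig <- runif(500) < 0.1
  res <- cgi_enrichment(rel, sig)
  expect_equal(sum(res$observed), 500)
  expect_error(cgi_enrichment(rep("island", 50), runif(50) < 0.5),
               "absent")
})

test_that("hypergeometric tail matches enumeration and edge identities", {
  expect_equal(hypergeometric_tail(10, 4, 5, 3), 66 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(10, 4, 5, 0), 1)
  # k = min(K, n): single-term tail
  expect_equal(hypergeometric_tail(10, 4, 5, 4),
               choose(4, 4) * choose(6, 1) / choose(10, 5), tolerance = 1e-12)
  set.seed(32)
  for (i in 1:10) {
    N <- sample(10:200, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    expect_equal(hypergeometric_tail(N, K, n, k),
                 oracle_hyper_tail(N, K, n, k), tolerance = 1e-9)
    # ge - gt tail difference is the point mass at k
    expect_equal(hypergeometric_tail(N, K, n, k, "ge") -
                   hypergeometric_tail(N, K, n, k, "gt"),
                 stats::dhyper(k, K, N - K, n), tolerance = 1e-9)
  }
  expect_error(hypergeometric_tail(10, 12, 5, 3), "inconsistent")
})

test_that("imprinted Spearman matches hand midranks and flags extremes", {
  p <- c(1e-5, 1e-4, 0.5, 0.2, 0.8, 0.2)
  flag <- c(1, 0, 0, 1, 0, 0)
  got <- imprinted_spearman(p, flag)
  # hand midrank computation: ranks of -log10 p and of the binary flag
  expect_equal(got$rho, stats::cor(rank(-log10(p)), rank(flag)),
               tolerance = 1e-12)
  # imprinted genes holding the smallest p-values maximize rho over placements
  set.seed(33)
  p2 <- sort(runif(20))
  best <- imprinted_spearman(p2, c(rep(1, 4), rep(0, 16)))$rho
  for (i in 1:20) {
    flags <- sample(c(rep(1, 4), rep(0, 16)))
    expect_lte(imprinted_spearman(p2, flags)$rho, best + 1e-12)
  }
  expect_error(imprinted_spearman(p, rep(1, 6)), "constant")
})

test_that("imprinted Spearman p-values are calibrated under the null", {
  set.seed(34)
  reject <- mean(replicate(300, {
    p <- runif(150)
    flag <- sample(c(rep(1, 10), rep(0, 140)))
    imprinted_spearman(p, flag)$p < 0.05
  }))
  expect_gt(reject, 0.02)
  expect_lt(reject, 0.09)
})

test_that("PWF is flat without bias and recovers a planted monotone trend", {
  set.seed(35)
  counts <- sample(1:60, 2000, replace = TRUE)
  flat <- fit_pwf(runif(2000) < 0.1, counts)
  expect_lt(diff(range(flat$weights)), 0.05)
  expect_equal(mean(flat$weights), flat$target_rate, tolerance = 1e-6)

  prob <- counts / max(counts) * 0.4
  sig <- runif(2000) < prob
  pwf <- fit_pwf(sig, counts, genes = sprintf("g%04d", 1:2000))
  # monotone non-decreasing in probe count
  ord <- order(counts)
  expect_true(all(diff(pwf$weights[ord]) >= -1e-12))
  expect_gt(stats::cor(pwf$weights, prob, method = "spearman"), 0.9)
  expect_error(fit_pwf(rep(TRUE, 10), 1:10), "contrast")
  expect_error(fit_pwf(c(TRUE, FALSE), c(3, 3)), "distinct")
})

test_that("Wallenius machinery is exact against an independent integral oracle", {
  # independent route: the classical integral representation of the pmf
  oracle_dwall <- function(x, m1, m2, n, w) {
    D <- w * (m1 - x) + (m2 - (n - x))
    f <- function(t) choose(m1, x) * choose(m2, n - x) *
      (1 - t^(w / D))^x * (1 - t^(1 / D))^(n - x)
    stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
  }
  for (cfg in list(c(5, 10, 6, 2), c(8, 12, 10, 0.5), c(4, 4, 4, 3))) {
    m1 <- cfg[1]; m2 <- cfg[2]; n <- cfg[3]; w <- cfg[4]
    pmf <- wallenius_pmf(m1, m2, n, w)
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    for (x in 0:min(m1, n))
      expect_equal(unname(pmf[x + 1]), oracle_dwall(x, m1, m2, n, w),
                   tolerance = 1e-8)
  }
  # odds 1 reduces exactly to the central hypergeometric
  expect_equal(wallenius_tail(3, 6, 14, 8, 1),
               hypergeometric_tail(20, 6, 8, 3), tolerance = 1e-12)
})

test_that("weighted category test reduces to hypergeometric for a constant PWF", {
  genes <- sprintf("g%03d", 1:200)
  pwf <- structure(list(weights = stats::setNames(rep(0.1, 200), genes),
                        target_rate = 0.1), class = "pwf")
  category <- genes[1:30]
  sig <- genes[seq(1, 200, by = 7)]
  got <- weighted_category_test(category, sig, pwf)
  ref <- hypergeometric_tail(200, 30, length(sig),
                             length(intersect(category, sig)))
  expect_equal(got$p, ref, tolerance = 1e-6)
})

test_that("Wallenius p agrees with the weighted-sampling oracle on a toy universe", {
  set.seed(36)
  genes <- sprintf("g%02d", 1:50)
  w <- stats::setNames(ifelse(genes %in% genes[1:10], 0.3, 0.1), genes)
  pwf <- structure(list(weights = w, target_rate = mean(w)), class = "pwf")
  category <- genes[1:10]          # category coincides with the high-weight genes
  sig <- genes[c(1:4, 20, 30, 40)]
  got <- weighted_category_test(category, sig, pwf)
  n_draws <- 100000
  urn <- w / (1 - w)            # urn weights are the odds implied by the PWF
  hits <- vapply(seq_len(n_draws), function(b)
    sum(sample(genes, length(sig), prob = urn) %in% category), integer(1))
  p_mc <- mean(hits >= got$k)
  se <- sqrt(p_mc * (1 - p_mc) / n_draws)
  expect_lt(abs(got$p - p_mc), 3 * se + 1e-12)
})

test_that("weighted category test is calibrated on a biased null universe", {
  set.seed(37)
  genes <- sprintf("g%04d", 1:800)
  counts <- sample(1:50, 800, replace = TRUE)
  reject <- 0L; runs <- 200
  for (b in seq_len(runs)) {
    prob <- 0.02 + 0.1 * counts / max(counts)
    sig_flag <- runif(800) < prob
    pwf <- fit_pwf(sig_flag, counts, genes = genes)
    category <- sample(genes, 60)      # category independent of the bias
    p <- weighted_category_test(category, genes[sig_flag], pwf)$p
    if (p < 0.05) reject <- reject + 1L
  }
  expect_gte(reject / runs, 0.01)
  expect_lte(reject / runs, 0.10)
})

test_that("plain gene-set enrichment validates its universe", {
  genes <- sprintf("g%02d", 1:40)
  res <- geneset_enrichment(genes[1:5], genes[c(1, 2, 10)], genes)
  expect_equal(res$k, 2L)
  expect_equal(res$p, oracle_hyper_tail(40, 5, 3, 2), tolerance = 1e-10)
  expect_error(geneset_enrichment(c("none"), genes[1], genes), "intersect")
})
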