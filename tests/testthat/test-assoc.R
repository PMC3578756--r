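test_that("Fisher allele test matches enumeration and stats::fisher.test", {
  # [[12, 388], [3, 397]]: minor counts 12 in cases, 3 in controls
  p <- .fisher2x2_cpp(12L, 388L, 3L, 397L)
  expect_equal(round(p, 5), 0.03350)
  expect_equal(p, fisher_enum_oracle(12, 388, 3, 397))
  expect_equal(p, fisher.test(matrix(c(12, 388, 3, 397), 2,
                                     byrow = TRUE))$p.value,
               tolerance = 1e-10)
  expect_equal(.fisher2x2_cpp(10L, 10L, 10L, 10L), 1)
  # symmetry under case/control swap
  expect_equal(.fisher2x2_cpp(7L, 23L, 2L, 28L),
               .fisher2x2_cpp(2L, 28L, 7L, 23L))
  # spot grid against both oracles
  set.seed(1)
  for (i in 1:60) {
    a <- rbinom(1, 15, 0.4); b <- rbinom(1, 20, 0.5)
    cc <- rbinom(1, 15, 0.2); d <- rbinom(1, 20, 0.6)
    ours <- .fisher2x2_cpp(a, b, cc, d)
    expect_equal(ours, fisher_enum_oracle(a, b, cc, d), tolerance = 1e-12)
    expect_equal(ours,
                 fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("fisher_allele_pvalues works from panel dosages", {
  # 10 cases all carrying the minor allele once, 10 controls without
  H <- matrix(0L, 40, 1)
  H[seq(1, 20, 2), 1] <- 1L
  panel <- toy_panel(H, rep(c("case", "control"), each = 10))
  expect_equal(fisher_exact_allele_test(panel, 1),
               fisher_enum_oracle(10, 10, 0, 20))
})

test_that("ESM statistic reproduces its defining algebra", {
  # markers exactly at the null expectation give Z = 0
  L <- 9
  p_null <- (1:L) / (L + 1)
  expect_equal(esm_statistic(p_null, M = 4), 0)
  # worked two-marker example
  p <- c(0.001, 0.01, 3:9 / 10)
  expect_equal(esm_statistic(p, M = 2), (3 - 1) + (2 + log10(2 / 10)),
               tolerance = 1e-12)
  expect_equal(round(esm_statistic(p, M = 2), 4), 3.3010)
  # monotone: shrinking any included p strictly increases Z
  p2 <- p
  p2[2] <- 0.002
  expect_gt(esm_statistic(p2, M = 2), esm_statistic(p, M = 2))
  # invariant to marker order
  expect_equal(esm_statistic(sample(p), M = 2), esm_statistic(p, M = 2))
  # M larger than L truncates
  expect_equal(esm_statistic(p, M = 50), esm_statistic(p, M = L))
  expect_error(esm_statistic(numeric(0), M = 2), "empty")
  # alternative null-quantile hook
  expect_equal(esm_statistic(p, M = 1, null_quantile = function(i, L) i / L),
               3 - log10(9))
})

test_that("logistic scan handles balanced, separating, monomorphic markers", {
  n <- 40
  dos_bal <- rep(c(0L, 1L, 2L, 1L, 0L), 8)         # identical in both groups
  dos_sep <- c(rep(1L, 20), rep(0L, 20))           # carried only by cases
  dos_mono <- rep(1L, 40)
  H <- matrix(0L, 2 * n, 3)
  H[2 * which(dos_bal >= 1) - 1, 1] <- 1L
  H[2 * which(dos_bal == 2), 1] <- 1L
  H[2 * which(dos_sep == 1) - 1, 2] <- 1L
  H[seq(1, 2 * n, 2), 3] <- 1L
  panel <- toy_panel(H, rep(c("case", "control"), each = 20))
  p_lrt <- logistic_scan(panel, method = "lrt")
  p_wald <- logistic_scan(panel, method = "wald")
  expect_equal(p_lrt[1], 1, tolerance = 1e-6)      # no signal
  expect_lt(p_lrt[2], 1e-6)                        # separation: tiny p, no crash
  expect_true(is.finite(p_wald[2]))                # Wald: conservative, finite
  expect_true(is.na(p_lrt[3]) && is.na(p_wald[3]))  # monomorphic skipped
  expect_equal(logistic_single_marker(panel, 1, method = "lrt"), p_lrt[1])
})

test_that("Madsen-Browning rank sum behaves at its boundary cases", {
  n <- 20
  # all dosages zero: every score ties, rank sum = n_case * (n + 1) / 2
  D0 <- matrix(0L, n, 3)
  expect_equal(madsen_browning_stat(D0, rep(c(1, 0), each = 10)),
               10 * (n + 1) / 2)
  # one marker carried only by cases pushes the case rank sum above the mean
  D1 <- cbind(c(rep(1L, 5), rep(0L, 15)))
  expect_gt(madsen_browning_stat(D1, rep(c(1, 0), each = 10)),
            10 * (n + 1) / 2)
})

test_that("Hotelling T2 reduces to the squared pooled t at K = 1 and", {
  set.seed(2)
  x <- rbinom(30, 2, 0.3)
  while (var(x) == 0) x <- rbinom(30, 2, 0.3)
  is_case <- rep(c(TRUE, FALSE), each = 15)
  X <- cbind(1 - x)
  expect_equal(li_leal_stat(X, is_case), t2_onecolumn_oracle(1 - x, is_case),
               tolerance = 1e-10)
  # identical case/control score matrices: statistic 0
  Xs <- rbind(matrix(rbinom(45, 2, 0.4), 15), matrix(0, 15, 3))
  Xs[16:30, ] <- Xs[1:15, ]
  expect_equal(li_leal_stat(Xs, is_case), 0, tolerance = 1e-10)
})

test_that("li_leal_test's fast path agrees with the direct statistic", {
  set.seed(3)
  H <- matrix(rbinom(2 * 60 * 12, 1, 0.15), 120, 12)
  H <- H[, colSums(H) > 0 & colSums(H) < 120, drop = FALSE]
  panel <- toy_panel(H, rep(c("case", "control"), each = 30))
  res <- li_leal_test(panel, K = ncol(H), n_perm = 50)
  direct <- li_leal_stat(1 - panel$dosages[, order(panel$markers$maf_panel)],
                         panel$status == "case")
  expect_equal(res$observed, direct, tolerance = 1e-6)
})

test_that("permutation machinery is calibrated and deterministic", {
  set.seed(4)
  H <- matrix(rbinom(2 * 40 * 8, 1, 0.2), 80, 8)
  H <- H[, colSums(H) > 0 & colSums(H) < 80, drop = FALSE]
  panel <- toy_panel(H, rep(c("case", "control"), each = 20))
  # a statistic ignoring the labels gives z = 0, p = 1
  res0 <- permutation_test(panel, function(p, ind) 42, n_perm = 100,
                           statistic_name = "constant")
  expect_equal(res0$z, 0)
  expect_equal(res0$p, 1)
  # z/p bookkeeping
  set.seed(5)
  res <- esm_test(panel, M = 5, n_perm = 200, min_minor_count = 1)
  expect_equal(res$z, (res$observed - res$perm_mean) / res$perm_sd)
  expect_equal(res$p, min(1, 2 * pnorm(-abs(res$z))))
  # identical seed, identical result
  set.seed(6)
  r1 <- esm_test(panel, M = 5, n_perm = 100, min_minor_count = 1)
  set.seed(6)
  r2 <- esm_test(panel, M = 5, n_perm = 100, min_minor_count = 1)
  expect_identical(r1$perm_stats, r2$perm_stats)
  # one-tailed option
  set.seed(7)
  r3 <- madsen_browning_test(panel, n_perm = 100, alternative = "greater")
  expect_equal(r3$p, pnorm(r3$z, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("region tests recover a planted association", {
  # cases enriched for several rare variants spread over markers
  set.seed(8)
  n <- 60
  H <- matrix(rbinom(2 * n * 30, 1, 0.04), 2 * n, 30)
  # plant: odd rows (first haplotype) of cases get extra rare alleles
  for (j in 1:12) H[2 * sample(1:20, 6) - 1, j] <- 1L
  H <- H[, colSums(H) > 0 & colSums(H) < 2 * n, drop = FALSE]
  panel <- toy_panel(H, rep(c("case", "control"), c(20, 40)))
  res <- esm_test(panel, M = 10, n_perm = 300, min_minor_count = 2)
  expect_gt(res$z, 2)
  res_mb <- madsen_browning_test(panel, n_perm = 300)
  expect_gt(res_mb$z, 1)
})
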