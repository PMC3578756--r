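toy_sample <- function(haps, mutations) {
  structure(list(haplotypes = haps, mutations = mutations,
                 n = length(haps)), class = "hap_sample")
}

mut4 <- data.frame(position = c(0.1, 0.3, 0.6, 0.9),
                   effect = c(0, 0.1, 0, 0.05),
                   origin_generation = 0L, count = 0L)

test_that("diversity on toy samples matches brute-force pairwise counts", {
  # two identical haplotypes: pi = 0
  s0 <- toy_sample(list(c(1L, 2L), c(1L, 2L)), mut4)
  expect_equal(diversity(s0)$pi, 0)
  expect_equal(diversity(s0)$S, 0)
  # mixed sample, checked against explicit Hamming enumeration
  haps <- list(c(1L, 2L), c(2L, 3L), integer(0), c(1L, 2L, 4L))
  s <- toy_sample(haps, mut4)
  H <- matrix(0L, 4, 4)
  for (i in 1:4) H[i, haps[[i]]] <- 1L
  expect_equal(diversity(s)$pi, pi_bruteforce(H))
  expect_equal(diversity(s)$S, 4)
  # class splits
  expect_equal(diversity(s, "causative")$S, 2)
  expect_equal(diversity(s, "neutral")$S, 2)
})

test_that("pi from pairwise differences equals the SFS identity", {
  set.seed(1)
  for (rep in 1:5) {
    n <- 12
    m <- 30
    H <- matrix(rbinom(n * m, 1, 0.2), n, m)
    haps <- apply(H, 1, function(x) which(x == 1L), simplify = FALSE)
    mut <- data.frame(position = seq_len(m) / (m + 1),
                      effect = rep(c(0, 0.1), length.out = m),
                      origin_generation = 0L, count = 0L)
    s <- toy_sample(haps, mut)
    expect_equal(diversity(s)$pi, pi_from_sfs(sfs(s)))
    expect_equal(diversity(s)$pi, pi_bruteforce(H))
  }
})

test_that("sfs is empty for monomorphic input and ~1/i for neutral sims", {
  s0 <- toy_sample(list(integer(0), integer(0)), mut4)
  expect_equal(sum(sfs(s0)$sites), 0)
  # aggregate neutral SFS over replicates against the 1/i expectation
  agg <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    p <- sim_params_scaled(N = 120, theta = 8, theta_d = 0, rho = 8,
                           n_generations = 960)
    pop <- evolve(p, seed = 300 + r)
    samp <- population_sample(pop, 5)
    agg <- agg + sfs(samp, "neutral")$sites
  }
  expected <- (1 / 1:9) / sum(1 / 1:9)
  observed <- agg / sum(agg)
  expect_lt(max(abs(observed - expected)), 0.05)
})

test_that("selection skews the causative SFS toward rare variants", {
  prop1 <- function(lambda, seed) {
    # at lambda = 0 the causative-site mutations all have effect 0, so the
    # neutral baseline is read from the "all" class of the same runs
    cls <- if (lambda > 0) "causative" else "all"
    agg <- 0
    for (r in 1:12) {
      p <- sim_params_scaled(N = 150, theta = 0, theta_d = 8, rho = 10,
                             lambda_effect = lambda, no_neutral = TRUE,
                             sigma_s = 0.1, n_generations = 1200)
      pop <- evolve(p, seed = seed + r)
      agg <- agg + sfs(population_sample(pop, 10), cls)$sites
    }
    agg[1] / sum(agg)
  }
  set.seed(2)
  p_neutral <- prop1(0, 500)
  p_selected <- prop1(0.5, 600)
  expect_gt(p_selected, p_neutral)
})

test_that("r2 has its closed-form values on toy panels", {
  # 4 haplotypes {AB, Ab, aB, ab} in equal counts: r2 = 0
  H <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
  panel <- toy_panel(H, c("case", "control"))
  expect_equal(ld_r2(panel, 1, 2), 0)
  expect_equal(ld_r2(panel, 1, 1), 1)
  # perfect coupling
  H2 <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(0L, 0L))
  panel2 <- toy_panel(H2, c("case", "control"))
  expect_equal(ld_r2(panel2, 1, 2), 1)
  # symmetry and label-swap invariance
  set.seed(3)
  H3 <- matrix(rbinom(40, 1, 0.4), 20, 2)
  panel3 <- toy_panel(H3, rep(c("case", "control"), each = 5))
  expect_equal(ld_r2(panel3, 1, 2), ld_r2(panel3, 2, 1))
  H4 <- H3
  H4[, 1] <- 1L - H4[, 1]
  panel4 <- toy_panel(H4, rep(c("case", "control"), each = 5))
  expect_equal(ld_r2(panel4, 1, 2), ld_r2(panel3, 1, 2))
})

test_that("tag analysis ranks causative markers by r2", {
  set.seed(4)
  H <- matrix(rbinom(120, 1, 0.4), 20, 6)
  H[, 2] <- H[, 1]           # causative marker 2 perfectly tags marker 1
  eff <- c(0, 0.1, 0, 0.2, 0, 0)
  panel <- toy_panel(H, rep(c("case", "control"), each = 5), effect = eff)
  res <- tag_analysis(panel, significant_markers = 1L)
  expect_equal(nrow(res$per_marker), 1)
  expect_equal(res$per_marker$top_causal, 2L)
  expect_equal(res$per_marker$top_r2, 1)
  expect_equal(res$per_marker$second_causal, 4L)
  expect_equal(res$n_unique_tagged, 1L)
  # no causative markers -> empty
  panel0 <- toy_panel(H, rep(c("case", "control"), each = 5))
  res0 <- tag_analysis(panel0, significant_markers = 1L)
  expect_equal(nrow(res0$per_marker), 0)
  expect_equal(res0$n_unique_tagged, 0L)
})

test_that("singleton burden splits by genotype at the focal marker", {
  # 4 individuals; markers: 1 = common focal, 2-3 = causative singletons
  H <- rbind(c(1L, 1L, 0L), c(1L, 0L, 0L),   # ind 1: hom focal, 1 singleton
             c(1L, 0L, 1L), c(0L, 0L, 0L),   # ind 2: het focal, 1 singleton
             c(0L, 0L, 0L), c(0L, 0L, 0L),   # ind 3: no copies
             c(1L, 0L, 0L), c(1L, 0L, 0L))   # ind 4: hom focal
  panel <- toy_panel(H, c("case", "case", "control", "control"),
                     effect = c(0, 0.2, 0.2))
  out <- singleton_burden_by_genotype(panel, marker = 1)
  expect_equal(out$n, c(1L, 1L, 2L))
  expect_equal(out$mean, c(0, 1, 0.5))
  # panel without singletons: all zeros
  panel2 <- toy_panel(H[, 1, drop = FALSE],
                      c("case", "case", "control", "control"))
  out2 <- singleton_burden_by_genotype(panel2, marker = 1)
  expect_true(all(out2$mean[out2$n > 0] == 0))
})

test_that("null-marker matching honours the p-value and count rules", {
  H <- cbind(rep(c(1L, 0L), each = 10), rep(c(1L, 0L), 10),
             c(rep(1L, 9), rep(0L, 11)), rep(c(0L, 1L), 10))
  panel <- toy_panel(H, rep(c("case", "control"), each = 5))
  pv <- c(1e-9, 0.5, 1e-6, 0.8)
  # candidates must have p > 1e-4: markers 2 and 4 (counts 10, 10)
  m <- match_null_marker(panel, focal = 1, p_values = pv)
  expect_equal(m, 2L)
  expect_true(match_null_marker(panel, 1, c(1e-9, 1e-5, 1e-6, 0.9)) == 4L)
  expect_true(is.na(match_null_marker(panel, 1, c(1e-9, 1e-5, 1e-6, 1e-5))))
})
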