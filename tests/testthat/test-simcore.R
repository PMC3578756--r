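test_that("initialize_population builds 2N empty haplotypes", {
  pop <- initialize_population(sim_params(N = 5, n_generations = 0))
  expect_length(pop$haplotypes, 10L)
  expect_true(all(lengths(pop$haplotypes) == 0L))
  expect_equal(nrow(pop$mutations), 0L)
  expect_equal(pop$generation, 0L)
  expect_error(sim_params(N = 0), "positive")
})

test_that("evolve with zero generations returns the initial population", {
  p <- sim_params(N = 4, n_generations = 0)
  pop <- evolve(p, seed = 1)
  expect_length(pop$haplotypes, 8L)
  expect_equal(nrow(pop$mutations), 0L)
})

test_that("gametes without recombination or mutation copy one parent", {
  mut <- data.frame(position = c(0.2, 0.5, 0.9), effect = c(0, 0.1, 0),
                    origin_generation = 0L, count = 1L)
  p <- sim_params(N = 2, mu_neutral = 0, mu_causative = 0, r = 0,
                  n_generations = 0)
  set.seed(1)
  for (i in 1:20) {
    g <- make_gamete(c(1L, 3L), 2L, mut, p)
    expect_true(identical(g$haplotype, c(1L, 3L)) ||
                  identical(g$haplotype, 2L))
    expect_equal(nrow(g$mutations), 3L)
  }
})

test_that("crossover gametes respect segment structure and stay sorted", {
  # with mu = 0 every gamete allele comes from a parent, and positions are
  # sorted; with hapA = all sites and hapB = none, the gamete's carried
  # positions form alternating segments of [0,1)
  mut <- data.frame(position = seq(0.05, 0.95, by = 0.1), effect = 0,
                    origin_generation = 0L, count = 1L)
  p <- sim_params(N = 2, mu_neutral = 0, mu_causative = 0, r = 3,
                  n_generations = 0)
  set.seed(2)
  for (i in 1:50) {
    g <- make_gamete(seq_len(10), integer(0), mut, p)$haplotype
    expect_true(all(g %in% 1:10))
    expect_true(!is.unsorted(mut$position[g]))
  }
})

test_that("new causative effects average to lambda", {
  mut <- data.frame(position = numeric(0), effect = numeric(0),
                    origin_generation = integer(0), count = integer(0))
  p <- sim_params(N = 2, mu_neutral = 0, mu_causative = 5, r = 0,
                  lambda_effect = 0.1, n_generations = 0)
  set.seed(3)
  eff <- unlist(lapply(1:400, function(i) {
    make_gamete(integer(0), integer(0), mut, p)$mutations$effect
  }))
  expect_gt(length(eff), 1500)
  expect_true(all(eff > 0))
  # LLN: mean of Exponential(0.1) draws, 4 SE window
  expect_lt(abs(mean(eff) - 0.1), 4 * 0.1 / sqrt(length(eff)))
})

test_that("N = 1 without mutation or recombination reproduces the parent", {
  mut3 <- data.frame(position = c(0.1, 0.4, 0.8), effect = c(0.05, 0.03, 0.02),
                     origin_generation = 0L, count = c(2L, 1L, 1L))
  pop <- structure(list(generation = 0L, N = 1L,
                        haplotypes = list(c(1L, 2L), c(1L, 3L)),
                        mutations = mut3,
                        fixed = data.frame(position = numeric(0),
                                           effect = numeric(0),
                                           origin_generation = integer(0),
                                           generation_fixed = integer(0)),
                        fixed_burden = 0, optimum = 0,
                        params = sim_params(N = 1, mu_neutral = 0,
                                            mu_causative = 0, r = 0,
                                            lambda_effect = 0.1,
                                            n_generations = 0)),
                   class = "wf_population")
  set.seed(4)
  off <- next_generation(pop)
  # site 1 is shared by both parental haplotypes and survives (or fixes);
  # each offspring haplotype must equal one of the parental haplotypes
  pos_par <- lapply(pop$haplotypes, function(h) mut3$position[h])
  pos_off <- lapply(off$haplotypes,
                    function(h) sort(c(off$mutations$position[h],
                                       off$fixed$position)))
  for (h in pos_off)
    expect_true(any(vapply(pos_par, function(pp) identical(sort(pp), h),
                           logical(1))))
})

test_that("runs are deterministic given the seed", {
  p <- sim_params_scaled(N = 60, theta = 8, theta_d = 2, rho = 8,
                         lambda_effect = 0.1, n_generations = 300)
  a <- evolve(p, seed = 9)
  b <- evolve(p, seed = 9)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$haplotypes, b$haplotypes)
  c2 <- evolve(p, seed = 10)
  expect_false(identical(a$mutations, c2$mutations))
})

test_that("segregating positions are unique and counts match haplotypes", {
  p <- sim_params_scaled(N = 80, theta = 20, theta_d = 5, rho = 20,
                         lambda_effect = 0.2, n_generations = 640)
  pop <- evolve(p, seed = 5)
  expect_gt(nrow(pop$mutations), 0)
  expect_false(anyDuplicated(c(pop$mutations$position,
                               pop$fixed$position)) > 0)
  expect_identical(recount_mutations(pop), pop$mutations$count)
  expect_true(all(pop$mutations$count >= 1L))
  expect_true(all(pop$mutations$count <= 2L * pop$N - 1L))
})

test_that("neutral calibration: pi and S match coalescent expectations", {
  # lambda = 0, theta = 5: E[pi] = 5, E[S_n] = theta * sum(1/i) in a
  # sample of n haplotypes; averaged over replicates, 3 MC SE window
  theta <- 5
  n_rep <- 50
  pis <- numeric(n_rep)
  Ss <- numeric(n_rep)
  n_samp <- 20
  for (r in seq_len(n_rep)) {
    p <- sim_params_scaled(N = 150, theta = theta, theta_d = 0, rho = 10,
                           n_generations = 1200)
    pop <- evolve(p, seed = 100 + r)
    samp <- population_sample(pop, n_samp / 2)
    d <- diversity(samp, "neutral")
    pis[r] <- d$pi
    Ss[r] <- d$S
  }
  expect_lt(abs(mean(pis) - theta), 3 * sd(pis) / sqrt(n_rep))
  ES <- theta * sum(1 / seq_len(n_samp - 1))
  expect_lt(abs(mean(Ss) - ES), 3 * sd(Ss) / sqrt(n_rep))
})

test_that("fixed causative mutations move into the burden and recenter", {
  # tiny population + large effects drive fixations quickly
  p <- sim_params(N = 10, mu_neutral = 0, mu_causative = 0.5, r = 0,
                  lambda_effect = 0.2, sigma_e = 0.01, n_generations = 400)
  pop <- evolve(p, seed = 6)
  expect_gt(nrow(pop$fixed), 0)
  expect_equal(pop$fixed_burden, sum(pop$fixed$effect))
  expect_equal(pop$optimum, pop$fixed_burden)
  # no retained mutation is fixed or lost
  expect_true(all(pop$mutations$count >= 1L &
                    pop$mutations$count <= 2L * pop$N - 1L))
  # with recentering disabled the optimum stays at 0
  p2 <- sim_params(N = 10, mu_neutral = 0, mu_causative = 0.5, r = 0,
                   lambda_effect = 0.2, sigma_e = 0.01, n_generations = 400,
                   recenter_optimum = FALSE)
  pop2 <- evolve(p2, seed = 6)
  expect_equal(pop2$optimum, 0)
})

test_that("population text serialization round-trips", {
  p <- sim_params_scaled(N = 40, theta = 10, theta_d = 2, rho = 10,
                         lambda_effect = 0.1, n_generations = 200)
  pop <- evolve(p, seed = 7)
  dir <- withr::local_tempdir()
  write_population(pop, dir)
  pop2 <- read_population(dir)
  expect_equal(pop2$mutations$position, pop$mutations$position)
  expect_equal(pop2$mutations$count, pop$mutations$count)
  expect_identical(pop2$haplotypes, pop$haplotypes)
  expect_equal(pop2$fixed_burden, pop$fixed_burden)
  expect_equal(pop2$params$mu_causative, pop$params$mu_causative)
})
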