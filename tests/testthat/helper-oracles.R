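# Independent oracles and hand-built fixtures used across the suite.

# Two-sided Fisher exact p by direct enumeration of the hypergeometric
# support with binomial coefficients (independent of the package's kernel).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  m <- a + c
  x <- max(0, m - r2):min(r1, m)
  pr <- choose(m, x) * choose(r1 + r2 - m, r1 - x) / choose(r1 + r2, r1)
  pobs <- pr[x == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Mean pairwise Hamming distance over all haplotype pairs (brute force).
pi_bruteforce <- function(hap_matrix) {
  n <- nrow(hap_matrix)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(hap_matrix[i, ] != hap_matrix[j, ])
  tot / choose(n, 2)
}

# Squared pooled-variance two-sample t statistic (closed form used as the
# K = 1 Hotelling oracle).
t2_onecolumn_oracle <- function(x, is_case) {
  x1 <- x[is_case]
  x0 <- x[!is_case]
  n1 <- length(x1)
  n0 <- length(x0)
  sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  ((mean(x1) - mean(x0))^2) / (sp2 * (1 / n1 + 1 / n0))
}

# Hand-built panel: dosage/haplotype matrices given directly, cases first.
toy_panel <- function(haplotypes, status, effect = NULL, position = NULL,
                      pop_freq = NULL) {
  n <- length(status)
  stopifnot(nrow(haplotypes) == 2 * n)
  m <- ncol(haplotypes)
  dc <- colSums(haplotypes)
  f <- dc / (2 * n)
  minor_is_derived <- f <= 0.5
  dos <- haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
  flip <- which(!minor_is_derived)
  if (length(flip) > 0) dos[, flip] <- 2L - dos[, flip]
  status <- factor(status, levels = c("case", "control"))
  ctl <- which(status == "control")
  if (is.null(pop_freq)) pop_freq <- f
  pop_minor_is_derived <- pop_freq <= 0.5
  d_ctl_derived <- colSums(dos[ctl, , drop = FALSE])
  # q_control in terms of the population-minor allele
  d_der <- haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
  fd_ctl <- colSums(d_der[ctl, , drop = FALSE]) / (2 * length(ctl))
  q_control <- ifelse(pop_minor_is_derived, fd_ctl, 1 - fd_ctl)
  structure(list(
    dosages = dos, haplotypes = haplotypes, status = status,
    markers = data.frame(
      position = if (is.null(position)) seq_len(m) / (m + 1) else position,
      effect = if (is.null(effect)) rep(0, m) else effect,
      origin_generation = rep(0L, m), derived_count = as.integer(dc),
      maf_panel = pmin(f, 1 - f), minor_is_derived = minor_is_derived,
      pop_freq = pop_freq, q_control = q_control),
    phenotypes = NULL, n_cases = sum(status == "case"),
    n_controls = sum(status == "control")), class = "cc_panel")
}

# Small equilibrium population for panel/popgen mechanics (not full scale).
small_sim_pop <- function(N = 200, theta = 20, theta_d = 2, rho = 20,
                          lambda = 0.1, gens = 4 * N, seed = 42) {
  p <- sim_params_scaled(N = N, theta = theta, theta_d = theta_d, rho = rho,
                         lambda_effect = lambda, n_generations = gens)
  evolve(p, seed = seed)
}
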