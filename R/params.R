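#' Simulation parameters
#'
#' Container for the parameters of the forward Wright-Fisher simulation of a
#' single gene region.  Rates are per generation: `mu_neutral` and
#' `mu_causative` are mutation rates per gamete, `r` is the recombination
#' rate per diploid.  `lambda_effect` is the mean of the exponential
#' distribution of causative effect sizes (on the liability scale; 0 means
#' no causative variation), `sigma_e` the environmental standard deviation
#' and `sigma_s` the standard deviation of the Gaussian stabilizing-selection
#' fitness function.
#'
#' @param N Diploid population size.
#' @param mu_neutral Neutral mutation rate per gamete per generation.
#' @param mu_causative Causative mutation rate per gamete per generation.
#' @param r Recombination rate per diploid per generation.
#' @param lambda_effect Mean effect size of new causative mutations.
#' @param sigma_e Environmental standard deviation of the liability.
#' @param sigma_s Standard deviation of the Gaussian stabilizing-selection
#'   function.
#' @param n_generations Number of generations to evolve; defaults to `8 * N`,
#'   the burn-in used throughout for sampling at mutation-selection balance.
#' @param seed Optional integer seed consumed by [evolve()].
#' @param recenter_optimum Logical; when causative mutations fix, add their
#'   effect to every haplotype as a constant "fixed burden" and move the
#'   stabilizing-selection optimum to that constant (default `TRUE`).  With
#'   `FALSE` the optimum stays at 0, so fixations permanently displace the
#'   population from the optimum.
#'
#' @return An object of class `sim_params` (a validated list).
#' @seealso [sim_params_scaled()] for the theta/rho parameterization.
#' @examples
#' p <- sim_params(N = 100, mu_neutral = 0.025, mu_causative = 0.0025,
#'                 r = 0.025, lambda_effect = 0.1, n_generations = 100)
#' p
#' @export
sim_params <- function(N, mu_neutral = 0.00125, mu_causative = 0.000125,
                       r = 0.00125, lambda_effect = 0, sigma_e = 0.075,
                       sigma_s = 1, n_generations = 8L * N, seed = NULL,
                       recenter_optimum = TRUE) {
  stopifnot(length(N) == 1L, is.numeric(N))
  if (N < 1) stop("N must be a positive integer")
  N <- as.integer(N)
  rates <- c(mu_neutral = mu_neutral, mu_causative = mu_causative, r = r,
             lambda_effect = lambda_effect, sigma_e = sigma_e)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates, lambda_effect and sigma_e must be finite and >= 0")
  if (!is.finite(sigma_s) || sigma_s <= 0) stop("sigma_s must be > 0")
  if (n_generations < 0) stop("n_generations must be >= 0")
  structure(list(N = N, mu_neutral = mu_neutral, mu_causative = mu_causative,
                 r = r, lambda_effect = lambda_effect, sigma_e = sigma_e,
                 sigma_s = sigma_s, n_generations = as.integer(n_generations),
                 seed = seed, recenter_optimum = isTRUE(recenter_optimum)),
            class = "sim_params")
}

#' Scaled (theta/rho) parameterization
#'
#' Convenience constructor expressing mutation and recombination as the
#' population-scaled rates `theta = 4*N*mu_neutral`, `theta_d =
#' 4*N*mu_causative` and `rho = 4*N*r`, so that reduced-`N` runs preserve
#' the scaled parameters of the full-size model (`N = 20000`,
#' `theta = rho = 100`, `theta_d = 10`, i.e. a typical 100-kb human region
#' with a causative rate one tenth of the neutral rate).
#'
#' @param N Diploid population size.
#' @param theta Scaled neutral mutation rate `4*N*mu_neutral`.
#' @param theta_d Scaled causative mutation rate `4*N*mu_causative`.
#' @param rho Scaled recombination rate `4*N*r`.
#' @param no_neutral If `TRUE`, set the neutral rate to 0 and simulate only
#'   causative sites (orders of magnitude faster; used for heritability
#'   sweeps where linked neutral markers are not needed).
#' @inheritParams sim_params
#' @param ... Passed on to [sim_params()].
#' @return A `sim_params` object.
#' @examples
#' sim_params_scaled(N = 1000, theta = 100, theta_d = 10, rho = 100,
#'                   lambda_effect = 0.1)
#' @export
sim_params_scaled <- function(N, theta = 100, theta_d = 10, rho = 100,
                              lambda_effect = 0, no_neutral = FALSE, ...) {
  mu_n <- if (no_neutral) 0 else theta / (4 * N)
  sim_params(N = N, mu_neutral = mu_n, mu_causative = theta_d / (4 * N),
             r = rho / (4 * N), lambda_effect = lambda_effect, ...)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Wright-Fisher simulation parameters\n")
  cat(sprintf("  N = %d diploids, %d generations\n", x$N, x$n_generations))
  cat(sprintf("  mu_neutral = %g, mu_causative = %g, r = %g (per gamete/diploid)\n",
              x$mu_neutral, x$mu_causative, x$r))
  cat(sprintf("  theta = %g, theta_d = %g, rho = %g\n",
              4 * x$N * x$mu_neutral, 4 * x$N * x$mu_causative, 4 * x$N * x$r))
  cat(sprintf("  lambda = %g, sigma_e = %g, sigma_s = %g\n",
              x$lambda_effect, x$sigma_e, x$sigma_s))
  invisible(x)
}
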