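#' Haplotype effect sum
#'
#' The phenotypic effect of a haplotype is additive over the causative
#' mutations it carries (neutral mutations contribute 0), plus the
#' population's fixed causative burden.
#'
#' @param hap Integer vector of mutation indices.
#' @param mutations Mutation table with an `effect` column.
#' @param fixed_burden Constant effect carried by every haplotype from fixed
#'   causative mutations (default 0).
#' @return Non-negative effect sum.
#' @export
haplotype_effect <- function(hap, mutations, fixed_burden = 0) {
  fixed_burden + sum(mutations$effect[hap])
}

#' Genotypic value under the gene-based model
#'
#' The genotypic value of a diploid is the geometric mean of its two
#' haplotype effect sums, `sqrt(E1 * E2)`.  This makes mutations within the
#' region non-complementing: only the configuration of effects per
#' haplotype matters (not which sites are homo- or heterozygous), and a
#' mutation-free haplotype fully rescues the phenotype.  By the AM-GM
#' inequality the value is at most the additive mid-value `(E1 + E2) / 2`,
#' i.e. gene action is partially recessive.
#'
#' @param E1,E2 Non-negative haplotype effect sums (vectorized).
#' @return `sqrt(E1 * E2)`.
#' @examples
#' genotypic_value(0.10, 0.15)  # 0.1224745
#' genotypic_value(0, 5)        # one wild-type haplotype rescues: 0
#' @export
genotypic_value <- function(E1, E2) {
  if (any(E1 < 0) || any(E2 < 0)) stop("haplotype effects must be >= 0")
  sqrt(E1 * E2)
}

#' Liability phenotype
#'
#' `P = G + x` with `x ~ Normal(0, sigma_e^2)`; the continuous liability on
#' which case/control status is later thresholded.
#'
#' @param G Genotypic value(s).
#' @param sigma_e Environmental standard deviation.
#' @return Liability vector of the same length as `G`.
#' @export
liability <- function(G, sigma_e) {
  if (sigma_e < 0) stop("sigma_e must be >= 0")
  G + rnorm(length(G), 0, sigma_e)
}

#' Gaussian stabilizing-selection fitness
#'
#' `w = exp(-(P - optimum)^2 / (2 * sigma_s^2))`: relative fitness in
#' `(0, 1]`, maximal at the optimum (0 unless the fixed-burden recentering
#' of [sim_params()] has moved it).
#'
#' @param P Liability value(s).
#' @param sigma_s Stabilizing-selection standard deviation (> 0).
#' @param optimum Phenotypic optimum (default 0).
#' @return Fitness vector in `(0, 1]`.
#' @examples
#' gaussian_fitness(1, sigma_s = 1)  # exp(-0.5)
#' @export
gaussian_fitness <- function(P, sigma_s = 1, optimum = 0) {
  if (sigma_s <= 0) stop("sigma_s must be > 0")
  exp(-((P - optimum)^2) / (2 * sigma_s^2))
}

#' Per-diploid phenotype records for a population
#'
#' Computes, for each of the `N` diploids (haplotypes `2i - 1` and `2i`),
#' the haplotype effect sums `E1` and `E2` (including the fixed burden), the
#' genotypic value `G`, a fresh environmental deviate `x`, the liability
#' `P = G + x` and the relative fitness `w`.
#'
#' @param pop A `wf_population`.
#' @param sigma_e,sigma_s Override the population's parameters if given.
#' @return A data frame of class `phenotype_records` with columns
#'   `E1`, `E2`, `G`, `x`, `P`, `w`.
#' @export
compute_phenotypes <- function(pop, sigma_e = pop$params$sigma_e,
                               sigma_s = pop$params$sigma_s) {
  eff <- pop$mutations$effect
  hap_eff <- vapply(pop$haplotypes, function(h) sum(eff[h]), numeric(1))
  E1 <- pop$fixed_burden + hap_eff[seq(1, length(hap_eff), by = 2)]
  E2 <- pop$fixed_burden + hap_eff[seq(2, length(hap_eff), by = 2)]
  G <- genotypic_value(E1, E2)
  x <- rnorm(length(G), 0, sigma_e)
  P <- G + x
  w <- gaussian_fitness(P, sigma_s, optimum = pop$optimum)
  structure(data.frame(E1 = E1, E2 = E2, G = G, x = x, P = P, w = w),
            class = c("phenotype_records", "data.frame"))
}

#' Broad-sense heritability
#'
#' `H^2 = Var(G) / Var(P)` over the realized population: the fraction of
#' liability variance attributable to genotypic values of the focal gene
#' region.
#'
#' @param records A `phenotype_records` data frame (or any data frame with
#'   columns `G` and `P`).
#' @return `H^2` in `[0, 1]` (up to sampling noise).
#' @export
broad_sense_heritability <- function(records) {
  if (nrow(records) < 2L) stop("need at least 2 phenotype records")
  vp <- var(records$P)
  if (vp == 0) stop("zero phenotypic variance")
  var(records$G) / vp
}

#' Genotypic value under alternative gene-action models
#'
#' For comparison with the gene-based (geometric-mean) model, computes the
#' genotypic value that the same pair of haplotype effect sums would give
#' under textbook quantitative-genetic models: `additive` is `E1 + E2`,
#' `dominant` is `max(E1, E2)` (the more-mutated haplotype dominates) and
#' `recessive` is `min(E1, E2)` (the less-mutated haplotype dominates;
#' these max/min definitions are interpretive conventions of this package).
#' For all non-negative inputs `recessive <= geometric <= additive`.
#'
#' @param E1,E2 Non-negative haplotype effect sums (vectorized).
#' @param model One of `"geometric"`, `"additive"`, `"dominant"`,
#'   `"recessive"`.
#' @return Genotypic value(s) under the requested model.
#' @examples
#' sapply(c("additive", "dominant", "recessive", "geometric"),
#'        function(m) gene_action_value(0.1, 0.2, m))
#' @export
gene_action_value <- function(E1, E2,
                              model = c("geometric", "additive", "dominant",
                                        "recessive")) {
  model <- match.arg(model)
  if (any(E1 < 0) || any(E2 < 0)) stop("haplotype effects must be >= 0")
  switch(model,
         geometric = sqrt(E1 * E2),
         additive = E1 + E2,
         dominant = pmax(E1, E2),
         recessive = pmin(E1, E2))
}
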