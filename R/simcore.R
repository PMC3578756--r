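#' Initialize a mutation-free population
#'
#' Creates a population of `2N` empty haplotypes at generation 0 with an
#' empty mutation table.
#'
#' @param params A [sim_params()] object.
#' @return A `wf_population` object: a list with elements `generation`, `N`,
#'   `haplotypes` (a list of `2N` integer vectors of row indices into
#'   `mutations`, sorted by position), `mutations` (data frame with columns
#'   `position`, `effect`, `origin_generation`, `count`), `fixed` (log of
#'   fixed causative mutations), `fixed_burden` (summed effect of fixed
#'   causative mutations, carried by every haplotype), `optimum` (current
#'   stabilizing-selection optimum) and `params`.
#' @examples
#' pop <- initialize_population(sim_params(N = 5, n_generations = 0))
#' length(pop$haplotypes)  # 10
#' @export
initialize_population <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  empty_mut <- data.frame(position = numeric(0), effect = numeric(0),
                          origin_generation = integer(0), count = integer(0))
  structure(list(generation = 0L, N = params$N,
                 haplotypes = rep(list(integer(0)), 2L * params$N),
                 mutations = empty_mut,
                 fixed = data.frame(position = numeric(0), effect = numeric(0),
                                    origin_generation = integer(0),
                                    generation_fixed = integer(0)),
                 fixed_burden = 0, optimum = 0, params = params),
            class = "wf_population")
}

.pop_from_cpp <- function(res, params) {
  structure(list(generation = res$generation, N = params$N,
                 haplotypes = res$haplotypes, mutations = res$mutations,
                 fixed = res$fixed, fixed_burden = res$fixed_burden,
                 optimum = res$optimum, params = params),
            class = "wf_population")
}

.run_generations <- function(pop, params, n_generations, compact_interval = 20L) {
  res <- .wf_evolve_cpp(pop$haplotypes, pop$mutations$position,
                        pop$mutations$effect, pop$mutations$origin_generation,
                        pop$fixed, pop$fixed_burden, pop$generation,
                        params$N, params$mu_neutral, params$mu_causative,
                        params$r, params$lambda_effect, params$sigma_e,
                        params$sigma_s, as.integer(n_generations),
                        params$recenter_optimum, as.integer(compact_interval))
  .pop_from_cpp(res, params)
}

#' Evolve a population to mutation-selection balance
#'
#' Runs the forward Wright-Fisher simulation for `params$n_generations`
#' generations (default `8N`, the burn-in after which samples are taken).
#' Each generation, every individual's liability and Gaussian fitness are
#' computed, `2N` gametes are produced from parents sampled with probability
#' proportional to fitness (independently, with replacement), and each
#' gamete undergoes Poisson recombination and Poisson mutation (see
#' [make_gamete()]).  Runs are deterministic given `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.  `NULL` leaves the
#'   RNG state untouched.
#' @return A `wf_population` (see [initialize_population()]).
#' @examples
#' p <- sim_params_scaled(N = 50, theta = 10, theta_d = 1, rho = 10,
#'                        n_generations = 200, seed = 1)
#' pop <- evolve(p)
#' nrow(pop$mutations)
#' @export
evolve <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  pop <- initialize_population(params)
  if (params$n_generations == 0L) return(pop)
  .run_generations(pop, params, params$n_generations)
}

#' Advance a population by one (or more) generations
#'
#' @param pop A `wf_population`.
#' @param params A [sim_params()] object (defaults to the population's own).
#' @param n_generations Number of generations to step (default 1).
#' @return The advanced `wf_population`.
#' @export
next_generation <- function(pop, params = pop$params, n_generations = 1L) {
  stopifnot(inherits(pop, "wf_population"))
  .run_generations(pop, params, n_generations)
}

#' Form one gamete from a parental diploid
#'
#' Draws `Poisson(r)` crossover breakpoints uniform on `[0,1)` and alternates
#' segments between the two parental haplotypes starting from a randomly
#' chosen strand, then adds `Poisson(mu_neutral + mu_causative)` new
#' mutations at fresh uniform positions; each new mutation is causative with
#' probability `mu_causative / (mu_neutral + mu_causative)` with effect drawn
#' from `Exponential(mean = lambda_effect)`, otherwise neutral (effect 0).
#'
#' @param hap_a,hap_b Integer vectors of mutation indices (rows of
#'   `mutations`) for the two parental haplotypes, sorted by position.
#' @param mutations Mutation table (data frame with `position` and `effect`).
#' @param params A [sim_params()] object.
#' @param origin_generation Origin generation recorded for new mutations.
#' @return A list with `haplotype` (indices into the returned `mutations`)
#'   and `mutations` (the input table with any new mutations appended).
#' @examples
#' p <- sim_params(N = 2, mu_neutral = 0, r = 0, n_generations = 0)
#' mut <- data.frame(position = 0.5, effect = 0,
#'                   origin_generation = 0L, count = 1L)
#' make_gamete(1L, integer(0), mut, p)$haplotype
#' @export
make_gamete <- function(hap_a, hap_b, mutations, params,
                        origin_generation = 0L) {
  res <- .make_gamete_cpp(as.integer(hap_a), as.integer(hap_b),
                          mutations$position, mutations$effect,
                          params$mu_neutral, params$mu_causative, params$r,
                          params$lambda_effect, as.integer(origin_generation))
  n_new <- length(res$new_position)
  if (n_new > 0L) {
    mutations <- rbind(mutations,
                       data.frame(position = res$new_position,
                                  effect = res$new_effect,
                                  origin_generation = as.integer(origin_generation),
                                  count = rep(1L, n_new)))
  }
  list(haplotype = res$haplotype, mutations = mutations)
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("Wright-Fisher population: N = %d diploids, generation %d\n",
              x$N, x$generation))
  n_caus <- sum(x$mutations$effect > 0)
  cat(sprintf("  %d segregating mutations (%d causative, %d neutral)\n",
              nrow(x$mutations), n_caus, nrow(x$mutations) - n_caus))
  cat(sprintf("  fixed causative burden: %g (%d fixations)\n",
              x$fixed_burden, nrow(x$fixed)))
  invisible(x)
}

#' Recompute mutation counts from haplotypes
#'
#' Book-keeping check: tallies every mutation's occurrences across the `2N`
#' haplotypes.  At all times this must equal the stored `count` column.
#'
#' @param pop A `wf_population`.
#' @return Integer vector of counts, aligned with `pop$mutations`.
#' @export
recount_mutations <- function(pop) {
  m <- nrow(pop$mutations)
  tab <- tabulate(unlist(pop$haplotypes), nbins = m)
  as.integer(tab)
}

#' Write and read populations as plain text
#'
#' `write_population()` stores a population as a directory of plain-text
#' files: `mutations.tsv` (the mutation-table export with columns `position`,
#' `effect`, `origin_generation`, `count`), `fixed.tsv`, `haplotypes.txt`
#' (one line per haplotype of space-separated mutation row indices) and
#' `meta.tsv`.  `read_population()` restores it.
#'
#' @param pop A `wf_population`.
#' @param dir Directory to create/read.
#' @return `write_population()` returns `dir` invisibly; `read_population()`
#'   returns a `wf_population` (with its `params` restored).
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(pop$mutations, file.path(dir, "mutations.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(pop$fixed, file.path(dir, "fixed.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  writeLines(vapply(pop$haplotypes, paste, "", collapse = " "),
             file.path(dir, "haplotypes.txt"))
  p <- pop$params
  meta <- data.frame(key = c("generation", "N", "fixed_burden", "optimum",
                             "mu_neutral", "mu_causative", "r",
                             "lambda_effect", "sigma_e", "sigma_s",
                             "n_generations", "recenter_optimum"),
                     value = c(pop$generation, pop$N, pop$fixed_burden,
                               pop$optimum, p$mu_neutral, p$mu_causative,
                               p$r, p$lambda_effect, p$sigma_e, p$sigma_s,
                               p$n_generations, as.numeric(p$recenter_optimum)))
  write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  meta <- read.table(file.path(dir, "meta.tsv"), header = TRUE, sep = "\t")
  mv <- setNames(meta$value, meta$key)
  params <- sim_params(N = mv[["N"]], mu_neutral = mv[["mu_neutral"]],
                       mu_causative = mv[["mu_causative"]], r = mv[["r"]],
                       lambda_effect = mv[["lambda_effect"]],
                       sigma_e = mv[["sigma_e"]], sigma_s = mv[["sigma_s"]],
                       n_generations = mv[["n_generations"]],
                       recenter_optimum = mv[["recenter_optimum"]] > 0)
  haps_raw <- readLines(file.path(dir, "haplotypes.txt"))
  haps <- lapply(strsplit(haps_raw, " ", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    as.integer(x)
  })
  structure(list(generation = as.integer(mv[["generation"]]),
                 N = as.integer(mv[["N"]]), haplotypes = haps,
                 mutations = read.table(file.path(dir, "mutations.tsv"),
                                        header = TRUE, sep = "\t"),
                 fixed = read.table(file.path(dir, "fixed.tsv"),
                                    header = TRUE, sep = "\t"),
                 fixed_burden = mv[["fixed_burden"]],
                 optimum = mv[["optimum"]], params = params),
            class = "wf_population")
}
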