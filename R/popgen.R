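.sample_counts <- function(x) {
  if (inherits(x, "hap_sample")) {
    list(counts = tabulate(unlist(x$haplotypes), nbins = nrow(x$mutations)),
         n = x$n, mutations = x$mutations)
  } else if (inherits(x, "wf_population")) {
    list(counts = x$mutations$count, n = 2L * x$N, mutations = x$mutations)
  } else {
    stop("expected a hap_sample or wf_population")
  }
}

.class_index <- function(mutations, mutation_class) {
  switch(mutation_class,
         all = rep(TRUE, nrow(mutations)),
         neutral = mutations$effect == 0,
         causative = mutations$effect > 0,
         stop("unknown mutation class"))
}

#' Site frequency spectrum
#'
#' Counts of segregating sites at derived-allele count `i = 1, ..., n - 1`
#' in a sample of `n` haplotypes, per mutation class.  Derived-allele
#' polarity is known exactly from the simulator's origin records.
#'
#' @param x A `hap_sample` (from [population_sample()]) or `wf_population`.
#' @param mutation_class One of `"all"`, `"neutral"`, `"causative"`.
#' @return An `sfs_summary` data frame with columns `derived_count`,
#'   `sites` and `proportion` (normalized over segregating bins), plus
#'   attributes `n` and `mutation_class`.
#' @export
sfs <- function(x, mutation_class = c("all", "neutral", "causative")) {
  mutation_class <- match.arg(mutation_class)
  sc <- .sample_counts(x)
  keep <- .class_index(sc$mutations, mutation_class)
  cnt <- sc$counts[keep]
  cnt <- cnt[cnt > 0L & cnt < sc$n]
  sites <- tabulate(cnt, nbins = sc$n - 1L)
  total <- sum(sites)
  out <- data.frame(derived_count = seq_len(sc$n - 1L), sites = sites,
                    proportion = if (total > 0) sites / total else
                      rep(0, sc$n - 1L))
  structure(out, n = sc$n, mutation_class = mutation_class,
            class = c("sfs_summary", "data.frame"))
}

#' Segregating sites and pairwise diversity
#'
#' `S` is the number of segregating sites and `pi` the mean number of
#' pairwise differences between two randomly chosen haplotypes,
#' `pi = sum_i 2 c_i (n - c_i) / (n (n - 1))` over sites with derived count
#' `c_i` (equivalent to averaging Hamming distances over all haplotype
#' pairs).  Under neutrality `E[pi] = 4 N mu` for the corresponding
#' mutation class.
#'
#' @inheritParams sfs
#' @return A list with elements `S` and `pi`.
#' @export
diversity <- function(x, mutation_class = c("all", "neutral", "causative")) {
  mutation_class <- match.arg(mutation_class)
  sc <- .sample_counts(x)
  keep <- .class_index(sc$mutations, mutation_class)
  cnt <- sc$counts[keep]
  cnt <- cnt[cnt > 0L & cnt < sc$n]
  n <- as.numeric(sc$n)
  list(S = length(cnt), pi = sum(2 * cnt * (n - cnt)) / (n * (n - 1)))
}

#' Pairwise diversity from a site frequency spectrum
#'
#' The SFS identity `pi = sum_i i (n - i) xi_i * 2 / (n (n - 1))`, where
#' `xi_i` is the number of sites with derived count `i`.
#'
#' @param spectrum An `sfs_summary` from [sfs()].
#' @return The value of `pi`.
#' @export
pi_from_sfs <- function(spectrum) {
  n <- as.numeric(attr(spectrum, "n"))
  i <- spectrum$derived_count
  sum(2 * i * (n - i) * spectrum$sites) / (n * (n - 1))
}

#' Linkage disequilibrium between two markers
#'
#' Squared correlation of allele indicators across haplotypes (true phase,
#' which the simulator provides).  For imported genotype data without
#' phase, set `use_phase = FALSE` to obtain the genotype-based composite
#' analogue from dosage columns.  `r^2` is symmetric in its arguments and
#' invariant to swapping allele labels at either marker.
#'
#' @param panel A `cc_panel`.
#' @param marker_a,marker_b Marker column indices.
#' @param use_phase Use the phased haplotype matrix (default `TRUE`).
#' @return `r^2` in `[0, 1]` (`NA` if either marker is monomorphic).
#' @export
ld_r2 <- function(panel, marker_a, marker_b, use_phase = TRUE) {
  M <- if (use_phase) panel$haplotypes else panel$dosages
  a <- M[, marker_a]
  b <- M[, marker_b]
  if (var(a) == 0 || var(b) == 0) return(NA_real_)
  cor(a, b)^2
}

#' Which causative sites do significant common markers tag?
#'
#' For each supplied significant (typically common, neutral) marker, ranks
#' all causative markers in the panel by `r^2` with it and records the top
#' two, together with the identity, panel frequency and effect size of the
#' most strongly tagged causative site.
#'
#' @param panel A `cc_panel`.
#' @param significant_markers Integer indices of significant markers.
#' @return A list with `per_marker` (data frame: `marker`, `top_causal`,
#'   `top_r2`, `second_causal`, `second_r2`, `tagged_freq`, `tagged_effect`)
#'   and `n_unique_tagged`, the number of distinct top-tagged causative
#'   sites.  Both are empty when the panel carries no causative markers.
#' @export
tag_analysis <- function(panel, significant_markers) {
  caus <- which(panel$markers$effect > 0)
  empty <- data.frame(marker = integer(0), top_causal = integer(0),
                      top_r2 = numeric(0), second_causal = integer(0),
                      second_r2 = numeric(0), tagged_freq = numeric(0),
                      tagged_effect = numeric(0))
  if (length(caus) == 0L || length(significant_markers) == 0L)
    return(list(per_marker = empty, n_unique_tagged = 0L))
  rows <- lapply(significant_markers, function(j) {
    r2 <- vapply(caus, function(k) ld_r2(panel, j, k), numeric(1))
    ord <- order(r2, decreasing = TRUE)
    top <- caus[ord[1]]
    second <- if (length(caus) > 1L) caus[ord[2]] else NA_integer_
    data.frame(marker = j, top_causal = top, top_r2 = r2[ord[1]],
               second_causal = second,
               second_r2 = if (length(caus) > 1L) r2[ord[2]] else NA_real_,
               tagged_freq = panel$markers$maf_panel[top],
               tagged_effect = panel$markers$effect[top])
  })
  per_marker <- do.call(rbind, rows)
  list(per_marker = per_marker,
       n_unique_tagged = length(unique(per_marker$top_causal)))
}

#' Frequency-matched non-associated marker
#'
#' Finds the marker closest in panel minor-allele count to `focal` among
#' markers with single-marker p-value above `p_min` (default `1e-4`, i.e.
#' not associated with status).  Matching prefers markers within
#' `tol_count` allele copies; ties are broken by position order.
#'
#' @param panel A `cc_panel`.
#' @param focal Focal marker index.
#' @param p_values Per-marker p-values aligned with the panel's markers.
#' @param p_min Non-association cutoff.
#' @param tol_count Preferred allele-count tolerance.
#' @return Index of the matched marker (or `NA` if none qualifies).
#' @export
match_null_marker <- function(panel, focal, p_values, p_min = 1e-4,
                              tol_count = 1L) {
  n2 <- 2L * (panel$n_cases + panel$n_controls)
  mc <- pmin(panel$markers$derived_count, n2 - panel$markers$derived_count)
  cand <- which(!is.na(p_values) & p_values > p_min &
                  seq_along(p_values) != focal)
  if (length(cand) == 0L) return(NA_integer_)
  dd <- abs(mc[cand] - mc[focal])
  near <- cand[dd <= tol_count]
  if (length(near) > 0L) return(near[1])
  cand[which.min(dd)]
}

#' Causative-singleton burden by genotype at a marker
#'
#' For each genotype class (0, 1, 2 copies of the derived allele at the
#' given marker), the mean and standard error of the number of causative
#' panel singletons (causative sites present exactly once in the whole
#' panel) carried per individual.  Comparing the most significant marker
#' against a frequency-matched non-associated marker
#' ([match_null_marker()]) asks whether significant markers tag haplotypes
#' with an unusual rare-allele burden.
#'
#' @param panel A `cc_panel`.
#' @param marker Marker index at which genotype classes are formed.
#' @return Data frame with columns `genotype`, `n`, `mean`, `se`.
#' @export
singleton_burden_by_genotype <- function(panel, marker) {
  singl <- which(panel$markers$effect > 0 & panel$markers$derived_count == 1L)
  n <- panel$n_cases + panel$n_controls
  burden <- if (length(singl) > 0L) {
    d <- panel$haplotypes[, singl, drop = FALSE]
    odd <- seq(1, 2 * n, by = 2)
    rowSums(d[odd, , drop = FALSE]) + rowSums(d[odd + 1, , drop = FALSE])
  } else rep(0, n)
  ad <- panel$haplotypes[seq(1, 2 * n, by = 2), marker] +
    panel$haplotypes[seq(2, 2 * n, by = 2), marker]
  out <- lapply(0:2, function(g) {
    b <- burden[ad == g]
    data.frame(genotype = g, n = length(b),
               mean = if (length(b) > 0) mean(b) else NA_real_,
               se = if (length(b) > 1) sd(b) / sqrt(length(b)) else NA_real_)
  })
  do.call(rbind, out)
}
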