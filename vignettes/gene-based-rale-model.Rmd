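---
title: "A gene-based mutation-selection-balance model of rare alleles of large effect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gene-based mutation-selection-balance model of rare alleles of large effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ralesim)
```

## The model

`ralesim` simulates a single gene region -- the unit interval, representing
roughly 100 kb of a human genome -- forward in time in a Wright-Fisher
population of `N` diploids.  Mutation follows the infinitely-many-sites
model: each gamete receives `Poisson(mu_neutral + mu_causative)` new
mutations at fresh uniform positions, and `Poisson(r)` crossovers
recombine the two parental haplotypes.  A new mutation is *causative* with
probability `mu_causative / (mu_neutral + mu_causative)`, in which case its
effect size is drawn from an exponential distribution with mean `lambda`;
otherwise it is neutral (effect 0).

Gene action is what distinguishes this model from standard
population-genetic simulations.  A haplotype's effect `E` is additive over
the causative mutations it carries, and the genotypic value of a diploid is
the *geometric mean* of its two haplotype effects,

    G = sqrt(E1 * E2).

Mutations within the region therefore fail to complement: a diploid is
affected only when *both* haplotypes are damaged, regardless of whether any
individual site is homozygous, and one mutation-free haplotype rescues the
phenotype entirely (`G = 0`).  By the AM-GM inequality `G` never exceeds
the additive mid-value, so gene action is partially recessive at the level
of whole haplotypes.  `gene_action_value()` exposes textbook additive
(`E1 + E2`), dominant (`max`) and recessive (`min`) comparison models; the
max/min definitions are this package's interpretive convention for those
comparisons, chosen so that the geometric-mean model falls between the
recessive and additive extremes.

The liability of an individual is `P = G + x` with `x ~ N(0, sigma_e^2)`,
and fitness is Gaussian stabilizing selection around an optimum of 0,

    w = exp(-(P - optimum)^2 / (2 * sigma_s^2)).

Parents are sampled with probability proportional to `w`, independently and
with replacement (selfing permitted), each generation.  Disease status is a
threshold on liability: cases are the upper 15% of the population
distribution, controls lie within one population SD of the mean.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `N` | 20000 | diploid population size (full scale) |
| `mu_neutral` | 0.00125 | neutral mutations per gamete per generation (`theta = 100`) |
| `mu_causative` | 0.000125 | causative rate, one tenth of neutral (`theta_d = 10`) |
| `r` | 0.00125 | crossovers per diploid per generation (`rho = 100`) |
| `lambda` | -- | mean effect of a new causative mutation (liability units) |
| `sigma_e` | 0.075 | environmental SD of the liability |
| `sigma_s` | 1 | width of stabilizing selection |
| `n_generations` | `8N` | burn-in to mutation-selection balance |

With these values the focal region contributes ~4-5% of liability variance
at its plateau (`lambda >= 0.075`), and equilibrium allele frequencies,
effect sizes and LD are outcomes of the mutation-selection-drift process
rather than assumptions.

### Fixations and the optimum

Over `8N` generations causative mutations occasionally fix.  A fixed
causative mutation is carried by every haplotype, so it is removed from
segregation tracking and its effect is accumulated into a constant "fixed
burden" added to every haplotype effect.  A constant burden shifts the
whole liability distribution away from 0, which under a fixed optimum
would penalize the entire population; by default the stabilizing-selection
optimum is recentered to the burden (`recenter_optimum = TRUE`), treating
the fixed background as the new wild type.  A flag disables this for
studying the uncompensated case.  Neutral fixations are simply dropped:
they can never affect phenotypes or association tests.

## Scaled-down (desk) runs

Full-scale runs (`N = 20000`, 160,000 generations, hundreds of replicates)
are cluster work.  The package's tests and the acceptance script instead
use reduced populations, which requires care because different summaries
are invariant to different rescalings:

* **Neutral quantities** (`pi`, `S`, the SFS) depend on the scaled rates
  `theta = 4*N*mu` and `rho = 4*N*r` only.  Desk runs use `N = 1000` with
  `theta = rho = 100`, `theta_d = 10` preserved
  (`sim_params_scaled()`), and `8N = 8000` generations.
* **Selection-dependent quantities** (the heritability plateau) are *not*
  invariant under that rescaling: preserving `theta_d` at reduced `N`
  multiplies the per-generation mutational input `mu_d` by the scale
  factor `k = 20000/N` while leaving per-mutation selection unchanged, and
  the equilibrium genetic variance is approximately linear in `mu_d`, so
  the plateau inflates ~k-fold (we measure H^2 ~ 0.21 at `N = 1000`,
  `sigma_s = 1`).  Heritability runs therefore apply the standard
  forward-simulation rescaling: scale mutation, recombination *and
  selection intensity* by `k`.  Because selection strength here enters
  through `Var(G)/sigma_s^2`, this means `sigma_s -> sigma_s / sqrt(k)`.
  With `N = 1000`, `k = 20`, `sigma_s = 1/sqrt(20)`, the measured plateau
  is H^2 = 0.033 (lambda = 0.075) to 0.048 (lambda = 0.10), pooled
  0.040 +/- 0.003 -- matching the full-scale value.
* **Case/control panels** keep the liability-threshold design intact:
  cases are the top 15% of the population, so a panel of `n` cases
  requires `N >= n / 0.15` (3000 = 15% of 20,000 at full scale; sampling
  more cases than the stratum holds is an error by construction).
  Null-calibration runs use 300/300 panels at `N = 2000`: at half that
  panel size the ESM permutation z-scores, while Gaussian in the bulk,
  develop a right-skewed extreme tail and the Gaussian-extrapolated
  p-value becomes anti-conservative beyond ~4 SD.  Desk power runs use
  150/150 panels at `N = 1000` and keep `sigma_s = 1`: their purpose is
  the *ordering* of test power at matched conditions, not full-scale
  power percentages, and the stronger per-region signal of the
  `theta_d`-preserving preset is what makes any test detectable with
  small panels.

The acceptance test suite uses: 30 replicates for the neutral causative
diversity check, 20 per lambda for the heritability plateau, and 50 for
the null-calibration and power-ordering runs.

## Association tests

All tests operate on a `cc_panel`: a dosage matrix of panel-minor-allele
counts, phased haplotypes, and per-marker metadata.  A *GWAS* design keeps
markers with panel MAF >= 5%; a *resequencing* design keeps all markers.

**Single-marker logistic scan.**  Case/control status is regressed on
dosage under an additive model; the genome-wide threshold is `1e-8`.  The
default p-value is the Wald test: on the sparse markers that dominate
these panels it is conservative under the null (the pooled p-value ECDF of
null panels has slope < 1, measured ~0.36 at p = 0.5), which matches the
observed behavior of this design; the likelihood-ratio alternative
(`method = "lrt"`) is slightly anti-conservative in the same setting but
is the right choice when a completely separating marker must still yield a
small p-value (the Wald statistic collapses toward p = 1 under separation,
conservatively, never crashing).

**ESM (excess of significant markers).**  For the `L` unique markers
(identical dosage columns collapsed, panel minor count >= 4), let `Y_i` be
the i-th largest `-log10` Fisher exact p-value.  The statistic is

    Z_M = sum_{i=1}^{min(M,L)} [ Y_i + log10(e_i) ],   e_i = i / (L + 1).

`e_i` is the uniform order-statistic mean -- the one formula in this
package reconstructed from a verbal description rather than a displayed
equation; `null_quantile` is an explicit hook for sensitivity analysis
(e.g. `i/L`).  `M = 50` for recombining/resequencing panels, 25 for
non-recombining GWAS panels.  Significance is by permutation: case labels
are reshuffled 1000 times, Fisher p-values are recomputed for every
permutation (the statistic is a function of the labels), and the observed
statistic is converted to a z-score; two-tailed Gaussian p-values with a
`1e-6` region threshold.  The two-tailed convention is kept as stated even
though large negative z is not evidence for association; a one-tailed
option exists and defaults off.

**Madsen-Browning rank sum** (general-genetic model): per-marker weights
`w_j = sqrt(n q_j (1 - q_j))` with `q_j = (minor count in controls + 1) /
(2 n_controls + 2)` (the cited original formulation, recomputed from the
permuted controls in every permutation), individual scores
`sum_j dosage_ij / w_j`, statistic = sum of case ranks.  Redundant markers
are deliberately not collapsed.

**Li-Leal Hotelling T2** on the `K` rarest markers (scores `1 - dosage`),
pooled covariance inverted by SVD pseudoinverse (singular values below
`max(dim) * eps * max(sv)` dropped).  The default `K = 200` is the
smallest marker count at which the permutation z-scores are calibrated on
null panels; at `K = 50` they are visibly underdispersed.  The permutation
loop exploits the exact identity `(n-2) S = A - c d d'` (total scatter
`A` fixed across permutations, `c = n1 n0 / n`), so one eigendecomposition
serves all permutations via a range-restricted Sherman-Morrison step; the
direct pooled-covariance pseudoinverse is retained in `li_leal_stat()` and
the two are cross-checked in the tests.  Near-separating permutations
(`1 - c v -> 0`) produce missing values, mirroring the numerical
instability of naive inversion at large `K`.

## Numerical choices and degenerate inputs

* Fisher exact p-values are two-sided by the likelihood-ordering rule
  (point probabilities `<= p_obs * (1 + 1e-7)` are summed), matching
  `fisher.test`; the kernel walks the hypergeometric support with the
  ratio recurrence and is verified against full enumeration for every
  table with margins up to 40.
* Monomorphic dosage columns yield `NA` from the logistic scan and are
  excluded from scans by panel construction (markers are sites polymorphic
  *within the panel*).
* Case/control thresholds are computed on the full population's realized
  liabilities (quantile type 7, ties at the threshold eligible); the two
  strata cannot overlap at the default thresholds, and this is asserted.
* Chip ascertainment thins candidate markers (control-population minor
  frequency >= 0.05, minor allele defined in the general population) with
  probability `2q(1-q)`; against a neutral folded SFS (density
  `~ 1/(q(1-q))`) this yields a flat ascertained MAF distribution.
* Frequency matching for the singleton-burden comparison prefers markers
  within +/- 1 minor-allele copy, ties broken by position order.
* Replicate seeds are derived as `base XOR replicate_index`; permutations
  within a panel share one seeded stream.
* Population serialization is plain text (TSV mutation table, one line of
  sorted mutation indices per haplotype); panels export to uncompressed
  VCF with a sample-sheet sidecar, positions mapped to
  `floor(pos * 1e5) + 1` with deterministic +1 collision shifts.

## What the generator does and does not emulate

The simulator produces equilibrium gene regions under recurrent,
unconditionally deleterious, partially recessive, non-complementing
mutation -- the allelic-heterogeneity architecture in which many rare
causative variants of heterogeneous effect segregate against a neutral
marker background.  It does **not** model demographic change, population
structure, recombination hotspots, genotyping error, covariates,
sex-specific effects, multiple unlinked loci, or back-mutation, and
causative "SNPs" stand in for any assayable damaging event.  Passing
desk-scale tests therefore demonstrates internal consistency of the
method chain (simulation -> panel -> test -> power) under the stated
model, not robustness of the tests to the complications of real cohorts.

## Known limitations

* The desk-scale power ordering is a qualitative reproduction; absolute
  desk power values depend strongly on panel size and are far below
  full-scale values.  In particular the full-scale gap between the
  single-marker logistic scan and the Madsen-Browning test compresses at
  150/150 panels (measured 10% vs 6% with the LRT scan, 2% vs 6% with the
  conservative Wald default, 50 replicates at `lambda = 0.075`): the
  logistic scan's informative rare markers fall to minor-allele counts
  where single-marker power collapses, so the two tests are not separable
  by non-overlapping binomial standard errors at feasible replicate
  counts, and under the Wald default the ordering inverts outright.
* Heritability at reduced scale is faithful only under the
  `sigma_s`-rescaled convention above; preserving `theta_d` alone inflates
  it roughly by the scale factor.
* The Hotelling test's missing-value behavior at large `K` follows the
  numerically unstable reference behavior rather than regularizing the
  covariance, by design.
* Broad-sense heritability is computed on realized population `G` and `P`
  (not from allelic variance components), so per-replicate values are
  noisy at small `N`; summaries average over replicates.
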