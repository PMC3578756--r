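#' Single-marker logistic regression
#'
#' Logistic regression of case/control status onto the dosage of the minor
#' allele under an additive model.  The default p-value is the Wald test of
#' the dosage coefficient, which on the sparse markers typical of these
#' panels behaves conservatively under the null (the p-value ECDF of
#' null-model panels has slope below 1); the likelihood-ratio test against
#' the intercept-only model is available behind `method = "lrt"` and is
#' preferable when a separating marker must still yield a small p-value
#' (the Wald test degrades toward p = 1 under complete separation, the
#' Hauck-Donner effect -- conservative, never a crash).  Monomorphic
#' markers are skipped (`NA`).  The conventional genome-wide threshold
#' applied downstream is `1e-8`.
#'
#' @param panel A `cc_panel`.
#' @param markers Integer marker indices (default: all markers).
#' @param method `"wald"` (default) or `"lrt"`.
#' @return Numeric vector of p-values, one per requested marker.
#' @export
logistic_scan <- function(panel, markers = seq_len(nrow(panel$markers)),
                          method = c("wald", "lrt")) {
  method <- match.arg(method)
  y <- as.integer(panel$status == "case")
  n <- length(y)
  k <- sum(y)
  null_dev <- -2 * (k * log(k / n) + (n - k) * log(1 - k / n))
  vapply(markers, function(j) {
    d <- panel$dosages[, j]
    if (all(d == d[1])) return(NA_real_)
    fit <- suppressWarnings(
      glm.fit(cbind(1, d), y, family = binomial(),
              control = list(maxit = 100)))
    if (method == "lrt") {
      pchisq(null_dev - fit$deviance, df = 1, lower.tail = FALSE)
    } else {
      v <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
      if (is.null(v)) return(NA_real_)
      2 * pnorm(-abs(fit$coefficients[2] / sqrt(v[2, 2])))
    }
  }, numeric(1))
}

#' @rdname logistic_scan
#' @param marker A single marker index.
#' @export
logistic_single_marker <- function(panel, marker, method = c("lrt", "wald")) {
  logistic_scan(panel, markers = marker, method = method)
}

#' Fisher exact allele-count test
#'
#' Two-sided Fisher exact p-value from the 2x2 table of minor/major allele
#' counts in cases versus controls (the per-marker test underlying the ESM
#' statistic).
#'
#' @param panel A `cc_panel`.
#' @param markers Marker indices (default: all markers).
#' @return Numeric vector of p-values.
#' @export
fisher_allele_pvalues <- function(panel, markers = seq_len(nrow(panel$markers))) {
  is_case <- panel$status == "case"
  D <- panel$dosages[, markers, drop = FALSE]
  a <- as.integer(colSums(D[is_case, , drop = FALSE]))
  tot <- as.integer(colSums(D))
  b <- 2L * panel$n_cases - a
  cc <- tot - a
  d <- 2L * panel$n_controls - cc
  .fisher2x2_cpp(a, b, cc, d)
}

#' @rdname fisher_allele_pvalues
#' @param marker A single marker index.
#' @export
fisher_exact_allele_test <- function(panel, marker) {
  fisher_allele_pvalues(panel, markers = marker)
}

#' Excess-of-significant-markers (ESM) statistic
#'
#' Given a vector of per-marker p-values from `L` unique markers, let `Y_i`
#' be the i-th largest value of `-log10(p)`.  The statistic is
#' `Z_M = sum_{i=1}^{m} (Y_i - (-log10(e_i)))` with `m = min(M, L)`, where
#' `e_i` is the null expectation of the i-th smallest p-value; by default
#' the uniform order-statistic mean `e_i = i / (L + 1)`.  `Z_M` grows when
#' a region carries an excess of marginally significant markers; it is
#' strictly decreasing in each included p-value and invariant to marker
#' order.
#'
#' The uniform order-statistic form of `e_i` is this package's
#' reconstruction of the null expectation; `null_quantile` is a hook for
#' sensitivity analysis (e.g. `function(i, L) i / L`).
#'
#' @param pvalues P-values of unique markers (after redundancy collapse and
#'   the minimum minor-count filter).
#' @param M Number of most-significant markers summed (50 for recombining /
#'   resequencing panels, 25 for non-recombining GWAS panels).
#' @param null_quantile Function `(i, L)` giving the null-expected i-th
#'   smallest p-value.
#' @return The value of `Z_M`.
#' @examples
#' # 2 strong markers among L = 9, the rest at their null expectation:
#' p <- c(0.001, 0.01, 3:9 / 10)
#' esm_statistic(p, M = 2)  # 3.30103
#' @export
esm_statistic <- function(pvalues, M,
                          null_quantile = function(i, L) i / (L + 1)) {
  L <- length(pvalues)
  if (L == 0L) stop("empty p-value vector")
  m <- min(M, L)
  Y <- sort(-log10(pvalues), decreasing = TRUE)[seq_len(m)]
  e <- -log10(null_quantile(seq_len(m), L))
  sum(Y - e)
}

.perm_case_matrix <- function(n, n_cases, n_perm) {
  P <- matrix(0, nrow = n, ncol = n_perm)
  for (k in seq_len(n_perm))
    P[sample.int(n, n_cases), k] <- 1
  P
}

.region_result <- function(name, observed, perm_stats, n_perm,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  ok <- is.finite(perm_stats)
  mu <- mean(perm_stats[ok])
  s <- sd(perm_stats[ok])
  if (!is.finite(observed) || !is.finite(mu) || !is.finite(s)) {
    z <- NA_real_
    p <- NA_real_
  } else if (s > 0) {
    z <- (observed - mu) / s
    p <- if (alternative == "two.sided") 2 * pnorm(-abs(z)) else
      pnorm(z, lower.tail = FALSE)
    p <- min(1, max(p, .Machine$double.xmin))
  } else {
    z <- if (observed == mu) 0 else sign(observed - mu) * Inf
    p <- if (z == 0) 1 else .Machine$double.xmin
  }
  structure(list(statistic_name = name, observed = observed, perm_mean = mu,
                 perm_sd = s, z = z, p = p, n_permutations = n_perm,
                 alternative = alternative, perm_stats = perm_stats),
            class = "region_test")
}

#' @export
print.region_test <- function(x, ...) {
  cat(sprintf("%s region test: observed = %.4g, permutation %0.4g +/- %.4g (n = %d)\n",
              x$statistic_name, x$observed, x$perm_mean, x$perm_sd,
              x$n_permutations))
  cat(sprintf("  z = %.3f, %s p = %.3g\n", x$z,
              if (x$alternative == "two.sided") "two-tailed" else "one-tailed",
              x$p))
  invisible(x)
}

#' ESM region test with permutation significance
#'
#' Computes the ESM statistic on the panel's unique markers (identical
#' dosage columns collapsed, panel minor-allele count at least
#' `min_minor_count`), then permutes case/control labels `n_perm` times,
#' recomputing the Fisher p-value vector and the statistic for every
#' permutation, and converts the observed statistic to a z-score against
#' the permutation distribution.  Two-tailed Gaussian p-values follow the
#' shared significance procedure (threshold `1e-6` downstream).
#'
#' @param panel A `cc_panel`.
#' @param M Markers summed (see [esm_statistic()]).
#' @param study `"resequencing"` or `"gwas"` marker set.
#' @param n_perm Number of label permutations.
#' @param min_minor_count Minimum panel minor-allele count (default 4).
#' @param alternative Two-tailed by default (the stated procedure); a
#'   one-tailed option is available.
#' @inheritParams esm_statistic
#' @return A `region_test` object.
#' @export
esm_test <- function(panel, M = 50, study = c("resequencing", "gwas"),
                     n_perm = 1000, min_minor_count = 4,
                     null_quantile = function(i, L) i / (L + 1),
                     alternative = c("two.sided", "greater")) {
  study <- match.arg(study)
  idx <- filter_markers(panel, study = study,
                        min_minor_count = min_minor_count,
                        collapse_redundant = TRUE)
  if (length(idx) == 0L)
    stop("no markers pass the ESM filters")
  D <- panel$dosages[, idx, drop = FALSE]
  L <- ncol(D)
  n <- nrow(D)
  n_cases <- panel$n_cases
  n_controls <- panel$n_controls
  tot <- as.integer(colSums(D))
  is_case <- as.numeric(panel$status == "case")

  fisher_p <- function(a) {
    a <- as.integer(a)
    .fisher2x2_cpp(a, 2L * n_cases - a, tot - a,
                   2L * n_controls - (tot - a))
  }
  obs <- esm_statistic(fisher_p(crossprod(D, is_case)), M, null_quantile)

  P <- .perm_case_matrix(n, n_cases, n_perm)
  A <- crossprod(D, P)  # minor-allele counts in permuted cases, L x n_perm
  a <- as.integer(as.vector(A))
  pv <- .fisher2x2_cpp(a, 2L * n_cases - a, rep(tot, n_perm) - a,
                       2L * n_controls - (rep(tot, n_perm) - a))
  pv <- matrix(pv, nrow = L)
  perm_stats <- vapply(seq_len(n_perm),
                       function(k) esm_statistic(pv[, k], M, null_quantile),
                       numeric(1))
  .region_result(sprintf("ESM (M = %d, %s)", M, study), obs, perm_stats,
                 n_perm, alternative = alternative)
}

.mb_statistic <- function(D, case_ind, n_cases, n_controls, tot) {
  ctl_minor <- tot - as.vector(crossprod(D, case_ind))
  q <- (ctl_minor + 1) / (2 * n_controls + 2)
  w <- sqrt((n_cases + n_controls) * q * (1 - q))
  scores <- as.vector(D %*% (1 / w))
  sum(rank(scores)[case_ind == 1])
}

#' Madsen-Browning rank-sum test (general genetic model)
#'
#' Each individual's score at a marker is its minor-allele dosage (0/1/2),
#' weighted by `1 / w_j` with `w_j = sqrt(n q_j (1 - q_j))` and
#' `q_j = (minor count in controls + 1) / (2 n_controls + 2)`, summed over
#' markers; the statistic is the sum of the ranks of case scores among all
#' individuals.  Redundant markers are deliberately not collapsed.  Weights
#' are recomputed from the permuted control set in every permutation.
#'
#' @param panel A `cc_panel`.
#' @param study `"resequencing"` (all markers) or `"gwas"` (MAF >= 5%).
#' @param n_perm Number of label permutations.
#' @inheritParams esm_test
#' @return A `region_test` object.
#' @export
madsen_browning_test <- function(panel, study = c("resequencing", "gwas"),
                                 n_perm = 1000,
                                 alternative = c("two.sided", "greater")) {
  study <- match.arg(study)
  idx <- filter_markers(panel, study = study)
  if (length(idx) == 0L) stop("no markers pass the study filter")
  D <- panel$dosages[, idx, drop = FALSE]
  tot <- colSums(D)
  is_case <- as.numeric(panel$status == "case")
  obs <- .mb_statistic(D, is_case, panel$n_cases, panel$n_controls, tot)
  P <- .perm_case_matrix(nrow(D), panel$n_cases, n_perm)
  # batched: per-permutation control frequencies -> weights -> scores
  C <- tot - crossprod(D, P)  # minor counts in permuted controls, m x n_perm
  q <- (C + 1) / (2 * panel$n_controls + 2)
  W <- 1 / sqrt((panel$n_cases + panel$n_controls) * q * (1 - q))
  Sc <- D %*% W  # individual scores, n x n_perm
  perm_stats <- vapply(seq_len(n_perm), function(k) {
    sum(rank(Sc[, k])[P[, k] == 1])
  }, numeric(1))
  .region_result(sprintf("Madsen-Browning (%s)", study), obs, perm_stats,
                 n_perm, alternative = alternative)
}

#' @rdname madsen_browning_test
#' @param dosages Minor-allele dosage matrix (individuals x markers).
#' @param is_case Logical or 0/1 vector of case indicators.
#' @export
madsen_browning_stat <- function(dosages, is_case) {
  is_case <- as.numeric(is_case)
  .mb_statistic(dosages, is_case, sum(is_case == 1),
                sum(is_case == 0), colSums(dosages))
}

.pseudoinverse <- function(S) {
  sv <- svd(S)
  tol <- max(dim(S)) * .Machine$double.eps * max(sv$d)
  keep <- sv$d > tol
  if (!any(keep)) return(matrix(0, ncol(S), nrow(S)))
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' Li-Leal multiple-marker Hotelling T2 test
#'
#' Two-sample Hotelling T2 between case and control mean vectors of
#' genotype scores (aa = -1, Aa = 0, AA = 1 with `a` the minor allele,
#' i.e. `1 - dosage`) on the `K` rarest markers by panel minor-allele
#' frequency, with the pooled covariance inverted by singular-value
#' pseudoinverse.  Redundant markers are not collapsed.  The default
#' `K = 200` is the smallest marker count at which the permutation
#' z-scores of this statistic are well calibrated on null panels (smaller
#' `K` gives underdispersed z-scores).
#'
#' Internally the permutation loop uses the exact identity
#' `(n-2) S = A - c d d'` relating the pooled within-group scatter `S` to
#' the fixed total scatter `A` (`c = n1 n0 / n`, `d` the mean difference),
#' so `A` is eigendecomposed once and each permutation costs one projected
#' quadratic form (Sherman-Morrison on the range of `A`; `d` always lies
#' in that range).  A separation-degenerate permutation (`1 - c v = 0`)
#' yields a missing value, mirroring the numerical instability of direct
#' inversion; an unusable observed statistic yields a missing p-value
#' rather than an error.
#'
#' @param panel A `cc_panel`.
#' @param K Number of rarest markers used (paper grid: 50, 100, 200, 250).
#' @param n_perm Number of label permutations.
#' @inheritParams esm_test
#' @return A `region_test` object (fields may be `NA` when the statistic is
#'   numerically unusable).
#' @export
li_leal_test <- function(panel, K = 200, n_perm = 1000,
                         alternative = c("two.sided", "greater")) {
  m <- nrow(panel$markers)
  ridx <- order(panel$markers$maf_panel)[seq_len(min(K, m))]
  X <- 1 - panel$dosages[, ridx, drop = FALSE]
  n <- nrow(X)
  n1 <- panel$n_cases
  n0 <- panel$n_controls
  cc <- n1 * n0 / n
  mu <- colMeans(X)
  A <- crossprod(X) - n * tcrossprod(mu)
  ee <- eigen(A, symmetric = TRUE)
  tol <- max(dim(A)) * .Machine$double.eps * max(ee$values, 0)
  keep <- ee$values > tol
  U <- ee$vectors[, keep, drop = FALSE]
  lam <- ee$values[keep]
  csum <- colSums(X)
  t2 <- function(case_ind) {
    s1 <- as.vector(crossprod(X, case_ind))
    d <- s1 / n1 - (csum - s1) / n0
    v <- sum(as.vector(crossprod(U, d))^2 / lam)
    out <- cc * (n - 2) * v / (1 - cc * v)
    if (!is.finite(out) || out < 0) NA_real_ else out
  }
  is_case <- as.numeric(panel$status == "case")
  obs <- t2(is_case)
  P <- .perm_case_matrix(n, n1, n_perm)
  perm_stats <- vapply(seq_len(n_perm), function(k) t2(P[, k]), numeric(1))
  .region_result(sprintf("Li-Leal Hotelling T2 (K = %d)", min(K, m)), obs,
                 perm_stats, n_perm, alternative = alternative)
}

#' @rdname li_leal_test
#' @param scores Genotype score matrix (individuals x markers; -1/0/1).
#' @param is_case Logical or 0/1 case indicator.
#' @export
li_leal_stat <- function(scores, is_case) {
  is_case <- as.numeric(is_case)
  n1 <- sum(is_case == 1)
  n0 <- sum(is_case == 0)
  n <- n1 + n0
  mu1 <- colSums(scores[is_case == 1, , drop = FALSE]) / n1
  mu0 <- colSums(scores[is_case == 0, , drop = FALSE]) / n0
  X1 <- sweep(scores[is_case == 1, , drop = FALSE], 2, mu1)
  X0 <- sweep(scores[is_case == 0, , drop = FALSE], 2, mu0)
  S <- (crossprod(X1) + crossprod(X0)) / (n - 2)
  d <- mu1 - mu0
  (n1 * n0 / n) * drop(t(d) %*% .pseudoinverse(S) %*% d)
}

#' Permutation significance for an arbitrary region statistic
#'
#' Shared permutation machinery: permutes case/control labels uniformly,
#' recomputes `stat_fun` for each permutation and converts the observed
#' statistic to a z-score and a two-tailed Gaussian p-value (the region
#' significance threshold applied downstream is `1e-6`).  Deterministic
#' given the RNG state; all permutations draw from one stream.
#'
#' @param panel A `cc_panel`.
#' @param stat_fun Function `(panel, is_case)` returning a scalar
#'   statistic, where `is_case` is a 0/1 vector replacing the panel labels.
#' @param n_perm Number of permutations (default 1000).
#' @param statistic_name Label for printing.
#' @inheritParams esm_test
#' @return A `region_test` object.
#' @export
permutation_test <- function(panel, stat_fun, n_perm = 1000,
                             statistic_name = "custom",
                             alternative = c("two.sided", "greater")) {
  is_case <- as.numeric(panel$status == "case")
  obs <- stat_fun(panel, is_case)
  n <- length(is_case)
  perm_stats <- vapply(seq_len(n_perm), function(k) {
    ind <- numeric(n)
    ind[sample.int(n, panel$n_cases)] <- 1
    stat_fun(panel, ind)
  }, numeric(1))
  .region_result(statistic_name, obs, perm_stats, n_perm,
                 alternative = alternative)
}
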