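#' Power over a grid of mean effect sizes
#'
#' Orchestrates replicate runs of the full pipeline -- forward simulation to
#' mutation-selection balance, liability-threshold case/control panel,
#' association tests -- over a grid of `lambda` values, and estimates power
#' as the proportion of replicates significant at the stated thresholds
#' (`1e-8` for the single-marker logistic scan, where a replicate counts if
#' any marker in the region reaches the threshold; `1e-6` for the
#' region-based tests).  Binomial Monte Carlo standard errors accompany
#' every power estimate.  Replicates use independent seeded streams derived
#' from `seed` by XOR with the replicate index, so results merge
#' order-independently.
#'
#' The `desk` scale preset (the default parameters) preserves the
#' full-size model's scaled rates (`theta = rho = 100`, `theta_d = 10`) at
#' `N = 1000` with panels of 150 cases and 150 controls (the upper-15%
#' stratum of 1000 individuals); it is intended for ordering and
#' calibration properties, not for reproducing full-scale power
#' percentages.
#'
#' @param lambdas Mean causative effect sizes to simulate.
#' @param n_replicates Replicates per lambda.
#' @param tests Character subset of `"logit"`, `"esm"`, `"mb"`, `"ll"`.
#' @param studies Character subset of `"resequencing"`, `"gwas"` (the
#'   Li-Leal test uses the panel's rarest markers and is reported under
#'   `"resequencing"` only).
#' @param N,theta,theta_d,rho Scaled simulation parameters.
#' @param no_neutral Simulate causative sites only (no neutral markers;
#'   only sensible for heritability-style summaries).
#' @param sigma_e,sigma_s Phenotype model parameters.
#' @param n_generations Generations per replicate (default `8N`).
#' @param n_cases,n_controls Panel sizes.
#' @param M ESM marker count; `K` Li-Leal marker count.
#' @param n_perm Permutations per region test.
#' @param alpha_single,alpha_region Significance thresholds.
#' @param seed Base seed.
#' @return A list with `power` (one row per lambda x test x study:
#'   `lambda`, `test`, `study`, `recombination`, `n_replicates`,
#'   `n_significant`, `power`, `se`, `threshold`) and `results` (per
#'   replicate: the minimal single-marker p and each region test's p).
#' @export
run_power_grid <- function(lambdas = c(0, 0.075, 0.25), n_replicates = 25,
                           tests = c("logit", "esm", "mb", "ll"),
                           studies = c("resequencing", "gwas"),
                           N = 1000, theta = 100, theta_d = 10, rho = 100,
                           no_neutral = FALSE, sigma_e = 0.075, sigma_s = 1,
                           n_generations = 8 * N,
                           n_cases = 150, n_controls = 150, M = 50, K = 200,
                           n_perm = 1000, alpha_single = 1e-8,
                           alpha_region = 1e-6, seed = 1) {
  tests <- match.arg(tests, c("logit", "esm", "mb", "ll"), several.ok = TRUE)
  studies <- match.arg(studies, c("resequencing", "gwas"), several.ok = TRUE)
  rows <- list()
  for (li in seq_along(lambdas)) {
    lam <- lambdas[li]
    params <- sim_params_scaled(N = N, theta = theta, theta_d = theta_d,
                                rho = rho, lambda_effect = lam,
                                no_neutral = no_neutral, sigma_e = sigma_e,
                                sigma_s = sigma_s,
                                n_generations = n_generations)
    for (rep in seq_len(n_replicates)) {
      rep_id <- (li - 1L) * n_replicates + rep
      set.seed(bitwXor(as.integer(seed), rep_id))
      pop <- evolve(params, seed = NULL)
      panel <- draw_case_control(pop, n_cases = n_cases,
                                 n_controls = n_controls)
      for (study in studies) {
        idx <- filter_markers(panel, study = study)
        if ("logit" %in% tests) {
          pmin_logit <- if (length(idx) > 0)
            suppressWarnings(min(logistic_scan(panel, idx), na.rm = TRUE))
          else NA_real_
          rows[[length(rows) + 1L]] <-
            data.frame(lambda = lam, replicate = rep, test = "logit",
                       study = study, p = pmin_logit)
        }
        if ("esm" %in% tests) {
          p_esm <- tryCatch(esm_test(panel, M = M, study = study,
                                     n_perm = n_perm)$p,
                            error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <-
            data.frame(lambda = lam, replicate = rep, test = "esm",
                       study = study, p = p_esm)
        }
        if ("mb" %in% tests) {
          p_mb <- tryCatch(madsen_browning_test(panel, study = study,
                                                n_perm = n_perm)$p,
                           error = function(e) NA_real_)
          rows[[length(rows) + 1L]] <-
            data.frame(lambda = lam, replicate = rep, test = "mb",
                       study = study, p = p_mb)
        }
      }
      if ("ll" %in% tests) {
        p_ll <- tryCatch(li_leal_test(panel, K = K, n_perm = n_perm)$p,
                         error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <-
          data.frame(lambda = lam, replicate = rep, test = "ll",
                     study = "resequencing", p = p_ll)
      }
    }
  }
  results <- do.call(rbind, rows)
  grp <- unique(results[, c("lambda", "test", "study")])
  power_rows <- lapply(seq_len(nrow(grp)), function(i) {
    sel <- results$lambda == grp$lambda[i] & results$test == grp$test[i] &
      results$study == grp$study[i]
    p <- results$p[sel]
    thr <- if (grp$test[i] == "logit") alpha_single else alpha_region
    nsig <- sum(!is.na(p) & p <= thr)
    nrep <- sum(sel)
    pow <- nsig / nrep
    data.frame(lambda = grp$lambda[i], test = grp$test[i],
               study = grp$study[i],
               recombination = if (rho > 0) "on" else "off",
               n_replicates = nrep, n_significant = nsig, power = pow,
               se = sqrt(pow * (1 - pow) / nrep), threshold = thr)
  })
  list(power = do.call(rbind, power_rows), results = results)
}

#' Empirical CDF of p-values per test and lambda
#'
#' Tabulates the ECDF of `-log10(p)` for each test/lambda/study group from
#' the `results` element of [run_power_grid()].  Under the null
#' (`lambda = 0`) a well-calibrated test's p-value ECDF lies on the
#' diagonal; a slope below 1 indicates conservatism.
#'
#' @param results Data frame with columns `lambda`, `test`, `study`, `p`.
#' @return Data frame with columns `lambda`, `test`, `study`, `p`,
#'   `neg_log10_p`, `ecdf` (fraction of replicates with a p-value at or
#'   below `p`).
#' @export
pvalue_ecdf <- function(results) {
  results <- results[!is.na(results$p), , drop = FALSE]
  grp <- unique(results[, c("lambda", "test", "study")])
  out <- lapply(seq_len(nrow(grp)), function(i) {
    sel <- results$lambda == grp$lambda[i] & results$test == grp$test[i] &
      results$study == grp$study[i]
    p <- sort(results$p[sel])
    data.frame(lambda = grp$lambda[i], test = grp$test[i],
               study = grp$study[i], p = p, neg_log10_p = -log10(p),
               ecdf = seq_along(p) / length(p))
  })
  do.call(rbind, out)
}

#' Case-MAF distribution of top GWAS hits on imperfect chips
#'
#' For each case/control panel, draws `chips_per_panel` imperfect chips
#' ([ascertain_chip()]); on every chip the most significant logistic marker
#' is recorded (conditional on reaching `alpha`), and its minor-allele
#' frequency in the cases is binned (minor allele defined in the general
#' population).  The returned counts are Monte Carlo expectations per
#' panel set, i.e. occurrences divided by `chips_per_panel`, so with 250
#' panels the total is the expected number of replicates (out of 250) with
#' a significant chip marker.
#'
#' @param panels List of `cc_panel` objects.
#' @param chips_per_panel Chips drawn per panel.
#' @param alpha Single-marker significance threshold.
#' @param breaks MAF bin breaks.
#' @return Data frame with `bin_lo`, `bin_hi`, `expected_count`.
#' @export
top_hit_maf_distribution <- function(panels, chips_per_panel = 1000,
                                     alpha = 1e-8,
                                     breaks = seq(0, 1, by = 0.05)) {
  counts <- numeric(length(breaks) - 1L)
  for (panel in panels) {
    p_all <- suppressWarnings(logistic_scan(panel))
    n2case <- 2 * panel$n_cases
    case_rows <- which(panel$status == "case")
    d_derived <- panel$haplotypes[2 * case_rows - 1, , drop = FALSE] +
      panel$haplotypes[2 * case_rows, , drop = FALSE]
    f_case_derived <- colSums(d_derived) / n2case
    pop_minor_is_derived <- panel$markers$pop_freq <= 0.5
    case_maf <- ifelse(pop_minor_is_derived, f_case_derived,
                       1 - f_case_derived)
    for (chip in seq_len(chips_per_panel)) {
      idx <- ascertain_chip(panel)
      idx <- idx[!is.na(p_all[idx])]
      if (length(idx) == 0L) next
      sig <- idx[p_all[idx] <= alpha]
      if (length(sig) == 0L) next
      top <- sig[which.min(p_all[sig])]
      bin <- findInterval(case_maf[top], breaks, rightmost.closed = TRUE)
      if (bin >= 1L && bin <= length(counts))
        counts[bin] <- counts[bin] + 1
    }
  }
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             expected_count = counts / chips_per_panel)
}
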