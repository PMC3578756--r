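#' Draw a liability-threshold case/control panel
#'
#' Cases are sampled uniformly without replacement from individuals in the
#' upper tail of the population's realized liability distribution (default:
#' at or above the 85th percentile, i.e. the upper 15%), controls from
#' individuals within `control_sd_window` population standard deviations of
#' the population mean.  Thresholds are computed on the full population's
#' phenotypes; ties at the threshold are eligible.  The two strata are
#' disjoint by construction at the default thresholds (asserted).
#'
#' @param pop A `wf_population`.
#' @param phen Phenotype records from [compute_phenotypes()]; computed fresh
#'   if omitted.
#' @param n_cases,n_controls Panel sizes.
#' @param case_quantile Liability quantile above which individuals qualify
#'   as cases (default 0.85, the upper 15%).
#' @param control_sd_window Controls lie within this many population SDs of
#'   the population mean liability (default 1).
#' @return A `cc_panel` object: a list with `dosages` (individuals x markers
#'   matrix of panel-minor-allele copies in 0/1/2), `status` (factor
#'   case/control), `haplotypes` (phased 2n x markers 0/1 matrix of the
#'   derived allele), `markers` (data frame: `position`, `effect`,
#'   `origin_generation`, `derived_count` in the panel, `maf_panel`,
#'   `minor_is_derived` in the panel, `pop_freq` derived frequency in the
#'   population, `q_control` control-sample frequency of the
#'   population-minor allele), `phenotypes` of the sampled individuals, and
#'   sample sizes.  Markers are the sites polymorphic within the panel.
#' @examples
#' p <- sim_params_scaled(N = 100, theta = 20, theta_d = 2, rho = 20,
#'                        lambda_effect = 0.1, n_generations = 400, seed = 2)
#' pop <- evolve(p)
#' panel <- draw_case_control(pop, n_cases = 10, n_controls = 10)
#' table(panel$status)
#' @export
draw_case_control <- function(pop, phen = compute_phenotypes(pop),
                              n_cases = 3000, n_controls = 3000,
                              case_quantile = 0.85, control_sd_window = 1) {
  P <- phen$P
  case_thr <- quantile(P, case_quantile, names = FALSE)
  cases_ok <- which(P >= case_thr)
  if (n_cases > length(cases_ok))
    stop(sprintf("insufficient qualifying cases: %d needed, %d in the upper-%g%% stratum",
                 n_cases, length(cases_ok), 100 * (1 - case_quantile)))
  case_id <- sort(sample(cases_ok, n_cases))
  # with a right-skewed liability the 85th percentile can fall inside the
  # 1-SD window, so disjointness is enforced by excluding drawn cases
  ctl_ok <- setdiff(which(abs(P - mean(P)) <= control_sd_window * sd(P)),
                    case_id)
  if (n_controls > length(ctl_ok))
    stop(sprintf("insufficient qualifying controls: %d needed, %d within %g SD of the mean",
                 n_controls, length(ctl_ok), control_sd_window))
  ctl_id <- sort(sample(ctl_ok, n_controls))

  ids <- c(case_id, ctl_id)
  hap_rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  m_all <- nrow(pop$mutations)
  n <- length(ids)

  # phased derived-allele matrix for the sampled haplotypes
  hap_list <- pop$haplotypes[hap_rows]
  lens <- lengths(hap_list)
  H <- matrix(0L, nrow = 2L * n, ncol = m_all)
  if (sum(lens) > 0L)
    H[cbind(rep.int(seq_len(2L * n), lens), unlist(hap_list))] <- 1L

  dc <- colSums(H)
  keep <- which(dc > 0L & dc < 2L * n)  # polymorphic within the panel
  H <- H[, keep, drop = FALSE]
  dc <- dc[keep]

  d_derived <- H[seq(1, 2L * n, by = 2), , drop = FALSE] +
    H[seq(2, 2L * n, by = 2), , drop = FALSE]
  f_derived <- dc / (2 * n)
  minor_is_derived <- f_derived <= 0.5
  dos <- d_derived
  flip <- which(!minor_is_derived)
  if (length(flip) > 0L)
    dos[, flip] <- 2L - dos[, flip]

  status <- factor(rep(c("case", "control"), c(n_cases, n_controls)),
                   levels = c("case", "control"))

  # minor allele in the general population, and its frequency in controls
  pop_freq <- pop$mutations$count[keep] / (2 * pop$N)
  pop_minor_is_derived <- pop_freq <= 0.5
  ctl_rows <- which(status == "control")
  d_ctl <- colSums(d_derived[ctl_rows, , drop = FALSE]) / (2 * length(ctl_rows))
  q_control <- ifelse(pop_minor_is_derived, d_ctl, 1 - d_ctl)

  markers <- data.frame(position = pop$mutations$position[keep],
                        effect = pop$mutations$effect[keep],
                        origin_generation = pop$mutations$origin_generation[keep],
                        derived_count = as.integer(dc),
                        maf_panel = pmin(f_derived, 1 - f_derived),
                        minor_is_derived = minor_is_derived,
                        pop_freq = pop_freq,
                        q_control = q_control)
  ord <- order(markers$position)
  structure(list(dosages = dos[, ord, drop = FALSE],
                 haplotypes = H[, ord, drop = FALSE],
                 status = status, markers = markers[ord, , drop = FALSE],
                 phenotypes = phen[ids, , drop = FALSE],
                 n_cases = n_cases, n_controls = n_controls),
            class = "cc_panel")
}

#' @export
print.cc_panel <- function(x, ...) {
  cat(sprintf("Case/control panel: %d cases, %d controls, %d markers (%d causative)\n",
              x$n_cases, x$n_controls, nrow(x$markers),
              sum(x$markers$effect > 0)))
  invisible(x)
}

#' Select markers for a study design
#'
#' A GWAS genotypes all markers with panel minor allele frequency at or
#' above `maf_min` (default 5%); a resequencing study includes every
#' marker.  Region-based tests additionally require a minimum panel
#' minor-allele count (4 for the ESM test) and can collapse redundant
#' markers (identical dosage columns) to one representative.
#'
#' @param panel A `cc_panel`.
#' @param study `"resequencing"` (all markers) or `"gwas"` (common markers).
#' @param maf_min GWAS minor-allele-frequency cutoff (panel frequency).
#' @param min_minor_count Minimum panel minor-allele count, or `NULL`.
#' @param collapse_redundant Collapse identical dosage columns to the first
#'   representative.
#' @return Integer vector of marker column indices.
#' @export
filter_markers <- function(panel, study = c("resequencing", "gwas"),
                           maf_min = 0.05, min_minor_count = NULL,
                           collapse_redundant = FALSE) {
  study <- match.arg(study)
  idx <- seq_len(nrow(panel$markers))
  if (study == "gwas")
    idx <- idx[panel$markers$maf_panel[idx] >= maf_min]
  if (!is.null(min_minor_count)) {
    n2 <- 2L * (panel$n_cases + panel$n_controls)
    minor_count <- pmin(panel$markers$derived_count[idx],
                        n2 - panel$markers$derived_count[idx])
    idx <- idx[minor_count >= min_minor_count]
  }
  if (collapse_redundant && length(idx) > 1L) {
    dup <- duplicated(t(panel$dosages[, idx, drop = FALSE]))
    idx <- idx[!dup]
  }
  idx
}

#' Ascertain an imperfect genotyping chip
#'
#' Emulates SNP-chip marker ascertainment by heterozygosity-proportional
#' thinning: among candidate markers whose population-minor-allele control
#' frequency `q` is at least `maf_min`, marker `j` is kept iff a uniform
#' deviate is at most its expected control heterozygosity `2 q_j (1 - q_j)`.
#' Applied to a neutral marker pool this yields an approximately uniform
#' minor-allele-frequency distribution on `[maf_min, 0.5]` (some ascertained
#' frequencies may exceed 0.5 because the minor allele is defined in the
#' general population while `q` is measured in the control sample).
#'
#' @param panel A `cc_panel`.
#' @param maf_min Lower bound of the ascertainment frequency range.
#' @return Integer vector of chip marker indices.
#' @export
ascertain_chip <- function(panel, maf_min = 0.05) {
  q <- panel$markers$q_control
  cand <- which(q >= maf_min)
  u <- runif(length(cand))
  cand[u <= 2 * q[cand] * (1 - q[cand])]
}

#' Sample diploids from the population
#'
#' Draws `n_diploids` individuals without replacement and returns their `2n`
#' haplotypes together with the mutation table, for population-genetic
#' summaries ([sfs()], [diversity()]).
#'
#' @param pop A `wf_population`.
#' @param n_diploids Number of diploids to draw.
#' @return A `hap_sample` object (list with `haplotypes`, `mutations`, `n`).
#' @export
population_sample <- function(pop, n_diploids) {
  if (n_diploids > pop$N) stop("cannot sample more diploids than N")
  ids <- sort(sample(pop$N, n_diploids))
  hap_rows <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  structure(list(haplotypes = pop$haplotypes[hap_rows],
                 mutations = pop$mutations, n = 2L * n_diploids),
            class = "hap_sample")
}

#' Export a panel to VCF plus a sample sheet
#'
#' Writes an uncompressed VCF with phased genotypes for all panel markers.
#' Region coordinates in `[0,1)` are mapped to integer base pairs as
#' `floor(position * region_bp) + 1`, with deterministic +1 shifting of
#' collisions.  Effect size and origin generation are stored in the INFO
#' field (`EFF`, `ORG`); case/control status goes to a sidecar TSV
#' (`<file>.samples.tsv`).
#'
#' @param panel A `cc_panel`.
#' @param file Output VCF path.
#' @param region_bp Physical size the unit interval represents (default
#'   100 kb).
#' @return `file`, invisibly.
#' @export
write_panel_vcf <- function(panel, file, region_bp = 1e5) {
  m <- nrow(panel$markers)
  pos <- floor(panel$markers$position * region_bp) + 1
  if (m > 1L)
    for (j in 2:m)
      if (pos[j] <= pos[j - 1]) pos[j] <- pos[j - 1] + 1
  n <- panel$n_cases + panel$n_controls
  ids <- sprintf("I%04d", seq_len(n))
  a1 <- panel$haplotypes[seq(1, 2 * n, by = 2), , drop = FALSE]
  a2 <- panel$haplotypes[seq(2, 2 * n, by = 2), , drop = FALSE]
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=region1,length=100000>",
              "##INFO=<ID=EFF,Number=1,Type=Float,Description=\"Causative effect size (0 = neutral)\">",
              "##INFO=<ID=ORG,Number=1,Type=Integer,Description=\"Origin generation\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- vapply(seq_len(m), function(j) {
    gt <- paste0(a1[, j], "|", a2[, j])
    paste(c("region1", pos[j], sprintf("site%d", j), "A", "T", ".", "PASS",
            sprintf("EFF=%g;ORG=%d", panel$markers$effect[j],
                    panel$markers$origin_generation[j]),
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), file)
  write.table(data.frame(sample = ids, status = as.character(panel$status)),
              paste0(file, ".samples.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' Import a panel from VCF plus a sample sheet
#'
#' Reads a VCF (via the vcfR package) and the sidecar sample sheet written
#' by [write_panel_vcf()] (or any TSV with `sample` and `status` columns)
#' and reconstructs a `cc_panel` suitable for the association tests.
#' Phased genotypes are used when present; population-level frequencies are
#' unavailable for imported data, so the control-sample frequency stands in
#' for `q_control` and `pop_freq`.
#'
#' @param file VCF path.
#' @param sample_sheet Path to the status TSV (default `<file>.samples.tsv`).
#' @return A `cc_panel`.
#' @export
read_panel_vcf <- function(file, sample_sheet = paste0(file, ".samples.tsv")) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to import VCF files")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  sheet <- read.table(sample_sheet, header = TRUE, sep = "\t")
  status <- factor(sheet$status[match(colnames(gt), sheet$sample)],
                   levels = c("case", "control"))
  if (anyNA(status)) stop("sample sheet does not cover all VCF samples")
  a1 <- t(apply(gt, 1, function(x) as.integer(substr(x, 1, 1))))
  a2 <- t(apply(gt, 1, function(x) as.integer(substr(x, 3, 3))))
  n <- ncol(gt)
  m <- nrow(gt)
  H <- matrix(0L, nrow = 2L * n, ncol = m)
  H[seq(1, 2 * n, by = 2), ] <- t(a1)
  H[seq(2, 2 * n, by = 2), ] <- t(a2)
  ord <- order(status)  # cases first
  dos <- t(a1 + a2)[ord, , drop = FALSE]
  hap_ord <- as.vector(rbind(2L * ord - 1L, 2L * ord))
  H <- H[hap_ord, , drop = FALSE]
  status <- status[ord]

  dc <- colSums(H)
  f <- dc / (2 * n)
  minor_is_derived <- f <= 0.5
  flip <- which(!minor_is_derived)
  if (length(flip) > 0L) dos[, flip] <- 2L - dos[, flip]
  ctl <- which(status == "control")
  d_ctl <- colSums(dos[ctl, , drop = FALSE]) / (2 * length(ctl))

  eff <- suppressWarnings(as.numeric(vcfR::extract.info(v, "EFF")))
  org <- suppressWarnings(as.integer(vcfR::extract.info(v, "ORG")))
  markers <- data.frame(position = as.numeric(v@fix[, "POS"]) / 1e5,
                        effect = ifelse(is.na(eff), 0, eff),
                        origin_generation = ifelse(is.na(org), 0L, org),
                        derived_count = as.integer(dc),
                        maf_panel = pmin(f, 1 - f),
                        minor_is_derived = minor_is_derived,
                        pop_freq = f, q_control = d_ctl)
  structure(list(dosages = dos, haplotypes = H, status = status,
                 markers = markers, phenotypes = NULL,
                 n_cases = sum(status == "case"),
                 n_controls = sum(status == "control")),
            class = "cc_panel")
}
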