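#' Quality-control thresholds
#'
#' The four inclusion criteria applied, in order, by [apply_qc()]: sample call
#' rate, SNP call rate, minor allele frequency, and the exact Hardy-Weinberg
#' test p-value. All boundaries are inclusive (a value equal to the threshold
#' passes).
#'
#' @param sample_call_rate_min Minimum fraction of non-missing calls per
#'   sample (default 0.95).
#' @param snp_call_rate_min Minimum fraction of non-missing calls per SNP
#'   (default 0.95).
#' @param maf_min Minimum minor allele frequency, computed from non-missing
#'   calls (default 0.01).
#' @param hwe_p_min Minimum exact HWE p-value (default 1e-3).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.95,
                          snp_call_rate_min = 0.95,
                          maf_min = 0.01,
                          hwe_p_min = 1e-3) {
  vals <- c(sample_call_rate_min, snp_call_rate_min, maf_min, hwe_p_min)
  if (any(vals < 0 | vals > 1)) stop("all QC thresholds must lie in [0, 1]")
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 snp_call_rate_min = snp_call_rate_min,
                 maf_min = maf_min, hwe_p_min = hwe_p_min),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the allele counts: the p-value is the
#' total probability of all heterozygote counts whose conditional probability
#' under HWE is no larger than that of the observed count. A monomorphic site
#' returns 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("negative genotype count")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("no genotypes")
  n_a <- 2 * n_hom_alt + n_het  # copies of the rarer-or-either allele
  n_r <- 2 * n_hom_ref + n_het
  if (n_a == 0 || n_r == 0) return(1)
  n_minor <- min(n_a, n_r)
  # all heterozygote counts compatible with the allele counts (same parity)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  # log P(n_het = h | allele counts) up to a shared constant:
  #   n! / (n_hom_ref! n_het! n_hom_alt!) * 2^h / C(2n, n_a)
  homs_alt <- (n_a - hets) / 2
  homs_ref <- n - hets - homs_alt
  logp <- hets * log(2) - lgamma(hets + 1) - lgamma(homs_alt + 1) -
    lgamma(homs_ref + 1)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs + 1e-12])
}

#' Apply genotype quality control
#'
#' Applies the four filters in fixed order — sample call rate, SNP call rate,
#' minor allele frequency, exact HWE — each computed on the data surviving
#' the previous steps (so the per-step removal counts are order-dependent).
#'
#' @param dataset A [genotype_dataset()].
#' @param thresholds A [qc_thresholds()] object.
#' @return List with elements `dataset` (the filtered data) and `report`, a
#'   data frame of per-step removals (`step`, `unit`, `n_removed`,
#'   `n_remaining`).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  report <- data.frame(step = character(0), unit = character(0),
                       n_removed = integer(0), n_remaining = integer(0),
                       stringsAsFactors = FALSE)
  add <- function(step, unit, removed, remaining) {
    rbind(report, data.frame(step = step, unit = unit, n_removed = removed,
                             n_remaining = remaining,
                             stringsAsFactors = FALSE))
  }

  # 1. sample call rate
  cr_s <- rowMeans(!is.na(dataset$calls))
  keep_s <- cr_s >= thresholds$sample_call_rate_min
  dataset <- subset_dataset(dataset, samples = which(keep_s))
  report <- add("sample_call_rate", "samples", sum(!keep_s), sum(keep_s))

  # 2. SNP call rate (on retained samples)
  cr_m <- colMeans(!is.na(dataset$calls))
  keep_m <- cr_m >= thresholds$snp_call_rate_min
  dataset <- subset_dataset(dataset, snp_ids = which(keep_m))
  report <- add("snp_call_rate", "snps", sum(!keep_m), sum(keep_m))

  # 3. minor allele frequency (non-missing calls only)
  p <- allele_frequencies(dataset)
  maf <- pmin(p, 1 - p)
  keep_m <- !is.na(maf) & maf >= thresholds$maf_min
  dataset <- subset_dataset(dataset, snp_ids = which(keep_m))
  report <- add("maf", "snps", sum(!keep_m), sum(keep_m))

  # 4. exact HWE
  n_het <- colSums(dataset$calls == 1L, na.rm = TRUE)
  n_alt <- colSums(dataset$calls == 2L, na.rm = TRUE)
  n_ref <- colSums(dataset$calls == 0L, na.rm = TRUE)
  pvals <- vapply(seq_len(ncol(dataset$calls)), function(j) {
    if (n_ref[j] + n_het[j] + n_alt[j] == 0) return(1)  # fully missing SNP
    hwe_exact_p(n_ref[j], n_het[j], n_alt[j])
  }, numeric(1))
  keep_m <- pvals >= thresholds$hwe_p_min
  dataset <- subset_dataset(dataset, snp_ids = which(keep_m))
  report <- add("hwe", "snps", sum(!keep_m), sum(keep_m))

  list(dataset = dataset, report = report)
}
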