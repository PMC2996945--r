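#' Allele-frequency differential delta
#'
#' The absolute difference in allele frequencies between the two parental
#' populations, `delta = |p1 - p2|`. Vectorized.
#'
#' @param p1,p2 Allele frequencies in \code{[0, 1]}.
#' @return `|p1 - p2|`.
#' @export
compute_delta <- function(p1, p2) {
  check_freq(p1); check_freq(p2)
  abs(p1 - p2)
}

check_freq <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("allele frequencies must lie in [0, 1]")
  }
  invisible(p)
}

#' Wright's two-population F_ST
#'
#' Variance-standardized differentiation between two populations:
#' `F_ST = s^2 / (p_bar (1 - p_bar))` with `p_bar = (p1 + p2)/2` and
#' `s^2 = ((p1 - p_bar)^2 + (p2 - p_bar)^2) / 2` (population variance over
#' K = 2 populations, equal weights). Sites fixed for the same allele in both
#' populations (`p_bar` 0 or 1) return 0. Vectorized.
#'
#' @param p1,p2 Allele frequencies in \code{[0, 1]}.
#' @return F_ST in \code{[0, 1]}.
#' @export
compute_fst <- function(p1, p2) {
  check_freq(p1); check_freq(p2)
  p_bar <- (p1 + p2) / 2
  s2 <- ((p1 - p_bar)^2 + (p2 - p_bar)^2) / 2
  denom <- p_bar * (1 - p_bar)
  out <- ifelse(denom == 0, 0, s2 / denom)
  as.numeric(out)
}

#' Attainable F_ST range at fixed delta
#'
#' Minimum and maximum of [compute_fst()] over all parental frequency pairs
#' with `|p1 - p2| = delta`, found by grid search over the lower frequency
#' `p1` in `[0, 1 - delta]`. Closed forms are `delta^2` (minimum, at
#' `p_bar = 1/2`) and `delta / (2 - delta)` (maximum, at the boundary).
#'
#' The grid is evaluated in integer-scaled form: with `k = 1/resolution`,
#' `d = delta k` and `p1 = i/k`, F_ST reduces to the exact rational
#' `d^2 / ((2i + d)(2k - 2i - d))`, so grid values carry no accumulated
#' floating-point error (e.g. the minimum at `delta = 0.6` is exactly 0.36).
#' `delta` is snapped to the nearest multiple of `resolution`.
#'
#' @param delta Fixed allele-frequency differential in \code{[0, 1]}.
#' @param resolution Grid step for `p1` (default 1e-4).
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
fst_bounds_given_delta <- function(delta, resolution = 1e-4) {
  stopifnot(length(delta) == 1, delta >= 0, delta <= 1,
            resolution > 0, resolution <= 1)
  if (delta == 0) return(c(min = 0, max = 0))
  k <- round(1 / resolution)
  d <- round(delta * k)
  if (d == 0) return(c(min = 0, max = 0))
  i <- 0:(k - d)
  f <- d^2 / ((2 * i + d) * (2 * k - 2 * i - d))
  c(min = min(f), max = max(f))
}

#' Attainable delta range at fixed F_ST
#'
#' Minimum and maximum of delta over all parental frequency pairs attaining a
#' given two-population F_ST: `2 F / (1 + F)` to `sqrt(F)` (the inverses of
#' the boundary and symmetric cases of [fst_bounds_given_delta()]).
#'
#' @param fst F_ST value in \code{[0, 1]}.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
delta_bounds_given_fst <- function(fst) {
  stopifnot(length(fst) == 1, fst >= 0, fst <= 1)
  c(min = 2 * fst / (1 + fst), max = sqrt(fst))
}

#' Shannon information content of a marker for ancestry
#'
#' Mutual information (in bits) between the allelic state of a random allele
#' drawn from an admixed individual and the ancestral origin of the
#' chromosome carrying it. The joint allele-by-ancestry cells are
#' `a00 = (1 - m) p_yri`, `a01 = m p_ceu`, `a10 = (1 - m)(1 - p_yri)`,
#' `a11 = m (1 - p_ceu)`, where `m` is the European admixture proportion.
#' Vectorized over frequencies.
#'
#' @param p_ceu,p_yri Frequencies of the same allele in the two parental
#'   populations.
#' @param m European admixture proportion (default 0.2).
#' @param base Logarithm base (default 2, i.e. bits).
#' @return Non-negative information content.
#' @export
compute_sic <- function(p_ceu, p_yri, m = 0.2, base = 2) {
  check_freq(p_ceu); check_freq(p_yri)
  stopifnot(m >= 0, m <= 1)
  a <- cbind((1 - m) * p_yri, m * p_ceu, (1 - m) * (1 - p_yri),
             m * (1 - p_ceu))
  row1 <- a[, 1] + a[, 2]          # P(allele present)
  # product of the allele and ancestry marginals, cell by cell
  indep <- cbind(row1 * (1 - m), row1 * m, (1 - row1) * (1 - m),
                 (1 - row1) * m)
  term <- a * log(a / indep, base = base)
  term[!is.finite(term)] <- 0      # 0 log 0 = 0
  pmax(rowSums(term), 0)
}

#' Qualitative interpretation of an F_ST value
#'
#' Wright's guideline categories: little \code{[0, 0.05)}, moderate
#' \code{[0.05, 0.15)}, large \code{[0.15, 0.25)}, very large
#' \code{[0.25, 1]}.
#'
#' @param fst F_ST value(s) in \code{[0, 1]}.
#' @return Factor with levels `little`, `moderate`, `large`, `very_large`.
#' @export
classify_fst <- function(fst) {
  stopifnot(all(fst >= 0 & fst <= 1))
  cut(fst, breaks = c(-Inf, 0.05, 0.15, 0.25, Inf), right = FALSE,
      labels = c("little", "moderate", "large", "very_large"))
}

#' Observed and expected heterozygosity over a SNP subset
#'
#' Observed heterozygosity is the fraction of heterozygous non-missing calls
#' per SNP, averaged over SNPs; expected heterozygosity is the mean of
#' `2 p (1 - p)` with `p` the non-missing alt-allele frequency. SNPs with no
#' non-missing calls are excluded (with a message).
#'
#' @param dataset A [genotype_dataset()].
#' @param snp_subset Character vector of SNP ids (default: all).
#' @return List with `observed` and `expected` heterozygosity and `n_snps`
#'   used.
#' @export
heterozygosity_summary <- function(dataset, snp_subset = NULL) {
  if (is.null(snp_subset)) snp_subset <- dataset$snps$snp_id
  if (length(snp_subset) == 0) stop("empty SNP subset")
  if (!all(snp_subset %in% dataset$snps$snp_id)) {
    stop("subset contains SNPs absent from the dataset")
  }
  d <- subset_dataset(dataset, snp_ids = snp_subset)
  n_obs <- colSums(!is.na(d$calls))
  if (any(n_obs == 0)) {
    message(sum(n_obs == 0), " SNP(s) with no non-missing calls excluded")
  }
  use <- n_obs > 0
  het_obs <- colSums(d$calls[, use, drop = FALSE] == 1L, na.rm = TRUE) /
    n_obs[use]
  p <- colSums(d$calls[, use, drop = FALSE], na.rm = TRUE) / (2 * n_obs[use])
  list(observed = mean(het_obs), expected = mean(2 * p * (1 - p)),
       n_snps = sum(use))
}

#' Per-SNP differentiation statistics between two parental datasets
#'
#' Computes, for every SNP shared by two harmonized parental datasets, the
#' alt-allele frequencies, delta, the F_ST components (`p_bar`, `s2`), F_ST,
#' and the Shannon information content at admixture proportion `m`.
#'
#' @param parent1,parent2 Harmonized [genotype_dataset()] objects with an
#'   identical SNP table (population 1 plays the European/CEU role in the
#'   SIC computation).
#' @param m Admixture proportion for the SIC column (default 0.2).
#' @return Data frame with columns `snp_id`, `p1`, `p2`, `delta`, `p_bar`,
#'   `s2`, `fst`, `sic`.
#' @export
differentiation_stats <- function(parent1, parent2, m = 0.2) {
  if (!identical(parent1$snps$snp_id, parent2$snps$snp_id)) {
    stop("datasets are not harmonized (SNP lists differ); run harmonize()")
  }
  p1 <- allele_frequencies(parent1)
  p2 <- allele_frequencies(parent2)
  ok <- !is.na(p1) & !is.na(p2)
  p1[!ok] <- 0; p2[!ok] <- 0
  p_bar <- (p1 + p2) / 2
  out <- data.frame(
    snp_id = parent1$snps$snp_id,
    p1 = as.numeric(p1), p2 = as.numeric(p2),
    delta = compute_delta(p1, p2),
    p_bar = as.numeric(p_bar),
    s2 = as.numeric(((p1 - p_bar)^2 + (p2 - p_bar)^2) / 2),
    fst = compute_fst(p1, p2),
    sic = compute_sic(p1, p2, m = m),
    stringsAsFactors = FALSE
  )
  out$delta[!ok] <- NA_real_
  out$fst[!ok] <- NA_real_
  out$sic[!ok] <- NA_real_
  out
}
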