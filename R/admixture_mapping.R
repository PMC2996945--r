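#' Ancestry relative-risk model
#'
#' Multiplicative per-allele risk model on the African-origin allele count:
#' relative risk `psi2` for carriers of two African-origin alleles versus
#' zero (default 2.80, a typical African- vs European-American relative-risk
#' estimate for hypertensive heart disease), and `psi1 = sqrt(psi2)` for one
#' copy unless given.
#'
#' @param psi2 Relative risk of 2 vs 0 African-origin alleles (> 0).
#' @param psi1 Relative risk of 1 vs 0 copies (> 0); default `sqrt(psi2)`.
#' @return A list of class `risk_model`.
#' @export
risk_model <- function(psi2 = 2.80, psi1 = sqrt(psi2)) {
  stopifnot(psi2 > 0, psi1 > 0)
  structure(list(psi2 = psi2, psi1 = psi1), class = "risk_model")
}

#' Phenotype table
#'
#' @param sample_id Character vector of sample ids.
#' @param status Vector coercible to `"case"`/`"control"`.
#' @return Data frame of class `phenotype_table` with columns `sample_id`,
#'   `status` (factor control/case).
#' @export
phenotype_table <- function(sample_id, status) {
  status <- as.character(status)
  if (!all(status %in% c("case", "control"))) {
    stop('status must be "case" or "control"')
  }
  structure(data.frame(sample_id = as.character(sample_id),
                       status = factor(status, levels = c("control", "case")),
                       stringsAsFactors = FALSE),
            class = c("phenotype_table", "data.frame"))
}

check_phenotypes <- function(field, phen) {
  if (!all(phen$sample_id %in% field$samples)) {
    stop("phenotype table contains samples absent from the posterior field")
  }
  idx <- match(phen$sample_id, field$samples)
  list(cases = idx[phen$status == "case"],
       controls = idx[phen$status == "control"])
}

# rho indexed by EUROPEAN count k = 0,1,2: African count is 2 - k.
rho_by_keur <- function(risk) c(risk$psi2, risk$psi1, 1)

#' Case-only locus-genome LOD score
#'
#' Compares the ancestry at each grid locus with the genome-wide average
#' among cases only, under a fixed ancestry relative-risk model. Per case j
#' and locus i the likelihood-ratio factor is
#' `T_ij = sum_k q_ijk rho_k / sum_k pi_jk rho_k`, with `q` the local
#' posterior, `pi_j` the genome-wide prior from `m_j`, and `rho` the relative
#' risk by African-origin allele count; `LOD_i = sum_cases log10 T_ij`
#' (the likelihood-ratio statistic divided by 2 ln 10).
#'
#' @param field An `ancestry_posterior_field`.
#' @param params An [admixture_params()] or `admix_fit` (for the per-
#'   individual genome-wide `m`).
#' @param phen A [phenotype_table()] with at least one case.
#' @param risk A [risk_model()].
#' @return Numeric vector of per-grid-locus LOD scores.
#' @export
locus_genome_lod <- function(field, params, phen, risk = risk_model()) {
  if (inherits(params, "admix_fit")) params <- params$params
  grp <- check_phenotypes(field, phen)
  if (length(grp$cases) < 1) stop("need at least one case")
  rho <- rho_by_keur(risk)
  m <- params$m[grp$cases]
  pri <- ancestry_prior(m)
  denom <- as.numeric(pri %*% rho)       # per case
  L <- dim(field$q)[2]
  vapply(seq_len(L), function(i) {
    q <- field$q[grp$cases, i, , drop = TRUE]
    if (is.null(dim(q))) q <- matrix(q, nrow = 1)
    num <- as.numeric(q %*% rho)
    sum(log10(num / denom))
  }, numeric(1))
}

#' Case-control ancestry z statistic
#'
#' At each grid locus, each individual's deviation of local African ancestry
#' from their genome-wide average, `D_ij = E_q[k_Afr]/2 - (1 - m_j)`, is
#' compared between cases and controls with a Welch-type two-sample z:
#' `z_i = (mean_case D - mean_ctrl D) / sqrt(s2_case/n_case +
#' s2_ctrl/n_ctrl)`; approximately standard normal when no locus affects
#' disease. Zero variance in both groups gives z = 0.
#'
#' @param field An `ancestry_posterior_field`.
#' @param params An [admixture_params()] or `admix_fit`.
#' @param phen A [phenotype_table()] with at least two cases and two
#'   controls.
#' @return Numeric vector of per-grid-locus z values.
#' @export
case_control_z <- function(field, params, phen) {
  if (inherits(params, "admix_fit")) params <- params$params
  grp <- check_phenotypes(field, phen)
  if (length(grp$cases) < 2 || length(grp$controls) < 2) {
    stop("need at least two cases and two controls")
  }
  # E[k_Afr]/2 = (2 - E[k_Eur])/2 at each locus
  ek_eur <- function(rows, i) {
    q <- field$q[rows, i, , drop = TRUE]
    if (is.null(dim(q))) q <- matrix(q, nrow = 1)
    q[, 2] + 2 * q[, 3]
  }
  a_case <- 1 - params$m[grp$cases]
  a_ctrl <- 1 - params$m[grp$controls]
  n1 <- length(grp$cases); n2 <- length(grp$controls)
  L <- dim(field$q)[2]
  vapply(seq_len(L), function(i) {
    d1 <- (2 - ek_eur(grp$cases, i)) / 2 - a_case
    d2 <- (2 - ek_eur(grp$controls, i)) / 2 - a_ctrl
    se2 <- var(d1) / n1 + var(d2) / n2
    if (se2 == 0) return(0)
    (mean(d1) - mean(d2)) / sqrt(se2)
  }, numeric(1))
}

#' Admixture-mapping statistics over a posterior field
#'
#' Convenience wrapper computing both the locus-genome LOD and the
#' case-control z at every grid locus, with significance flags.
#'
#' @inheritParams locus_genome_lod
#' @param lod_threshold Genome-wide LOD significance threshold (default 2).
#' @param z_threshold Genome-wide |z| threshold; defaults to 4.2, the value
#'   for AIM panels (use 4.7 for random-marker panels).
#' @return Data frame of class `mapping_statistics`: `chrom`, `cm`, `lod`,
#'   `z`, `lod_flag`, `z_flag`.
#' @export
admixture_map <- function(field, params, phen, risk = risk_model(),
                          lod_threshold = 2, z_threshold = 4.2) {
  lod <- locus_genome_lod(field, params, phen, risk)
  z <- case_control_z(field, params, phen)
  out <- cbind(field$grid,
               data.frame(lod = lod, z = z,
                          lod_flag = lod >= lod_threshold,
                          z_flag = abs(z) >= z_threshold))
  class(out) <- c("mapping_statistics", "data.frame")
  attr(out, "thresholds") <- c(lod = lod_threshold, z = z_threshold)
  out
}

#' Significant loci from mapping statistics
#'
#' @param stats A `mapping_statistics` data frame (from [admixture_map()])
#'   or any data frame with `lod` and `z` columns.
#' @param lod_threshold LOD threshold (default 2).
#' @param z_threshold |z| threshold (default 4.2 for AIM panels; 4.7 for
#'   random panels).
#' @return The rows whose `lod >= lod_threshold` or `|z| >= z_threshold`,
#'   with a `reason` column.
#' @export
significance_calls <- function(stats, lod_threshold = 2, z_threshold = 4.2) {
  stopifnot(lod_threshold > 0, z_threshold > 0)
  hit_lod <- stats$lod >= lod_threshold
  hit_z <- abs(stats$z) >= z_threshold
  keep <- hit_lod | hit_z
  out <- as.data.frame(stats)[keep, , drop = FALSE]
  reason <- character(sum(keep))
  reason[hit_lod[keep] & hit_z[keep]] <- "lod+z"
  reason[hit_lod[keep] & !hit_z[keep]] <- "lod"
  reason[!hit_lod[keep] & hit_z[keep]] <- "z"
  out$reason <- reason
  rownames(out) <- NULL
  out
}
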