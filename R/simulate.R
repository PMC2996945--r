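#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: a two-way
#' admixed cohort under the hybrid-isolation model (a single admixture event
#' `lambda_gen` generations ago, no subsequent gene flow), with parental
#' reference panels drawn at known allele frequencies.
#'
#' @param n_individuals Admixed cohort size (default 100).
#' @param n_parental Individuals per parental reference panel (default 100).
#' @param n_snps Total SNP count, spread evenly over chromosomes (default
#'   500).
#' @param n_chrom Number of chromosomes (default 22, emulating the human
#'   autosomes).
#' @param chrom_length_cm Genetic length of each chromosome in cM (default
#'   160, giving a human-scale autosomal map of about 35 Morgans).
#' @param delta_preset Parental frequency sampler: `"aims"` draws
#'   differentials delta uniform on \code{[0.6, 0.8]} (AIM-like markers);
#'   `"random"` emulates the genome-wide delta spectrum (mean differential
#'   about 0.14).
#' @param m_beta Shape parameters `c(alpha, beta)` of the Beta distribution
#'   of individual European ancestry proportions; default `c(2, 8)` (mean
#'   0.2, matching typical African-American estimates).
#' @param lambda_gen Generations since admixture (default 7).
#' @param missing_rate Uniform genotype missingness (default 0.01).
#' @param risk_locus Optional disease locus: list with `chrom`, `cm` and
#'   `psi2` (ancestry relative risk for 2 vs 0 African-origin alleles).
#' @param ld_blocks Optional planted LD in the parental panels: list with
#'   `span` (SNPs per block) and `copy_prob` (per-allele probability of
#'   copying the block leader's allele); used to exercise LD pruning. `NULL`
#'   (default) draws frequencies independently across SNPs.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100, n_parental = 100, n_snps = 500,
                       n_chrom = 22, chrom_length_cm = 160,
                       delta_preset = c("aims", "random"),
                       m_beta = c(2, 8), lambda_gen = 7, missing_rate = 0.01,
                       risk_locus = NULL, ld_blocks = NULL, seed = 1L) {
  delta_preset <- match.arg(delta_preset)
  stopifnot(n_individuals >= 1, n_parental >= 1, n_snps >= 1, n_chrom >= 1,
            chrom_length_cm > 0, length(m_beta) == 2, all(m_beta > 0),
            lambda_gen > 0, missing_rate >= 0, missing_rate <= 1)
  if (!is.null(risk_locus)) {
    stopifnot(all(c("chrom", "cm", "psi2") %in% names(risk_locus)))
  }
  structure(list(n_individuals = n_individuals, n_parental = n_parental,
                 n_snps = n_snps, n_chrom = n_chrom,
                 chrom_length_cm = chrom_length_cm,
                 delta_preset = delta_preset, m_beta = m_beta,
                 m_sampler = NULL, lambda_gen = lambda_gen,
                 missing_rate = missing_rate, risk_locus = risk_locus,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

# Shared SNP scaffold: ids, chromosomes, positions (1 cM ~ 1 Mb).
sim_snp_table <- function(config) {
  per_chrom <- diff(round(seq(0, config$n_snps, length.out = config$n_chrom + 1)))
  snps <- do.call(rbind, lapply(seq_len(config$n_chrom), function(ch) {
    k <- per_chrom[ch]
    if (k == 0) return(NULL)
    cm <- sort(runif(k, 0, config$chrom_length_cm))
    data.frame(chrom = as.character(ch), pos_cm = cm,
               pos_bp = as.integer(round(cm * 1e6) + seq_len(k)),
               stringsAsFactors = FALSE)
  }))
  snps$snp_id <- sprintf("snp%05d", seq_len(nrow(snps)))
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(nrow(pairs), nrow(snps), replace = TRUE)
  snps$ref <- pairs[pick, 1]
  snps$alt <- pairs[pick, 2]
  snps[, c("snp_id", "chrom", "pos_bp", "pos_cm", "ref", "alt")]
}

# Parental allele-frequency pairs under the named preset.
sim_freq_pairs <- function(n, preset) {
  if (preset == "aims") {
    delta <- runif(n, 0.6, 0.8)
    p_bar <- runif(n, delta / 2, 1 - delta / 2)
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    p_ceu <- p_bar + sgn * delta / 2
    p_yri <- p_bar - sgn * delta / 2
  } else {
    p_ceu <- runif(n, 0.05, 0.95)
    p_yri <- pmin(pmax(p_ceu + rnorm(n, 0, 0.1755), 0.01), 0.99)
  }
  cbind(p_ceu = p_ceu, p_yri = p_yri)
}

#' Simulate parental reference panels
#'
#' Draws per-SNP parental allele-frequency pairs under the configured preset
#' and parental genotypes as binomial(2, p) per individual. With
#' `ld_blocks`, SNPs within each block copy the block leader's alleles with
#' probability `copy_prob` (per allele), planting genotype correlation.
#'
#' @param config A [sim_config()].
#' @return List with `pop1`/`pop2` ([genotype_dataset()] objects; pop1 plays
#'   the European role), and `freqs` (data frame `snp_id`, `p_ceu`,
#'   `p_yri` of the true frequencies).
#' @export
simulate_parental <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  snps <- sim_snp_table(config)
  n_snp <- nrow(snps)
  fp <- sim_freq_pairs(n_snp, config$delta_preset)

  draw_pop <- function(p, label, prefix) {
    n <- config$n_parental
    calls <- matrix(rbinom(n * n_snp, 2, rep(p, each = n)), nrow = n)
    if (!is.null(config$ld_blocks)) {
      span <- config$ld_blocks$span
      cp <- config$ld_blocks$copy_prob
      for (ch in unique(snps$chrom)) {
        idx <- which(snps$chrom == ch)
        starts <- idx[seq(1, length(idx), by = span)]
        for (s in starts) {
          block <- idx[idx >= s & idx < s + span]
          for (j in setdiff(block, s)) {
            # per-allele copy of the leader, approximating r ~ copy_prob
            copy1 <- rbinom(n, 1, cp)
            copy2 <- rbinom(n, 1, cp)
            lead1 <- as.integer(calls[, s] == 2) +
              rbinom(n, 1, 0.5) * as.integer(calls[, s] == 1)
            lead2 <- pmin(calls[, s] - lead1, 1)
            own1 <- rbinom(n, 1, p[j]); own2 <- rbinom(n, 1, p[j])
            calls[, j] <- (copy1 * lead1 + (1 - copy1) * own1) +
              (copy2 * lead2 + (1 - copy2) * own2)
          }
        }
      }
    }
    if (config$missing_rate > 0) {
      calls[matrix(runif(length(calls)) < config$missing_rate,
                   nrow = n)] <- NA_integer_
    }
    genotype_dataset(sprintf("%s%04d", prefix, seq_len(n)), snps, calls,
                     population = label)
  }

  list(pop1 = draw_pop(fp[, "p_ceu"], "POP1", "p1_"),
       pop2 = draw_pop(fp[, "p_yri"], "POP2", "p2_"),
       freqs = data.frame(snp_id = snps$snp_id, p_ceu = fp[, "p_ceu"],
                          p_yri = fp[, "p_yri"], stringsAsFactors = FALSE))
}

# One haplotype's ancestry tracts along a chromosome of given length:
# initial state Bernoulli(m), Poisson(lambda * L_morgan) breakpoints at
# uniform positions, ancestry re-drawn Bernoulli(m) at each breakpoint
# ("pool" model). Returns list(breaks = cM positions, states = 0/1 European
# indicator per segment, length(states) = length(breaks) + 1).
sim_haplotype_tracts <- function(m, lambda, length_cm) {
  n_break <- rpois(1, lambda * length_cm / 100)
  breaks <- sort(runif(n_break, 0, length_cm))
  states <- rbinom(n_break + 1, 1, m)
  list(breaks = breaks, states = states)
}

# Ancestry (0/1 European) of a haplotype at positions cm.
tract_state_at <- function(tract, cm) {
  tract$states[findInterval(cm, tract$breaks) + 1L]
}

#' Simulate an admixed cohort under the hybrid-isolation model
#'
#' Each individual draws a European ancestry proportion `m_j` from the
#' configured Beta distribution; each of their two haplotypes per chromosome
#' draws ancestry tracts by the breakpoint-and-redraw process (breakpoints
#' Poisson with rate `lambda_gen` per Morgan; ancestry Bernoulli(`m_j`) at
#' the chromosome start and after every breakpoint). Alleles are drawn from
#' the tract ancestry's parental frequency; missingness is applied
#' uniformly.
#'
#' @param config A [sim_config()].
#' @param freqs True parental frequency table (`snp_id`, `p_ceu`, `p_yri`),
#'   e.g. from [simulate_parental()]; must cover the same SNP scaffold
#'   (i.e. use the same `config` sizes).
#' @return List with `dataset` (the admixed [genotype_dataset()]) and
#'   `truth` (class `truth_set`: `m` per individual, `k_eur` matrix of true
#'   European allele counts at every SNP, and the per-haplotype tract
#'   lists).
#' @export
simulate_admixed <- function(config, freqs) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  snps <- sim_snp_table(config)
  if (!identical(snps$snp_id, freqs$snp_id)) {
    stop("frequency table does not match the config's SNP scaffold")
  }
  set.seed(config$seed + 1L)

  n <- config$n_individuals
  m <- if (!is.null(config$m_sampler)) {
    config$m_sampler(n)
  } else {
    rbeta(n, config$m_beta[1], config$m_beta[2])
  }
  n_snp <- nrow(snps)
  k_eur <- matrix(0L, n, n_snp)
  calls <- matrix(NA_integer_, n, n_snp)
  tracts <- vector("list", n)
  chroms <- unique(snps$chrom)

  for (j in seq_len(n)) {
    tr_j <- list()
    for (ch in chroms) {
      idx <- which(snps$chrom == ch)
      cm <- snps$pos_cm[idx]
      h1 <- sim_haplotype_tracts(m[j], config$lambda_gen,
                                 config$chrom_length_cm)
      h2 <- sim_haplotype_tracts(m[j], config$lambda_gen,
                                 config$chrom_length_cm)
      a1 <- tract_state_at(h1, cm)  # 1 = European
      a2 <- tract_state_at(h2, cm)
      k_eur[j, idx] <- a1 + a2
      p1 <- ifelse(a1 == 1, freqs$p_ceu[idx], freqs$p_yri[idx])
      p2 <- ifelse(a2 == 1, freqs$p_ceu[idx], freqs$p_yri[idx])
      calls[j, idx] <- rbinom(length(idx), 1, p1) + rbinom(length(idx), 1, p2)
      tr_j[[ch]] <- list(h1 = h1, h2 = h2)
    }
    tracts[[j]] <- tr_j
  }
  if (config$missing_rate > 0) {
    calls[matrix(runif(length(calls)) < config$missing_rate,
                 nrow = n)] <- NA_integer_
  }
  samples <- sprintf("adm%04d", seq_len(n))
  truth <- structure(list(m = setNames(m, samples),
                          k_eur = k_eur, tracts = tracts,
                          snps = snps, samples = samples,
                          chrom_length_cm = config$chrom_length_cm),
                     class = "truth_set")
  list(dataset = genotype_dataset(samples, snps, calls,
                                  population = "ADMIXED"),
       truth = truth)
}

#' True ancestry at an arbitrary genomic position
#'
#' @param truth A `truth_set` from [simulate_admixed()].
#' @param chrom Chromosome label.
#' @param cm Genetic position in cM.
#' @return Integer vector: each individual's true European-origin allele
#'   count at the position.
#' @export
true_ancestry_at <- function(truth, chrom, cm) {
  chrom <- as.character(chrom)
  vapply(truth$tracts, function(tr_j) {
    tract_state_at(tr_j[[chrom]]$h1, cm) + tract_state_at(tr_j[[chrom]]$h2, cm)
  }, integer(1))
}

#' Assign case/control phenotypes from an ancestry risk locus
#'
#' Case probability is proportional to `psi2^(k_Afr / 2)` at the risk locus,
#' where `k_Afr` is the individual's true African-origin allele count there
#' (so carriers of two African-origin alleles are `psi2` times as likely to
#' be sampled as cases as carriers of none). `n_cases` cases are drawn
#' without replacement with those weights and `n_controls` controls
#' uniformly from the remainder. With no risk locus (or `psi2 = 1`) labels
#' are assigned at random.
#'
#' @param truth A `truth_set` from [simulate_admixed()].
#' @param risk_locus List with `chrom`, `cm`, `psi2`, or `NULL` for the null
#'   model.
#' @param n_cases,n_controls Numbers to sample.
#' @param seed Integer seed.
#' @return A [phenotype_table()].
#' @export
assign_phenotypes <- function(truth, risk_locus, n_cases, n_controls,
                              seed = 1L) {
  n <- length(truth$samples)
  if (n_cases + n_controls > n) {
    stop("not enough individuals to sample the requested cases and controls")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(risk_locus) || risk_locus$psi2 == 1) {
    w <- rep(1, n)
  } else {
    k_afr <- 2L - true_ancestry_at(truth, risk_locus$chrom, risk_locus$cm)
    w <- risk_locus$psi2^(k_afr / 2)
  }
  cases <- sample.int(n, n_cases, prob = w)
  controls <- sample(setdiff(seq_len(n), cases), n_controls)
  phenotype_table(
    sample_id = c(truth$samples[cases], truth$samples[controls]),
    status = rep(c("case", "control"), c(n_cases, n_controls))
  )
}
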