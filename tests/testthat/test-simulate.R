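# Synthetic parental panels and hybrid-isolation admixed cohorts.

test_that("the aims preset draws differentials in [0.6, 0.8]", {
  par <- simulate_parental(sim_config(n_parental = 5, n_snps = 400,
                                      delta_preset = "aims", seed = 61))
  d <- abs(par$freqs$p_ceu - par$freqs$p_yri)
  expect_true(all(d >= 0.6 & d <= 0.8))
  expect_true(all(par$freqs$p_ceu >= 0 & par$freqs$p_ceu <= 1))
  expect_true(all(par$freqs$p_yri >= 0 & par$freqs$p_yri <= 1))
})

test_that("the random preset emulates a genome-wide differential spectrum", {
  par <- simulate_parental(sim_config(n_parental = 5, n_snps = 2000,
                                      delta_preset = "random", seed = 62))
  d <- abs(par$freqs$p_ceu - par$freqs$p_yri)
  expect_gt(mean(d), 0.08)
  expect_lt(mean(d), 0.20)
  expect_gt(mean(d >= 0.6), 0)      # a thin informative tail exists
  expect_lt(mean(d >= 0.6), 0.05)
})

test_that("generation is seed-deterministic and leaves the RNG untouched", {
  cfg <- sim_config(n_individuals = 10, n_parental = 10, n_snps = 30,
                    n_chrom = 2, chrom_length_cm = 100, seed = 63)
  a <- simulate_parental(cfg)
  b <- simulate_parental(cfg)
  expect_datasets_equal(a$pop1, b$pop1)
  expect_identical(a$freqs, b$freqs)
  s1 <- simulate_admixed(cfg, a$freqs)
  s2 <- simulate_admixed(cfg, a$freqs)
  expect_datasets_equal(s1$dataset, s2$dataset)
  expect_identical(s1$truth$m, s2$truth$m)
  cfg2 <- cfg; cfg2$seed <- 64L
  expect_false(identical(simulate_parental(cfg2)$freqs$p_ceu,
                         a$freqs$p_ceu))
  # global RNG stream is unaffected by the internal seeding
  set.seed(99); x1 <- runif(3)
  set.seed(99); invisible(simulate_parental(cfg)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("parental and admixed generators share one SNP scaffold", {
  cfg <- sim_config(n_individuals = 5, n_parental = 5, n_snps = 40,
                    n_chrom = 3, seed = 65)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  expect_identical(par$pop1$snps, sim$dataset$snps)
  expect_identical(par$pop1$snps, par$pop2$snps)
})

test_that("parental sample frequencies estimate the true frequencies", {
  par <- simulate_parental(sim_config(n_parental = 200, n_snps = 300,
                                      missing_rate = 0.01, seed = 66))
  est <- allele_frequencies(par$pop1)
  expect_lt(mean(abs(est - par$freqs$p_ceu)), 0.04)
  est2 <- allele_frequencies(par$pop2)
  expect_lt(mean(abs(est2 - par$freqs$p_yri)), 0.04)
})

test_that("a vanishing recombination rate yields whole-chromosome tracts", {
  cfg <- sim_config(n_individuals = 20, n_snps = 60, n_chrom = 3,
                    lambda_gen = 1e-9, missing_rate = 0, seed = 67)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  for (ch in unique(sim$dataset$snps$chrom)) {
    idx <- sim$dataset$snps$chrom == ch
    k <- sim$truth$k_eur[, idx, drop = FALSE]
    expect_true(all(apply(k, 1, function(r) length(unique(r)) == 1)))
  }
})

test_that("a degenerate ancestry sampler produces a single-ancestry cohort", {
  cfg <- sim_config(n_individuals = 10, n_snps = 40, n_chrom = 2,
                    missing_rate = 0, seed = 68)
  cfg$m_sampler <- function(n) rep(1, n)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  expect_true(all(sim$truth$m == 1))
  expect_true(all(sim$truth$k_eur == 2L))
})

test_that("breakpoint counts match the Poisson rate per Morgan", {
  cfg <- sim_config(n_individuals = 50, n_snps = 44, seed = 69)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  n_breaks <- unlist(lapply(sim$truth$tracts, function(tr_j) {
    vapply(tr_j, function(tc) {
      c(length(tc$h1$breaks), length(tc$h2$breaks))
    }, numeric(2))
  }))
  # lambda * L = 7 * 1.6 Morgans = 11.2 expected per haplotype;
  # 2200 haplotypes give a standard error of about 0.07
  expect_equal(mean(n_breaks), 11.2, tolerance = 0.05)
})

test_that("realized ancestry matches the Beta admixture distribution", {
  cfg <- sim_config(n_individuals = 100, n_snps = 110, seed = 70)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  expect_equal(mean(1 - sim$truth$m), 0.8, tolerance = 0.05)
  expect_equal(mean(2 - sim$truth$k_eur) / 2, 0.8, tolerance = 0.05)
  # realized marker ancestry tracks each individual's m
  expect_gt(cor(sim$truth$m, rowMeans(sim$truth$k_eur) / 2), 0.9)
})

test_that("truth matrix agrees with tract lookup at marker positions", {
  cfg <- sim_config(n_individuals = 8, n_snps = 30, n_chrom = 2, seed = 71)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  set.seed(1)
  for (j in sample(nrow(sim$truth$snps), 5)) {
    expect_identical(
      unname(sim$truth$k_eur[, j]),
      true_ancestry_at(sim$truth, sim$truth$snps$chrom[j],
                       sim$truth$snps$pos_cm[j]))
  }
})

test_that("planted LD blocks raise adjacent genotype correlation", {
  base <- sim_config(n_parental = 150, n_snps = 80, n_chrom = 2,
                     missing_rate = 0, seed = 72)
  with_ld <- base
  with_ld$ld_blocks <- list(span = 4, copy_prob = 0.9)
  p_ind <- simulate_parental(base)$pop1
  p_ld <- simulate_parental(with_ld)$pop1
  adj_r2 <- function(d) {
    mean(vapply(seq_len(ncol(d$calls) - 1), function(j) {
      if (d$snps$chrom[j] != d$snps$chrom[j + 1]) return(NA_real_)
      genotype_r2(d$calls[, j], d$calls[, j + 1])
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(adj_r2(p_ind), 0.1)
  expect_gt(adj_r2(p_ld), 0.4)
})

test_that("null phenotypes are balanced and seed-reproducible", {
  cfg <- sim_config(n_individuals = 60, n_snps = 22, seed = 73)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  ph <- assign_phenotypes(sim$truth, NULL, n_cases = 20, n_controls = 25,
                          seed = 5)
  expect_equal(sum(ph$status == "case"), 20)
  expect_equal(sum(ph$status == "control"), 25)
  expect_false(any(duplicated(ph$sample_id)))
  expect_identical(ph, assign_phenotypes(sim$truth, NULL, 20, 25, seed = 5))
  expect_error(assign_phenotypes(sim$truth, NULL, 40, 30, seed = 5),
               "not enough")
})

test_that("an extreme risk locus makes every case an African homozygote", {
  cfg <- sim_config(n_individuals = 300, n_snps = 20, n_chrom = 1,
                    chrom_length_cm = 100, seed = 74)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  rl <- list(chrom = "1", cm = 50, psi2 = 1e9)
  ph <- assign_phenotypes(sim$truth, rl, n_cases = 30, n_controls = 30,
                          seed = 6)
  k_afr <- 2L - true_ancestry_at(sim$truth, "1", 50)
  names(k_afr) <- sim$truth$samples
  expect_true(all(k_afr[ph$sample_id[ph$status == "case"]] == 2L))
})

test_that("case enrichment approximates the configured relative risk", {
  cfg <- sim_config(n_individuals = 5000, n_snps = 10, n_chrom = 1,
                    chrom_length_cm = 100, m_beta = c(5, 5), seed = 75)
  par <- simulate_parental(cfg)
  sim <- simulate_admixed(cfg, par$freqs)
  rl <- list(chrom = "1", cm = 40, psi2 = 2.8)
  ph <- assign_phenotypes(sim$truth, rl, n_cases = 500, n_controls = 500,
                          seed = 7)
  k_afr <- 2L - true_ancestry_at(sim$truth, "1", 40)
  names(k_afr) <- sim$truth$samples
  is_case <- sim$truth$samples %in% ph$sample_id[ph$status == "case"]
  rate <- tapply(is_case, k_afr, mean)
  # ratio of case rates between 2 and 0 African-origin alleles ~ psi2 = 2.8
  # (slightly depleted by without-replacement sampling); band fixed a priori
  expect_gt(rate[["2"]] / rate[["0"]], 2.1)
  expect_lt(rate[["2"]] / rate[["0"]], 3.6)
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(sim_config(risk_locus = list(chrom = "1", cm = 10)), "psi2")
  expect_error(sim_config(missing_rate = 2), "missing_rate")
  expect_error(sim_config(m_beta = c(1, -1)), "m_beta")
  cfg <- sim_config(n_snps = 10, n_chrom = 1)
  par <- simulate_parental(cfg)
  bad <- par$freqs
  bad$snp_id <- rev(bad$snp_id)
  expect_error(simulate_admixed(cfg, bad), "scaffold")
})
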