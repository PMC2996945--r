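# Six-step AIM selection, VIF pruning, random panels and panel summaries.
# (Brute-force selection oracle and LD fixture live in helper-oracles.R.)

test_that("genotype r2 matches hand computation and handles edge cases", {
  g <- c(0, 1, 2, 1, 0, 2)
  expect_equal(genotype_r2(g, g), 1)
  expect_equal(genotype_r2(g, 2 - g), 1)  # perfect negative correlation
  h <- c(2, 1, 0, 1, 1, 0)
  expect_equal(genotype_r2(g, h), brute_r2(g, h))
  expect_equal(genotype_r2(rep(1, 6), g), 0)  # constant vector
  expect_error(genotype_r2(c(0, NA, NA), c(NA, 1, 1)), "fewer than 2")
  expect_error(genotype_r2(1:3, 1:4), "length")
})

test_that("a single qualifying SNP yields a panel of exactly that SNP", {
  set.seed(41)
  n <- 50
  g1 <- cbind(rbinom(n, 2, 0.9), rbinom(n, 2, 0.5))
  g2 <- cbind(rbinom(n, 2, 0.1), rbinom(n, 2, 0.5))
  p1 <- make_dataset(g1, population = "P1")
  p2 <- make_dataset(g2, population = "P2")
  panel <- select_aims(p1, p2, selection_config("delta", threshold = 0.6))
  expect_equal(nrow(panel$panel), 1)
  expect_equal(panel$panel$snp_id, "s001")
})

test_that("an LD pair across bins drops the lower-criterion bin entirely", {
  n <- 60
  set.seed(42)
  base <- rbinom(n, 2, 0.85)
  g1 <- cbind(base, base)          # r2 = 1 in parent 1
  g2 <- cbind(rbinom(n, 2, 0.05), rbinom(n, 2, 0.15))
  snps_bp <- c(5e5, 15e5)          # two different 1-Mb bins
  p1 <- make_dataset(g1, pos_bp = snps_bp, population = "P1")
  p2 <- make_dataset(g2, pos_bp = snps_bp, population = "P2")
  panel <- select_aims(p1, p2, selection_config("delta", threshold = 0.5))
  expect_equal(nrow(panel$panel), 1)
  # the retained SNP is the one with the larger delta (SNP 1)
  expect_equal(panel$panel$snp_id, "s001")
  expect_equal(nrow(panel$discarded), 1)
})

test_that("selection matches the brute-force re-implementation on a planted fixture", {
  fx <- build_ld_fixture()
  for (crit in c("delta", "fst")) {
    cfg <- selection_config(crit)
    panel <- select_aims(fx$pop1, fx$pop2, cfg)
    oracle_idx <- brute_select(fx$pop1$calls, fx$pop2$calls, fx$pop1$snps,
                               threshold = cfg$threshold, criterion = crit)
    expect_identical(panel$panel$snp_id, fx$pop1$snps$snp_id[oracle_idx])
    # final-panel invariants: one SNP per bin, r2 < 0.4 in BOTH parents
    expect_false(any(duplicated(paste(panel$panel$chrom, panel$panel$bin))))
    for (ch in unique(panel$panel$chrom)) {
      ids <- panel$panel$snp_id[panel$panel$chrom == ch]
      if (length(ids) < 2) next
      for (i in seq_along(ids)[-1]) for (k in seq_len(i - 1)) {
        expect_lt(genotype_r2(fx$pop1$calls[, ids[i]], fx$pop1$calls[, ids[k]]),
                  0.4)
        expect_lt(genotype_r2(fx$pop2$calls[, ids[i]], fx$pop2$calls[, ids[k]]),
                  0.4)
      }
    }
  }
})

test_that("raising the threshold never enlarges the panel", {
  fx <- build_ld_fixture(seed = 32)
  sizes <- vapply(c(0.4, 0.5, 0.6, 0.7, 0.8), function(th) {
    nrow(select_aims(fx$pop1, fx$pop2,
                     selection_config("delta", threshold = th))$panel)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("with no LD the panel is the top-criterion SNP of every qualifying bin", {
  par <- simulate_parental(sim_config(n_parental = 150, n_snps = 60,
                                      n_chrom = 2, chrom_length_cm = 100,
                                      delta_preset = "aims",
                                      missing_rate = 0, seed = 17))
  cfg <- selection_config("delta", threshold = 0.5)
  panel <- select_aims(par$pop1, par$pop2, cfg)
  st <- differentiation_stats(par$pop1, par$pop2)
  st$bin <- floor((par$pop1$snps$pos_bp - 1) / cfg$bin_size_bp)
  st$chrom <- par$pop1$snps$chrom
  maf_ok <- pmin(st$p1, 1 - st$p1) >= 0.01 & pmin(st$p2, 1 - st$p2) >= 0.01
  qual <- st[maf_ok & st$delta >= 0.5, ]
  expected <- do.call(rbind, lapply(split(qual, paste(qual$chrom, qual$bin)),
                                    function(s) s[which.max(s$delta), ]))
  # no planted LD: with high probability nothing is pruned
  expect_setequal(panel$panel$snp_id, expected$snp_id)
})

test_that("selection is invariant to input SNP order", {
  fx <- build_ld_fixture(seed = 33)
  perm <- sample(nrow(fx$pop1$snps))
  shuf <- function(d) {
    genotype_dataset(d$samples, d$snps[perm, ], d$calls[, perm], d$population)
  }
  a <- select_aims(fx$pop1, fx$pop2, selection_config("delta"))
  b <- select_aims(shuf(fx$pop1), shuf(fx$pop2), selection_config("delta"))
  expect_identical(a$panel$snp_id, b$panel$snp_id)
})

# -- VIF pruning --

# Brute-force oracle with the same window walk but VIFs from explicit lm fits.
vif_oracle <- function(calls, snps_chrom, window = 50, slide = 5,
                       vif_max = 1.1) {
  keep <- rep(TRUE, ncol(calls))
  for (ch in unique(snps_chrom)) {
    idx_ch <- which(snps_chrom == ch)
    start <- 1
    repeat {
      alive <- idx_ch[keep[idx_ch]]
      if (start > length(alive)) break
      win <- alive[start:min(start + window - 1, length(alive))]
      if (length(win) >= 2) {
        repeat {
          g <- calls[, win[keep[win]], drop = FALSE]
          cols <- win[keep[win]]
          if (length(cols) < 2) break
          vifs <- vapply(seq_along(cols), function(k) {
            y <- g[, k]; X <- g[, -k, drop = FALSE]
            fit <- stats::lm(y ~ X)
            r2 <- summary(fit)$r.squared
            if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
          }, numeric(1))
          if (max(vifs) <= vif_max + 1e-12) break
          keep[cols[which.max(vifs)]] <- FALSE
        }
      }
      if (start + window - 1 >= length(alive)) break
      start <- start + slide
    }
  }
  keep
}

test_that("independent SNPs are all retained by VIF pruning", {
  d <- random_dataset(n = 200, p = 30, missing_rate = 0, seed = 21)
  kept <- vif_prune(d, window_snps = 10, slide_snps = 3, vif_max = 2)
  expect_identical(kept, d$snps$snp_id)
})

test_that("a duplicated SNP column loses exactly one copy", {
  d <- random_dataset(n = 100, p = 20, missing_rate = 0, seed = 22)
  d$calls[, 7] <- d$calls[, 6]
  kept <- vif_prune(d, window_snps = 10, slide_snps = 5, vif_max = 1.5)
  expect_equal(sum(!(d$snps$snp_id %in% kept)), 1)
  expect_true(sum(d$snps$snp_id[c(6, 7)] %in% kept) == 1)
})

test_that("windowed pruning matches a brute-force lm-based oracle", {
  set.seed(23)
  n <- 150; p <- 60
  calls <- matrix(rbinom(n * p, 2, rep(runif(p, 0.2, 0.8), each = n)),
                  nrow = n)
  # planted 3-SNP dependency: SNP 30 ~ near-exact function of 28 and 29
  calls[, 30] <- pmin(pmax(round((calls[, 28] + calls[, 29]) / 2 +
                                   rbinom(n, 1, 0.02)), 0), 2)
  d <- make_dataset(calls)
  kept <- vif_prune(d, window_snps = 20, slide_snps = 5, vif_max = 1.1)
  oracle_keep <- vif_oracle(calls, d$snps$chrom, window = 20, slide = 5,
                            vif_max = 1.1)
  expect_identical(kept, d$snps$snp_id[oracle_keep])
})

test_that("random panels follow the rounding convention and are seeded", {
  ids <- sprintf("id%05d", seq_len(21637))
  expect_identical(random_panel(ids, 1, seed = 5), ids)
  expect_length(random_panel(ids, 0.1, seed = 5), 2164)  # round(2163.7)
  expect_identical(random_panel(ids, 0.1, seed = 5),
                   random_panel(ids, 0.1, seed = 5))
  expect_false(identical(random_panel(ids, 0.1, seed = 5),
                         random_panel(ids, 0.1, seed = 6)))
})

# -- panel summaries --

toy_panel <- function(bp, chrom = rep("1", length(bp)), cm = bp / 1e6) {
  data.frame(snp_id = sprintf("t%02d", seq_along(bp)), chrom = chrom,
             pos_bp = as.integer(bp), pos_cm = cm, ref = "A", alt = "G",
             delta = 0.7, fst = 0.45, sic = 0.3, stringsAsFactors = FALSE)
}

test_that("mean inter-marker distance excludes centromere-spanning gaps", {
  p <- toy_panel(c(1e6, 4e6))
  s <- panel_summary(p)
  expect_equal(s$mean_gap_cm, 3)
  expect_false(s$centromeres_excluded)

  cen <- data.frame(chrom = "1", start_bp = 2e6, end_bp = 3e6)
  s2 <- panel_summary(p, centromeres = cen)
  expect_true(is.na(s2$mean_gap_cm))
  expect_equal(s2$n_gaps, 0)
})

test_that("summary gaps equal direct enumeration on a simulated panel", {
  set.seed(77)
  bp <- sort(sample.int(150e6, 100))
  chrom <- rep(c("1", "2"), each = 50)
  bp[51:100] <- sort(sample.int(100e6, 50))
  p <- toy_panel(bp, chrom = chrom)
  cen <- data.frame(chrom = c("1", "2"), start_bp = c(60e6, 40e6),
                    end_bp = c(70e6, 45e6))
  s <- panel_summary(p, centromeres = cen)
  gaps <- numeric(0)
  for (ch in c("1", "2")) {
    sub <- p[p$chrom == ch, ]
    sub <- sub[order(sub$pos_bp), ]
    cc <- cen[cen$chrom == ch, ]
    for (i in seq_len(nrow(sub) - 1)) {
      spans <- sub$pos_bp[i] < cc$start_bp && sub$pos_bp[i + 1] > cc$end_bp
      if (!spans) gaps <- c(gaps, sub$pos_cm[i + 1] - sub$pos_cm[i])
    }
  }
  expect_equal(s$n_gaps, length(gaps))
  expect_equal(s$mean_gap_cm, mean(gaps))
  expect_equal(sum(s$per_chromosome$n), 100)
})
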