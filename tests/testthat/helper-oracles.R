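# Independent oracle implementations shared across test files: brute-force
# re-implementations written without the package's internals.

# -- independent brute-force re-implementation of the six-step selection --
# Straightforward data-frame loops; correlation computed from the textbook
# sum formula rather than cor().
brute_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2) - sx^2 / n
  syy <- sum(y^2) - sy^2 / n
  sxy <- sum(x * y) - sx * sy / n
  if (sxx == 0 || syy == 0) return(0)
  (sxy / sqrt(sxx * syy))^2
}

brute_select <- function(p1_calls, p2_calls, snps, threshold = 0.6,
                         criterion = "delta", bin_bp = 1e6, r2_max = 0.4,
                         maf_min = 0.01) {
  f1 <- colMeans(p1_calls, na.rm = TRUE) / 2
  f2 <- colMeans(p2_calls, na.rm = TRUE) / 2
  crit <- if (criterion == "delta") {
    abs(f1 - f2)
  } else {
    pb <- (f1 + f2) / 2
    ifelse(pb * (1 - pb) == 0, 0, ((f1 - f2)^2 / 4) / (pb * (1 - pb)))
  }
  ok <- pmin(f1, 1 - f1) >= maf_min & pmin(f2, 1 - f2) >= maf_min &
    crit >= threshold
  pool <- data.frame(j = which(ok), chrom = snps$chrom[ok],
                     bp = snps$pos_bp[ok], crit = crit[ok],
                     bin = floor((snps$pos_bp[ok] - 1) / bin_bp),
                     stringsAsFactors = FALSE)
  pool <- pool[order(as.numeric(pool$chrom), pool$bin, -pool$crit, pool$bp), ]
  repeat {
    tops <- pool[!duplicated(paste(pool$chrom, pool$bin)), ]
    # find the highest-r2 conflicting pair over all chromosomes
    best <- NULL; best_r2 <- -1
    for (ch in unique(tops$chrom)) {
      tch <- tops[tops$chrom == ch, ]
      if (nrow(tch) < 2) next
      for (i in seq_len(nrow(tch) - 1)) for (k in (i + 1):nrow(tch)) {
        r2 <- max(brute_r2(p1_calls[, tch$j[i]], p1_calls[, tch$j[k]]),
                  brute_r2(p2_calls[, tch$j[i]], p2_calls[, tch$j[k]]))
        if (r2 >= 0.4 && r2 > best_r2) {
          best_r2 <- r2
          ci <- round(tch$crit[i], 4); ck <- round(tch$crit[k], 4)
          drop <- if (ci < ck) i else if (ck < ci) k
                  else if (tch$bp[i] > tch$bp[k]) i else k
          best <- tch$j[drop]
        }
      }
    }
    if (is.null(best)) break
    pool <- pool[pool$j != best, ]
    if (nrow(pool) == 0) break
  }
  tops <- pool[!duplicated(paste(pool$chrom, pool$bin)), ]
  sort(tops$j)
}

# Parental fixture builder: 200 SNPs on 3 chromosomes with planted LD blocks
# (exact copies -> criterion ties -> the distal rule; noisy copies -> r2
# between 0.4 and 1).
build_ld_fixture <- function(seed = 31) {
  set.seed(seed)
  n <- 120; p <- 200
  chrom <- as.character(rep(1:3, times = c(80, 70, 50)))
  bp <- unlist(lapply(c(80, 70, 50), function(k) {
    sort(sample.int(12e6, k))
  }))
  d <- runif(p, 0.3, 0.9)
  pb <- runif(p, pmax(d / 2, 0.05), pmin(1 - d / 2, 0.95))
  f1 <- pmin(pmax(pb + d / 2, 0), 1)
  f2 <- pmin(pmax(pb - d / 2, 0), 1)
  g1 <- matrix(rbinom(n * p, 2, rep(f1, each = n)), nrow = n)
  g2 <- matrix(rbinom(n * p, 2, rep(f2, each = n)), nrow = n)
  # exact duplicates across neighbouring bins: criterion tie + r2 = 1
  for (pair in list(c(3, 12), c(90, 101), c(155, 168))) {
    g1[, pair[2]] <- g1[, pair[1]]
    g2[, pair[2]] <- g2[, pair[1]]
  }
  # noisy copies: r2 high but < 1, criterion values differ
  for (pair in list(c(20, 31), c(45, 60), c(110, 125))) {
    swap <- runif(n) < 0.15
    g1[, pair[2]] <- ifelse(swap, rbinom(n, 2, f1[pair[2]]), g1[, pair[1]])
    g2[, pair[2]] <- ifelse(swap, rbinom(n, 2, f2[pair[2]]), g2[, pair[1]])
  }
  g1[matrix(runif(n * p) < 0.01, nrow = n)] <- NA_integer_
  g2[matrix(runif(n * p) < 0.01, nrow = n)] <- NA_integer_
  snps <- data.frame(snp_id = sprintf("fx%03d", 1:p), chrom = chrom,
                     pos_bp = bp, pos_cm = bp / 1e6, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  list(pop1 = genotype_dataset(sprintf("a%03d", 1:n), snps, g1, "P1"),
       pop2 = genotype_dataset(sprintf("b%03d", 1:n), snps, g2, "P2"))
}

# Independent oracle: enumerate all 2^L x 2^L ordered haplotype-ancestry
# paths of one diploid individual and accumulate exact posteriors of the
# European allele count and the exact likelihood. Feasible for L <= 6.
enumerate_posterior <- function(g, cm, m, lambda, pc, py) {
  L <- length(g)
  paths <- as.matrix(expand.grid(rep(list(0:1), L)))  # 1 = European
  hap_prob <- apply(paths, 1, function(h) {
    p <- if (h[1] == 1) m else 1 - m
    if (L > 1) {
      for (t in 2:L) {
        e <- exp(-lambda * (cm[t] - cm[t - 1]) / 100)
        pE <- if (h[t - 1] == 1) e + (1 - e) * m else (1 - e) * m
        p <- p * (if (h[t] == 1) pE else 1 - pE)
      }
    }
    p
  })
  post <- matrix(0, L, 3)
  tot <- 0
  for (i in seq_len(nrow(paths))) {
    for (j in seq_len(nrow(paths))) {
      w <- hap_prob[i] * hap_prob[j]
      for (t in seq_len(L)) {
        if (!is.na(g[t])) {
          f1 <- if (paths[i, t] == 1) pc[t] else py[t]
          f2 <- if (paths[j, t] == 1) pc[t] else py[t]
          pg <- switch(g[t] + 1L,
                       (1 - f1) * (1 - f2),
                       f1 * (1 - f2) + (1 - f1) * f2,
                       f1 * f2)
          w <- w * pg
        }
      }
      tot <- tot + w
      for (t in seq_len(L)) {
        k <- paths[i, t] + paths[j, t]
        post[t, k + 1] <- post[t, k + 1] + w
      }
    }
  }
  list(post = post / tot, loglik = log(tot))
}
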