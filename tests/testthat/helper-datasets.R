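# Small builders used across the suite.

# A genotype_dataset from a dosage matrix (samples x snps), with evenly
# spaced positions on one or more chromosomes.
make_dataset <- function(calls, chrom = NULL, pos_bp = NULL, pos_cm = NULL,
                         population = "TEST") {
  calls <- as.matrix(calls)
  n <- nrow(calls); p <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", p)
  if (is.null(pos_bp)) pos_bp <- stats::ave(seq_len(p), chrom,
                                            FUN = function(i) seq_along(i) * 1e5)
  snps <- data.frame(
    snp_id = sprintf("s%03d", seq_len(p)),
    chrom = chrom, pos_bp = as.integer(pos_bp),
    pos_cm = if (is.null(pos_cm)) NA_real_ else pos_cm,
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  genotype_dataset(sprintf("i%03d", seq_len(n)), snps, calls, population)
}

# A random dataset with missing data, used for round-trip tests.
random_dataset <- function(n = 50, p = 100, missing_rate = 0.05, seed = 1,
                           population = "SIM") {
  set.seed(seed)
  freqs <- runif(p, 0.05, 0.95)
  calls <- matrix(rbinom(n * p, 2, rep(freqs, each = n)), nrow = n)
  calls[matrix(runif(n * p) < missing_rate, nrow = n)] <- NA_integer_
  chrom <- as.character(rep(1:2, length.out = p))
  pos <- stats::ave(seq_len(p), chrom, FUN = seq_along) * 12345L
  pairs <- rbind(c("A", "G"), c("C", "T"), c("G", "C"), c("T", "A"))
  pick <- sample.int(4, p, replace = TRUE)
  snps <- data.frame(snp_id = sprintf("rs%04d", seq_len(p)), chrom = chrom,
                     pos_bp = pos, pos_cm = pos / 1e6,
                     ref = pairs[pick, 1], alt = pairs[pick, 2],
                     stringsAsFactors = FALSE)
  genotype_dataset(sprintf("smp%03d", seq_len(n)), snps, calls, population)
}

expect_datasets_equal <- function(a, b) {
  expect_identical(a$samples, b$samples)
  expect_equal(a$snps[c("snp_id", "chrom", "pos_bp", "ref", "alt")],
               b$snps[c("snp_id", "chrom", "pos_bp", "ref", "alt")])
  expect_identical(unname(a$calls), unname(b$calls))
}
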