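#' Construct a genotype dataset
#'
#' The universal container for diploid biallelic SNP genotypes: a samples x
#' SNPs dosage matrix (copies of the alternate allele, 0/1/2, `NA` = missing)
#' plus per-SNP metadata.
#'
#' @param samples Character vector of unique sample identifiers.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos_bp` and
#'   `ref`, `alt` (single bases in A/C/G/T), optionally `pos_cm`. Rows are
#'   sorted by (chromosome, bp position) on construction.
#' @param calls Integer matrix, `length(samples)` rows x `nrow(snps)` columns,
#'   entries in `{0, 1, 2, NA}`.
#' @param population Free-text population label (e.g. `"CEU"`).
#'
#' @return An object of class `genotype_dataset` with elements `samples`,
#'   `snps`, `calls` and `population`. `calls` carries sample ids as rownames
#'   and SNP ids as colnames.
#' @export
genotype_dataset <- function(samples, snps, calls, population = "unknown") {
  samples <- as.character(samples)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos_bp", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("pos_cm" %in% names(snps))) snps$pos_cm <- NA_real_
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos_bp <- as.integer(snps$pos_bp)
  snps$pos_cm <- as.numeric(snps$pos_cm)
  snps$ref <- toupper(as.character(snps$ref))
  snps$alt <- toupper(as.character(snps$alt))

  if (anyDuplicated(samples)) stop("duplicate sample ids")
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  bad <- !(snps$ref %in% c("A", "C", "G", "T")) |
    !(snps$alt %in% c("A", "C", "G", "T")) | snps$ref == snps$alt
  if (any(bad)) {
    stop("invalid ref/alt alleles at snp(s): ",
         paste(head(snps$snp_id[bad], 5), collapse = ", "))
  }
  if (any(snps$pos_bp < 0, na.rm = TRUE)) stop("negative bp position")

  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(snps)) {
    stop(sprintf("calls matrix is %d x %d, expected %d x %d",
                 nrow(calls), ncol(calls), length(samples), nrow(snps)))
  }
  vals <- calls[!is.na(calls)]
  if (length(vals) > 0 && (min(vals) < 0L || max(vals) > 2L)) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }

  ord <- order(chrom_rank(snps$chrom), snps$pos_bp)
  snps <- snps[ord, , drop = FALSE]
  rownames(snps) <- NULL
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples, snps$snp_id)

  structure(
    list(samples = samples, snps = snps, calls = calls,
         population = as.character(population)),
    class = "genotype_dataset"
  )
}

# Chromosome sort order: 1..22 numerically, then X, then anything else.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  r <- ifelse(!is.na(n), n, ifelse(chrom == "X", 23, 24))
  r
}

#' @export
print.genotype_dataset <- function(x, ...) {
  n_missing <- sum(is.na(x$calls))
  cat(sprintf("genotype_dataset: %d samples x %d SNPs (population: %s)\n",
              length(x$samples), nrow(x$snps), x$population))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", n_missing,
              100 * n_missing / max(1, length(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset
#'
#' @param dataset A `genotype_dataset`.
#' @param samples Optional character vector (or logical/integer index) of
#'   samples to keep.
#' @param snp_ids Optional character vector (or logical/integer index) of SNPs
#'   to keep.
#' @return The subsetted `genotype_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, snp_ids = NULL) {
  keep_s <- seq_along(dataset$samples)
  if (!is.null(samples)) {
    keep_s <- if (is.character(samples)) {
      match(samples, dataset$samples)
    } else {
      keep_s[samples]
    }
    if (anyNA(keep_s)) stop("unknown sample id(s)")
  }
  keep_m <- seq_len(nrow(dataset$snps))
  if (!is.null(snp_ids)) {
    keep_m <- if (is.character(snp_ids)) {
      match(snp_ids, dataset$snps$snp_id)
    } else {
      keep_m[snp_ids]
    }
    if (anyNA(keep_m)) stop("unknown snp id(s)")
  }
  genotype_dataset(
    samples = dataset$samples[keep_s],
    snps = dataset$snps[keep_m, , drop = FALSE],
    calls = dataset$calls[keep_s, keep_m, drop = FALSE],
    population = dataset$population
  )
}

#' Alternate-allele frequencies of a dataset
#'
#' Computed from non-missing calls only; SNPs with no non-missing calls get
#' `NA`.
#'
#' @param dataset A `genotype_dataset`.
#' @return Named numeric vector of alt-allele frequencies, one per SNP.
#' @export
allele_frequencies <- function(dataset) {
  n_obs <- colSums(!is.na(dataset$calls))
  freq <- colSums(dataset$calls, na.rm = TRUE) / (2 * n_obs)
  freq[n_obs == 0] <- NA_real_
  setNames(as.numeric(freq), dataset$snps$snp_id)
}

datasets_equal <- function(a, b) {
  identical(a$samples, b$samples) &&
    isTRUE(all.equal(a$snps[c("snp_id", "chrom", "pos_bp", "ref", "alt")],
                     b$snps[c("snp_id", "chrom", "pos_bp", "ref", "alt")])) &&
    identical(is.na(a$calls), is.na(b$calls)) &&
    identical(a$calls[!is.na(a$calls)], b$calls[!is.na(b$calls)])
}
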