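#' Read a genotype dataset from a text genotype file
#'
#' Supported dialects:
#' \describe{
#'   \item{`ped`}{PLINK text `.ped` plus a `.map` marker file. Both the
#'     standard 4-column `.map` (chrom, id, cM, bp) and the 6-column
#'     `.bim`-style variant (chrom, id, cM, bp, alt, ref) are accepted; the
#'     6-column form carries allele labels explicitly (column 5 is the counted
#'     allele, as in PLINK's A1). With a 4-column map, alleles are inferred
#'     from the genotypes: the minor allele becomes the counted (alt) allele,
#'     ties broken lexicographically. `path` may name either the `.ped` file
#'     or the common prefix.}
#'   \item{`vcf`}{VCF 4.x; biallelic SNP rows only. Multiallelic or non-SNP
#'     records are skipped and counted in a message.}
#'   \item{`eigenstrat`}{EIGENSTRAT-style `.geno`/`.snp`/`.ind` triple. The
#'     `.geno` digit is the count of reference-allele copies (9 = missing);
#'     the `.snp` file gives id, chromosome, genetic position in Morgans,
#'     physical position and the reference/variant alleles.}
#' }
#' Missing genotypes (`0 0`, `./.`, `9`) are normalized to `NA`.
#'
#' @param path File path (for `ped`/`eigenstrat`, any member file or the
#'   common prefix of the file set).
#' @param format One of `"ped"`, `"vcf"`, `"eigenstrat"`.
#' @param population Population label to attach; for `eigenstrat` defaults to
#'   the label in the `.ind` file when uniform.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("ped", "vcf", "eigenstrat"),
                           population = NULL) {
  format <- match.arg(format)
  switch(format,
    ped = read_ped(path, population),
    vcf = read_vcf(path, population),
    eigenstrat = read_eigenstrat(path, population)
  )
}

#' Write a genotype dataset to a text genotype file
#'
#' Inverse of [read_genotypes()]: files written here read back into an equal
#' dataset (same samples, SNP metadata and calls, missing preserved). Genetic
#' positions absent from the dataset are written as 0.
#'
#' @param dataset A [genotype_dataset()].
#' @param path Output path; for `ped`/`eigenstrat` the common prefix
#'   (extensions are appended).
#' @param format One of `"ped"`, `"vcf"`, `"eigenstrat"`.
#' @return Invisibly, the path(s) written.
#' @export
write_genotypes <- function(dataset, path,
                            format = c("ped", "vcf", "eigenstrat")) {
  format <- match.arg(format)
  switch(format,
    ped = write_ped(dataset, path),
    vcf = write_vcf(dataset, path),
    eigenstrat = write_eigenstrat(dataset, path)
  )
}

strip_ext <- function(path, exts) {
  for (e in exts) path <- sub(paste0("\\.", e, "$"), "", path)
  path
}

## ---- PLINK .ped/.map ----

read_ped <- function(path, population = NULL) {
  prefix <- strip_ext(path, c("ped", "map"))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path)) stop("missing .ped file: ", ped_path)
  if (!file.exists(map_path)) stop("missing .map file: ", map_path)

  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!(ncol(map) %in% c(4L, 6L))) {
    stop(".map must have 4 or 6 columns, found ", ncol(map))
  }
  n_snp <- nrow(map)
  have_alleles <- ncol(map) == 6L

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n_sample <- length(lines)
  samples <- character(n_sample)
  # allele pairs per sample, stored as two character matrices
  a1 <- matrix(NA_character_, n_sample, n_snp)
  a2 <- matrix(NA_character_, n_sample, n_snp)
  for (i in seq_len(n_sample)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * n_snp) {
      stop(sprintf("malformed .ped record at line %d: %d fields, expected %d",
                   i, length(f), 6 + 2 * n_snp))
    }
    samples[i] <- f[2]
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1, by = 2, length.out = n_snp)]
    a2[i, ] <- g[seq(2, by = 2, length.out = n_snp)]
  }
  a1[a1 == "0"] <- NA_character_
  a2[a2 == "0"] <- NA_character_

  if (have_alleles) {
    alt <- toupper(map[[5]])
    ref <- toupper(map[[6]])
  } else {
    ref <- alt <- character(n_snp)
    bases <- c("A", "C", "G", "T")
    for (j in seq_len(n_snp)) {
      obs <- c(a1[, j], a2[, j])
      obs <- obs[!is.na(obs)]
      tab <- sort(table(factor(obs, levels = unique(obs))), decreasing = TRUE)
      al <- names(tab)
      if (length(al) > 2) {
        stop("more than two alleles at SNP ", map[[2]][j])
      }
      if (length(al) == 2) {
        # minor allele counted; frequency tie broken lexicographically
        if (tab[1] == tab[2]) al <- sort(al)
        ref[j] <- al[1]
        alt[j] <- al[2]
      } else if (length(al) == 1) {
        ref[j] <- al[1]
        alt[j] <- setdiff(bases, al[1])[1]
      } else {
        ref[j] <- "A"; alt[j] <- "C"  # fully missing column
      }
    }
  }

  # compare per-SNP allele vectors against the (sample x SNP) allele matrices
  alt_m <- matrix(alt[col(a1)], nrow = n_sample, ncol = n_snp)
  ref_m <- matrix(ref[col(a1)], nrow = n_sample, ncol = n_snp)
  calls <- (a1 == alt_m) + (a2 == alt_m)
  bad <- (!is.na(a1) & !(a1 == alt_m | a1 == ref_m)) |
         (!is.na(a2) & !(a2 == alt_m | a2 == ref_m))
  if (any(bad)) {
    stop("genotype allele not matching ref/alt at SNP ",
         map[[2]][which(colSums(bad) > 0)[1]])
  }

  cm <- suppressWarnings(as.numeric(map[[3]]))
  genotype_dataset(
    samples = samples,
    snps = data.frame(snp_id = map[[2]], chrom = map[[1]],
                      pos_bp = as.integer(map[[4]]),
                      pos_cm = ifelse(cm == 0, NA_real_, cm),
                      ref = ref, alt = alt, stringsAsFactors = FALSE),
    calls = calls,
    population = if (is.null(population)) "unknown" else population
  )
}

write_ped <- function(dataset, path) {
  prefix <- strip_ext(path, c("ped", "map"))
  snps <- dataset$snps
  cm <- ifelse(is.na(snps$pos_cm), 0, snps$pos_cm)
  map <- data.frame(snps$chrom, snps$snp_id, cm, snps$pos_bp,
                    snps$alt, snps$ref)
  write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  n_snp <- nrow(snps)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_along(dataset$samples)) {
    g <- dataset$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, snps$alt, snps$ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, snps$alt, snps$ref))
    pair <- character(2 * n_snp)
    pair[seq(1, by = 2, length.out = n_snp)] <- a1
    pair[seq(2, by = 2, length.out = n_snp)] <- a2
    writeLines(paste(c(dataset$samples[i], dataset$samples[i], "0", "0",
                       "0", "-9", pair), collapse = " "), con)
  }
  invisible(paste0(prefix, c(".ped", ".map")))
}

## ---- VCF ----

read_vcf <- function(path, population = NULL) {
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  is_snp <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0) {
    message(n_skip, " multiallelic/non-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])

  dosage <- apply(gt, 2, function(col) {
    col <- gsub("\\|", "/", col)
    d <- rep(NA_integer_, length(col))
    d[col == "0/0"] <- 0L
    d[col %in% c("0/1", "1/0")] <- 1L
    d[col == "1/1"] <- 2L
    d
  })
  dosage <- matrix(dosage, nrow = nrow(gt), dimnames = dimnames(gt))

  genotype_dataset(
    samples = colnames(gt),
    snps = data.frame(snp_id = ids,
                      chrom = sub("^chr", "", fix[, "CHROM"]),
                      pos_bp = as.integer(fix[, "POS"]),
                      ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
                      stringsAsFactors = FALSE),
    calls = t(dosage),
    population = if (is.null(population)) "unknown" else population
  )
}

write_vcf <- function(dataset, path) {
  snps <- dataset$snps
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=aimpanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$samples), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(snps)), function(j) {
    g <- dataset$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(snps$chrom[j], snps$pos_bp[j], snps$snp_id[j], snps$ref[j],
            snps$alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

## ---- EIGENSTRAT-style triple ----

read_eigenstrat <- function(path, population = NULL) {
  prefix <- strip_ext(path, c("geno", "snp", "ind"))
  geno_path <- paste0(prefix, ".geno")
  snp_path <- paste0(prefix, ".snp")
  ind_path <- paste0(prefix, ".ind")
  for (p in c(geno_path, snp_path, ind_path)) {
    if (!file.exists(p)) stop("missing file: ", p)
  }
  snp <- read.table(snp_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(snp) < 6) stop(".snp file must have 6 columns (id chrom morgans bp ref alt)")
  ind <- read.table(ind_path, header = FALSE, stringsAsFactors = FALSE)
  lines <- readLines(geno_path)
  lines <- lines[nzchar(lines)]
  if (length(lines) != nrow(snp)) {
    stop(sprintf(".geno has %d rows but .snp lists %d SNPs",
                 length(lines), nrow(snp)))
  }
  digits <- vapply(lines, function(l) {
    as.integer(strsplit(l, "")[[1]])
  }, integer(nrow(ind)), USE.NAMES = FALSE)
  digits <- matrix(digits, nrow = nrow(ind))  # samples x snps
  if (any(!(digits %in% c(0L, 1L, 2L, 9L)))) {
    stop("invalid .geno code (must be 0/1/2/9)")
  }
  calls <- 2L - digits  # digit counts reference-allele copies
  calls[digits == 9L] <- NA_integer_

  morgans <- as.numeric(snp[[3]])
  pop <- population
  if (is.null(pop)) {
    labs <- unique(as.character(ind[[3]]))
    pop <- if (length(labs) == 1) labs else "unknown"
  }
  genotype_dataset(
    samples = as.character(ind[[1]]),
    snps = data.frame(snp_id = snp[[1]], chrom = snp[[2]],
                      pos_bp = as.integer(snp[[4]]),
                      pos_cm = ifelse(morgans == 0, NA_real_, 100 * morgans),
                      ref = toupper(snp[[5]]), alt = toupper(snp[[6]]),
                      stringsAsFactors = FALSE),
    calls = calls,
    population = pop
  )
}

write_eigenstrat <- function(dataset, path) {
  prefix <- strip_ext(path, c("geno", "snp", "ind"))
  snps <- dataset$snps
  morgans <- ifelse(is.na(snps$pos_cm), 0, snps$pos_cm / 100)
  snp <- data.frame(snps$snp_id, snps$chrom, formatC(morgans, format = "f",
                    digits = 8), snps$pos_bp, snps$ref, snps$alt)
  write.table(snp, paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ind <- data.frame(dataset$samples, "U", dataset$population)
  write.table(ind, paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  digit <- 2L - dataset$calls
  digit[is.na(digit)] <- 9L
  rows <- apply(digit, 2, paste, collapse = "")  # one line per SNP
  writeLines(as.character(rows), paste0(prefix, ".geno"))
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

## ---- Harmonization ----

#' Harmonize SNP content across genotype datasets
#'
#' Restricts all datasets to the SNPs shared by every one of them (matched on
#' `snp_id`) and puts them on a common allele orientation (that of the first
#' dataset). A SNP whose ref/alt are swapped relative to the first dataset is
#' recoded (`g -> 2 - g`); a SNP whose alleles cannot be reconciled is
#' dropped. Strand-ambiguous pairs (A/T, C/G) are kept only when ref and alt
#' agree exactly — a swap there is indistinguishable from a strand flip, so
#' those SNPs are dropped and counted.
#'
#' @param datasets List of two or more [genotype_dataset()] objects.
#' @return List of datasets of the same length, all with an identical SNP
#'   table; attribute `"dropped"` carries the number of shared SNPs removed
#'   for allele conflicts.
#' @export
harmonize <- function(datasets) {
  if (length(datasets) < 2) stop("need at least two datasets")
  ids <- Reduce(intersect, lapply(datasets, function(d) d$snps$snp_id))
  if (length(ids) == 0) stop("no SNPs shared by all datasets")

  ref_ds <- datasets[[1]]
  ref_snps <- ref_ds$snps[match(ids, ref_ds$snps$snp_id), , drop = FALSE]
  ambiguous <- (ref_snps$ref == "A" & ref_snps$alt == "T") |
    (ref_snps$ref == "T" & ref_snps$alt == "A") |
    (ref_snps$ref == "C" & ref_snps$alt == "G") |
    (ref_snps$ref == "G" & ref_snps$alt == "C")

  keep <- rep(TRUE, length(ids))
  flip <- vector("list", length(datasets))  # per-dataset recode flags
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    s <- d$snps[match(ids, d$snps$snp_id), , drop = FALSE]
    same <- s$ref == ref_snps$ref & s$alt == ref_snps$alt
    swapped <- s$ref == ref_snps$alt & s$alt == ref_snps$ref
    ok <- same | (swapped & !ambiguous)
    keep <- keep & ok
    flip[[k]] <- swapped & !ambiguous
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " shared SNP(s) dropped for irreconcilable alleles")
  }
  ids <- ids[keep]
  if (length(ids) == 0) stop("no SNPs shared by all datasets after allele reconciliation")

  out <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    idx <- match(ids, d$snps$snp_id)
    calls <- d$calls[, idx, drop = FALSE]
    fl <- flip[[k]][keep]
    if (any(fl)) calls[, fl] <- 2L - calls[, fl, drop = FALSE]
    snps <- ref_ds$snps[match(ids, ref_ds$snps$snp_id), , drop = FALSE]
    out[[k]] <- genotype_dataset(d$samples, snps, calls, d$population)
  }
  attr(out, "dropped") <- n_dropped
  out
}

## ---- Genetic map ----

#' Read a genetic-map anchor table
#'
#' Tab-separated columns: chromosome, physical position (bp), genetic position
#' (cM). A header line is detected and skipped.
#'
#' @param path TSV file path.
#' @return A `genetic_map` data frame with columns `chrom`, `bp`, `cm`,
#'   anchors sorted and strictly increasing in both coordinates per
#'   chromosome.
#' @export
read_genetic_map <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (suppressWarnings(is.na(as.numeric(tab[2, 2])))) {
    stop("genetic map must have numeric bp in column 2")
  }
  if (suppressWarnings(is.na(as.numeric(tab[1, 2])))) {
    tab <- tab[-1, , drop = FALSE]  # header line
  }
  genetic_map(data.frame(chrom = sub("^chr", "", tab[[1]]),
                         bp = as.numeric(tab[[2]]), cm = as.numeric(tab[[3]]),
                         stringsAsFactors = FALSE))
}

#' Construct (and validate) a genetic-map table
#'
#' @param anchors Data frame with columns `chrom`, `bp`, `cm`.
#' @return The validated, sorted `genetic_map` data frame.
#' @export
genetic_map <- function(anchors) {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("chrom", "bp", "cm") %in% names(anchors)))
  anchors$chrom <- as.character(anchors$chrom)
  anchors <- anchors[order(chrom_rank(anchors$chrom), anchors$bp), , drop = FALSE]
  for (ch in unique(anchors$chrom)) {
    a <- anchors[anchors$chrom == ch, ]
    if (any(diff(a$bp) <= 0) || any(diff(a$cm) <= 0)) {
      stop("map anchors must be strictly increasing in bp and cM on chromosome ", ch)
    }
  }
  rownames(anchors) <- NULL
  class(anchors) <- c("genetic_map", "data.frame")
  anchors
}

#' Interpolate genetic positions from a map
#'
#' Fills `pos_cm` by piecewise-linear interpolation between the flanking
#' anchors of each chromosome; positions outside the anchored range take the
#' nearest anchor's cM (constant extrapolation).
#'
#' @param snps SNP table (as in a [genotype_dataset()]) or a
#'   `genotype_dataset` itself.
#' @param map_table A `genetic_map` from [genetic_map()] or
#'   [read_genetic_map()].
#' @return The input with `pos_cm` filled.
#' @export
interpolate_cm <- function(snps, map_table) {
  is_ds <- inherits(snps, "genotype_dataset")
  tab <- if (is_ds) snps$snps else snps
  missing_chr <- setdiff(unique(tab$chrom), unique(map_table$chrom))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) absent from genetic map: ",
         paste(missing_chr, collapse = ", "))
  }
  for (ch in unique(tab$chrom)) {
    a <- map_table[map_table$chrom == ch, ]
    idx <- tab$chrom == ch
    if (nrow(a) == 1) {
      tab$pos_cm[idx] <- a$cm
    } else {
      tab$pos_cm[idx] <- stats::approx(a$bp, a$cm, xout = tab$pos_bp[idx],
                                       rule = 2, ties = "ordered")$y
    }
  }
  if (is_ds) {
    snps$snps <- tab
    snps
  } else {
    tab
  }
}

#' Read a centromere interval table (BED)
#'
#' Three tab-separated columns: chromosome, start, end (0-based half-open, as
#' in BED). Returned with 1-based inclusive `start_bp`/`end_bp`.
#'
#' @param path BED file path.
#' @return Data frame with columns `chrom`, `start_bp`, `end_bp`.
#' @export
read_centromeres <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(chrom = sub("^chr", "", as.character(tab[[1]])),
             start_bp = as.integer(tab[[2]]) + 1L,
             end_bp = as.integer(tab[[3]]),
             stringsAsFactors = FALSE)
}
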