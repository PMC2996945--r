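#' Selection configuration for AIM panels
#'
#' @param criterion Ranking statistic: `"delta"` (allele-frequency
#'   differential, default threshold 0.6) or `"fst"` (two-population F_ST,
#'   default threshold 0.4).
#' @param threshold Minimum criterion value for a SNP to qualify; defaults to
#'   0.6 for delta and 0.4 for F_ST (the two are comparable: at delta = 0.6
#'   the attainable F_ST range is 0.36–0.43).
#' @param bin_size_bp Width of the consecutive non-overlapping chromosome
#'   bins, default 1 Mb.
#' @param r2_max Pairwise genotype r-squared above which two selected SNPs are
#'   considered in LD (default 0.4); applied in either parental sample.
#' @param maf_min Minimum minor allele frequency required in both parental
#'   populations (default 0.01).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(criterion = c("delta", "fst"), threshold = NULL,
                             bin_size_bp = 1e6, r2_max = 0.4,
                             maf_min = 0.01) {
  criterion <- match.arg(criterion)
  if (is.null(threshold)) threshold <- if (criterion == "delta") 0.6 else 0.4
  stopifnot(threshold > 0, threshold <= 1, r2_max > 0, r2_max <= 1,
            bin_size_bp > 0, maf_min >= 0, maf_min <= 1)
  structure(list(criterion = criterion, threshold = threshold,
                 bin_size_bp = as.numeric(bin_size_bp), r2_max = r2_max,
                 maf_min = maf_min),
            class = "selection_config")
}

#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' entries (composite LD from unphased genotypes). A constant vector gives 0.
#'
#' @param g1,g2 Dosage vectors of equal length.
#' @return r-squared in \code{[0, 1]}.
#' @export
genotype_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) stop("fewer than 2 pairwise-complete genotype pairs")
  x <- g1[ok]; y <- g2[ok]
  if (var(x) == 0 || var(y) == 0) return(0)
  min(cor(x, y)^2, 1)
}

# 0-based bin index of a 1-based bp coordinate.
bin_index <- function(pos_bp, bin_size_bp) floor((pos_bp - 1) / bin_size_bp)

#' Select ancestry-informative markers
#'
#' Six-step iterative selection from two harmonized parental datasets:
#' \enumerate{
#'   \item drop SNPs with minor allele frequency below `maf_min` in either
#'     parental population;
#'   \item keep SNPs whose criterion (delta or F_ST) is at least `threshold`;
#'   \item split each chromosome into consecutive non-overlapping bins of
#'     `bin_size_bp` and sort SNPs within each bin by descending criterion;
#'   \item per chromosome, compute pairwise genotype r-squared between the
#'     current top-ranked SNPs of all bins, in each parental dataset;
#'   \item for any pair with r-squared at or above `r2_max` in either parent,
#'     discard the member with the smaller criterion value (compared at 4
#'     decimal places) from its bin and promote that bin's next SNP; on a tie
#'     the distal SNP (larger bp coordinate) is discarded; conflicting pairs
#'     are resolved highest-r-squared first;
#'   \item iterate steps 4–5 until no pair of bin-top SNPs is in LD in either
#'     parent.
#' }
#' Bins left without a qualifying SNP simply yield no marker.
#'
#' @param parent1,parent2 Harmonized parental [genotype_dataset()] objects
#'   (identical SNP tables).
#' @param config A [selection_config()].
#' @return An object of class `aim_panel`: list with `panel` (data frame of
#'   selected SNPs with their statistics and bin indices, ordered by
#'   chromosome and position), `config`, `n_iterations`, and `discarded`
#'   (data frame logging every discarded SNP and the reason).
#' @export
select_aims <- function(parent1, parent2, config = selection_config()) {
  if (!identical(parent1$snps$snp_id, parent2$snps$snp_id)) {
    stop("parental datasets are not harmonized; run harmonize() first")
  }
  stats <- differentiation_stats(parent1, parent2)
  snps <- parent1$snps

  # step 1: MAF filter in both parents
  maf1 <- pmin(stats$p1, 1 - stats$p1)
  maf2 <- pmin(stats$p2, 1 - stats$p2)
  ok <- !is.na(stats$delta) & maf1 >= config$maf_min & maf2 >= config$maf_min

  # step 2: criterion threshold
  crit <- if (config$criterion == "delta") stats$delta else stats$fst
  ok <- ok & crit >= config$threshold

  empty_panel <- function(n_iter, discarded) {
    structure(list(
      panel = cbind(snps[0, , drop = FALSE], stats[0, -1, drop = FALSE],
                    data.frame(criterion = numeric(0), bin = integer(0))),
      config = config, n_iterations = n_iter, discarded = discarded
    ), class = "aim_panel")
  }
  discarded <- data.frame(snp_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  if (!any(ok)) {
    warning("no SNP passes the MAF and criterion filters; empty panel")
    return(empty_panel(0L, discarded))
  }

  # step 3: bins, ranked by descending criterion (ties: proximal first)
  cand <- data.frame(idx = which(ok),
                     chrom = snps$chrom[ok],
                     pos_bp = snps$pos_bp[ok],
                     crit = crit[ok],
                     crit4 = round(crit[ok], 4),
                     bin = bin_index(snps$pos_bp[ok], config$bin_size_bp),
                     stringsAsFactors = FALSE)
  cand <- cand[order(chrom_rank(cand$chrom), cand$bin, -cand$crit,
                     cand$pos_bp), , drop = FALSE]
  cand$key <- paste(cand$chrom, cand$bin)

  # current top of each bin: first row per key
  top_rows <- function(cand) cand[!duplicated(cand$key), , drop = FALSE]

  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    tops <- top_rows(cand)
    worst <- NULL  # (row of tops to discard, r2, snp_id of partner)
    best_r2 <- -1
    for (ch in unique(tops$chrom)) {
      t_ch <- tops[tops$chrom == ch, , drop = FALSE]
      k <- nrow(t_ch)
      if (k < 2) next
      g1 <- parent1$calls[, t_ch$idx, drop = FALSE]
      g2 <- parent2$calls[, t_ch$idx, drop = FALSE]
      r2a <- pairwise_r2(g1)
      r2b <- pairwise_r2(g2)
      r2 <- pmax(r2a, r2b)
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          if (r2[i, j] >= config$r2_max && r2[i, j] > best_r2) {
            best_r2 <- r2[i, j]
            # discard smaller criterion (4 dp); tie -> distal (larger bp)
            ci <- t_ch$crit4[i]; cj <- t_ch$crit4[j]
            drop_i <- if (ci < cj) i
                      else if (cj < ci) j
                      else if (t_ch$pos_bp[i] > t_ch$pos_bp[j]) i else j
            worst <- t_ch[drop_i, , drop = FALSE]
          }
        }
      }
    }
    if (is.null(worst)) break
    discarded <- rbind(discarded, data.frame(
      snp_id = snps$snp_id[worst$idx],
      reason = sprintf("r2 %.4f >= %.2f with a bin-top SNP on chrom %s",
                       best_r2, config$r2_max, worst$chrom),
      stringsAsFactors = FALSE))
    cand <- cand[cand$idx != worst$idx, , drop = FALSE]
    if (nrow(cand) == 0) break
  }

  if (nrow(cand) == 0) {
    warning("all candidates discarded during LD pruning; empty panel")
    return(empty_panel(n_iter, discarded))
  }
  tops <- top_rows(cand)
  sel <- tops$idx[order(chrom_rank(tops$chrom), tops$pos_bp)]
  panel <- cbind(snps[sel, , drop = FALSE],
                 stats[sel, setdiff(names(stats), "snp_id"), drop = FALSE],
                 data.frame(criterion = crit[sel],
                            bin = bin_index(snps$pos_bp[sel],
                                            config$bin_size_bp)))
  rownames(panel) <- NULL
  structure(list(panel = panel, config = config, n_iterations = n_iter,
                 discarded = discarded),
            class = "aim_panel")
}

# Pairwise r^2 matrix over columns of a dosage matrix, pairwise-complete,
# constant columns -> 0 with the column itself -> 0 on the diagonal unused.
pairwise_r2 <- function(g) {
  suppressWarnings(r <- cor(g, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r2 <- r^2
  diag(r2) <- 0
  r2
}

#' @export
print.aim_panel <- function(x, ...) {
  cat(sprintf("aim_panel: %d markers (criterion %s >= %.4g, %d iterations, %d discarded)\n",
              nrow(x$panel), x$config$criterion, x$config$threshold,
              x$n_iterations, nrow(x$discarded)))
  if (nrow(x$panel) > 0) {
    cat(sprintf("  mean delta %.3f, mean F_ST %.3f, mean SIC %.3f bits\n",
                mean(x$panel$delta), mean(x$panel$fst), mean(x$panel$sic)))
  }
  invisible(x)
}

#' Variance-inflation-factor LD pruning
#'
#' Sliding-window VIF pruning of a genotype dataset: within each window of
#' `window_snps` consecutive SNPs (advancing by `slide_snps`), each SNP's VIF
#' `1 / (1 - R^2)` is computed from the squared multiple correlation of its
#' dosage on the other SNPs in the window; while any VIF exceeds `vif_max`,
#' the SNP with the largest VIF is removed (a SNP perfectly determined by the
#' others, e.g. a duplicated column, has infinite VIF and goes first). A VIF
#' of 1 means the SNP is independent of all others in the window.
#'
#' @param dataset A [genotype_dataset()] (SNPs are in position order by
#'   construction).
#' @param window_snps Window width in SNPs (default 50).
#' @param slide_snps Window advance in SNPs (default 5).
#' @param vif_max VIF ceiling (default 1.1).
#' @return Character vector of retained SNP ids, in position order.
#' @export
vif_prune <- function(dataset, window_snps = 50, slide_snps = 5,
                      vif_max = 1.1) {
  stopifnot(window_snps >= 2, slide_snps >= 1, vif_max >= 1)
  keep <- rep(TRUE, nrow(dataset$snps))
  names(keep) <- dataset$snps$snp_id
  for (ch in unique(dataset$snps$chrom)) {
    idx_ch <- which(dataset$snps$chrom == ch)
    start <- 1L
    while (start <= length(idx_ch)) {
      in_ch <- idx_ch[keep[idx_ch]]
      if (start > length(in_ch)) break
      win <- in_ch[start:min(start + window_snps - 1L, length(in_ch))]
      if (length(win) >= 2) {
        drop <- prune_window(dataset$calls[, win, drop = FALSE], vif_max)
        keep[win[drop]] <- FALSE
      }
      if (start + window_snps - 1L >= length(in_ch)) break
      start <- start + slide_snps
    }
  }
  dataset$snps$snp_id[keep]
}

# Iteratively remove the highest-VIF column until all VIFs <= vif_max.
# Returns the logical index of removed columns (relative to input).
prune_window <- function(g, vif_max) {
  m <- ncol(g)
  active <- seq_len(m)
  removed <- rep(FALSE, m)
  repeat {
    if (length(active) < 2) break
    v <- window_vifs(g[, active, drop = FALSE])
    if (max(v) <= vif_max + 1e-12) break
    worst <- which.max(v)
    removed[active[worst]] <- TRUE
    active <- active[-worst]
  }
  removed
}

# VIF of each column of a dosage matrix given the others, via the inverse of
# the correlation matrix; perfect collinearity (including duplicated or
# constant-difference columns) yields Inf.
window_vifs <- function(g) {
  m <- ncol(g)
  suppressWarnings(r <- cor(g, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  e <- eigen(r, symmetric = TRUE)
  if (min(e$values) >= 1e-10) return(diag(solve(r)))
  # singular: columns involved in an exact dependency get infinite VIF;
  # the rest get R^2 from the minimum-norm (pseudo-inverse) regression,
  # which equals the projection onto the predictor column space
  null_vecs <- e$vectors[, e$values < 1e-10, drop = FALSE]
  involved <- rowSums(null_vecs^2) > 1e-12
  v <- numeric(m)
  for (k in seq_len(m)) {
    if (involved[k]) {
      v[k] <- Inf
      next
    }
    others <- setdiff(seq_len(m), k)
    a <- r[others, others, drop = FALSE]
    b <- r[others, k]
    ea <- eigen(a, symmetric = TRUE)
    pos <- ea$values > 1e-10
    coefs <- ea$vectors[, pos, drop = FALSE] %*%
      ((t(ea$vectors[, pos, drop = FALSE]) %*% b) / ea$values[pos])
    r2 <- min(sum(coefs * b), 1 - 1e-12)
    v[k] <- 1 / (1 - r2)
  }
  v
}

#' Random marker panel
#'
#' Uniform sample without replacement of `round(fraction * N)` SNP ids,
#' reproducible by seed.
#'
#' @param snp_ids Character vector of SNP ids to sample from.
#' @param fraction Fraction to keep, in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of sampled ids (original order preserved).
#' @export
random_panel <- function(snp_ids, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- round(fraction * length(snp_ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- sort(sample.int(length(snp_ids), n))
  snp_ids[keep]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Summarize an AIM panel
#'
#' Per-chromosome marker counts and physical spans, the mean adjacent-marker
#' genetic distance excluding gaps that span a centromere, and mean
#' delta/F_ST/SIC.
#'
#' @param panel An `aim_panel` from [select_aims()] (or a data frame with its
#'   `panel` columns).
#' @param map_table Optional [genetic_map()] used to fill missing cM
#'   positions.
#' @param centromeres Optional centromere interval table (columns `chrom`,
#'   `start_bp`, `end_bp`, as from [read_centromeres()]); when absent, all
#'   gaps are included and the result is flagged.
#' @return List of class `panel_summary` with `per_chromosome` (data frame:
#'   `chrom`, `n`, `start_mb`, `end_mb`), `mean_gap_cm` (NA when no gap
#'   qualifies), `n_gaps`, `centromeres_excluded` flag and `mean_stats`.
#' @export
panel_summary <- function(panel, map_table = NULL, centromeres = NULL) {
  tab <- if (inherits(panel, "aim_panel")) panel$panel else panel
  if (nrow(tab) == 0) stop("empty panel")
  if (!is.null(map_table)) tab <- interpolate_cm(tab, map_table)
  if (any(is.na(tab$pos_cm))) {
    stop("panel lacks cM positions; supply a genetic map")
  }

  per_chrom <- do.call(rbind, lapply(split(tab, tab$chrom), function(s) {
    data.frame(chrom = s$chrom[1], n = nrow(s),
               start_mb = min(s$pos_bp) / 1e6, end_mb = max(s$pos_bp) / 1e6,
               stringsAsFactors = FALSE)
  }))
  per_chrom <- per_chrom[order(chrom_rank(per_chrom$chrom)), , drop = FALSE]
  rownames(per_chrom) <- NULL

  gaps <- numeric(0)
  for (ch in unique(tab$chrom)) {
    s <- tab[tab$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos_bp), , drop = FALSE]
    if (nrow(s) < 2) next
    g_cm <- diff(s$pos_cm)
    keep <- rep(TRUE, length(g_cm))
    if (!is.null(centromeres)) {
      cen <- centromeres[centromeres$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(cen))) {
        # a gap spans the centromere when its flanking markers straddle it
        spans <- s$pos_bp[-nrow(s)] < cen$start_bp[r] &
                 s$pos_bp[-1] > cen$end_bp[r]
        keep <- keep & !spans
      }
    }
    gaps <- c(gaps, g_cm[keep])
  }

  structure(list(
    per_chromosome = per_chrom,
    mean_gap_cm = if (length(gaps) > 0) mean(gaps) else NA_real_,
    n_gaps = length(gaps),
    centromeres_excluded = !is.null(centromeres),
    mean_stats = c(delta = mean(tab$delta), fst = mean(tab$fst),
                   sic = mean(tab$sic))
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat(sprintf("panel_summary: %d markers on %d chromosome(s)\n",
              sum(x$per_chromosome$n), nrow(x$per_chromosome)))
  cat(sprintf("  mean inter-marker gap: %s cM over %d gaps%s\n",
              ifelse(is.na(x$mean_gap_cm), "NA",
                     sprintf("%.3f", x$mean_gap_cm)),
              x$n_gaps,
              if (x$centromeres_excluded) " (centromere-spanning excluded)"
              else " (no centromere table: all gaps included)"))
  cat(sprintf("  mean delta %.3f, F_ST %.3f, SIC %.3f\n",
              x$mean_stats["delta"], x$mean_stats["fst"],
              x$mean_stats["sic"]))
  invisible(x)
}
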