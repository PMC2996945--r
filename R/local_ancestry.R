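#' Admixture model parameters
#'
#' Parameters of the hybrid-isolation two-ancestry model: per-individual
#' European admixture proportion `m`, the shared number of generations since
#' admixture `lambda_gen`, and the per-SNP parental allele frequencies.
#'
#' @param m Numeric vector of per-individual European ancestry proportions;
#'   clamped to `[1e-6, 1 - 1e-6]`.
#' @param lambda_gen Generations since the admixture event; must lie in
#'   `[0.5, 50]`.
#' @param parental_freqs Data frame with columns `snp_id`, `p_ceu`, `p_yri`
#'   (alt-allele frequencies in the European- and African-ancestry parental
#'   populations).
#' @return A list of class `admixture_params`.
#' @export
admixture_params <- function(m, lambda_gen = 7, parental_freqs = NULL) {
  stopifnot(is.numeric(m), all(m >= 0 & m <= 1))
  if (lambda_gen < 0.5 || lambda_gen > 50) {
    stop("lambda_gen must lie in [0.5, 50]")
  }
  if (!is.null(parental_freqs)) {
    stopifnot(all(c("snp_id", "p_ceu", "p_yri") %in% names(parental_freqs)))
  }
  structure(list(m = pmin(pmax(m, 1e-6), 1 - 1e-6),
                 lambda_gen = lambda_gen,
                 parental_freqs = parental_freqs),
            class = "admixture_params")
}

# Align parental frequencies to a dataset's SNP table (ordered, clamp-free).
aligned_freqs <- function(dataset, parental_freqs) {
  idx <- match(dataset$snps$snp_id, parental_freqs$snp_id)
  if (anyNA(idx)) stop("parental frequencies missing for some dataset SNPs")
  cbind(parental_freqs$p_ceu[idx], parental_freqs$p_yri[idx])
}

#' Local-ancestry posterior field
#'
#' Runs the hybrid-isolation forward-backward HMM for every individual and
#' returns posterior probabilities over the unordered European-origin allele
#' count k in {0, 1, 2} on a uniform genetic grid. Grid points are inserted
#' into the chain as silent loci (emission 1), so posteriors between markers
#' are the model's own interpolation. Parental frequencies of exactly 0 or 1
#' are clamped to `[1e-4, 1 - 1e-4]`.
#'
#' @param dataset A [genotype_dataset()] with cM positions.
#' @param params An [admixture_params()] carrying `parental_freqs`.
#' @param grid_spacing_cm Grid spacing in cM (default 1).
#' @param at_markers If `TRUE`, evaluate at marker positions instead of a
#'   uniform grid.
#' @return Object of class `ancestry_posterior_field`: list with `q` (array
#'   individuals x grid loci x 3), `grid` (data frame `chrom`, `cm`),
#'   `samples`, and `loglik` (per-individual log-likelihood).
#' @export
posterior_field <- function(dataset, params, grid_spacing_cm = 1,
                            at_markers = FALSE) {
  stopifnot(inherits(params, "admixture_params"))
  if (any(is.na(dataset$snps$pos_cm))) {
    stop("dataset lacks cM positions; run interpolate_cm()")
  }
  if (length(params$m) != length(dataset$samples)) {
    stop("length(m) must equal the number of samples")
  }
  freqs <- aligned_freqs(dataset, params$parental_freqs)
  n <- length(dataset$samples)

  grid_list <- list()
  q_list <- list()
  loglik <- numeric(n)
  for (ch in unique(dataset$snps$chrom)) {
    idx <- which(dataset$snps$chrom == ch)
    cm_marker <- dataset$snps$pos_cm[idx]
    grid_cm <- if (at_markers) {
      NULL
    } else {
      seq(min(cm_marker), max(cm_marker), by = grid_spacing_cm)
    }
    be <- build_emissions(dataset$calls[, idx, drop = FALSE],
                          freqs[idx, , drop = FALSE], cm_marker, grid_cm)
    fb <- hmm_forward_backward(be$emis, be$cm, params$m, params$lambda_gen)
    loglik <- loglik + fb$loglik
    eval_at <- if (at_markers) be$is_marker else !be$is_marker
    q_list[[ch]] <- fb$post[, eval_at, , drop = FALSE]
    grid_list[[ch]] <- data.frame(chrom = ch, cm = be$cm[eval_at],
                                  stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grid_list)
  rownames(grid) <- NULL
  q <- array(NA_real_, c(n, nrow(grid), 3),
             dimnames = list(dataset$samples, NULL, paste0("k", 0:2)))
  off <- 0L
  for (ch in names(q_list)) {
    w <- dim(q_list[[ch]])[2]
    q[, off + seq_len(w), ] <- q_list[[ch]]
    off <- off + w
  }
  structure(list(q = q, grid = grid, samples = dataset$samples,
                 loglik = loglik),
            class = "ancestry_posterior_field")
}

#' @export
print.ancestry_posterior_field <- function(x, ...) {
  cat(sprintf("ancestry_posterior_field: %d individuals x %d grid loci (%d chromosome(s))\n",
              dim(x$q)[1], dim(x$q)[2], length(unique(x$grid$chrom))))
  invisible(x)
}

# Posterior mean European-haplotype fraction per individual at marker loci,
# plus total log-likelihood, for given (m, lambda). Workhorse of the EM loop.
posterior_mean_fraction <- function(dataset, freqs, m, lambda,
                                    want_post = TRUE) {
  n <- length(dataset$samples)
  ek_sum <- numeric(n)
  n_loci <- 0L
  loglik <- numeric(n)
  for (ch in unique(dataset$snps$chrom)) {
    idx <- which(dataset$snps$chrom == ch)
    be <- build_emissions(dataset$calls[, idx, drop = FALSE],
                          freqs[idx, , drop = FALSE],
                          dataset$snps$pos_cm[idx])
    fb <- hmm_forward_backward(be$emis, be$cm, m, lambda,
                               want_post = want_post)
    loglik <- loglik + fb$loglik
    if (want_post) {
      ek <- fb$post[, , 2, drop = FALSE] + 2 * fb$post[, , 3, drop = FALSE]
      ek_sum <- ek_sum + rowSums(ek[, , 1, drop = FALSE])
      n_loci <- n_loci + length(idx)
    }
  }
  list(frac = if (want_post) ek_sum / (2 * n_loci) else NULL,
       loglik = sum(loglik))
}

#' Fit individual admixture and generations since admixture
#'
#' Estimates each individual's European admixture proportion `m_j` by an EM
#' fixed point (update `m_j` to the posterior mean European-haplotype
#' fraction over marker loci) and the cohort-shared generations parameter
#' `lambda` by one-dimensional maximum-likelihood search over `[0.5, 50]`;
#' the two updates are alternated twice.
#'
#' @param dataset A [genotype_dataset()] with cM positions (the admixed
#'   cohort).
#' @param parental_freqs Data frame with `snp_id`, `p_ceu`, `p_yri`.
#' @param lambda_init Starting value for lambda (default 7, a typical
#'   African-American estimate).
#' @param tol Convergence tolerance on `max |delta m|` (default 1e-4).
#' @param max_iter Maximum EM iterations per alternation (default 100).
#' @param fit_lambda Set `FALSE` to keep lambda at `lambda_init`.
#' @return An object of class `admix_fit`: list with `params`
#'   ([admixture_params()]), `m` (named per-individual estimates), `lambda`,
#'   `loglik`, `n_iter`, `converged`, and the call.
#' @export
fit_admixture <- function(dataset, parental_freqs, lambda_init = 7,
                          tol = 1e-4, max_iter = 100, fit_lambda = TRUE) {
  if (length(dataset$samples) < 1) stop("need at least one individual")
  if (nrow(dataset$snps) < 2) stop("need at least two markers")
  if (any(is.na(dataset$snps$pos_cm))) {
    stop("dataset lacks cM positions; run interpolate_cm()")
  }
  freqs <- aligned_freqs(dataset, parental_freqs)

  n <- length(dataset$samples)
  m <- rep(0.5, n)
  lambda <- lambda_init
  n_iter <- 0L
  converged <- FALSE
  n_outer <- if (fit_lambda) 2L else 1L
  for (outer in seq_len(n_outer)) {
    for (it in seq_len(max_iter)) {
      n_iter <- n_iter + 1L
      pm <- posterior_mean_fraction(dataset, freqs, m, lambda)
      m_new <- pmin(pmax(pm$frac, 1e-6), 1 - 1e-6)
      delta <- max(abs(m_new - m))
      m <- m_new
      if (delta < tol) { converged <- TRUE; break }
      converged <- FALSE
    }
    if (fit_lambda) {
      opt <- optimize(function(l) {
        posterior_mean_fraction(dataset, freqs, m, l,
                                want_post = FALSE)$loglik
      }, interval = c(0.5, 50), maximum = TRUE, tol = 0.01)
      lambda <- opt$maximum
    }
  }
  if (!converged) {
    warning("EM did not reach tolerance within max_iter; returning best estimate")
  }
  loglik <- posterior_mean_fraction(dataset, freqs, m, lambda,
                                    want_post = FALSE)$loglik
  structure(list(
    params = admixture_params(m, lambda, parental_freqs),
    m = setNames(m, dataset$samples),
    lambda = lambda,
    loglik = loglik,
    n_iter = n_iter,
    converged = converged,
    n_samples = n,
    n_markers = nrow(dataset$snps),
    call = match.call()
  ), class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat("Hybrid-isolation admixture model fit\n")
  cat(sprintf("  %d individuals, %d markers\n", x$n_samples, x$n_markers))
  cat(sprintf("  European ancestry m: mean %.3f (sd %.3f)\n",
              mean(x$m), stats::sd(x$m)))
  cat(sprintf("  generations since admixture lambda: %.2f\n", x$lambda))
  cat(sprintf("  log-likelihood: %.2f (%d EM iterations%s)\n", x$loglik,
              x$n_iter, if (x$converged) "" else ", not converged"))
  invisible(x)
}

#' @export
summary.admix_fit <- function(object, ...) {
  out <- list(
    m_mean = mean(object$m), m_sd = stats::sd(object$m),
    m_quartiles = stats::quantile(object$m, c(0.25, 0.5, 0.75)),
    african_mean = mean(1 - object$m),
    lambda = object$lambda, loglik = object$loglik,
    n_samples = object$n_samples, n_markers = object$n_markers,
    converged = object$converged
  )
  class(out) <- "summary.admix_fit"
  out
}

#' @export
print.summary.admix_fit <- function(x, ...) {
  cat("Hybrid-isolation admixture model fit\n")
  cat(sprintf("  individuals: %d   markers: %d\n", x$n_samples, x$n_markers))
  cat(sprintf("  European ancestry: mean %.3f +/- %.3f (quartiles %.3f / %.3f / %.3f)\n",
              x$m_mean, x$m_sd, x$m_quartiles[1], x$m_quartiles[2],
              x$m_quartiles[3]))
  cat(sprintf("  African ancestry:  mean %.3f\n", x$african_mean))
  cat(sprintf("  lambda (generations): %.2f\n", x$lambda))
  cat(sprintf("  log-likelihood: %.2f%s\n", x$loglik,
              if (x$converged) "" else "  (EM not converged)"))
  invisible(x)
}

#' @export
coef.admix_fit <- function(object, ...) {
  c(lambda = object$lambda, m = unname(object$m))
}

#' @export
logLik.admix_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_samples + 1, class = "logLik")
}

#' Predict local-ancestry posteriors from a fitted admixture model
#'
#' @param object An `admix_fit`.
#' @param newdata A [genotype_dataset()] (defaults must be supplied; the fit
#'   does not store the genotype data).
#' @param grid_spacing_cm Grid spacing passed to [posterior_field()].
#' @param ... Unused.
#' @return An `ancestry_posterior_field`.
#' @export
predict.admix_fit <- function(object, newdata, grid_spacing_cm = 1, ...) {
  posterior_field(newdata, object$params, grid_spacing_cm = grid_spacing_cm)
}

#' Simulate cohorts from a fitted admixture model
#'
#' Draws new admixed cohorts under the fitted hybrid-isolation parameters
#' (individual `m` values resampled from the fitted set, fitted lambda,
#' fitted parental frequencies).
#'
#' @param object An `admix_fit`.
#' @param nsim Number of cohorts.
#' @param seed Integer seed.
#' @param config Optional [sim_config()] template; its `n_snps`,
#'   `chromosomes` and sizes are reused.
#' @param ... Unused.
#' @return A list of `nsim` results of [simulate_admixed()].
#' @export
simulate.admix_fit <- function(object, nsim = 1, seed = 1L, config = NULL,
                               ...) {
  if (is.null(config)) {
    config <- sim_config(n_individuals = object$n_samples,
                         n_snps = object$n_markers,
                         lambda_gen = object$lambda, seed = seed)
  } else {
    config$lambda_gen <- object$lambda
    config$seed <- seed
  }
  config$m_sampler <- function(n) {
    sample(unname(object$m), n, replace = TRUE)
  }
  pf <- object$params$parental_freqs
  lapply(seq_len(nsim), function(i) {
    cfg <- config
    cfg$seed <- seed + i - 1L
    simulate_admixed(cfg, pf)
  })
}

#' Plot a fitted admixture model
#'
#' Histogram of the per-individual European ancestry estimates.
#'
#' @param x An `admix_fit`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.admix_fit <- function(x, ...) {
  graphics::hist(x$m, breaks = 20, col = "grey80",
                 main = "Individual European ancestry",
                 xlab = expression(hat(m)[j]), ...)
  graphics::abline(v = mean(x$m), col = "red3", lwd = 2)
  invisible(x)
}

# Shannon entropy (bits) of each row of a probability matrix; 0 log 0 = 0.
row_entropy <- function(p) {
  t <- p * log2(p)
  t[!is.finite(t)] <- 0
  pmax(-rowSums(t), 0)
}

#' Entropy-based map power
#'
#' For each grid locus i, `X_ij` is the entropy (bits) of individual j's
#' local-ancestry posterior and `G_j` the entropy of the genome-wide prior
#' `((1-m)^2, 2m(1-m), m^2)`. Relative power is
#' `r_i = 1 - sum_j X_ij / sum_j G_j`, clamped to \code{[0, 1]}: `r_i = 0`
#' when the posteriors carry no information beyond genome-wide ancestry, and
#' `r_i = 1` when local ancestry is known perfectly. `r_avg` is the mean of
#' `r_i` over grid loci.
#'
#' @param field An `ancestry_posterior_field`.
#' @param params An [admixture_params()] (or `admix_fit`) supplying the
#'   per-individual `m`.
#' @return Object of class `map_power_result`: list with `r_i` (per locus),
#'   `r_avg`, `G_j` (per-individual prior entropy) and the grid.
#' @export
map_power <- function(field, params) {
  if (inherits(params, "admix_fit")) params <- params$params
  stopifnot(inherits(field, "ancestry_posterior_field"),
            inherits(params, "admixture_params"))
  m <- params$m
  if (length(m) != dim(field$q)[1]) {
    stop("params$m length does not match the posterior field")
  }
  G_j <- row_entropy(ancestry_prior(m))
  if (sum(G_j) <= 0) {
    stop("all prior entropies are zero (m at boundary); map power undefined")
  }
  L <- dim(field$q)[2]
  X_sum <- vapply(seq_len(L), function(i) {
    sum(row_entropy(field$q[, i, , drop = TRUE]))
  }, numeric(1))
  r_i <- pmin(pmax(1 - X_sum / sum(G_j), 0), 1)
  structure(list(r_i = r_i, r_avg = mean(r_i), G_j = G_j,
                 grid = field$grid),
            class = "map_power_result")
}

#' @export
print.map_power_result <- function(x, ...) {
  cat(sprintf("map_power_result: r_avg = %.3f over %d grid loci (range %.3f-%.3f)\n",
              x$r_avg, length(x$r_i), min(x$r_i), max(x$r_i)))
  invisible(x)
}

#' Sample-size inflation factor
#'
#' Relative to a study with perfect local-ancestry information
#' (`r_avg = 1`), `1 / r_avg` times as many samples must be genotyped for
#' comparable power. Reported rounded to 2 decimals.
#'
#' @param r_avg Average map power, in (0, 1].
#' @return `round(1 / r_avg, 2)`.
#' @export
effective_sample_factor <- function(r_avg) {
  if (any(r_avg <= 0) || any(r_avg > 1)) stop("r_avg must lie in (0, 1]")
  round(1 / r_avg, 2)
}

#' Fractions of loci exceeding map-power thresholds
#'
#' @param result A `map_power_result`.
#' @param thresholds Numeric thresholds (default 0.50, 0.75, 0.80).
#' @return Named numeric vector: fraction of grid loci with
#'   `r_i >= threshold`.
#' @export
power_threshold_fractions <- function(result,
                                      thresholds = c(0.50, 0.75, 0.80)) {
  stopifnot(inherits(result, "map_power_result"))
  setNames(vapply(thresholds, function(th) mean(result$r_i >= th),
                  numeric(1)),
           paste0("r>=", format(thresholds)))
}
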