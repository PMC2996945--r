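# Two-ancestry hidden Markov model under the hybrid-isolation model.
#
# Hidden state at a locus is the unordered count k in {0,1,2} of
# European-origin alleles. The diploid chain is the product of two
# independent, exchangeable haploid chains, so the unordered count is itself
# Markov (lumpability by haplotype symmetry). Each haploid chain re-draws its
# ancestry Bernoulli(m) at exponential(lambda)-spaced breakpoints per Morgan:
# over genetic distance d Morgans, with e = exp(-lambda d),
#   P(next = European | cur = European) = e + (1 - e) m
#   P(next = European | cur = African)  = (1 - e) m
# Stationary start: haplotype European with probability m.
#
# All forward/backward passes are vectorized over individuals: alpha/beta are
# n x 3 matrices updated locus by locus, with per-individual transition
# entries computed elementwise (m may differ between individuals).

# Emission probabilities P(g | k) for a dosage vector g at one SNP with
# clamped parental alt-allele frequencies (pc European, py African).
# Returns n x 3 matrix (columns k = 0, 1, 2 European alleles); missing -> 1.
emission_probs <- function(g, pc, py) {
  n <- length(g)
  e <- matrix(1, n, 3)
  obs <- !is.na(g)
  gg <- g[obs]
  e[obs, 1] <- stats::dbinom(gg, 2, py)
  e[obs, 3] <- stats::dbinom(gg, 2, pc)
  het <- pc * (1 - py) + (1 - pc) * py
  e1 <- c((1 - pc) * (1 - py), het, pc * py)
  e[obs, 2] <- e1[gg + 1L]
  e
}

# Per-individual 3x3 transition entries over distance d Morgans, given the
# haploid probabilities u = P(E|E) and w = P(E|A) (vectors over individuals).
# Returns a list of 9 vectors t[[from]][[to]], from/to in 1..3 (k = 0..2).
transition_entries <- function(m, lambda, d) {
  e <- exp(-lambda * d)
  u <- e + (1 - e) * m   # haplotype stays/becomes European from European
  w <- (1 - e) * m       # haplotype becomes European from African
  list(
    # from k = 0 (both African)
    list((1 - w)^2, 2 * w * (1 - w), w^2),
    # from k = 1 (one of each)
    list((1 - u) * (1 - w), u * (1 - w) + (1 - u) * w, u * w),
    # from k = 2 (both European)
    list((1 - u)^2, 2 * u * (1 - u), u^2)
  )
}

# Stationary (genome-wide) distribution of k given m: ((1-m)^2, 2m(1-m), m^2).
ancestry_prior <- function(m) {
  cbind((1 - m)^2, 2 * m * (1 - m), m^2)
}

# Forward-backward over one chromosome for all individuals at once.
#
# emis: list of n x 3 emission matrices, one per locus (in cM order)
# cm: locus positions (cM), m: per-individual admixture, lambda: generations
# want_post: compute posteriors (else forward-only log-likelihood)
#
# Returns list(loglik = per-individual log-likelihood,
#              post = n x L x 3 array of state posteriors or NULL).
hmm_forward_backward <- function(emis, cm, m, lambda, want_post = TRUE) {
  L <- length(emis)
  n <- nrow(emis[[1]])
  prior <- ancestry_prior(m)

  alpha <- vector("list", L)
  scale_log <- matrix(0, n, L)
  a <- prior * emis[[1]]
  s <- rowSums(a)
  s[s == 0] <- .Machine$double.xmin
  alpha[[1]] <- a / s
  scale_log[, 1] <- log(s)
  if (L > 1) {
    for (t in 2:L) {
      tr <- transition_entries(m, lambda, (cm[t] - cm[t - 1]) / 100)
      ap <- alpha[[t - 1]]
      a <- matrix(0, n, 3)
      for (to in 1:3) {
        acc <- ap[, 1] * tr[[1]][[to]] + ap[, 2] * tr[[2]][[to]] +
          ap[, 3] * tr[[3]][[to]]
        a[, to] <- acc * emis[[t]][, to]
      }
      s <- rowSums(a)
      s[s == 0] <- .Machine$double.xmin
      alpha[[t]] <- a / s
      scale_log[, t] <- log(s)
    }
  }
  loglik <- rowSums(scale_log)
  if (!want_post) return(list(loglik = loglik, post = NULL))

  post <- array(NA_real_, c(n, L, 3))
  b <- matrix(1, n, 3)
  g <- alpha[[L]] * b
  post[, L, ] <- g / rowSums(g)
  if (L > 1) {
    for (t in (L - 1):1) {
      tr <- transition_entries(m, lambda, (cm[t + 1] - cm[t]) / 100)
      be <- b * emis[[t + 1]]
      bn <- matrix(0, n, 3)
      for (from in 1:3) {
        bn[, from] <- be[, 1] * tr[[from]][[1]] + be[, 2] * tr[[from]][[2]] +
          be[, 3] * tr[[from]][[3]]
      }
      s <- rowSums(bn)
      s[s == 0] <- .Machine$double.xmin
      b <- bn / s
      g <- alpha[[t]] * b
      post[, t, ] <- g / rowSums(g)
    }
  }
  list(loglik = loglik, post = post)
}

# Build per-locus emission list for one chromosome, optionally augmented with
# silent grid loci (emission 1). Parental frequencies are clamped away from 0
# and 1 so no genotype has probability exactly zero.
#
# Returns list(emis, cm, is_marker).
build_emissions <- function(calls_ch, freqs_ch, cm_marker, grid_cm = NULL,
                            freq_clamp = 1e-4) {
  pc <- pmin(pmax(freqs_ch[, 1], freq_clamp), 1 - freq_clamp)
  py <- pmin(pmax(freqs_ch[, 2], freq_clamp), 1 - freq_clamp)
  n <- nrow(calls_ch)
  cm_all <- c(cm_marker, grid_cm)
  is_marker <- c(rep(TRUE, length(cm_marker)), rep(FALSE, length(grid_cm)))
  ord <- order(cm_all, !is_marker)
  cm_all <- cm_all[ord]
  is_marker <- is_marker[ord]
  marker_of <- cumsum(is_marker)  # which marker a marker-locus corresponds to
  emis <- vector("list", length(cm_all))
  for (t in seq_along(cm_all)) {
    if (is_marker[t]) {
      j <- marker_of[t]
      emis[[t]] <- emission_probs(calls_ch[, j], pc[j], py[j])
    } else {
      emis[[t]] <- matrix(1, n, 3)
    }
  }
  list(emis = emis, cm = cm_all, is_marker = is_marker)
}
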