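---
title: "Ancestry-informative marker panels and admixture mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-informative marker panels and admixture mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimpanel)
```

# The scientific problem

Admixture mapping localizes disease genes in recently admixed populations
(such as African Americans) by scanning the genome for regions where affected
individuals carry more ancestry from one parental population than their
genome-wide average. The method needs far fewer markers than association
mapping because admixture linkage disequilibrium extends over centimorgans,
but the markers must be *ancestry informative*: their allele frequencies must
differ strongly between the two parental populations.

`aimpanel` implements the full desk-scale workflow for two-way admixture:

1. quantify per-SNP ancestry informativeness between two parental reference
   panels;
2. select a genome-spanning panel of ancestry-informative markers (AIMs)
   from a dense SNP array, thinning within-population linkage
   disequilibrium (LD);
3. infer each admixed individual's locus-by-locus ancestry with a hidden
   Markov model (HMM) and estimate their genome-wide admixture proportion
   and the time since admixture;
4. score the genome with case-only and case-control admixture-mapping
   statistics;
5. simulate admixed cohorts with known truth to validate every step.

# Measures of marker informativeness

For alt-allele frequencies $p_1$ (European-ancestry parental population) and
$p_2$ (African-ancestry parental population):

* the **frequency differential** $\delta = |p_1 - p_2|$;
* **Wright's two-population $F_{ST}$**, the across-population frequency
  variance standardized by the pooled heterozygosity:
  $F_{ST} = s^2 / (\bar p(1-\bar p))$ with $\bar p = (p_1+p_2)/2$ and
  $s^2 = ((p_1-\bar p)^2 + (p_2-\bar p)^2)/2 = \delta^2/4$;
* the **Shannon information content** (SIC): the mutual information, in
  bits, between the allelic state of a randomly drawn allele from an admixed
  individual and the ancestry of the chromosome carrying it, at admixture
  proportion $m$.

```{r}
compute_delta(0.9, 0.2)
compute_fst(0.8, 0.2)        # delta = 0.6 at symmetric frequencies
compute_sic(0.2, 0.9, m = 0.2)
```

The two thresholds used for panel selection are comparable: at fixed
$\delta$, $F_{ST}$ ranges over $[\delta^2,\ \delta/(2-\delta)]$, so
$\delta \ge 0.6$ corresponds to $F_{ST}$ between 0.36 and 0.43.
`fst_bounds_given_delta()` finds this range by grid search; the grid is
evaluated in integer-scaled rational arithmetic so that, e.g., the minimum
at $\delta = 0.6$ is *exactly* 0.36 rather than 0.36 up to floating-point
error. The inverse bounds are closed-form:

```{r}
fst_bounds_given_delta(0.6)
delta_bounds_given_fst(0.4)
```

# Selecting an AIM panel

`select_aims()` runs a six-step iterative algorithm on two harmonized
parental datasets:

1. drop SNPs with minor allele frequency below 0.01 in either population;
2. keep SNPs whose criterion ($\delta$ or $F_{ST}$) meets the threshold
   (0.6 and 0.4 by default);
3. split each chromosome into 1-Mb bins and rank SNPs within a bin by
   descending criterion;
4. compute pairwise genotype $r^2$ (composite LD from unphased dosages)
   between the current top-ranked SNPs of all bins on a chromosome, in
   each parental sample;
5. for any pair with $r^2 \ge 0.4$ in *either* parental population,
   discard the member with the smaller criterion (compared at 4 decimal
   places; ties discard the distal SNP) and promote that bin's next
   candidate — the highest-$r^2$ conflict is resolved first;
6. iterate until no two bin-top SNPs are in LD.

The result is at most one marker per Mb bin, mutually unlinked within each
parental population. `vif_prune()` provides the complementary
variance-inflation-factor thinning used for *random* (non-AIM) panels:
sliding windows of 50 SNPs advancing by 5, removing the highest-VIF SNP
while any VIF exceeds 1.1; a SNP exactly determined by its neighbours gets
an infinite VIF and is removed first.

```{r}
cfg <- sim_config(n_parental = 150, n_snps = 300, n_chrom = 4,
                  chrom_length_cm = 120, delta_preset = "aims", seed = 42)
par <- simulate_parental(cfg)
panel <- select_aims(par$pop1, par$pop2, selection_config("delta"))
panel
```

# Local ancestry under the hybrid-isolation model

The demographic model is **hybrid isolation**: a single admixture event
$\lambda$ generations ago, no later gene flow. Each haplotype of an
individual with European admixture proportion $m$ is a mosaic of ancestry
tracts; crossovers since admixture occur at rate $\lambda$ per Morgan and
each breakpoint re-draws ancestry Bernoulli($m$) from the ancestral "pool".
Over genetic distance $d$ Morgans, with $e = e^{-\lambda d}$, a haploid
ancestry chain therefore moves to "European" with probability
$e + (1-e)m$ from European and $(1-e)m$ from African.

The two haplotypes are exchangeable and independent, so the *unordered*
count $k \in \{0,1,2\}$ of European-origin alleles is itself a Markov chain
(a lumping of the four ordered states), and the diploid HMM runs directly
on three states. Emissions are binomial in the parental allele frequency
for $k = 0, 2$ and the heterogeneous mixture for $k = 1$; missing genotypes
emit 1. `posterior_field()` evaluates posterior ancestry on a uniform cM
grid by inserting *silent* loci (emission 1) into the chain, so values
between markers are the model's own interpolation, not post-hoc smoothing.
The forward–backward pass is vectorized across individuals.

Because the simulator uses the identical generative process, parameter
recovery is a clean oracle for the whole pipeline:

```{r}
adm_cfg <- sim_config(n_individuals = 40, n_snps = 300, n_chrom = 4,
                      chrom_length_cm = 120, delta_preset = "aims",
                      seed = 42)
sim <- simulate_admixed(adm_cfg, par$freqs)
fit <- fit_admixture(sim$dataset, par$freqs)
fit
mean(abs(fit$m - sim$truth$m))
```

`fit_admixture()` follows the classic modelling idiom: it returns an
`admix_fit` object with `print()`, `summary()`, `coef()`, `logLik()`,
`predict()` (posterior field for a dataset), `plot()` (ancestry histogram)
and `simulate()` (new cohorts under the fitted parameters) methods. The
estimation alternates an EM fixed point for the individual proportions
$m_j$ (update to the posterior mean European-haplotype fraction across
markers) with a one-dimensional likelihood search for $\lambda$ over
$[0.5, 50]$ generations.

# Map power

How much of the ancestry signal does a panel actually extract? At grid
locus $i$, let $X_{ij}$ be the entropy (bits) of individual $j$'s
local-ancestry posterior and $G_j$ the entropy of their genome-wide prior
$((1-m_j)^2,\, 2m_j(1-m_j),\, m_j^2)$. The relative map power

$$r_i = 1 - \frac{\sum_j X_{ij}}{\sum_j G_j}$$

is 0 when the markers say nothing beyond genome-wide ancestry and 1 when
local ancestry is read perfectly. The ratio-of-sums form weights
individuals by their prior uncertainty, so individuals with extreme
$m_j$ (whose local ancestry is nearly known a priori) do not dilute the
average. A study on a panel with average power $r_{avg}$ needs
$1/r_{avg}$ times the ideal sample size:

```{r}
field <- posterior_field(sim$dataset, fit$params, grid_spacing_cm = 2)
mp <- map_power(field, fit)
mp
effective_sample_factor(mp$r_avg)
power_threshold_fractions(mp)
```

# Mapping statistics

Two complementary statistics scan the grid (`admixture_map()` computes
both):

* **Case-only locus–genome LOD.** Under an ancestry risk model with
  relative risks $(1, \psi_1, \psi_2)$ for 0/1/2 African-origin alleles
  (default $\psi_2 = 2.80$, $\psi_1 = \sqrt{\psi_2}$, i.e. multiplicative
  per allele), each case contributes
  $\log_{10}\left(\sum_k q_{ijk}\rho_k \big/ \sum_k \pi_{jk}\rho_k\right)$,
  comparing their local posterior $q$ with their genome-wide prior $\pi_j$.
  The genome-wide significance threshold is LOD $\ge 2$.
* **Case-control $z$.** Each individual's deviation of local African
  ancestry from their genome-wide expectation,
  $D_{ij} = E_q[k_{Afr}]/2 - (1 - m_j)$, is compared between cases and
  controls with a Welch-type two-sample $z$; thresholds $|z| \ge 4.2$ for
  AIM panels and $4.7$ for denser random panels. This statistic is immune
  to a mis-specified risk model at the cost of genotyping controls.

```{r}
risk <- list(chrom = "2", cm = 60, psi2 = 2.8)
phen <- assign_phenotypes(sim$truth, risk, n_cases = 15, n_controls = 15,
                          seed = 7)
stats <- admixture_map(field, fit, phen)
head(significance_calls(stats), 3)
```

(With only 15 cases this toy scan is underpowered; the package's test
suite runs the calibrated replicate study at realistic sizes.)

# The simulator: scope and limits

`sim_config()` defaults *are* the reference study conditions: 22
chromosomes of 160 cM (a human-scale autosomal map of about 35 Morgans),
$m_j \sim \mathrm{Beta}(2, 8)$ (mean European ancestry 0.2),
$\lambda = 7$ generations, 1% missingness. Two frequency presets cover the
designs of interest: `"aims"` draws $\delta \sim U(0.6, 0.8)$ (a selected
AIM panel), `"random"` draws a genome-wide-like spectrum with mean
$\delta \approx 0.14$. Optional planted LD blocks exercise the pruning
steps, and an optional ancestry risk locus with weighted case sampling
($w = \psi_2^{k_{Afr}/2}$) feeds the mapping statistics. All randomness
flows from one integer seed, and generators restore the caller's RNG
state.

Deliberate non-goals: coalescent-realistic haplotype structure,
recombination-rate heterogeneity, genotyping error beyond uniform
missingness, more than two ancestral populations, and phased-haplotype
local ancestry.

# Numerical and design notes

* The genome-wide map length matters for admixture estimation: the
  irreducible gap between an individual's *realized* ancestry fraction and
  their latent $m_j$ scales with the number of independent tracts, which is
  why the default geometry is a full-scale 35-Morgan map rather than a toy
  genome.
* The exact Hardy–Weinberg test (`hwe_exact_p()`) enumerates all
  heterozygote counts compatible with the allele counts in log space and
  sums the probabilities not exceeding the observed table's (two-sided
  conditional test); QC applies its four filters in a fixed order (sample
  call rate, SNP call rate, MAF, HWE), each on the data surviving the
  previous step.
* Selection ties are compared at 4 decimal places of the criterion,
  matching the precision at which such tables are customarily reported.
* In `window_vifs()`, an exactly collinear SNP receives an infinite VIF
  via the eigenstructure of the window correlation matrix; the remaining
  SNPs use the minimum-norm (pseudo-inverse) regression, which equals the
  projection onto the predictor space.
* Frequencies of exactly 0 or 1 are clamped to $[10^{-4}, 1-10^{-4}]$
  inside the HMM so no genotype has probability zero under any ancestry.
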