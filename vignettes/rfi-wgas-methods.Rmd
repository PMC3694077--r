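---
title: "Models and methods for divergent-line RFI genome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for divergent-line RFI genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfiwgas)
```

This vignette is the package's own account of the statistics it
implements: the phenotype models, the divergence scan, the BayesB
sampler and its window summaries, the association layer, and the design
choices made where more than one reasonable construction existed.

## Residual feed intake and the phenotype models

Average daily gain is the least-squares slope of biweekly body weight on
days on test; `compute_adg()` is exactly that regression. Average daily
feed intake fits each animal's daily intake as a quadratic in day and
returns the mean of the fitted curve over the animal's own integer test
days (`compute_adfi()`). Fitting a smooth curve and averaging it — rather
than averaging raw records — makes the estimate insensitive to which
particular days are missing; the per-animal quadratic is our reading of
a "quadratic random regression" in a setting where the population-level
random-regression machinery is not otherwise specified.

RFI is defined through a single-trait animal model for ADFI with

* fixed effects: line, on-test group, sex, and generation-by-line cell
  intercepts;
* covariates, each with a separate slope per generation-by-line cell:
  `onwt − 40` (kg), `age at on-test − 90` (d), `offwt − 115` (kg),
  metabolic mid-weight (mean on-test weight^0.75, kg^0.75), `adga`
  (ADG linearly corrected to a 135 d test midpoint) and `offbfa`
  (back fat corrected to a 115 kg off-test weight); the correction
  slopes are pooled within-group regressions estimated from the data,
  recorded as such because the exact functional form of these
  pre-adjustments is a convention rather than a derivable quantity;
* random effects: animal (pedigree **A**⁻¹), dam, and pen-within-group,
  at user-supplied variance ratios λ = σ²ₑ/σ²ᵤ (a simple EM-REML,
  `em_reml()`, can estimate them; tests use the simulator's truth).

`compute_rfi()` returns `RFI = ADFI − Xb̂`: the fixed-effect and
covariate prediction is removed, the random-effect predictions are not.
This keeps the animal genetic deviation (plus residual) inside RFI,
which is what makes RFI selectable — a line difference in RFI is exactly
a difference in mean genetic deviation plus drift of the environment
terms, and it is what the divergent lines realized. A flag
(`subtract_random`) removes dam/pen or all random-effect predictions for
users who want the alternative construction; whether the original
analysis removed them is not stated anywhere we could check, so both
are exposed and the default keeps them in.

Because the fixed part contains every generation-by-line intercept and
per-cell slopes, OLS residual algebra makes RFI average zero and be
uncorrelated with every covariate within each cell — two properties the
test suite asserts at 1e-8/1e-6. With a nonzero animal ratio the cell
mean of RFI equals the estimated mean breeding value of the cell, which
is how the line divergence shows up.

`build_a_inverse()` uses Henderson's rules with Mendelian sampling
variances `dᵢ = 0.5 − 0.25(F_s + F_d)` (0.75 or 1 with unknown parents)
and inbreeding coefficients from the Meuwissen–Luo L-decomposition;
`solve_mme()` solves the mixed-model equations with a corner constraint
(aliased fixed columns, found by pivoted QR, are set to zero), so
solutions are reproducible and documented rather than dependent on
contrast defaults.

## The drift-controlled divergence scan

At the focal generation the allele_b frequency of each line is computed
on the same fixed allele per SNP (allele_b is the dataset minor allele,
fixed at load time). The signed difference (HIGH − LOW) is standardized
within five founder-MAF bins — `[0, 0.1), [0.1, 0.2), [0.2, 0.3),
[0.3, 0.4), [0.4, 0.5]` — because drift moves rare alleles more than
common ones; binning on generation-0 MAF makes the null comparison
"like with like". Within each bin the population mean and SD of the
differences define `z = (diff − mean)/sd`, two-sided normal P values,
and BH q values over all scored SNPs. The scan standardizes the
*differences* (not the two line frequencies separately): it is the only
construction that yields one Z per SNP, and it makes the scan exactly
antisymmetric under swapping line labels. Bins with fewer than two
scoreable SNPs or zero SD are flagged, not scored, and flagged SNPs are
excluded from the BH denominator.

Under pure drift with equal line sizes the within-bin Z is standard
normal to good approximation (frequency changes are sums of many small
binomial steps); the acceptance suite checks per-bin
Kolmogorov–Smirnov normality in 20/20 drift replicates and a type-I
rate at P < 0.05 within three binomial standard errors.

## BayesB and window mapping

The model is

$$y = Xb + \sum_{j=1}^{k} z_j a_j \delta_j + e,$$

with flat priors on the fixed effects `b` (sex, pen-by-group, and an
age-at-on-test covariate with a slope per line-by-parity cell),
genotypes coded −10/0/10 with missing values imputed at the SNP mean
code, `P(δⱼ = 0) = π` (default 0.995), `aⱼ | σ²ⱼ ~ N(0, σ²ⱼ)` with
`σ²ⱼ ~ ν_a S_a / χ²_{ν_a}` (ν_a = 4), and
`σ²ₑ ~ ν_e S_e / χ²_{ν_e}` (ν_e = 10).

Prior scales are solved from an expected heritability: `S_a` so that
`k (1−π) · mean var(zⱼ) · E[σ²ⱼ]` equals `h²_expected · var(y)`, and
`S_e` from `(1 − h²_expected) var(y)`. This is the standard construction
when software-internal scales are not published; the expected h² only
positions the prior and the data dominate at the chain lengths used.

The sampler is single-site Gibbs with one deliberate choice: the
inclusion indicator δⱼ is drawn from the likelihood with aⱼ *integrated
out* given the current locus variance (drawn from its prior when the
locus is excluded, from its conjugate full conditional when included).
Updating δ at fixed aⱼ would be reducible at the point mass aⱼ = 0; the
marginalized update is the classic way around it. Residuals are updated
in place so each locus costs O(n) per iteration, and the running
residual is audited against a fresh reconstruction every 1,000
iterations (the audit maximum is reported; tests require < 1e-8). The
chain uses R's RNG, so a seed makes the entire fit bit-reproducible.
Defaults — 51,050 iterations, 1,000 burn-in, output frequency 50 —
give 1,001 saved states; saved states carry the sparse (index, effect)
pairs, σ²ₑ, and the genetic variance var(g) across the analyzed
individuals (the empirical-variance convention, so window percentages
need not sum to 100 and are not forced to).

Windows are non-overlapping 1 Mb bins keyed by
`(chrom, floor((pos−1)/1e6))`; SNPs on unassigned contigs are excluded
from window results. Per state, a window's genetic value is the sum of
its included marker effects times coded genotypes; the window's percent
of genetic variance is the posterior mean of its share, the PPA is the
fraction of states where that share is nonzero, and candidates are
windows at or above 5× the even-spread expectation `100%/n_windows`
(with 2,815 windows: 0.04%, threshold 0.2%). Genomic heritability is
summarized per state as `var(g)/(var(g)+σ²ₑ)`.

## Association, genomic control and stratification

`adjust_phenotype()` takes OLS residuals from the fixed model above
(singleton line-by-parity cells are merged into the nearest parity with
a warning), `single_snp_assoc()` regresses the residual on allele
dosage per SNP (t with n−2 df; monomorphic SNPs get P = 1), and
`genomic_control()` divides the χ² statistics by
λ = median(χ²)/0.4549364 when λ > 1 — never when λ < 1, so correction
cannot be anti-conservative. Significance is reported under both
conventions used for this design: GC-corrected P < 0.01 and BH q < 0.05.
`ibs_mds()` builds the identity-by-state similarity (shared-allele
fraction over co-typed SNPs) and classically scales 1 − IBS;
`qq_points()` pairs sorted observed −log10 P with `−log10((i−0.5)/m)`.

## The simulator and what it does (and does not) emulate

`sim_config()` defaults describe the desk-scale study design: 160
founders split into two lines, 80 pigs per line per generation for 9
generations (G0–G8), the LOW line truncation-selected downward on the
simulated RFI phenotype every generation and the HIGH line mated at
random until generation 5 and selected upward thereafter, 20% of each
sex kept as parents. The marker panel is 1,000 SNPs on 18 autosomes
plus X (treated autosomally and flagged as such) with founder MAF
uniform on [0.05, 0.5]; 0.5% of SNPs are QTL (matching a fitted
fraction of 1 − π = 0.005) and effects are scaled so founder genetic
variance hits the heritability target of 0.4 — inside the 0.3–0.5 range
reported for these traits — with dam and pen variances of 0.05 each on
a unit phenotypic scale. Selection acts on the phenotype rather than on
estimated breeding values: it is what a feeder observes, and no
acceptance property depends on the realized response magnitude. The
records layer maps the standardized selection trait to kg/day (SD 0.15)
inside a feed-intake equation with growth, back-fat, sex, pen-group and
age terms, so `compute_rfi()` has real covariate structure to strip.

Founders are in linkage equilibrium and LD accumulates only through
drift and selection; there is no coalescent backstory, no mutation, no
realistic pig linkage map (1 cM/Mb throughout), and no genotype-error
model beyond missingness and a planted fraction of failing quality
scores. Passing tests therefore demonstrate correctness of the
machinery under a known sparse architecture, not performance on real
SNP-chip LD patterns.

Two simulation scenarios are fixed choices worth recording. The BayesB
recovery scenario plants 20 QTL in 20 *distinct* 1 Mb windows with the
lead QTL at 20% of a true genomic h² of 0.5 (n = 1,000, k = 2,000,
11,000-iteration chain): without the distinct-window constraint two
random QTL can share a window and legitimately outrank the lead, which
says nothing about the sampler. The divergence-scan power scenario uses
both lines selected from generation 1 at 20% with 160 pigs per line:
the scan's power is governed by the drift null, and at the historical
line size of ~80 with one line unselected for half the experiment the
drift-scaled signal of a handful of QTL is not reliably separable —
a faithful property of the design, so the power demonstration uses the
tighter-drift scenario while the study-design defaults stay as they
are.

## Numerical conventions and limitations

* QC inequalities are strict (call rate > 0.80, quality score > 0.40,
  HWE P > 1e-4); HWE is the 1-df chi-square test, with monomorphic SNPs
  passing by convention (P = 1) but flagged. The HWE mask can be
  restricted to a subset (e.g. founders), since pooled diverged lines
  violate HWE by construction; the default is all animals.
* Allele orientation is fixed at load: allele_b is the dataset minor
  allele, ties broken toward the lexicographically larger allele, and
  monomorphic SNPs carry dosage 0 of an absent allele_b.
* Windows, positions and the MAP dialect are 1-based.
* The BayesB locus variance is updated by its conjugate conditional
  given the sampled effect, and δ by the marginalized ratio given that
  variance — one of the two classical BayesB update orders; output
  thinning applies to all saved quantities.
* Problem sizes in the test suite (up to n = 1,000 × k = 2,000 with
  11,000 iterations; 20 drift replicates of 2,000 SNPs) were chosen so
  the whole suite runs in a couple of minutes on one core while leaving
  Monte Carlo error well inside the asserted tolerances.
* Known limitations: no haplotype-level analyses (window-level SNP
  reporting replaces them), no multi-trait models, no genomic
  relationship matrix in the RFI step, no intensity-based QC (the
  platform quality score is accepted as given), and the EM-REML option
  is a convenience for desk-scale pedigrees, not an AI-REML
  replacement.
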