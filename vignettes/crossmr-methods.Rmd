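---
title: "Methods: cross-trait look-ups and two-sample MR in crossmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait look-ups and two-sample MR in crossmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmr)
```

`crossmr` packages two workflows that are usually stitched together ad hoc
when studying genetic overlap between anthropometric and mental
phenotypes: a cross-trait look-up of genome-wide-significant SNPs across a
panel of summary-statistic files, and a two-sample Mendelian randomization
(MR) analysis between one exposure and one outcome. This vignette records
the models, the conventions, and every numerical decision the
implementation makes, including the places where the underlying
methodology is genuinely under-specified and the package had to choose.

## 1. The look-up model

The input is a catalog of SNP–trait associations filtered to genome-wide
significance (P ≤ 5×10⁻⁸) for anthropometric traits, plus one
summary-statistic table per mental phenotype.

### Locus clustering

SNPs associated with correlated traits cluster heavily, so counting raw
SNPs overstates the number of independent signals. `define_loci()`
partitions SNPs in two stages:

1. **Positional window.** Within a chromosome, SNPs are sorted by position
   and merged greedily left to right: a candidate joins the open cluster
   when it lies within the half-window (default 500 kb) of the cluster's
   running midpoint, defined as `(min + max)/2` of the member positions
   and recomputed after every merge. "Midpoint of the locus" is not a
   fully determined notion once clusters grow; the greedy running-midpoint
   rule was chosen because it is deterministic, independent of input row
   order (the sort fixes the scan order), and reduces to the obvious
   answer on well-separated clusters. A message flags any locus whose span
   exceeds 1 Mb, where this convention starts to matter.
2. **Equilibrium splitting.** Within a positional cluster, a SNP pair is
   *demonstrably independent* only when its measured LD satisfies both
   r² < 0.01 and D′ < 0.01. Pairs with unknown LD count as linked: absence
   of evidence never splits a locus. Splitting is single-linkage — the
   connected components of the "linked" relation become the final loci —
   so a locus is split only into groups with no linked path between them.

Loci are numbered consecutively in genomic order. The test suite checks
this implementation against a brute-force oracle (naive rescanning plus
boolean-matrix transitive closure) on hundreds of randomized instances.

### Bonferroni correction and hits

The family-wise correction divides α (default 0.05) by the number of
*SNPs*, not SNP×phenotype pairs — deliberately conservative in the SNP
dimension (no LD pruning of the test family) while treating phenotypes as
separate univariate screens. With 1,005 SNPs this yields the threshold
0.05/1005 = 4.98×10⁻⁵ (3 significant figures; computation keeps full
precision). The stricter SNP×phenotype family is available via
`per_phenotype_correction = TRUE`. Hits are significant when
`P < threshold` (strict inequality). Missing SNPs are reported in a
coverage table; proxy SNPs are never substituted.

### Lead SNPs and effect directions

Within a locus the lead SNP maximizes the number of significant phenotype
hits; ties break by the lowest P-value among those hits; a final
lexicographic rsID tie-break (a package invention, logged when used) makes
the choice deterministic.

Direction concordance asks whether the anthropometric-trait-increasing
allele also increases the mental phenotype. Both betas are aligned to the
anthropometric effect allele first, so the call is invariant to how either
file labels its alleles (a property the tests exercise by relabelling).
Within a look-up panel, tables are assumed strand-consistent, so
palindromic SNPs resolve by allele labels there; strand ambiguity is
handled strictly only in the MR harmonization, where two independent
consortia are being combined. Zero betas are indeterminate and excluded
from counts with a message. Counts are stratified into loci whose
contributing anthropometric traits include a BMI-type label versus loci
unique to BMI-adjusted measures, mirroring how overlap results are usually
tabulated.

## 2. Harmonization

Two-sample MR combines an exposure study and an outcome study that may
report effects for opposite alleles or opposite strands.
`harmonize_pair()` resolves, in order: identical allele pairs (keep),
swapped pairs (negate the outcome beta), strand-complement pairs
(relabel, then the same logic). Anything irreconcilable is excluded as
`ambiguous`.

Palindromic SNPs (A/T or C/G) are special: their allele pair is identical
on both strands, so labels cannot resolve the strand. The default
`strict` mode excludes them. An `eaf-infer` mode keeps palindromes whose
effect-allele frequency is informative (outside \[0.42, 0.58\] in both
studies) and uses frequency agreement to orient the outcome record; it is
off by default because reproducing the strict behaviour is the package's
reference configuration and frequency-based inference adds assumptions
(comparable ancestry, accurate EAF).

`harmonize_datasets()` vectorizes this logic over whole tables;
`harmonize_pair()` is the scalar reference implementation and the test
suite asserts exact agreement between the two paths. Exclusions are
accounted exactly: shared SNPs = retained + palindromic + ambiguous, plus
a list of exposure SNPs absent from the outcome.

Instruments are *not* re-oriented to exposure-positive at harmonization.
Only MR-Egger needs that convention, so it is applied inside the Egger
estimator; all other estimators are orientation-invariant (tested).

## 3. MR estimators

For instrument *j*: exposure effect γ̂ⱼ with SE σ_Xⱼ, outcome effect Γ̂ⱼ
with SE σ_Yⱼ.

**IVW.** β̂ = Σwⱼ(Γ̂ⱼ/γ̂ⱼ)/Σwⱼ with wⱼ = γ̂ⱼ²/σ_Yⱼ². Three algebraically
identical formulations (weighted mean of Wald ratios, fixed-effect
meta-analysis, WLS through the origin) are asserted equal to 10
significant digits in the tests. The default SE is multiplicative random
effects — the fixed-effects SE inflated by `max(1, sqrt(Q/(n−1)))` — the
common choice for large instrument panels with expected heterogeneity;
under-dispersion never deflates the SE. P-values use the standard normal.

**MR-Egger.** WLS of Γ̂ on γ̂ with a free intercept and weights 1/σ_Yⱼ²,
after flipping instruments to γ̂ⱼ > 0. The intercept estimates the average
directional pleiotropic effect (valid under InSIDE: instrument strength
independent of direct effects); its test is the pleiotropy diagnostic.
Coefficient SEs use the weighted-regression residual SD floored at 1
(inflate if > 1, never deflate), and P-values use the t distribution on
n − 2 df, matching standard MR-Egger practice.

**RAPS.** The standardized profile residual is
tⱼ(β, τ²) = (Γ̂ⱼ − βγ̂ⱼ)/√(σ_Yⱼ² + β²σ_Xⱼ² + τ²); the estimate solves
Σ ρ′(tⱼ)·∂tⱼ/∂β = 0. Simple mode fixes τ² = 0; overdispersed mode
alternates with the moment equation Σ(tⱼ² − 1) = 0 for τ² ≥ 0. ρ is the
identity (l2) or Huber with tuning constant 1.345. The solver is damped
Newton with numerical derivatives (tolerance 10⁻⁸ on the score) and a
sign-change bisection fallback over β ∈ \[−10, 10\]; non-convergence is
reported in the result, never thrown. The SE is the M-estimation sandwich
B/A² form, ignoring τ²-estimation uncertainty. With all σ_X = 0 and l2
loss the score reduces analytically to the IVW normal equation, and the
tests assert that identity to 8 significant digits; the general root is
checked against a 10⁻⁶-step grid scan of the score.

**Diagnostics.** Cochran's Q uses IVW weights around the (fixed-effects)
pooled estimate on n − 1 df. Two instrument-strength F conventions exist
in the literature and reports rarely say which was used, so both are
implemented and reported: the mean per-SNP (γ̂ⱼ/σ_Xⱼ)² and the
regression-identity form (n − k − 1)/k · r²/(1 − r²); neither is asserted
against any particular published value. The Wald-ratio SE is first-order
by default — exposure uncertainty belongs to RAPS, not to an inflated
ratio SE — with the second-order form behind a flag. Single-SNP and
leave-one-out tables flag per-SNP significance at α = 0.05 and sign
changes against the full estimate. Plot data (scatter with fitted lines,
forest with 95% CIs, funnel of estimate vs 1/SE) are emitted as plain
tables; rendering is left to the user's plotting stack.

**Power.** For a binary outcome, with b = ln(OR per exposure SD),
v = c(1 − c) the case-fraction variance factor, and non-centrality
z = |b|·√(N·r²·v), two-sided power at level α is
Φ(z − z₁₋α/₂) + Φ(−z − z₁₋α/₂). At OR = 1 this equals α exactly. At the
reference configuration (N = 105,318, 38.6% cases, r² = 0.039) the formula
gives 1.00 at OR = 1.28 and 0.767 at OR = 1.09 — the latter is what this
closed form yields for a nominal "80% power" scenario, and the tests
bound it within ±0.05 of 0.80. A simulation of the instrument-level IVW
z-test under the same generative model agrees with the closed form within
Monte-Carlo error (tested).

## 4. What the synthetic generator emulates

`simulate_mr_study()` realizes exactly the generative model the
estimators assume: γⱼ drawn as |N(mean, sd)|, direct effects αⱼ drawn
independently of γⱼ (InSIDE holds; `inside_violation` mixes in a
γ-correlated component to demonstrate Egger failure), latent outcome
effect β·γⱼ + αⱼ, and observed effects with Gaussian noise at
SE = 1/√(2·MAF·(1−MAF)·N) (times 1/√(c(1−c)) for a binary outcome). Tying
SE to MAF and N makes F statistics and power analyses internally
consistent. Defaults emulate a body-fat-distribution exposure against a
psychiatric case-control outcome: 319 instruments, exposure N = 694,649,
outcome N = 105,318 with case fraction 40,675/105,318, γ scale chosen so
the mean per-SNP F is near 90, and a palindromic fraction of 9/328.

It does **not** emulate: LD between instruments (draws are independent),
winner's-curse selection of instruments, sample overlap between exposure
and outcome studies, allele-frequency differences between studies, or
non-Gaussian effect-size distributions. Passing tests therefore show the
estimators are correct *under their own assumptions*; they do not show
robustness to the violations real consortium data can contain (notably
overlap-induced bias, which the two-sample framework assumes away).

`simulate_lookup_study()` plants well-separated loci (anchor spacing
2 Mb > 2× the 500 kb window, members within 100 kb) and gives one
designated member per overlapping locus a P-value of 10⁻⁶ in one
phenotype, all other pairs drawing P ≥ 0.01. The floor must stay above
the Bonferroni threshold implied by the study size (0.05/80 = 6.25×10⁻⁴
at the defaults) so that planted truth is the unique solution; that
constraint, not realism, fixes the default floor. Defaults (40 loci × 2
SNPs, 15 phenotypes, concordant fraction 1/3) mirror the scale of a
typical anthropometric→mental look-up panel in which opposite directions
are roughly twice as common as concordant ones. Null P-values are uniform
rather than realistically correlated, and "LD" exists only implicitly via
locus membership.

## 5. Numerical and design choices

- Positions are 1-based; loci are closed intervals — GWAS-catalog
  convention.
- Alleles are upper-cased on read; indels/multi-character alleles are
  rejected with a logged exclusion (SNP-only analyses).
- Readers take explicit column dialects with shipped presets rather than
  guessing headers; a misread effect-allele column is the costliest
  silent failure in this field.
- Odds ratios are log-transformed on read and the conversion recorded;
  `exp(beta)` round-trips to 10 significant digits.
- Missing EAF is allowed everywhere except `eaf-infer` harmonization,
  which refuses records lacking it.
- Numeric output is serialized at full double precision (`%.17g`), so
  write/read round trips are exact to the last ulp.
- All stochastic routines take explicit integer seeds; metadata sidecars
  record thresholds, seeds and package version.
- Tie-breaks (lead-SNP rsID order) and degenerate inputs (single
  instrument IVW-MRE → fixed with warning; empty harmonization
  intersection → error; zero betas in direction calls → logged
  exclusion) are all deterministic and documented in the function docs.

Problem sizes in the test suite were chosen to give tight Monte-Carlo
error at interactive runtimes: 500 replicates × 200 instruments for
parameter recovery, 1,000 replicates for type-I error and Q calibration,
5,000 instruments for Egger intercept recovery, 200 randomized instances
(≤ 60 SNPs) for the clustering oracle, and 50,000 replicates for the
power simulation.

## 6. Known limitations

- No MR-PRESSO, weighted-median/mode, multivariable MR, or Steiger
  filtering; the suite covers IVW, Egger and RAPS only.
- No remote queries (GWAS Catalog API, LDlink) and no liftover: LD and
  positions must be supplied in the input tables on one build.
- Strand inference from a reference genome is out of scope; strict mode
  simply discards palindromes.
- The overdispersed-RAPS sandwich SE treats τ² as fixed at its estimate,
  which slightly understates uncertainty for small instrument panels.
- Trait-term matching in `read_catalog()` is case-insensitive substring
  matching by default; curated catalog labels vary enough that users
  should review the matched label set rather than trust any automatic
  rule.
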