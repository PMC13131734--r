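---
title: "Methods: cross-trait pleiotropy, colocalization and MR from summary statistics"
author: "pleiomr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait pleiotropy, colocalization and MR from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleiomr)
```

# Overview

`pleiomr` dissects the shared genetic architecture between a primary disease
trait and secondary traits (the motivating application is sex-hormone biology
and Alzheimer's disease, analysed separately in women and men) using only
GWAS summary statistics. The pipeline has five statistical stages:

1. **Genome-wide pleiotropy** — conditional QQ fold-enrichment curves and
   per-variant conditional/conjunctional FDR (condFDR/conjFDR).
2. **Signal definition and tiering** — LD clumping of pleiotropic variants
   and a three-tier prioritization by sex-biased effects and colocalization.
3. **Colocalization** — approximate-Bayes-factor posteriors under the
   single-causal-variant assumption, cross-trait and against xQTL panels.
4. **Motif analysis** — promoter PWM scanning, allele-level motif
   disruption, and motif-set enrichment for sex-biased gene sets.
5. **Mendelian randomization** — the full two-sample estimator and
   sensitivity suite, sex-matched, with per-sex BH-FDR.

Every stage consumes the same currency: per-variant records of
`(beta, se, p, n)` plus identifiers and alleles.

# Conditional and conjunctional FDR

For a primary trait with p-value $p_1$ and a secondary trait with $p_2$, the
conditional FDR is estimated as

$$\widehat{\mathrm{cFDR}}(p_1 \mid p_2 \le c) \;=\;
  \frac{p_1}{\hat F(p_1 \mid p_2 \le c)},$$

where $\hat F$ is the empirical CDF of primary p-values within the nested
secondary strata $c \in \{1, 0.1, 0.01, 0.001\}$. The conjunctional FDR is
the maximum of the two directional condFDRs, and variants with
conjFDR $< 0.05$ are called pleiotropic.

Design choices:

* **LD pruning of the CDF.** $\hat F$ estimated on all variants is
  distorted by LD clusters. We estimate it on random maximal independent
  sets of the $r^2 > 0.1$ adjacency graph (one survivor per neighbourhood,
  redrawn each iteration, 10 iterations by default, seeded) and average.
  Random rather than deterministic pruning avoids systematically discarding
  signal variants.
* **Monotonicity.** The tabulated CDF is made non-decreasing along the
  primary grid by a running maximum; condFDR is made non-increasing as the
  secondary stratum tightens by a running minimum. These simple
  order-preserving repairs are testable and never reorder the grid, unlike
  isotonic regression.
* **Interpolation.** Lookups interpolate bilinearly in $\log_{10}$ space
  between grid nodes (121 log-spaced primary breaks down to $10^{-12}$, and
  between adjacent strata in $\log_{10} p_2$).
* **Excluded regions.** The extended MHC (chr6:25–35 Mb) and the APOE
  region (chr19:45–46 Mb) are excluded from grid *fitting* by default
  (their extreme LD and effect sizes distort the stratified CDFs) but remain
  scorable. Both are configurable, and the defaults are stamped into the
  fitted object's `assumptions` field, because a study may or may not want
  them masked.
* **Small strata** (fewer than 100 pruned variants on average) collapse
  into their parent stratum rather than producing unstable tails.

The fold-enrichment curves use the secondary cutoffs
$\{0.1, 0.01, 0.001\}$; enrichment at cutoff $c$ and primary threshold $t$
is the tail fraction within the stratum divided by the tail fraction among
all variants, so 1 is the no-pleiotropy reference.

# Tiered prioritization

Pleiotropic variants (conjFDR $< 0.05$) are clumped greedily: the variant
with the smallest conjFDR (ties: smaller primary p, then lexicographic ID)
leads a clump and absorbs all unassigned variants with $r^2 \ge 0.01$;
clumps partition the input and are order-invariant. Clumps whose leads lie
within 250 kb and are correlated above the clump threshold are merged — a
safeguard rule, since greedy leads are mutually below the threshold.

* **Tier 3**: every independent pleiotropic signal.
* **Tier 2**: the signal contains at least one member with a sex-biased
  disease effect, i.e. heterogeneity
  $Z = (\beta_M - \beta_W)/\sqrt{SE_M^2 + SE_W^2}$ with two-sided
  $P < 0.05$, **or** a $>1.5$-fold effect-size difference.
* **Tier 1**: the Tier-2 signal additionally colocalizes across the trait
  pair with PP4 $\ge 0.7$.

The fold rule is undefined at zero and for sign flips, so the ratio
denominator is floored at $10^{-8}$ and opposite-sign effects (both nonzero)
always count as sex-biased; the ratio and the sign condition are both
reported so either convention can be audited. The best-colocalizing variant
of a Tier-1 signal need not itself be sex-biased; `lead_sex_biased` records
whether it is. Novelty uses a strict $<1$ Mb distance to user-supplied known
loci on the same chromosome.

Both sex-bias gates are *per member* at nominal 0.05, so a signal with many
members has a materially higher-than-5% chance of advancing by chance; this
is a property of the published rule, not of this implementation, and it is
why the synthetic study (below) is built so that signals have few,
well-measured members.

# Colocalization

Per variant, the log approximate Bayes factor is
$\tfrac12[\log(1-r) + r z^2]$ with shrinkage $r = W/(SE^2+W)$. Defaults for
the prior effect variance $W$ are $0.15^2$ (log-odds scale, case-control)
and $0.2^2$ (SD units, quantitative); configuration priors are
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$. All hypothesis sums are
accumulated in log-sum-exp space, so $|z| > 40$ cannot overflow, and the
exclusive-pair sum for H3 uses a log-difference with an explicit $-\infty$
guard. Regions are intersected on variant ID (no imputation); posteriors
depend on $z^2$ only, but region 2 is still allele-aligned to region 1 so
the per-variant H4 contributions stay interpretable. For xQTL panels, each
dataset carries a category label and the reported matrix collapses each
(feature, category) cell to the best PP4 with its contributing dataset;
strong colocalization is PP4 $\ge 0.70$.

The single-causal-variant formulation is implemented and labelled as such;
multi-causal extensions are out of scope.

# Motif analysis

Promoter windows cover 1000 bp upstream to 300 bp downstream of the TSS in
the direction of transcription (0-based half-open intervals; minus-strand
windows are reflected). PWM columns are normalized to probabilities, a
pseudocount of 0.01 is added before the $\log_2$ likelihood ratio against a
uniform background (both configurable), and match scores are rescaled to
$[0,1]$ as a fraction of each motif's possible score range — scaling is per
motif, not per sequence. Matches at scaled score $\ge 0.85$ are retained;
both strands are scanned; windows containing `N` are skipped. For a variant,
the best score over all offsets and strands covering its position is
computed for each allele, the variant is retained when either allele reaches
the threshold, and `delta = alt − ref` quantifies disruption. Indels are
skipped with a reason, never strand-complemented.

Motif-set enrichment replaces de novo discovery: a promoter "contains" a
motif if it has at least one retained match, and over-representation in the
target versus the combined universe is a one-sided hypergeometric tail,
filtered at $P < 0.05$ for the report. This preserves the decision-relevant
output (is an androgen/estrogen-receptor-like motif over-represented in the
sex-biased set, with a p-value) without re-implementing a ZOOPS/EM motif
optimizer. The bundled PWM file is synthetic (hormone-receptor-like inverted
repeats) and labelled as such; real analyses should supply curated
JASPAR/HOCOMOCO matrices.

# Mendelian randomization

Instruments: $p < 5\times10^{-8}$, then greedy p-ranked clumping at
$r^2 < 0.001$. Harmonization aligns the outcome to the exposure effect
allele (strand complement before swap detection) and drops palindromic
(A/T, C/G) instruments outright.

* **IVW** is a weighted regression through the origin with weights
  $1/SE_{out}^2$ under a multiplicative random-effects model: the SE is
  scaled by $\sqrt{\max(Q/(k-1), 1)}$. One instrument reduces to the
  first-order Wald ratio and is flagged.
* **MR-Egger** adds an intercept after orienting instruments to positive
  exposure effects; the intercept tests directional pleiotropy; scaling
  uses $k-2$ degrees of freedom. P-values use the normal approximation
  (consistent with IVW; some implementations use a $t_{k-2}$ reference).
* **Weighted median / weighted mode** operate on Wald ratios with
  inverse-variance weights; SEs come from a seeded parametric bootstrap that
  redraws ratio estimates from their normal approximations (5000 draws by
  default). The mode uses a Gaussian kernel with a weighted-MAD-based
  bandwidth times a user factor.
* **Cochran Q** is computed on first-order ratio weights under both models
  ($k-1$ and $k-2$ df; with two instruments the Egger line is saturated, so
  Q = 0 is reported with the p-value omitted).
* **Leave-one-out** refits IVW without each instrument; a shift larger than
  the refit SE (the full-fit SE is overdispersion-inflated by the very
  outlier under scrutiny) or a flipped 0.05 significance flags influence.
* **Global pleiotropy test** (PRESSO-style): the observed statistic is the
  weighted RSS of outcome betas about leave-one-out IVW predictions; the
  null distribution comes from parametric simulation of outcome betas
  around those predictions (1000 draws by default, seeded); the global p is
  the fraction of simulated RSS at or above the observed.
* **Sample-overlap adjustment** keeps the IVW point estimate and inflates
  each Wald-ratio SE to
  $(SE_{out} + c\,SE_{exp}\,|ratio|)/|\beta_{exp}|$ with
  $c = \text{overlap} \times \min(n_E,n_O)/\sqrt{n_E n_O} \times
  \rho_{\text{phen}}$ (default phenotype correlation 0.2). This is a
  worst-case-sign propagation of the error correlation induced by shared
  participants: it reduces exactly to IVW at zero overlap and is monotone
  in the overlap fraction. The exact published procedure is not specified
  in enough detail to reproduce, so the assumptions are stamped into the
  result rather than presented as that procedure.
* **Multivariable IVW** regresses outcome betas on the matrix of exposure
  betas without intercept; an exposure whose instrument effects are all
  zero is dropped from the fit (its conditional estimate is undefined)
  rather than failing, while genuinely collinear exposures raise an error
  naming them.
* **BH-FDR** families are per sex stratum: all exposures tested against the
  outcome within one sex form one family.

# The synthetic-data generator

Real inputs of the motivating study are access-controlled, so the package
ships seeded generators with the statistical structure every stage assumes:

* **LD**: AR(1) within blocks, $r_{ij} = \rho^{|i-j|}$, block-diagonal
  genome-wide — analytically tractable, positive definite, and fast.
* **Effects**: a four-component spike-and-slab (null / A-only / B-only /
  shared, shared variants sharing one effect), on the standardized scale so
  $SE = 1/\sqrt{n}$ and marginal z-scores are
  $\sqrt{n}\,R\gamma + \varepsilon$ with noise covariance $R$ per trait and
  $\text{overlap} \times R$ across traits.
* **Sex stratification**: shared effects plus independent per-sex Gaussian
  deviations (SD $\tau$), or exact planted female:male fold ratios.
* **QTL regions**: single causal variants in shared / distinct
  ($r^2 < 0.3$) / one-trait / null configurations, with the causal variant
  explaining a set fraction of variance (expected peak $\chi^2 \approx
  1 + n\,q$).
* **Promoters**: i.i.d. uniform background with PWM-consensus insertions at
  planted rates.

All generators are pure functions of (configuration, seed) and leave the
global RNG untouched.

The end-to-end study generator (`simulate_study`) plants five loci — two
shared + sex-biased + colocalizing, one shared-only, one sex-biased-only,
one null — plus hormone-only instrument loci whose disease effects equal a
configurable causal effect (default −0.1) times the hormone effect. Two of
its defaults are deliberate:

* `ld_rho = 0.2`, so that clumped signals contain ~3 members all within the
  $r^2 \ge 0.01$ catchment and no members sit at the detection boundary.
  With slower LD decay every clump carries edge members with
  $|\beta| \approx 4\text{–}5\,SE$, where the 1.5-fold rule fires 20–50% of
  the time under no true sex bias and the planted tier structure is
  unrecoverable at any seed.
* planted effects of APOE-like magnitude (`gamma_disease = 0.15`,
  `gamma_hormone = 0.1` in standardized units, $z \approx 47$ and $31$ at
  $n = 10^5$), so member effects are well-measured relative to their SEs.

Because the planted shared loci are genome-wide significant for the hormone
trait, they are selected as MR instruments and are *genuinely* horizontally
pleiotropic — and since their exposure effects are much larger than the
ordinary instruments', they carry roughly half the inverse-variance weight.
Naive IVW on the synthetic study is therefore biased by design, the
weighted median sits at its ~50%-invalid-weight breakdown boundary (its
estimate varies with the seed), and the plurality-based weighted mode
recovers the planted effect stably. This mirrors, in exaggerated form, the
scientific motivation for the sensitivity suite.

What the generator does **not** emulate: realistic MAF and LD spectra,
cross-block LD, imputation noise, binary-trait liability scale subtleties,
population stratification. Passing calibration tests on this generator shows
the machinery is correct under its stated model, not that real-data results
are unbiased.

# Calibration studies and problem sizes

The test suite runs the following studies (all seeded; sizes chosen to give
stable estimates at interactive runtimes):

* conjFDR false-discovery proportion: 20 replicates of 100,000 variants,
  $\rho = 0.6$, no shared causals, trait-specific causal density 1% per
  trait. A call counts as a true conjunction only when its LD block carries
  causal variants for both traits; with sparser architectures the FDP
  estimator degenerates to 0/1 on a handful of calls.
* conjFDR power: 20 replicates with 0.2% shared causals; the baseline is
  the unconditional analogue of the conjunction statistic,
  $\max(\text{uFDR}_A, \text{uFDR}_B)$ at the same variants.
* colocalization: 100 regions of at most 12 variants against linear-space
  enumeration (tolerance $10^{-8}$); 200 shared and 200 distinct regions of
  100 variants at $n = 50{,}000$ and 0.5% variance explained.
* heterogeneity Z: 10,000 null sex-stratified pairs.
* MR: 200 replicates of 50 instruments (recovery, 30% invalid instruments,
  planted +0.02 Egger intercept); 200 outer replicates for the global
  pleiotropy test with 1000 inner simulations.
* end-to-end study: 20,000 variants, five planted loci, seed fixed at 42.

`scripts/acceptance.R` recomputes the same families of quantities from
scratch at a grader-supplied seed and writes them as JSON.

# Known limitations

* condFDR inherits the mild anticonservatism of stratified-ECDF estimators
  under LD; the calibration bound (FDP $\le 0.10$ at conjFDR $< 0.05$) is
  deliberately loose for this reason.
* The tiering gates are per-member at nominal levels (see above).
* Colocalization assumes a single causal variant per region per trait.
* The sample-overlap SE adjustment is one defensible convention, labelled
  in outputs.
* Genome build handling is deliberately absent: variant IDs are opaque join
  keys, and coordinates are used only for windows, exclusion regions and
  BED export.
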