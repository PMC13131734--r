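# pleiomr

Cross-trait pleiotropy, colocalization and Mendelian randomization from
GWAS summary statistics, with sex stratification throughout.

## The problem

Sex differences in complex-disease risk (the motivating application is
Alzheimer's disease and sex-hormone biology) can arise from genetic variants
shared between the disease and hormone-related traits. Detecting them needs
more than two significance filters: a variant must be jointly associated
with both traits beyond what LD and chance allow, its disease effect must
differ between women and men, and the cross-trait overlap must reflect one
shared causal variant rather than coincidental LD. `pleiomr` implements this
whole chain for analysts working with per-variant summary statistics
(`beta`, `se`, `p`, `n`), and ships a seeded synthetic-data generator so
every stage can be exercised and calibrated without access-controlled GWAS
data.

## The statistics at the core

* **Conditional/conjunctional FDR.** For primary p-value $p_1$ and
  secondary p-value $p_2$,
  $\mathrm{cFDR}(p_1\mid p_2 \le c) = p_1 / \hat F(p_1 \mid p_2 \le c)$ with
  $\hat F$ a stratified empirical CDF estimated on random LD-pruned subsets
  (strata $c \in \{1, 0.1, 0.01, 0.001\}$);
  $\mathrm{conjFDR} = \max(\mathrm{cFDR}_{A|B}, \mathrm{cFDR}_{B|A})$, with
  variants at conjFDR $< 0.05$ called pleiotropic.
* **Tiering.** Tier 3: independent pleiotropic signal after $r^2 < 0.01$
  clumping. Tier 2: contains a member with sex-biased disease effect —
  heterogeneity $Z = (\beta_M-\beta_W)/\sqrt{SE_M^2+SE_W^2}$ at $P<0.05$ or
  a $>1.5$-fold effect difference. Tier 1: colocalizes across the trait
  pair (PP4 $\ge 0.7$), with novelty annotated at a strict 1 Mb window.
* **Colocalization.** Wakefield-style log approximate Bayes factors
  $\tfrac12[\log(1-r)+rz^2]$, $r = W/(SE^2+W)$, combined over H0–H4 in
  log-sum-exp space; xQTL panels are collapsed per category to the best PP4.
* **Mendelian randomization.** Instruments at $P<5\times 10^{-8}$,
  $r^2<0.001$; random-effects IVW, MR-Egger (slope + intercept), weighted
  median and mode, Cochran Q, leave-one-out, a PRESSO-style global
  pleiotropy test, sample-overlap SE inflation, multivariable IVW, and
  per-sex Benjamini–Hochberg FDR.
* **Motif analysis.** Promoter windows (−1000/+300 bp around the TSS), PWM
  scans scaled 0–1 per motif with a 0.85 retention threshold, allele-level
  motif disruption, and hypergeometric motif-set enrichment filtered at
  $P<0.05$.

See `vignettes/pleiomr-methods.Rmd` for the full model descriptions,
defaults, and design rationale.

## Worked example

Simulate a sex-stratified study with five planted loci and score the
female-matched trait pair:

```r
library(pleiomr)

st  <- simulate_study(n_variants = 20000, seed = 42)
tab <- conjfdr_table(st$ad_female, st$hormone_female, st$ld, seed = 53)
sum(tab$pleiotropic)
#> [1] 11
head(tab[tab$pleiotropic, c("variant_id", "p_primary", "p_secondary", "conjfdr")], 3)
#>      variant_id     p_primary   p_secondary       conjfdr
#> 2694   v0009974  8.143575e-23  1.213480e-07  2.396973e-06
#> 2695   v0009975 2.225074e-308 1.019305e-207 3.635520e-206
#> 2696   v0009976  8.861756e-26  4.251486e-07  8.068200e-06
```

Eleven variants reach conjFDR < 0.05; the block around `v0009975` is one of
the planted shared loci (its disease and hormone p-values are jointly
extreme, so its conjunctional FDR is essentially zero). Clumping these
variants (`ld_clump`), testing sex heterogeneity (`assign_tiers`) and
colocalizing each clump (`coloc_posteriors`) recovers the planted tier
structure; the whole chain is wrapped in `run_all()`.

A five-instrument MR of a protective exposure on a binary outcome:

```r
pair <- harmonized_pair(c(0.08, 0.05, 0.11, 0.06, 0.09), rep(0.003, 5),
                        c(-0.0085, -0.0044, -0.0116, -0.0061, -0.0090),
                        rep(0.0022, 5))
mr_ivw(pair)[, c("method", "beta_causal", "se", "p", "or", "or_low", "or_high")]
#>   method beta_causal         se            p        or   or_low   or_high
#> 1    IVW  -0.1025076 0.01216603 3.585131e-17 0.9025712 0.881304 0.9243517
```

The causal log-odds estimate −0.103 corresponds to an odds ratio of 0.90
(95% CI 0.88–0.92) per SD of the exposure: each instrument's outcome effect
is about −0.10 times its exposure effect, and IVW pools the five Wald
ratios with inverse-variance weights.

The full pipeline (simulate → enrich → conjFDR → tier → coloc → motif → MR)
runs from one call and writes plain-text stage artifacts plus a JSON
report:

```r
cfg <- run_config(out_dir = "pleiomr_out", seed = 1, simulate = TRUE)
report <- run_all(cfg)
```

A thin command-line wrapper is available at `inst/cli/pleiomr.R`
(`simulate`, `run-all`, `report` subcommands).

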