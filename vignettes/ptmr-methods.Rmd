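---
title: "Methods: two-phase association and causation from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase association and causation from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptmr)
```

## Overview

`ptmr` integrates an outcome GWAS with cis-QTL evidence from several
molecular layers (plasma proteome, transcriptome in one or more tissues) in
two phases: an association phase (layer-wise association statistics, FDR
control, Bayesian colocalization, evidence-tier scoring) and a causation
phase (tier-gated two-sample Mendelian randomization with sensitivity
analyses). This vignette documents the models, the tunable parameters and
their defaults, the synthetic-data generator used for calibration, and the
numerical and design choices.

## Association statistic

For a feature with predictor weights $w$ over a cis window, GWAS z-scores
$z$ and LD correlation matrix $R$ (from a reference panel), the imputed
association statistic is

$$Z \;=\; \frac{w^\top z}{\sqrt{w^\top R w}},$$

standard normal under the null of no feature–outcome association. We keep
the weights as-is when some weighted variants are missing from the GWAS
(dropping variant and LD row jointly, no renormalization), matching how
FUSION-style software behaves; `n_snps_used` records the surviving count and
a feature with no usable variant is reported as `NA`, not 0. The statistic
is invariant to positive rescaling of $w$, and $w^\top R w \le 10^{-12}$
(e.g. perfectly collinear variants with cancelling weights) is a
degenerate-variance error rather than a division by a rounding artifact.

Benjamini–Hochberg adjustment is applied per layer and per outcome, after
collapsing duplicate feature records (e.g. several aptamers measuring one
protein) to the record with the smallest unadjusted p. Collapsing *before*
adjustment reproduces the one-row-per-feature layout users expect from
published layer tables; the alternative (adjust across all aptamers) is
slightly more conservative and was not adopted.

## Colocalization

Per-variant evidence is Wakefield's approximate Bayes factor: with
$V = \mathrm{se}^2$, prior effect variance $W$ and $z = \beta/\mathrm{se}$,

$$\log\mathrm{ABF} = \tfrac12\!\left[\log\frac{V}{V+W} + z^2\frac{W}{V+W}\right].$$

Under the one-causal-variant-per-trait assumption the five hypotheses have
unnormalised supports $S_0 = 1$, $S_1 = p_1\sum_j \mathrm{ABF}^{(1)}_j$,
$S_2 = p_2\sum_j \mathrm{ABF}^{(2)}_j$,
$S_3 = p_1 p_2 \bigl(\sum_j \mathrm{ABF}^{(1)}_j \sum_k \mathrm{ABF}^{(2)}_k
- \sum_j \mathrm{ABF}^{(1)}_j\mathrm{ABF}^{(2)}_j\bigr)$ and
$S_4 = p_{12}\sum_j \mathrm{ABF}^{(1)}_j \mathrm{ABF}^{(2)}_j$; posteriors
follow by normalisation. Defaults are the conventional per-variant priors
$p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior SDs 0.15 for
quantitative traits (the QTL side) and 0.2 on the log-odds scale for binary
outcomes; all are arguments. ABFs are computed from $(\beta, \mathrm{se})$
directly; no allele-frequency-based variance reconstruction is attempted.

Numerically, every sum runs in log space via log-sum-exp, so windows
containing $|z| > 40$ signals neither overflow nor collapse; the $S_3$
difference is computed as $\log(e^a - e^b)$ with the result clamped at
$-\infty$ (i.e. $S_3 = 0$) when $b \ge a$, which also makes a single shared
variant yield $\mathrm{PP}_{H3} = 0$ exactly. The test suite checks the
implementation against an exhaustive enumeration of all
$1 + m + m + m(m{-}1) + m$ causal configurations (computed with
density-ratio ABFs, an independent route) to $10^{-10}$.

## Evidence tiers

Per layer with data: +1 point if the layer's BH-adjusted p is below 0.05
(strict), +1 if $\mathrm{PP}_{H4} > 0.75$ (strict). With three layers the
score is 0–6 and maps to tiers $\{0\} \to$ None, $\{1,2\} \to$ Weak,
$\{3,4\} \to$ Moderate, $\{5,6\} \to$ Strong. "None" is our addition for
totality: the scoring function must accept a feature whose plasma layer is
non-significant even though the pipeline only invokes scoring for
plasma-significant features.

Direction consistency is a separate flag: `TRUE` iff every *significant*
non-plasma layer's Z shares the plasma Z's sign, `NA` with a single layer or
no significant co-layer. The flag never changes the score; it gates the MR
stage. Note one deliberate consequence of using significance-gated signs:
in the packaged 25-protein worked example the rule flags both MST1 (the
annotated case) and ABO, whose breast-tissue layer is significant with the
opposite sign to plasma — the example table annotates only MST1, but we
prefer the uniform rule to a per-feature exception, and the tier label is
unaffected.

## Mendelian randomization

Instruments: exposure variants with $p < 5\times10^{-8}$, falling back to
$5\times10^{-6}$ only when nothing passes; greedy LD clumping by ascending p
with defaults $r^2 = 0.001$ within a 10 Mb window (the convention behind
"default" clumping in two-sample MR practice). Harmonization re-expresses
outcome effects on the exposure's effect allele, resolving strand flips by
complementing and discarding palindromic variants whose effect-allele
frequency is uninformative (in $[0.42, 0.58]$ or missing) — the common
two-sample-MR default window.

Estimators:

* **Wald ratio** (one instrument): $\hat\beta = \beta_Y/\beta_X$,
  $\mathrm{se} = \mathrm{se}_Y/|\beta_X|$ (first-order delta method; exposure
  uncertainty ignored, standard for strong cis instruments).
* **IVW** ($k \ge 2$): fixed-effect meta-analysis of per-instrument ratios
  with weights $\beta_{X,j}^2/\mathrm{se}_{Y,j}^2$ — identical to weighted
  least squares of $\beta_Y$ on $\beta_X$ through the origin — with the
  standard error inflated by $\sqrt{Q/(k-1)}$ whenever Cochran's
  $Q/(k-1) > 1$ (multiplicative random effects). This mirrors the common
  default of two-sample MR software.
* **MR-Egger** ($k \ge 3$; with fewer instruments the Egger fields are `NA`,
  not an error): weighted regression with intercept after orienting exposure
  effects positive; residual scale floored at 1 so standard errors are never
  deflated below their fixed-effect value; t reference with $k-2$ df.
* **Steiger directionality**: per instrument
  $r^2 = z^2/(z^2 + n - 2)$ on each side, aggregated by summation (valid
  post-clumping, when instruments are approximately independent; `max` is a
  config alternative we considered and rejected as less powerful), direction
  "exposure→outcome" iff $\sum r^2_{\mathrm{exp}} > \sum r^2_{\mathrm{out}}$,
  p from a two-sided Z-test on the difference of Fisher-transformed
  aggregate correlations. By default Steiger acts as a *filter* (instruments
  explaining more outcome than exposure variance are dropped; `"report"`
  mode keeps them), because filtering is the stricter reading of
  reverse-causation control; the whole-feature direction is still reported
  from the aggregate test.

The gate: only Strong/Moderate features whose direction-consistency flag is
not `FALSE` enter MR; refusals are returned as statuses (`"gated"`,
`"not-estimable"`), never exceptions, so one feature cannot abort a run.
Replication against external cohorts is called "replicated" (some validation
with the same sign and p < 0.05), "trend" (same sign only), else
"not-replicated". Confidence intervals use $\exp(\hat\beta \pm 1.96\,
\mathrm{se})$.

## Synthetic data and what the calibrations show

The generator emulates the statistical structure of real summary-statistics
inputs without any individual-level data:

* **LD**: AR(1) blocks $r_{ij} = \rho^{|i-j|}$, default $\rho = 0.6$ and
  window sizes of 25–50 variants mimicking a cis window; chosen for analytic
  tractability (the marginal z model below is exact under it).
* **Marginal GWAS z-scores**: $z = \alpha\sqrt{n}\,Rw/\sqrt{w^\top Rw} +
  \varepsilon$, $\varepsilon \sim \mathrm{MVN}(0, R)$, $\beta = z/\sqrt n$,
  $\mathrm{se} = 1/\sqrt n$ — continuous-trait scaling in SD units even when
  emulating a binary outcome, since every downstream statistic consumes
  $(\beta, \mathrm{se}, z, n)$ identically; case/control counts are carried
  but only matter to the colocalization prior choice.
* **Study conditions**: the default `simulate_study()` uses 20 features of
  which 2 causal, three layers, QTL sample size 7 000 (a realistic plasma
  proteome discovery cohort), GWAS sample size 50 000, causal QTL
  non-centrality 12 and feature-level effect $\alpha = 0.05$ (so the induced
  association |Z| has expectation $\alpha\sqrt{n} \approx 11$ — a strong,
  clearly-powered signal appropriate for a recovery benchmark).
  MR instrument sets default to exposure $n = 10^4$, outcome $n = 5\times
  10^4$, true instrument effects $\mathcal N(0, 0.15^2)$ with observed
  estimates rejection-sampled past genome-wide significance; because the
  effect SD (0.15) is 15× the exposure standard error, winner's-curse
  attenuation from selecting on the observed estimate is negligible.

The suite's calibrations (fixed seeds, sizes chosen to keep the default run
under a minute for the deterministic parts and a few minutes in total):
50 enumeration-oracle instances at $m \le 6$; 100 shared-variant and 100
distinct-variant coloc scenarios at $m = 50$; 500-replicate IVW null
rejection and coverage; 500-replicate null-Z calibration; 100 seeded
end-to-end runs. Passing these shows internal correctness and calibration
*under the generator's assumptions* — AR(1) LD, one causal variant per
window, Gaussian noise, no allele-frequency structure, no sample overlap.
They do not demonstrate robustness to realistic MAF spectra, multi-signal
loci, mis-specified LD references, or trans effects, all of which are out of
scope here.

## Degenerate inputs and tie-breaks

Dirty summary rows (non-positive se, inconsistent stored z or p beyond
$10^{-8}$ relative / $10^{-6}$ absolute tolerance, identical alleles) are
dropped with a logged count rather than aborting; missing z or p is
back-filled from $\beta$ and se. Clumping breaks p ties by input order.
Duplicate-feature collapse keeps the first record at equal p. The printed
adjusted p `0.0000` in the worked-example table (below its four-decimal
print precision) is read as $10^{-12}$; any value below 0.05 scores
identically. Positions are 1-based and chromosome labels stored without a
`chr` prefix.

## Known limitations

Single-causal-variant colocalization (no SuSiE-style multi-signal
decomposition); no MR-PRESSO, weighted-median or multivariable MR; no
training of predictive weight models; no genotype-level I/O (VCF/PLINK),
liftover or variant-ID mapping. The direction-consistency rule treats the
plasma layer as the anchor; studies without a proteomic anchor layer would
need a different convention.
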