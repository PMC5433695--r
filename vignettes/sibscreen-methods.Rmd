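---
title: "Methods: sib-pair heritability and genotype risk screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sib-pair heritability and genotype risk screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibscreen)
```

`sibscreen` implements two complementary analyses of sibling-pair data for
a binary disease trait — heritability estimation from genome-wide
identity-by-descent (IBD) sharing, and individual risk scoring from a
small set of SNP genotypes — together with the simulator that makes both
testable without access to consortium family data.  This vignette is the
package's own account of the models, the parameters that matter, the
numerical choices, and the limitations a user should know about.

## 1. The Haseman-Elston heritability model

### Regression

For sib pair $i$ with binary phenotypes $P_{i1}, P_{i2} \in \{0, 1\}$ and
genome-wide IBD proportion $\hat\pi_i$, the package regresses the squared
phenotype difference on sharing:

$$ (P_{i1} - P_{i2})^2 = \alpha + \beta\,\hat\pi_i + \varepsilon_i. $$

For a binary trait the response is simply the discordance indicator, so
the regression asks whether discordant pairs share less of their genome
than concordant pairs.  Under an additive model the slope is negative and
the observed-scale narrow-sense heritability is

$$ \hat h^2_o = -\hat\beta / (2\hat\sigma^2_p), $$

with $\hat\sigma^2_p = P(1-P)$ the Bernoulli phenotypic variance at case
proportion $P$.  Assumptions: no inbreeding in the parents, additive
genetic variance only (no dominance — the sib liability correlation is
taken proportional to $\hat\pi$, not to $\hat\pi$ plus a $Z_2$ dominance
term), and approximate normality of genome-wide $\hat\pi$, for which
`ibd_normality_diagnostics()` reports skewness and excess kurtosis as a
diagnostic, never a gate.

When pairs carry a geographic `region` label, `fit_he_mixed()` absorbs
between-region intercept differences with a random effect,
$y = \alpha + \beta\hat\pi + u_{\text{region}} + \varepsilon$, fit by
REML through lme4.  With a single region, or on non-convergence, it falls
back to OLS with `region_variance = 0` and a message; lme4's defaults
govern convergence and the singular-fit check is disabled because a zero
between-region variance is an acceptable answer, not an error.

### Liability transformation

Families recruited through affected children contain far more cases than
a population with prevalence $K$, so the observed-scale estimate is moved
to the liability scale:

$$ h^2_L = \hat h^2_o \cdot \frac{K(1-K)}{z^2} \cdot \frac{K(1-K)}{P(1-P)},
\qquad T = \Phi^{-1}(1-K),\; z = \varphi(T). $$

`liability_multiplier()` exposes the factor itself.  Two useful closed
forms anchor the implementation and are asserted in the tests: at
$K = P = 0.5$ the multiplier is exactly $\pi/2$, and for fixed $P$ it is
strictly increasing in $K$ on $(0, 0.5]$ — which is why a table of
$h^2_L$ across assumed prevalences is necessarily monotone when the
underlying slope is shared.

This correction is a first-order (local) linearization of the
threshold model.  It is accurate when the sib liability correlation
$r = \hat\pi h^2$ is small; at $r$ approaching 0.5 (high heritability) it
under-corrects, which is one reason the package's parameter-recovery
checks show attenuation at high generating $h^2$ (see §5).

### Stratified bootstrap

`bootstrap_h2()` follows the published resampling design: split pairs
into the three concordance strata (AA, AU, UU), draw 300 pairs per
stratum with replacement, refit the regression on the 900-pair rebuild —
whose case proportion is exactly $P = 0.5$, hence
$\hat\sigma^2_p = 0.25$ — transform with the chosen $K$, and repeat
(default $B = 10{,}000$).  Two uncertainty measures are reported:

* `se` — the standard deviation of the replicate $h^2_L$ distribution:
  the spread an analyst should expect from a 900-pair balanced resample;
* `se_of_mean` — `se`$/\sqrt{B}$: the Monte-Carlo error of the reported
  point estimate (the replicate mean).

Published sib-pair tables of this kind print standard errors of order
0.002 with $B = 10{,}000$; that magnitude matches `se_of_mean`, not `se`,
so both are always exposed and the reader chooses.  Note that `se_of_mean`
only measures bootstrap noise: it says nothing about the (much larger)
sampling variability of the underlying cohort.

Replicates with degenerate $\hat\pi$ (zero variance) are skipped and
counted; more than 1% skipped is an error.  Negative heritability
estimates are never clamped — HE slopes can be positive by chance and
truncating them would bias the replicate distribution; `observed_h2()`
flags them with a warning instead.

One set of replicate slopes is shared across all requested prevalences
(`heritability_report()`), because only the multiplier depends on $K$;
this both saves time and makes the cross-$K$ monotonicity exact.

## 2. The 9-feature risk model

### Analysis unit

The classification unit is the **individual within a pair**, not the
pair.  Each affected-proband/unaffected-sib pair yields two mirrored
observations: the affected member scored against the sibling's genotypes
(label 1) and the unaffected member scored against the proband's
(label 0).  The design is therefore exactly balanced — $n$ pairs give
$n$ cases and $n$ controls — which is also what makes the reported AUC
standard errors as small as they are at cohort scale.  Concordant pairs
carry no discrimination signal in this design and are excluded with a
message; pairs recorded with the affected member in the sib slot are
re-oriented.

### Features, fit, evaluation

The predictor for a focal individual is
$G = (g_1..g_9)$: own allele dosages at the three SNPs (0/1/2, additive),
the sibling's three dosages, and three indicators of genotype equality at
each SNP.  Additive dosage coding is the default; a categorical
(two-dummy) coding is available via `build_features(coding =
"categorical")` for sensitivity analysis.  Pairs with any missing dosage
are dropped with a count (`drop_incomplete_genotypes()`); imputation is
deliberately out of scope.

`fit_logistic()` maximizes the binomial likelihood of
$\mathrm{logit}\,\Pr(P = 1 \mid G) = B_0 + \sum_j B_j g_j$ by IRLS with
step-halving.  Convergence requires both a log-likelihood change below
`tolerance` ($10^{-8}$ by default, at most 100 iterations) and a score
vector below $10^{-6}$ in absolute value; at convergence the fitted
probabilities sum to the case count (the score-equation identity, tested
to $10^{-6}$).  Complete separation is detected (diverging coefficients)
and reported as an error; an optional L2 `ridge` penalty, off by default,
is the documented fallback and is also what the single-indicator baseline
uses automatically when its binary indicator separates the classes —
the ROC of a binary test is well-defined regardless.

`roc_curve()` sweeps thresholds at midpoints between consecutive unique
scores, computes the AUC by the Mann-Whitney rank identity (ties count
one half, so the value is exact and invariant under monotone transforms
of the scores), and attaches the Hanley-McNeil standard error with a
truncated normal 95% interval.  `split_discovery_validation()` partitions
*pairs* (both mirrored observations stay together, so no individual leaks
between sets), stratified by sib phenotype where that varies.

Because the discovery AUC is computed in-sample, it carries the usual
optimism of a freshly fitted model (~9 free parameters); chance level
under a null simulation is an out-of-sample property, and the package's
tests assert it on cross-fitted scores.  Users comparing models should
rely on the validation-set AUC.

### Screening metrics

ROC position does not depend on prevalence, but clinical usefulness does.
`screening_metrics()` converts an operating point to predictive values by
Bayes' rule:

$$ \mathrm{PPV} = \frac{se\,K}{se\,K + (1-sp)(1-K)}, \qquad
   \mathrm{NPV} = \frac{sp\,(1-K)}{(1-se)\,K + sp\,(1-K)}. $$

For a rare disease the default operating point (`operating_point()`)
maximizes specificity subject to sensitivity $\ge 0.3$ — the lower-left
region of the ROC curve, where a positive result multiplies risk most.
The threshold is a caller decision; the default floor of 0.3 reflects
screening practice for low-prevalence conditions, where NPV is driven by
specificity and PPV is small regardless.

## 3. What the simulator emulates — and what it does not

`simulate_liability_pairs()` draws, per pair: $\hat\pi$ from a normal
distribution truncated to $[0,1]$ (mean 0.5, the full-sib expectation;
sd 0.04, the theoretical full-sib value — marker-estimated data are
noisier, and 0.056 is the documented "realistic" preset); two standard
normal liabilities with correlation $\hat\pi h^2$; phenotypes by
thresholding at $\Phi^{-1}(1-K)$.  Optional pieces: a shared per-region
liability intercept (defaults: 8 regions, sd 0.05 — artifact choices, as
real cohorts do not document their regional structure), and
affected-proband ascertainment by rejection.

`simulate_genotype_pairs()` adds three biallelic SNPs transmitted
Mendelianly from simulated Hardy-Weinberg parents, a logistic disease
model whose intercept is calibrated numerically (27-point genotype grid
× 121-point polygenic grid, `uniroot` to $10^{-10}$) so the population
risk equals $K$, a shared polygenic logit term with sib correlation
$\hat\pi$, and a synthetic DR3/4-like flag that fires with probability
0.8 for carriers of risk alleles at both of SNPs 2 and 3 and 0.1
otherwise.  Defaults — risk-allele frequencies (0.25, 0.35, 0.30),
per-allele odds ratios (3.0, 2.5, 2.0), polygenic sd 1.3, $h^2 = 0.8$,
$K = 0.005$ — are one-time choices of what a T1D-like cohort plausibly
looks like: strong HLA-class-II-tag effects, a prevalence in the
general-population range, heritability in the middle of the twin-study
range.

Deliberately **not** emulated: chromosome-level recombination ($\hat\pi$
is drawn directly, since the analyses consume only the genome-wide
proportion — a chromosome-level simulator is an extension point, not
built); linkage disequilibrium and real HLA haplotype structure; families
larger than two siblings; parental phenotypes; population stratification
beyond the region intercept.  Consequently, passing tests show that the
*methods* behave correctly under the stated statistical structure — they
cannot show that real consortium family data satisfy that structure.

`simulate_strata()` samples pairs *conditionally on concordance class*
(rejection from the same liability model) so that bootstrap-ready strata
of any size can be built without simulating the enormous base population
a rare disease would require.  The class-conditional $\hat\pi$
distributions are exactly those of the unconditional model, which is all
the stratified bootstrap consumes.

### The supplementary stand-in

The real sibling IBD tables from the original study are
consortium-derived and cannot be shipped.
`synthetic_supplementary_strata()` builds a clearly-labelled synthetic
replacement at the documented marginal conditions (IBD mean 0.516,
sd 0.056, truncated to the published range 0.226–0.715; three strata of
400 pairs) from the liability model at the package defaults.  Every file
it writes is prefixed `synthetic_`.  The stand-in reproduces the
qualitative structure — concordant-affected pairs share more IBD than
discordant ones — but **not** the real tables' exact stratum contrast,
which is precisely the quantity the published heritability values encode
and which the printed marginal summary does not determine.  Analyses run
on the stand-in therefore exercise the full pipeline faithfully without
being a numerical reproduction of the published table.

## 4. Numerical and design choices

* **PLINK dialect tolerance** — `.genome` files are parsed by header
  name, never column position; `PI_HAT` or `Z1`/`Z2` suffices, missing
  `PI_HAT` is reconstructed as $Z_1/2 + Z_2$, and when both are present
  but disagree beyond $10^{-3}$, `PI_HAT` wins with a warning (it is the
  regressor).  Numeric fields are written with six decimals, which bounds
  round-trip error at $5\times10^{-7}$.
* **Tie handling in the ROC** — thresholds at midpoints between unique
  scores; tied case-control scores contribute one half to the AUC.
* **Seed discipline** — one master seed fans out to named sub-streams
  (`derive_seed(seed, "split")`, `"bootstrap"`, ...) so a change in one
  stage's RNG consumption cannot silently perturb another stage; every
  report echoes its seed, and all outputs are bit-reproducible given it.
* **Degenerate inputs** — zero-variance $\hat\pi$ is a singular-design
  error in a direct fit but a counted skip inside bootstrap replicates;
  single-class labels are an error everywhere; zero denominators in
  PPV/NPV return 0/1 with a `degenerate` flag.
* **Problem sizes** — the shipped tests and the acceptance script use
  strata of 400, cohorts of ~1,250–1,400 pairs, recovery runs of 20,000
  pairs, and bootstraps of 2,000–10,000 replicates: the sizes the
  original study reports where it reports them, and comfortable desk-run
  sizes elsewhere.

## 5. Known limitations

* **The HE estimator is noisy at realistic stratum sizes.**  The slope
  rests on differences in mean $\hat\pi$ between concordance strata of
  order $\sigma_\pi^2 h^2 \approx 10^{-3}$, while the mean of a stratum
  with $n$ pairs is only estimated to $\sigma_\pi/\sqrt{n}$.  For an
  unascertained rare-disease cohort the AA stratum is tiny, and the
  resulting estimate can easily move by several tenths between cohorts of
  20,000 pairs.  The bootstrap `se` honestly reflects this; the tiny
  `se_of_mean` does not claim to.
* **Equal-thirds resampling is mildly biased.**  With strata resampled
  1:1:1, the small-$r$ limit of the pipeline recovers $\tfrac{8}{9}h^2$
  rather than $h^2$ (a 1:2:1 design would be exact); combined with the
  liability linearization this attenuates estimates at high generating
  heritability.  The package implements the published 1:1:1 design as
  specified rather than silently "improving" it.
* **In-sample discovery AUC is optimistic** (§2); use the validation AUC.
* **The DR3/4 flag is synthetic.**  The mapping from the three tag SNPs
  to true DR3/4 carriage is not re-derived; the simulated flag only gives
  the baseline model a realistic single-indicator arm.
* **Match indicators with missing genotypes are undefined** in the source
  analysis; the package sidesteps the question by dropping incomplete
  pairs.
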