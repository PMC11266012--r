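---
title: "Methods: two-sample MR, mediation, and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtwosample)
```

## The causal model and its assumptions

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure. For SNP $j$, the exposure GWAS provides
$\hat\gamma_j$ with standard error $\sigma_{Xj}$, and an independent
outcome GWAS provides $\hat\Gamma_j$ with $\sigma_{Yj}$. If SNP $j$ is a
valid instrument — associated with the exposure, independent of
confounders, and affecting the outcome only through the exposure — then
$\Gamma_j = \beta\,\gamma_j$ and each Wald ratio
$\hat\Gamma_j/\hat\gamma_j$ estimates the causal effect $\beta$.

The five pooled estimators relax instrument validity in different ways:
inverse-variance weighting (IVW) assumes all instruments valid; MR-Egger
allows directional pleiotropy under the InSIDE assumption (instrument
strength independent of direct effects); the weighted median tolerates up
to half the weight on invalid instruments; the mode-based estimators
require only that the largest cluster of agreeing ratios is valid. The
package always runs the full panel and reports whether the five estimates
agree in sign, because concordance of direction across assumptions is the
working credibility check for a screening analysis. IVW is the headline
estimator: classification of an exposure as risk or protective factor, and
the mediation gate, use the IVW p-value alone.

## Procedure, step by step

1. **Instrument selection** (`select_instruments`). SNPs associated with
   the exposure at $p < 5\times10^{-8}$; when fewer than `min_snps = 3`
   survive, the threshold relaxes down the ladder
   $5\times10^{-8} \to 5\times10^{-6} \to 5\times10^{-5}$. Three is the
   smallest count at which MR-Egger ($k-2$ residual df) is estimable. The
   reverse direction of a bidirectional screen conventionally starts at the
   relaxed rungs, with per-trait overrides for stubborn traits.
2. **Clumping** (`ld_clump`). Greedy, p-value-ordered pruning within a
   10 Mb window at $r^2 > 0.001$. Ties in $p$ break by (chromosome,
   position, SNP id), making the output invariant to input order. The LD
   source is explicit — dense matrix, sparse pair list, or function —
   because no bundled reference panel could match every ancestry. Missing
   pairs in a supplied sparse source count as unlinked ($r^2 = 0$), since
   sparse LD exports omit below-threshold pairs; with *no* LD source,
   within-window SNPs are conservatively treated as correlated, reducing to
   distance-only pruning.
3. **Harmonization** (`harmonize`). Outcome rows are aligned to the
   exposure's effect allele: direct match kept, swapped alleles flip the
   sign of $\hat\Gamma$ (and reflect the frequency), complementary alleles
   are strand-corrected. Palindromic SNPs (A/T, C/G) cannot be
   strand-resolved from alleles, so they are kept only when both studies'
   effect-allele frequencies fall on the same side of 0.5 and outside
   $0.5 \pm 0.08$; anything else — including missing frequencies — is
   dropped with an audited reason. The 0.08 window is the conservative
   convention for frequency-based inference; every instrument is accounted
   for as either retained or dropped-with-reason.
4. **Estimation and diagnostics.** IVW defaults to multiplicative random
   effects: the fixed-effects SE is scaled by $\max(1, \sqrt{Q/(k-1)})$,
   so heterogeneity widens intervals but the SE never drops below the
   fixed-effects one. Cochran's $Q$ always uses the *fixed-effects* slope,
   since $Q$ itself feeds the random-effects scale and must not be
   self-referential. Egger inference uses $t(k-2)$ — deliberately
   conservative at small $k$, where Egger is weakest. Heterogeneity is
   reported, never used to discard an analysis: cross-platform GWAS pairs
   routinely show significant $Q$ without invalidating the design.
5. **Leave-one-out** runs when the IVW p-value lands in $(0.04, 0.05)$:
   each of $k$ refits omits one SNP (a genuinely fresh IVW fit, not an
   incremental update), and stability of sign and of the 0.05 verdict is
   flagged.
6. **Multivariable MR** (`mvmr_ivw`). The union of the per-exposure
   instruments is jointly clumped (priority: smallest p across exposures),
   aligned to a common effect allele, and fitted by weighted no-intercept
   multiple regression; coefficient SEs scale by
   $\max(1,\sqrt{Q_{mv}/(k-m)})$ with $t(k-m)$ inference. Collinear
   exposures are a hard error naming the offending columns — silently
   dropping a lipid from its own adjustment set would change the estimand.
7. **Two-step mediation** (`run_mediation`). $\beta_{all}$ from
   exposure→outcome IVW, $\beta_1$ from exposure→mediator IVW, $\beta_2$
   from mediator→outcome IVW after deleting every step-2 instrument that
   also instruments the exposure (such SNPs' mediator associations are
   inherited from the exposure and would point the second arrow the wrong
   way). Mediation is declared only when both step p-values are below
   0.05. The decomposition
   $\beta_{12}=\beta_1\beta_2,\;
    \beta_{dir}=\beta_{all}-\beta_{12},\;
    \beta_{per}=\beta_{12}/\beta_{all}$
   is carried at full precision and rounded (3 dp) only at serialization:
   re-deriving published tables shows the reported proportions are
   consistent with full-precision products, not products of rounded
   entries. A delta-method SE for $\beta_{12}$,
   $\sqrt{\beta_1^2 s_2^2 + \beta_2^2 s_1^2}$, is provided; no interval is
   attached to $\beta_{per}$, which is reported as a point decomposition.
   $\beta_{per}$ is flagged undefined when $\beta_{all}=0$.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| ladder | 5e-8, 5e-6, 5e-5 | p-value | genome-wide significance, relaxed only on instrument shortage |
| `min_snps` | 3 | SNPs | smallest k with Egger df > 0 |
| `window_bp` | 1e7 | bp | 10 Mb clumping window |
| `r2_max` | 0.001 | $r^2$ | near-independence of retained instruments |
| `palindrome_eaf_window` | 0.08 | frequency | ambiguity band around 0.5 |
| `effects_model` | multiplicative random | — | dominant two-sample convention; fixed by flag |
| `n_boot` | 1000 | replicates | bootstrap SE for median/mode |
| `phi` | 1 | — | mode bandwidth multiplier |

## What the synthetic generator emulates — and what it does not

`simulate_two_sample` draws, per SNP: MAF uniform on (0.05, 0.5); true
exposure effect $\gamma_j \sim N(0.08, 0.02^2)$; pleiotropic outcome effect
$\alpha_j$ per regime (none / balanced / directional, with an optional
strength-coupled component that violates InSIDE); true outcome effect
$\beta\gamma_j + \alpha_j$. Observed betas add noise with
$se = (2n\,\mathrm{maf}(1-\mathrm{maf}))^{-1/2}$ — the SE of a per-allele
regression coefficient for a standardized continuous trait. Defaults
(k = 100 instruments, n = 200,000 per study) emulate a well-powered
European-ancestry GWAS pair in the range of the real obesity and lipid
datasets (≈14,000–440,000 samples); per-SNP effects of 0.08 SD at these
sample sizes give F-statistics in the hundreds, i.e. unambiguous
genome-wide instruments.

Deliberate simplifications: SNPs are statistically independent (identity
LD) and are therefore placed on a genomic grid spaced beyond the 10 Mb
clumping window, so clumping of simulated panels is a no-op — clumping
logic is instead tested against hand-built LD fixtures with a brute-force
oracle. The SE model is reused unchanged on the log-odds scale when
`binary_outcome = TRUE`; it is an adequate noise model for method testing
but **not** a case-control power model. The two studies never share
samples. Both studies report identical alleles and frequencies, so
harmonization stress cases (strand flips, frequency discordance) are
exercised by dedicated fixtures rather than by the generator. Passing
calibration and recovery tests on this generator therefore demonstrates
correctness of the estimators under the stated model — not robustness to
LD misspecification, sample overlap, allele-frequency drift between
studies, or case-control ascertainment.

`simulate_mediation_chain` adds a mediator: exposure SNPs carry
$\beta_1\gamma_j$ onto the mediator and mediator-only SNPs carry their own
effects; the outcome receives $direct\cdot X + \beta_2 M$, so the total
effect is $direct + \beta_1\beta_2$. Its baseline instrument strength
(0.05 ± 0.005, with the moderated MAF range 0.15–0.45) is deliberately
lower than the two-sample default: it keeps every designated instrument
safely significant for its own trait while the inherited
$\beta_1\gamma_j$ leakage of ordinary exposure SNPs onto the mediator
stays clearly below genome-wide significance, so the instrument sets
selected from the generated tables coincide with the designated ones.
Designated shared SNPs are instead drawn extra strong (0.2–0.24), making
their inherited mediator association itself significant — precisely the
"duplicated SNP" situation the step-2 deletion rule exists for.

## Numerical choices and degenerate inputs

- Weighted-median interpolation uses cumulative mid-weights
  $p_i = \sum_{j\le i} w_j - w_i/2$ and linear interpolation at 0.5, which
  reduces exactly to the sample median under equal weights and odd $k$.
- The mode estimators evaluate the weighted Gaussian KDE on a 512-point
  grid spanning $\bar r \pm 4\,\mathrm{sd}(r)$; identical ratios
  (zero bandwidth) short-circuit to the common ratio. Grid resolution is
  ~$8\,\mathrm{sd}/511$, well below the estimators' sampling noise.
- Bootstrap SEs redraw $(\hat\gamma_j, \hat\Gamma_j)$ from
  $N(\hat\cdot, se^2)$ under a caller-supplied seed; the RNG state is
  restored afterwards, so estimator calls never perturb ambient
  reproducibility.
- Wald-ratio SE uses the first-order delta approximation
  $\sigma_Y/|\hat\gamma|$ (standard for strong instruments); a
  second-order variant adding
  $\hat\Gamma^2\sigma_X^2/\hat\gamma^4$ is available by flag.
  $\hat\gamma = 0$ is a hard error.
- Degradation is explicit, never silent: $k=2$ runs IVW only, $k=1$ the
  Wald ratio only, each flagged; an emptied step-2 instrument set is a
  hard error.
- Serialized summary statistics print doubles with 17 significant digits,
  so write→read round-trips are exact and repeated writes byte-identical.

## Screening policy

No multiple-testing correction is applied across the screened exposures —
the analysis is a hypothesis-generating screen and classification uses raw
IVW p-values — but the classification table carries a Benjamini–Hochberg
FDR column for readers who want it; it never gates any decision. Failing
pairs (no instruments, nothing harmonizable) are skipped with a logged
reason rather than aborting the batch, and report rows plus skip rows
always account for every configured pair.

## Test problem sizes

The shipped test-and-calibration suite uses: 1000 seeded null replicates
(k = 100) for IVW size and Q/df calibration; 500 replicates for the Egger
intercept under balanced pleiotropy and 200 (k = 200) under directional
pleiotropy; 200 replicates for five-estimator recovery at $\beta = 0.3$
under a strong-instrument condition (exposure GWAS of 500,000 with 0.1-SD
instruments, chosen so weak-instrument dilution — a real ~0.2% relative
attenuation at the default strength — is negligible against Monte-Carlo
error); 30 replicates each for MVMR and end-to-end mediation recovery.
These sizes give Monte-Carlo standard errors comfortably inside the
asserted tolerances while keeping a full run of the suite to a few
minutes on one core.

## Known limitations

- No proxy-SNP substitution when an instrument is absent from the outcome
  study; absent SNPs are dropped and audited.
- No F-statistic filtering or conditional-F diagnostics for MVMR; no
  MVMR-Egger; no outlier-removal estimators (MR-PRESSO and relatives).
- The LD interface consumes a user-supplied reference; the package does
  not compute LD from genotypes.
- The decomposition's delta-method SE ignores the covariance between
  steps (they use disjoint instruments, but a shared outcome study can
  still correlate them weakly).
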