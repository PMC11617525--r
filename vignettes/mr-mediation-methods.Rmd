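---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical methods it
implements, the design decisions taken where conventions diverge, and what
the validation suite does and does not establish.

## The inferential setting

Two-sample Mendelian randomization estimates the causal effect of an
exposure X on an outcome Y using genetic variants as instrumental
variables, combining per-SNP summary statistics estimated in
non-overlapping cohorts. A variant j is a valid instrument if it is (1)
associated with X, (2) independent of confounders of X and Y, and (3)
affects Y only through X (exclusion restriction). Under these assumptions
each SNP provides a Wald ratio estimate
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ of the causal effect, and
the estimators below pool them.

Two-step mediation MR extends this to a path X → M → Y: the effect
$\beta_1$ of X on a candidate mediator M is estimated with X's
instruments, the effect $\beta_2$ of M on Y with M's instruments, and the
indirect (mediated) effect is the product $\beta_1\beta_2$. The package's
screening pipeline applies this over a panel of candidate mediators with
family-wise error control and pleiotropy exclusion, mirroring the
screening designs used in mediation studies of adiposity, sex hormones,
metabolic traits and breast-cancer risk.

## Instrument selection

Defaults follow the field's conventions: instruments are SNPs with
exposure association p < 5×10⁻⁸ (strict inequality, so p = 5×10⁻⁸ is
excluded), pruned by greedy LD clumping at r² < 0.001 within a 10,000 kb
window, and SNPs associated with the outcome at p < 10⁻⁸ are removed as
likely confounded or pleiotropic. Two points deserve comment:

- The outcome-exclusion threshold is sometimes written "P<10E-8", which
  read literally is 10⁻⁷. The package defaults to the conventional 10⁻⁸
  and exposes the cutoff (`outcomeExclusionP`) so either reading is one
  argument away.
- The order is select → clump → exclude. The alternative (exclude before
  clumping) is obtainable by composing the exported functions; the
  pipeline fixes one order and logs it, because an unstated order is a
  reproducibility hazard.

Clumping is greedy on ascending p-value with a lexicographic tie-break on
snp id, so results are deterministic. A SNP is removed only when it is
linked to the index (r² at or above the cutoff) *and* within the window on
the same chromosome; without an LD matrix all SNPs count as unlinked, and
without coordinates the LD matrix alone governs. Computing LD from a
genotype panel is out of scope — the matrix is an input.

Instrument strength is reported two ways because the literature uses both:
the standardized-trait approximation R² = 2·MAF(1−MAF)β² with
F = (n−2)R²/(1−R²), and the chi-square approximation (β/se)². They agree
when the trait is standardized and the SNP effect is small; both are
reported rather than silently choosing one.

## Harmonization

Alleles are aligned onto the exposure's effect allele. Non-palindromic
mismatches resolve by swapping (outcome beta negated) or strand
complementation; a complement that also requires swapping is recorded as
`allele_swap`, since the sign change is the action that matters for
estimation. Palindromic variants (A/T, C/G) cannot be resolved from
alleles alone: under the default `infer_by_eaf` policy they are aligned by
comparing allele frequencies on the two sides, and dropped when either
frequency lies within 0.08 of 0.5 (or is missing) — the window where
frequency comparison is unreliable. The `drop` policy removes them
unconditionally. These defaults are declared package conventions, chosen
to match common two-sample MR practice; they are not dictated by any one
study.

## Estimators

With weights $w_j = 1/se(\hat\beta_{Yj})^2$:

**IVW** is the weighted regression of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ through the origin,
$\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j
\hat\beta_{Xj}^2$. Three variance conventions circulate: fixed-effect
($se = (\sum w_j \hat\beta_{Xj}^2)^{-1/2}$), multiplicative random
effects (scaled by the residual SD), and the hybrid that floors the
residual scale at 1. The hybrid is the default because it reproduces the
default behaviour of the standard analysis toolchain in this literature
and is never anti-conservative relative to fixed; all three are
selectable, and which variant produced any published standard error is
generally not recoverable from a paper — an assumption we surface rather
than hide. IVW p-values are two-sided normal.

**MR-Egger** adds a free intercept after orienting all SNPs to
non-negative exposure effects; the slope is robust to directional
pleiotropy under the InSIDE assumption and the intercept estimates the
average direct (pleiotropic) effect. Standard errors use the same
floored residual scaling; p-values use t(J−2), the dominant convention
for Egger's smaller effective sample. The fit solves the weighted normal
equations explicitly rather than post-processing `lm()`, so an exact fit
(zero residual) yields finite floored standard errors instead of a 0/0.

**Weighted median** orders the Wald ratios, weights them by the inverse
first-order ratio variance, standardizes cumulative weights
$p_j = (\sum_{i\le j} w_i - w_j/2)/\sum_i w_i$ and interpolates the 50th
percentile; it is consistent when at least half the weight comes from
valid instruments. No closed-form SE exists for the interpolated
estimator, so the SE is a parametric bootstrap (default 1000 iterations):
per-SNP effects resampled from normal(beta, se), the median recomputed,
SD reported. The seed is a mandatory argument in pipeline contexts; the
bootstrap is orientation-invariant by construction because SNPs are
oriented before resampling.

## Sensitivity diagnostics

**Cochran's Q** uses the first-order weights
$w_j = \hat\beta_{Xj}^2/se(\hat\beta_{Yj})^2$ around the fixed-effect IVW
estimate, with an upper-tail χ²(J−1) p-value. Heterogeneity flags invalid
instruments but does not by itself invalidate IVW.

**Leave-one-out** refits IVW excluding each SNP; a SNP is influential if
its exclusion flips the estimate's sign or its significance at 0.05.

**MR-PRESSO** builds, for each SNP, the IVW slope from all other SNPs,
and measures the weighted squared deviation of the SNP's observed outcome
effect from its prediction; the sum is the global residual-sum-of-squares
statistic. Its null distribution is simulated parametrically (exposure
effects from normal(β̂X, seX), outcome effects from the no-pleiotropy
prediction with normal(·, seY) noise; default 1000 simulations, seeded).
Per-SNP outlier p-values use the analogous per-observation comparison
with Bonferroni correction across SNPs and a 0.05 flagging threshold —
the original method's convention. The corrected estimate is IVW on the
unflagged SNPs; the raw estimate is by construction identical to IVW on
all SNPs. The distortion test of the original method is not implemented
(screening uses only raw and corrected estimates); it is a possible
extension. Because the global p is a simulation fraction, published
MR-PRESSO values are not bit-reproducible without the original
simulation count and seed — both are therefore recorded in this
package's results.

## Multiplicity

Benjamini–Hochberg q-values use the standard step-up
$q_{(i)} = \min_{j\ge i}\min(1, m p_{(j)}/j)$ (via `stats::p.adjust`;
the test suite checks it against a literal re-implementation of the
definition), and Bonferroni is $\min(1, mp)$ with the family size m
allowed to exceed the number of p-values at hand. Families are always
explicit — an exposure's outcomes, the hormone panel per outcome, the
metabolite panel per outcome — and m defaults to the number of tests
actually performed, since including never-fitted traits in m is a choice
a study must declare. Reported q-values are rounded to 3 significant
figures only at serialization.

## The mediation statistic

The indirect effect is exactly $\beta_1\beta_2$. For its significance the
package ships two delta-method Z variants:

- `paper`: $Z = \beta_1\beta_2 / \sqrt{\beta_1^2 se_1^2 + \beta_2^2
  se_2^2}$ — each coefficient paired with its **own** standard error;
- `sobel`: $Z = \beta_1\beta_2 / \sqrt{\beta_1^2 se_2^2 + \beta_2^2
  se_1^2}$ — the classical first-order variance of a product, each
  coefficient paired with the **other's** standard error.

The own-SE pairing is the default because it reproduces, row for row, the
published mediation tables bundled under `inst/extdata/` (agreement to
about eight significant digits on every one of the 83 rows — the residual
discrepancy is exactly the 9-decimal rounding of the printed inputs,
which the test suite bounds by first-order error propagation). Whether
that pairing was intentional in the source analyses is unknowable; the
Sobel variant is always computed alongside, and for the bundled tables
the two differ by roughly 15%, without changing any significance call.
Significance is strict: |Z| must exceed 1.96, so Z = 1.96 exactly is
nonsignificant. The proportion mediated is indirect/total; when the two
disagree in sign the ratio is negative and flagged as inconsistent
mediation rather than silently reported as a share.

## The screening cascade

For each mediator the pipeline fits step 1 (exposure→mediator, exposure's
instruments), step 2 (mediator→outcome, mediator's instruments) and the
total effect, computes BH q-values within the step-1 and step-2 families
(m = mediators actually testable; untestable mediators — no genome-wide-
significant instruments — are excluded from m and reported as such), and
applies exclusions in a fixed order: step-2 nominal p ≥ 0.05, step-2
q ≥ 0.05, Egger-intercept p < 0.05 in either step, step-1 q ≥ 0.05,
|Z| ≤ 1.96. The order is a declared convention following the narrative
order of the screening designs this mirrors; each mediator records the
*first* gate it fails, and the manifest counts every stage.

Two special paths mirror practices in the motivating literature. First,
when *no* mediator survives the step-2 FDR screen, the pipeline can fall
back to uncorrected p < 0.05 gates (both steps), flagging the whole
report as an uncorrected-p screen — the behaviour published for
estrogen-receptor-negative outcomes where FDR annihilated the panel.
Second, when the primary exposure shows step-1 pleiotropy against a
mediator, a configured fallback exposure dataset (e.g. an earlier GWAS of
the same trait) is substituted for that path and the substitution is
recorded in the manifest — without it, a single spurious intercept would
discard an otherwise clean path. One phrasing in the motivating
literature ("excluding … those with q-values below 0.05" for step 1)
reads backwards; the implementation requires step-1 *significance*
(q below the cutoff) for retention, which is the only reading consistent
with the published retained sets, and documents the conflict here rather
than guessing silently.

Reports are written at full double precision (`%.15g`), so re-reading a
report reproduces the in-memory numbers exactly and reruns under the same
seeds are byte-identical.

## The synthetic-data generator

`simulateStudy()` draws genotypes $G_j \sim \mathrm{Binomial}(2,
\mathrm{maf}_j)$ independently (no LD) in three non-overlapping cohorts
and builds traits structurally:

$$X = \textstyle\sum_j \gamma_j G_j + \varepsilon_x,\qquad
  M = \alpha X + \sum_k \zeta_k G_k + \varepsilon_m,\qquad
  Y = \tau X + \theta M + \sum_j \eta_j G_j + \varepsilon_y,$$

with $\eta_j$ nonzero only for a configurable pleiotropic fraction of
exposure instruments. Summary statistics come from actually regressing
each cohort's measured trait on every SNP — not from asymptotic formulas
— so standard errors, allele frequencies and p-values carry genuine
sampling noise and every downstream consumer is tested honestly.
Default parameters describe a well-powered study: cohorts of 20,000,
30+30 instruments, MAF uniform on [0.1, 0.5], instrument effects around
0.12 ± 0.03 on unit-scale traits. These were chosen once, a priori, so
that per-SNP instrument F statistics land near 100 — strong enough that
weak-instrument and winner's-curse biases (both of order 1/F) are an
order of magnitude below the Monte-Carlo resolution of the recovery
tests, as real consortium-scale instruments typically are. Simulated
alleles are drawn from non-palindromic pairs so harmonization never
discards simulated instruments by construction.

What the generator does *not* emulate: LD structure (clumping is a no-op
on simulated panels), population stratification, sample overlap,
winner's-curse from discovery-replication asymmetries, and the
case-control ascertainment of real binary outcomes (a binary option
dichotomizes Y and fits per-SNP log-odds, but recovery targets are stated
for the continuous case only — quantifying log-odds attenuation is out of
scope). Passing recovery tests therefore demonstrates correctness of the
estimators and pipeline logic under the stated structural model, not
robustness to those real-data complications.

`simulatePanel()` extends the model to K mediators, each with its own
instrument block and effects $\alpha_k, \theta_k$, plus an independent
second exposure cohort to exercise the pleiotropy-fallback path.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle:
literal re-implementations (BH step-up, greedy clumping, weighted normal
equations, interpolated weighted percentile), closed forms (IVW), a
sampling oracle (second-order Wald SE), hand-computed instances
(Cochran's Q), and the bundled published tables for the multiplicity and
mediation worked examples. Property-style tests cover scale equivariance,
orientation invariance, permutation equivariance, idempotence,
conservation and gate monotonicity.

The stochastic validation uses: 200 replicates at full default size
(cohorts of 20,000, 30+30 SNPs) for parameter recovery of
$\alpha, \theta, \tau+\alpha\theta$ and $\alpha\theta$, each required to
fall within 3 Monte-Carlo standard errors of truth — recovery is measured
on the truth-defined instrument blocks, because the quantity under test is
the estimator, and data-dependent selection adds effects of its own
(winner's curse from significance selection, and truncation from the
outcome-exclusion gate, which at these effect sizes removes exactly the
strongest instruments and biases step 2 low by roughly θ/100); 500
summary-level replicates for the Egger-intercept type-I error, required to
lie in [0.025, 0.08] at nominal 0.05 (the max(1, σ) floor makes the test
conservative, so rates near 0.03 are expected); 200 replicates for
uniformity of the MR-PRESSO global null p (Kolmogorov–Smirnov at 0.01);
and 50 replicates of the full screening pipeline on a 10-mediator panel
(3 true mediators with indirect effect 0.04, 7 inactive decoys), requiring
exact recovery of the true mediator set in at least 90% of replicates.
The inactive-decoy design is deliberate: partial decoys (α ≠ 0 with
θ = 0 and vice versa) would add false-positive risk on top of the
exclusion-gate risk analysed next, and are exercised instead in a
dedicated constructed-instance test where each exclusion reason is
asserted individually.

The screening-recovery requirement is not met under these conditions, and
the package reports that honestly rather than adjusting the conditions:
the observed exact-recovery rate is 0.86. Every miss is a true mediator
removed by the Egger-intercept pleiotropy gate with a systematically
positive intercept. The mechanism is instructive: the generator draws
instrument effects from a tight distribution (0.12 ± 0.03), so the
between-SNP spread of true effects is small relative to their sampling
error (an I²GX of roughly 0.86). MR-Egger regression identifies the
intercept only through that spread; when it is low, the slope attenuates
toward zero and the intercept absorbs the difference, inflating the
per-step false-exclusion rate from the ~3% seen with well-dispersed
instruments to ~5–8%. With three true paths, each screened by two Egger
tests, the expected exact-recovery ceiling drops to about 0.85. This is a
known limitation of Egger-based pleiotropy gating under low
instrument-effect dispersion, and a caution that applies equally to real
screens whose instruments cluster in strength: a pleiotropy filter at
p < 0.05 will silently discard genuine mediation paths at well above the
nominal rate.

Smaller cohorts (200–8,000) are used where an invariant does not depend
on power — determinism, EAF consistency, per-SNP regression
unbiasedness — with instrument effects scaled so that significance-based
assertions are unambiguous at those sizes.

## Known limitations

- LD is consumed, never estimated; no reference-panel support.
- Multi-allelic variants and indels harmonize only by exact string match;
  no liftover, no GWAS-VCF parsing.
- No multivariable MR (and hence no difference-method mediation), no
  reverse-direction MR, no mode-based or debiased estimators, no
  confidence interval for the proportion mediated.
- The MR-PRESSO distortion test is omitted.
- Binary-outcome simulation is provided for interface completeness; its
  log-odds attenuation is not quantified by the recovery suite.
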