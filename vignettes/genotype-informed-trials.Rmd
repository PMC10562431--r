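---
title: "Genotype-informed weight-loss trials: models, design choices, and what the simulations do and do not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-informed weight-loss trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genodiet)
```

# The problem

Nutrigenomics proposes that common variants modulate how much weight an
individual loses on a high-fat versus a high-carbohydrate hypocaloric
diet. A trial testing that proposition needs four moving parts: (1) a
rule that turns a consumer genotype file into a *fat-responder* /
*carbohydrate-responder* label before randomization; (2) a randomization
scheme that crosses that label with the two diets while keeping the four
genotype-diet groups comparable; (3) an analysis that estimates the
concordant-versus-discordant diet effect with appropriate adjustment and
multiplicity control; and (4) a power framework tying the design to a
detectable effect. `genodiet` implements all four plus a synthetic-data
generator, so the full pipeline is exercisable and testable with no
participant data.

# Responder scoring

## The score

Each panel SNP contributes points on two axes according to the subject's
genotype; the axis totals are compared to thresholds $t_f$ and $t_c$:

- fat-responder: $F \ge t_f$ and $C < t_c$
- carbohydrate-responder: $C \ge t_c$ and $F < t_f$
- both / neither: otherwise (ineligible).

Comparisons are inclusive, so a subject exactly at both thresholds is
"both" and excluded — the conservative reading of an eligibility rule
that excludes dual responders. The four predicates partition the score
plane; that partition, its boundary behaviour, and its invariance to SNP
order are property-tested.

The engine is table-agnostic: panels, per-genotype points, thresholds,
and a version tag live in a YAML config (`load_score_table()`), so a
6-SNP legacy table, the 10-SNP table, or a toy 3-SNP test table are all
just configs. Missing panel calls are handled by policy:
`"reject"` (default for eligibility screening — a screenee without a
complete panel cannot be classified) or `"zero"` (missing SNPs contribute
nothing; for sensitivity analyses).

## Why the shipped table is synthetic

The published scoring criteria for this kind of panel live in trial
supplements that are not redistributable, so the shipped
`score_table_10snp_synthetic.yaml` is this package's own construction and
is labelled synthetic everywhere. Its structure is the plausible one —
0/1/2-type points per effect-allele count, with two SNPs scoring both
axes in opposite directions — and its numbers were fixed by a one-off
calibration (below). It is adequate for simulation and software testing
and inadequate for classifying real people.

## Calibration

The screening split to emulate is 41% fat-responders, 20%
carbohydrate-responders, 39% neither-or-both. A useful fact: if the two
axes used disjoint SNP sets, the axis totals would be independent, and no
marginal probabilities $(a, b)$ can satisfy $a(1-b) = 0.41$,
$b(1-a) = 0.20$ (the implied quadratic has a negative discriminant). The
observed split therefore requires *negatively correlated* axis scores,
which is why two SNPs score both axes in opposite directions.

`responder_class_probabilities()` computes the exact joint distribution
of $(F, C)$ by discrete convolution over SNPs under Hardy-Weinberg
genotype probabilities (panel SNPs independent), and
`calibrate_allele_freqs()` shifts frequencies on the log-odds scale (one
shift per axis) toward target fractions. Starting from field-realistic
frequencies, calibration selected the defaults in
`default_allele_freqs()` with thresholds $(4, 5)$, giving exact class
probabilities (0.410, 0.200, 0.304, 0.086) — i.e. 0.390 combined
both/neither. This was done once, before any downstream testing, and the
defaults are frozen; the sampled split of any finite screening batch then
scatters binomially around these values.

# Genotype file handling

Consumer arrays report on mixed strands. Orientation
(`normalize_alleles()`) accepts an observed pair if it is a subset of the
locus's expected alleles, complements it (flagging `strand_flipped`) if
the complement is, and errors otherwise. One consequence worth noting: a
homozygote for the complement of a reference allele (e.g. CC at an A/G
locus) is a *valid* strand flip to GG, not a mismatch — only pairs
matching neither the reference nor its complement are errors. A/T and C/G
loci are their own complement and cannot be disambiguated from the export
alone; they are accepted as-is with `ambiguous_strand = TRUE`. Three of
the ten panel loci (rs9939609, rs1801282, rs10423928) are ambiguous, so
the generator never strand-flips them: flipping an ambiguous locus
silently changes the genotype, which is precisely the real-world hazard
the flag exists to surface. The generator's 20% flip rate on the other
loci exercises recovery; orientation is idempotent and
complement-invariant by property test.

Missing-call sentinels (`--`, `00`, `0`, `DD`, `II`, empty) all map to a
single missing state; single-allele calls are duplicated to homozygous
pairs (all panel loci are autosomal, so this only affects filler
records); positions are carried as opaque labels and the panel keys on
rsID only — genome-build validation is out of scope.

# Trial design

## Randomization

Allocation is 1:1 within responder-class x sex strata using permuted
blocks: female blocks of 6 then 4, male blocks of 4 then 2, switching at
half of the stratum's enrolment (both the sizes and the switch fraction
are arguments). Completed blocks are exactly balanced by construction; a
partial final block can deviate by at most half a block.

Published trials of this design additionally balance baseline BMI with an
unpublished "randomization equation"; some mechanism must stand in for
it. Here, whenever both arms have open slots in the current block, a
biased coin (p = 0.8) favors the arm that would move the *trial-wide*
running between-arm mean-BMI difference closer to zero, and the coin is
fair while that difference is inside half the tolerance (default
tolerance 1.5 kg/m²). Two deliberate choices: the signal is trial-wide
rather than within-stratum, because small male strata (3-5 subjects) make
within-stratum means too noisy to control anything; and the dead band is
half the tolerance, so pressure engages before the difference can drift
past the tolerance itself. Under 1,000 seeded randomizations of 64- and
145-subject cohorts the between-arm difference has mean ≈ 0 and stays
within tolerance in ≈100% of runs. All parameters are exposed, so the
mechanism is swappable if the real equation ever surfaces.

## Energy prescription

Resting energy is Mifflin-St Jeor; the intake target is
`rmr x activity_factor − 750` kcal/day, snapped to the nearest tier in
1400-2800 by 200, ties rounding up (favoring meal-plan adequacy), clamped
at the ends. The activity factor is not something trial reports state;
1.4 (sedentary-to-light) is the default and is a config knob. Note the
snapping is genuinely nearest-tier: a 1707 kcal target is 93 kcal from
1800 and 107 from 1600, so it prescribes 1800.

# Synthetic data: what it emulates, what it does not

Defaults reproduce the marginal structure of a mid-size US weight-loss
cohort: age 54.4 (SD 13.2) years truncated to 18-75; BMI 34.9 (SD 5.1)
kg/m² truncated to the 27.0-47.5 eligibility window; 84% women; race
0.68/0.295/0.025; weight derived from BMI and sex-specific normal heights
(women 162.6 SD 6.4 cm, men 175.8 SD 7.0 — population-typical values);
log-normal fasting glucose (median 93 mg/dL) and insulin (median 12
µU/mL, sdlog 0.45, spanning normal to insulin-resistant). The outcome
model is

$$\Delta W = \mu + \beta_c \cdot \mathbb{1}[\text{concordant}]
  + \beta_w (W_0 - \bar W_0) + \varepsilon,\quad
  \varepsilon \sim N(0, \sigma^2)$$

with defaults $\mu = -4.8$ kg, $\beta_c = -0.6$ kg,
$\beta_w = 0.02$, and $\sigma = 2.8$ kg. The 2.8 kg is the
individual-level change-score SD a 2.0-kg-detectable design assumes;
published group-level "SDs" near 1 kg for such trials are standard errors
under this reading, and `residual_sd` is settable for anyone preferring
the other interpretation. Attrition is Bernoulli(0.11), non-informative
by default (an informative switch ties dropout to poor weight loss for
sensitivity work); a further 14.2% of eligibles never reach randomization.
Adherence draws per-week macro percentages around the per-arm means/SDs
observed in practice (e.g. high-carb week 4: 63.4/20.9/16.0% with SDs
2.3/2.4/1.0) and renormalizes to 100 — so a zero-SD configuration yields
records exactly at the renormalized means, a fraction below the raw ones
(the three means sum to 100.3).

Not emulated: linkage disequilibrium between panel SNPs (independent),
weekly weight trajectories (change scores only), item-level questionnaire
structure (scale changes are generated directly), measurement error in
anthropometrics, and any genotype-outcome link beyond the concordance
effect. Passing tests therefore demonstrate that the *machinery* is
correct and calibrated under the stated generative model — not that the
synthetic data would fool an epidemiologist, and not anything about real
cohorts.

# Analysis

The primary estimator is ANCOVA on the change score: a linear model of
$\Delta W$ on group (concordant/discordant, or diet arm within a
responder class) plus sex, race, and the baseline value, on complete
cases (no imputation; subjects without a week-12 outcome are excluded).
With two timepoints, a random-intercept longitudinal model with baseline
adjustment reduces to exactly this ANCOVA, which is why no separate
mixed-model route is shipped. CIs are t-based on residual degrees of
freedom. Degenerate inputs are handled explicitly: constant covariates
are dropped with a warning (not an error — small strata make constant sex
or race routine), and an exactly zero residual variance returns the
estimate with `degenerate = TRUE` and a missing p rather than a
fabricated one. With no covariates the estimator provably equals the
pooled-variance two-sample t-test, which the tests verify.

Holm-Bonferroni (`holm_adjust()`, delegating to `stats::p.adjust`)
handles secondary-endpoint families; the food-craving family has six
members (five subscales plus total), so a smallest raw p of 0.001
adjusts to 0.006. HOMA-IR uses the mass-unit denominator 405 (molar
22.5 selectable); its association with weight change is estimated with
diet arm, sex, and race as covariates, and the diet x HOMA-IR interaction
p comes from an F-test against the main-effects model.

# Power

For the two-sample contrast, `two_sample_power()` evaluates the
noncentral-t expression directly: with $n$ per arm,
$\lambda = \delta / (s\sqrt{2/n})$, $\nu = 2n - 2$, power
$= 1 - T_\nu(t_{\mathrm{crit}}; \lambda) + T_\nu(-t_{\mathrm{crit}};
\lambda)$ — both tails, i.e. genuinely two-sided. At the design point
(δ = 2.0 kg, s = 2.8 kg, α = 0.05) this gives 0.803 at 32/arm and 0.980
at 64/arm. The normal approximation replaces $t_{\mathrm{crit}}$ and the
t CDF with their Gaussian limits; the z-versus-t gap is about 0.012 at
n = 32 and below 0.005 by n = 100 — worth knowing because the
approximation error at the actual design size exceeds what one might
assume for "n ≥ 30".

`simulated_power()` validates the closed form against the estimator the
package actually uses. Its default analysis is unadjusted, matching the
closed form's assumptions; `adjust = TRUE` adds the sex/race/baseline
covariates, which in this generator are pure noise and measurably *cost*
power (~2.5 points at n = 32, driven mostly by the 2.5%-frequency race
category eating a degree of freedom with a near-empty design column).
That gap is a real property of covariate-adjusted small trials, not a
bug, and is why the two routes are kept distinct.

# Pipeline and reproducibility

`run_pipeline()` chains generate → parse → score → screen → randomize →
prescribe → simulate outcomes/adherence → analyse → report. Every stage
seeds from the run seed via fixed offsets, so config + seed determine
every number; runs re-executed with the same seed are byte-identical, and
the report cites the seed and an MD5 hash of the configuration. Subgroup
contrasts are only estimated when each arm has at least two completers —
tiny strata otherwise make the report fragile under batch use.

Problem sizes used in the shipped tests were chosen to make binomial or
CLT error bands decisive at 3-4 standard errors: 4,000-5,000 subjects for
marginal-moment checks, 500 replicates for Monte-Carlo size/power,
1,000 seeds for randomization balance, 275 for the screening split (the
scale at which that split is quoted), and 5,000/arm for effect recovery.

# Known limitations

- The synthetic score table is not the published instrument; conclusions
  about classification *rates* transfer only insofar as the calibrated
  split does.
- Strand-ambiguous loci are accepted as reported; a systematically
  flipped A/T locus in a real export would be silently mis-scored — the
  flag is surfaced so callers can decide.
- The BMI-balancing equation is a stand-in mechanism, config-swappable,
  chosen to meet the balance behaviour such trials report.
- Attrition is independent of outcome by default; informative dropout is
  available but no estimator here corrects for it (complete-case analysis
  is unbiased only under the non-informative default).
- The power module covers the two-sample contrast only; no group-
  sequential or adaptive features.
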