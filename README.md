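# genodiet

Design, simulation, and analysis tools for randomized weight-loss trials
in which participants are classified **a priori** as *fat-responders* or
*carbohydrate-responders* from a panel of diet-response SNPs read out of
direct-to-consumer (DTC) genotype exports, then randomized to a diet that
is concordant or discordant with their genotype.

It is written for biostatisticians and nutrigenomics researchers who want
to prototype, power, or stress-test such gene-diet interaction trials on
synthetic data before (or instead of) touching participant data.

## What it implements

- **DTC genotype parsing** — 23andMe-style (4-column) and AncestryDNA-style
  (5-column) raw exports, with vendor missing-call sentinels and
  Watson-Crick strand orientation (strand-ambiguous A/T and C/G loci
  flagged).
- **Responder scoring** — a config-driven genetic risk score over a 10-SNP
  panel (FGF21 rs838147, TCF7L2 rs12255372, IRS1 rs2943641, APOA5 rs662799,
  PLIN1 rs894160, APOA2 rs5082, FTO rs9939609, PPARG rs1801282, GIPR
  rs10423928, GYS2 rs1478290). Each genotype contributes points on a fat-
  and a carbohydrate-responsiveness axis; a subject is a fat-responder iff
  `fat_points >= t_f` and `carb_points < t_c` (symmetrically for
  carbohydrate-responders); meeting both or neither threshold is
  ineligible. The shipped point values are **synthetic** (see
  `?load_score_table`).
- **Trial design** — stratified permuted-block randomization (strata =
  responder class x sex; female blocks 6 then 4, male blocks 4 then 2)
  with a biased-coin BMI balancing rule; Mifflin-St Jeor resting energy
  (`10W + 6.25H - 5A + 5` male / `- 161` female, kcal/day); 750 kcal/day
  deficit prescriptions snapped to 1400-2800 kcal meal-plan tiers.
- **Analysis** — baseline-adjusted differences (ANCOVA on change scores,
  covariates sex, race, baseline), Holm-Bonferroni family adjustment,
  HOMA-IR (`glucose x insulin / 405`) association and diet-interaction
  models, adherence summaries, CONSORT-style flow accounting.
- **Power** — closed-form noncentral-t and normal-approximation power for
  the two-sample contrast, plus Monte-Carlo power of the actual estimator.
- **Synthetic data** — a seeded generator for genotype exports
  (Hardy-Weinberg, calibrated allele frequencies, missing calls, mixed
  strands), cohorts (age 54.4 SD 13.2; BMI 34.9 SD 5.1 truncated to
  27.0-47.5; 84% women), outcomes (residual SD 2.8 kg, ~11% attrition),
  and adherence records — so the whole pipeline runs end to end with no
  external data.

## Worked example

```r
library(genodiet)

st  <- load_score_table(default_score_config())
cfg <- simulation_config()          # the default trial conditions
run <- run_pipeline(cfg, st, seed = 7)

run$consort
#>               stage   n n_excluded
#> 1          screened 275         NA
#> 2         genotyped 264         11
#> 3 eligible_genotype 164        100
#> 4        randomized 144         20
#> 5         completed 124         20
#> 6          analyzed 124          0

run$effects$all[run$effects$all$outcome == "weight_change_kg",
                c("estimate", "ci_low", "ci_high", "p_value", "n_used")]
#>    estimate   ci_low     ci_high    p_value n_used
#>  -0.8864185 -1.778308 0.005471027 0.05139897   124
```

Reading the output: of 275 synthetic screenees, 264 had complete panel
calls; 164 (62%) carried an eligible fat- or carbohydrate-responsive
genotype, 144 were randomized, and 124 completed. The adjusted difference
says completers on a genotype-concordant diet lost 0.89 kg more than
discordant completers (95% CI −1.78 to +0.01 kg) — for this seed, a chance
excess over the configured −0.6 kg concordance effect.

Power of the planned design:

```r
two_sample_power(delta = 2.0, sd = 2.8, n_per_group = 32)  # 0.803
two_sample_power(delta = 2.0, sd = 2.8, n_per_group = 64)  # 0.980
```

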