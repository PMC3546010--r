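# bcepisodes

Rule-based derivation and classification of bloodstream-infection episodes
from positive blood cultures and hospital-administrative registries, with
concordance evaluation against physician assessments.

## What problem this solves

Positive blood cultures arrive as raw laboratory rows — one per organism per
bottle, sometimes without a draw date. Surveillance and outcome research
need *episodes*, each labelled four ways:

1. **contamination vs. bloodstream infection (BSI)** — a repeat-growth
   screen over common skin commensals (coagulase-negative staphylococci,
   *Propionibacterium*, *Bacillus*, *Micrococcus*, *Corynebacterium*, and
   provisional labels);
2. **monomicrobial vs. polymicrobial** — ≥ 2 distinct organism types within
   the episode;
3. **community- vs. hospital-onset** — from admission time offsets
   (`time_in = culture date − admission date`, `time_out = culture date −
   discharge date`), with explicit handling of same-day and overlapping
   ward transfers;
4. **healthcare-associated or not** — a hospital contact ending 1–30 days
   before a community-onset episode.

Physicians answer the same questions during routine notification. The
package links algorithm-derived *computer episodes* to physician-anchored
*reference episodes* and quantifies concordance per comparison with a 2×2
table (rows = algorithm, columns = physician), percent agreement
`(a+d)/n`, and Cohen's kappa

```
kappa = (Po − Pe) / (1 − Pe),   Po = (a+d)/n,
Pe = [(a+b)(a+c) + (c+d)(b+d)] / n²
```

with Landis–Koch verbal bands, plus crude 30-day-mortality odds ratios
between concordant and discrepant cells. A synthetic registry generator
plants episode classes by construction, so the entire pipeline is testable
without access to real patient data.

Intended users: clinical epidemiologists and infection-surveillance teams
working with laboratory databases and admission registries.

## Worked example

```r
library(bcepisodes)

cfg    <- synthetic_cohort_config(n_patients = 300, seed = 42)
cohort <- simulate_cohort(cfg)
report <- run_full_pipeline(cohort$cultures, cohort$contacts,
                            cohort$assessments, cohort$followup,
                            study_start = cfg$study_start)
print(report)
```

```
Blood-culture episode classification report
  cultures: 610  computer episodes: 340  reference episodes: 296 (linked 296)
  contamination_vs_bsi   n=  296  agreement  97.3%  kappa  0.92 (almost perfect)
  mono_vs_poly           n=  229  agreement  96.1%  kappa  0.82 (almost perfect)
  community_vs_hospital  n=  229  agreement  79.5%  kappa  0.51 (moderate)
  hca_vs_not             n=  138  agreement  65.2%  kappa  0.17 (slight)
```

Reading the output: 610 culture rows (with per-bottle duplicates and some
missing draw dates) collapse into 340 two-day computer episodes; 296
physician-assessed reference episodes all link to a computer episode. The
generator's default physician flip rates disagree with the planted truth
rarely for the contamination call and often for healthcare association, so
agreement is near-perfect for the first comparison and only slight for the
last — kappa corrects each percentage for the agreement expected from the
table margins alone. With all flip rates set to 0 every comparison returns
kappa = 1.00, and the classifiers recover 100% of planted labels.

Published cross-tabulations can be evaluated directly from their counts,
without reconstructing a cohort:

```r
evaluate_from_counts(7288, 276, 240, 1678, "contamination_vs_bsi")
#> $percent_agreement  0.9456
#> $kappa              0.8325
#> $band               "almost perfect"
```

A thin command-line front end covering `simulate`, `episodes`, `classify`,
`evaluate` (including `--from-counts a,b,c,d`) and `run-all` is installed at
`inst/cli/bcepi.R`.

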