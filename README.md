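# vitalid

Patient identity verification from routine vital signs, for clinical
informatics researchers and patient-safety engineers. `vitalid` asks a
narrow question at the bedside: *are these freshly observed vitals
consistent with the identity profile learned for the patient this record
claims to be?* It is an additional safety layer against chart swaps and
registration mix-ups - it supports or refutes a presumed identity and
raises alerts for human follow-up; it never claims to uniquely identify
anyone.

## The model

The core is a **gradient-descent-trained expert system (GDES)**: a rule-fact
network of seven facts (heart rate, end-tidal CO2, respiratory rate and
blood pressure inputs; two intermediates; one output) and three two-input
rules. Each rule outputs a convex combination of its inputs,

    r = w1*f1 + w2*f2,    w1 + w2 = 1,

so the network is a nested weighted average with every decision pathway
inspectable, and training can only re-weight existing associations, never
invent new ones. Per patient, 60,000 rows of a 10-minute, 100 Hz training
window are replayed through a textual command protocol (`SF` set-fact, `TR`
train, `PR` present); each `TR` apportions the error between the output and
the fixed target 0.500 across rules in proportion to their contribution to
the output, and shifts each rule's weights by `velocity * share * |error|`
toward the error-reducing input. A baseline `PR` then yields the profile's
*target value*; later observations are scored by their outputs' absolute
deviation from it, against margins of 0.01 / 0.025 / 0.05 / 0.1.

The package implements the full evaluation machinery around the model:
three network designs, comprehensive (cohort-maximum) and isolated
(patient-maximum) normalization, four baseline recipes, the 50 x 3 x 4
trial grid with its per-margin correct-to-incorrect ratios, a seeded
synthetic cohort generator in the original monitor-export file layout, and
a small CLI (`inst/cli/vitalid`) with `simulate`, `run-trials`, `verify`
and `report` subcommands. See the vignette in `vignettes/` for the methods
account.

## A worked example

```r
library(vitalid)

# A seeded 10-patient synthetic cohort: training segment 04, test segment 07
cohort <- generate_cohort(cohort_spec(n_patients = 10, separation = 2, master_seed = 7))
#> <vitalid_cohort> 10 patients, 2 segment(s), 1200000 rows

# Trial 3: train patient 3's profile on network design 3
cfg     <- trial_config(3, set_no = 3, pr_approach = "fixed_single")
profile <- train_profile(cfg, cohort, every_k = 10)
tidy(profile)
#> # A tibble: 3 x 6
#>   guid        input1         input2          w1     w2 output
#> 1 f51dc6c2-.. heart_rate     etco2          0.832 0.168  intermediate_1
#> 2 6d9413d2-.. resp_rate      blood_pressure 0.374 0.626  intermediate_2
#> 3 055545df-.. intermediate_1 intermediate_2 0.958 0.0419 output
```

Training has learned that, for this patient, heart rate and ETCO2 carry
nearly all the signal (final-rule weight 0.958 on their intermediate).
Generate the baseline target value and score all ten patients' test rows:

```r
baseline <- compute_baseline(profile)
format_gdes_value(baseline$target_value)
#> [1] "000.493"

evals <- evaluate_cohort(profile, baseline, cohort)
summarize_trial(evals, cfg$target_patient)
#> # A tibble: 1 x 11
#>   average_error avg_err lowest correct_0.01 ... false_0.01 false_0.025 false_0.05 false_0.1
#> 1         0.141 0.00342 TRUE   TRUE             1          2           2          5
```

Patient 3's own test rows deviate from the target value by 0.003 on
average - the lowest of all ten patients and within every margin - while
the other nine average 0.14; at the 0.025 margin only two impostors
survive, i.e. the profile ruled out seven of nine possible mix-ups.
Collection-level performance is the correct-to-incorrect ratio; on the
bundled reference tables:

```r
ref <- read_reference_tables()
ratio_at_margin(dplyr::filter(ref, table_id == 1), 0.01)
#> # A tibble: 1 x 5
#>   margin total_correct mean_false ratio ratio_rounded
#> 1   0.01             2        0.8   2.5           2.5
```

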