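# turnerscreen

Family-adjusted short-stature screening for Turner syndrome.

Short stature is a cardinal feature of Turner syndrome, but a girl with
tall parents can carry a substantial Turner growth deficit without falling
below the population cut-off of −2 SDS. Comparing her height SDS with the
**lower end of the parental target range (LTR)** — the family-specific
floor — recovers those girls. This package implements that evaluation for
auxologists and paediatric endocrinology researchers:

* **LMS growth-reference engine** — convert measurements to standard
  deviation scores and back, `z = ((x/M)^L − 1)/(L·S)` (log form as
  `L → 0`), with `L, M, S` linearly interpolated in age; height-for-age
  and birthweight-for-gestation; user-supplied `age,L,M,S` CSV references.
* **Parental targets** — mid-parental height for a daughter,
  `MPH = (mother + father − 12.5 cm)/2`, `LTR = MPH − 8.5 cm`, both as SDS
  at an adult age of 20 y, honouring measured/reported/missing provenance.
* **Screening evaluation** — strict-threshold classification
  (`Ht SDS < −2` for the population, `Ht SDS < LTR SDS` for the family),
  age-banded sensitivity tables (1–5 / 5.1–10 / 10.1–16 y), birthweight
  cut-off sensitivities, and the crude-screening predictive-value worked
  example.
* **Synthetic cohort generator** — a seeded, calibrated simulator of
  Turner clinic cohorts (height SDS −2.63 ± 0.94, LTR SDS −1.77 ± 0.81,
  ages 7.05 ± 4.05 y, the clinic karyotype census, below-average
  birthweight) with closed-form expectations used as Monte-Carlo oracles.
* **Pipeline** — cohort CSV in, classified records, sensitivity tables,
  per-provenance-stratum summaries and a reconciling run manifest out.

A packaged 14-girl fixture (`load_table3_fixture()`) reproduces verbatim
the published table of girls whose first accurate measurement fell at or
above their LTR, and pins the classifier's behaviour.

## Worked example

```r
library(turnerscreen)

height_ref <- synthetic_height_reference()     # analytic stand-in; supply a
bw_ref     <- synthetic_birthweight_reference()# national table for real data

cfg <- default_sim_config(height_ref, n_girls = 172, seed = 20260930)
cohort <- simulate_cohort(cfg, height_ref, bw_ref)
res <- run_analysis(cohort, height_ref, bw_ref)
res
#> <turner_analysis> 172 input, 172 analysed, 0 excluded
#>   below LTR: 69/90 (77%); short (< -2 SDS): 69/90 (77%) [both parents measured]
```

Of the 172 simulated girls, 90 had both parents measured; in that stratum
77% fell below their family's target-range floor. The full age-banded
table, birthweight sensitivities and stratum summaries are in
`res$sensitivity`, `res$birthweight` and `res$stratum_summary`, e.g.

```r
res$stratum_summary
#>        stratum  n mean_ht_sds mean_ltr_sds mean_ltr_minus_ht
#>  both_measured 90       -2.72        -1.82             0.892
#>   one_measured 35       -2.51        -1.72             0.783
#>  both_reported 15       -2.30        -1.62             0.680
```

— the LTR-minus-height gap shrinks when the father's height is reported
(he tends to overestimate) and partially recovers when both are reported
(the mother's underestimate cancels some of it).

The published-count arithmetic is a one-liner each, e.g. the crude
screening worked example:

```r
crude_screening_yield(53802, 0.5, 1/2000, 3)
#> $n_short_girls
#> [1] 800
#> $n_ts_girls
#> [1] 13
#> $ppv_percent
#> [1] 1.6
```

Of ~53,802 annual births, about 800 girls screen below the 3rd centile
but only ~13 of them have Turner syndrome: a 1.6% positive predictive
value for crude short-stature screening.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
full analysis on synthetic data, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R        # references + 172-girl cohort
Rscript analysis/02_run_screening_analysis.R # classification + tables
Rscript analysis/03_published_counts.R       # printed-count arithmetic
Rscript analysis/04_calibration_check.R      # generator parameter recovery
```

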