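# predimr

Two-sample Mendelian randomization and random-effects meta-analysis for
asking whether prediabetic glycaemic variation causes vascular disease.

## The problem

Prediabetes (fasting glucose 5.6–6.9 mmol/L, or the corresponding 2-h
glucose / HbA1c bands) is associated with coronary artery disease, stroke
and kidney disease in observational cohorts, but those associations are
confounded and subject to reverse causation. `predimr` implements the two
analyses that together address the causal question from summary data alone:

1. **Genetic arm** — two-sample Mendelian randomization (MR) using
   *exposure-only* instruments: variants associated with a glycaemic trait
   at genome-wide significance (p < 5×10⁻⁸) but *not* with diabetes itself
   (p > 0.05 in a diabetes GWAS), LD-clumped (r² < 0.2 within 1000 kb) and
   harmonized across exposure and outcome GWAS (including
   frequency-resolved palindromic variants). Causal effects are estimated
   by inverse-variance weighting (IVW),

   β̂ = Σ wⱼ γ̂ⱼ Γ̂ⱼ / Σ wⱼ γ̂ⱼ², wⱼ = 1/σ²_yⱼ,

   with MR-Egger (free intercept = average directional pleiotropy), the
   weighted median, robust (MM / Tukey bisquare) variants of IVW and Egger,
   Cochran's Q, leave-one-out, and an MR-PRESSO-style simulation battery
   (global RSS test, per-variant outlier test, distortion test).

2. **Observational arm** — DerSimonian–Laird random-effects pooling of
   published study-level risk ratios, with τ², I², Cochran's Q, subgroup
   and leave-one-study-out analyses, and Begg/Egger publication-bias tests.

A seeded synthetic-data generator produces every input either arm consumes
(GWAS summary files, LD tables, study tables) with ground truth attached,
so the full pipeline is validated end to end without external downloads.
See the methods vignette (`vignettes/prediabetes-mr-methods.Rmd`) for the
models, assumptions and design choices.

## Worked example

Simulate the default study conditions — 28 fasting-glucose instruments with
a true causal odds ratio of 1.26 per mmol/L against a CAD-scale outcome
GWAS — harmonize, and fit the estimator battery:

```r
library(predimr)
d   <- gen_mr_dataset(seed = 2024)
h   <- harmonize(d$exposure, d$outcome)
fit <- mr_fit(h, seed = 1)
summary(fit)
#> Two-sample MR: fasting_glucose_synth -> outcome_synth, 28 instruments
#>
#>           method   beta     se          OR (95% CI)        p
#>       ivw_robust 0.2572 0.0197 1.293 (1.244, 1.344) 4.25e-39
#>              ivw 0.2591 0.0192 1.296 (1.248, 1.345) 1.22e-41
#>     egger_robust 0.2132 0.0661 1.238 (1.087, 1.409) 1.25e-03
#>            egger 0.2228 0.0661 1.250 (1.098, 1.422) 7.57e-04
#>  weighted_median 0.2396 0.0268 1.271 (1.206, 1.339) 4.40e-19
#>
#> egger_robust intercept: 0.00426 (exp 1.004), p = 0.483
#> egger intercept: 0.00349 (exp 1.003), p = 0.566
#> Cochran's Q = 21.82, df = 27, p = 0.746
```

Every method recovers the generating effect (log 1.26 ≈ 0.231) within its
interval; the Egger intercepts sit at zero (exponentiated ≈ 1) because no
pleiotropy was simulated, and Q shows no excess heterogeneity. The
pleiotropy battery agrees:

```r
mr_presso(h, n_sim = 1000, seed = 1)
#> MR-PRESSO (n_sim = 1000): RSS = 23.4, global p = 0.7682
#> No outliers detected.
```

The observational arm, on a synthetic 21-study corpus generated around
RR 1.16 with between-study SD 0.05:

```r
g <- gen_meta_studies(seed = 2024)
meta_dl_records(g$studies)
#> Random-effects (DL) pooling of 21 studies
#>   RR = 1.165 (95% CI 1.070, 1.268), p = 0.000408
#>   Q = 33.90 (df 20, p = 0.0268), I2 = 41.0%, tau2 = 0.01438
```

The pooled RR lands on the generating value and the heterogeneity
statistics quantify the simulated between-study spread.

`run_mr_arm()` / `run_meta_arm()` orchestrate the full pipelines from a
config list (objects or file paths + column maps; see
`sumstats_column_preset()`), and `render_report()` writes deterministic
JSON/TSV reports.

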