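---
title: "Methods: two-sample MR and meta-analysis for prediabetes and vascular outcomes"
author: "predimr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and meta-analysis for prediabetes and vascular outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the two arms

Prediabetes — glycaemia above normal but below the diabetes diagnostic
threshold (e.g. fasting glucose 5.6–6.9 mmol/L) — is consistently associated
with vascular disease in observational cohorts, but association is not
causation. `predimr` implements the two complementary analyses used to probe
this question:

* a **genetic arm**: two-sample Mendelian randomization (MR) with
  "exposure-only" instruments — variants robustly associated with nondiabetic
  glycaemic traits but showing no nominal association with diabetes itself —
  so the instrument isolates prediabetic glucose variation from diabetes;
* an **observational arm**: DerSimonian–Laird (DL) random-effects pooling of
  published study-level risk estimates, with heterogeneity, subgroup,
  leave-one-study-out and publication-bias diagnostics.

Everything is driven by summary statistics; no individual-level data are
touched. A seeded synthetic-data generator emits every input either arm
consumes, with ground truth attached, so the whole pipeline is testable end
to end without downloading consortium files.

## The genetic-arm model

For instrument $j$ let $\hat\gamma_j$ (SE $\sigma_{xj}$) be its estimated
effect on the exposure and $\hat\Gamma_j$ (SE $\sigma_{yj}$) its estimated
effect on the outcome, from non-overlapping GWAS. The working model is

$$\hat\Gamma_j = \theta_0 + \beta\,\hat\gamma_j + \varepsilon_j,\qquad
\varepsilon_j \sim N(0,\ \phi\,\sigma_{yj}^2),$$

where $\beta$ is the causal effect per exposure unit and $\theta_0$ captures
average directional pleiotropy.

* **IVW** (`mr_ivw()`) forces $\theta_0 = 0$ and solves the weighted
  normal equations in closed form:
  $\hat\beta = \sum w_j\hat\gamma_j\hat\Gamma_j / \sum w_j\hat\gamma_j^2$,
  $w_j = 1/\sigma_{yj}^2$, with unscaled standard error
  $(\sum w_j\hat\gamma_j^2)^{-1/2}$.
* **MR-Egger** (`mr_egger()`) frees the intercept; a non-null intercept
  estimates directional pleiotropy, and the slope remains consistent under
  the InSIDE assumption (instrument strength independent of direct effects).
  Exposure effects are oriented positive during harmonization because the
  Egger intercept is only identified for a fixed orientation (a no-op for
  IVW and the median).
* **Weighted median** (`mr_weighted_median()`) combines per-variant Wald
  ratios $\hat\Gamma_j/\hat\gamma_j$ with weights
  $\hat\gamma_j^2/\sigma_{yj}^2$, interpolating the weighted cumulative
  distribution at 0.5; it is consistent when valid instruments carry at
  least half the weight. Its standard error is a parametric bootstrap
  (default 1000 replicates, seed recorded).
* **Robust variants** refit IVW/Egger by MM-estimation with Tukey's bisquare
  ($c = 4.685$, max 200 iterations, tolerance $10^{-8}$) on the
  precision-scaled variables, via `MASS::rlm`; extreme variants are
  down-weighted rather than removed. A non-converged robust fit falls back
  to the plain fit with a warning. Robust standard errors come from the
  robust asymptotic covariance of the MM fit.

**Dispersion.** Standard errors are scaled multiplicatively by
$\max(1, \sqrt{\mathrm{RSS}/(n - p)})$: between-instrument heterogeneity
inflates them, but an estimated dispersion below 1 never shrinks them.
**Inference** uses normal quantiles throughout (not $t$), for consistency
across plain, robust and bootstrap methods; at the instrument counts used
here (28–74) this makes nominal 5% tests run slightly above 5%, which the
validation suite's acceptance band anticipates. No multiple-testing
adjustment is applied anywhere, matching how such sensitivity batteries are
conventionally reported.

`mr_cochran_q()` reports $Q = \sum w_j(\hat\Gamma_j - \hat\beta\hat\gamma_j)^2$
with $n-1$ degrees of freedom; `mr_leave_one_out()` refits with each
instrument omitted.

## Instrument construction

`run_mr_arm()` applies, in order:

1. **Significance filter** — keep exposure variants with $p < 5\times10^{-8}$
   (strict; a variant exactly at the threshold is excluded).
2. **Disease exclusion** — keep candidates whose diabetes GWAS p-value is
   strictly greater than 0.05. Candidates absent from the disease GWAS
   cannot be certified non-associated and are dropped (counted separately);
   this is the conservative reading of an exclusion rule the instrument
   definition leaves open.
3. **LD clumping** — greedy: sort by ascending p (ties broken by rsid, so
   output is independent of input order), accept the best remaining variant,
   remove all remaining variants on the same chromosome within 1000 kb with
   $r^2 \ge 0.2$ against it. Cross-chromosome pairs never clump, whatever
   the $r^2$ table says, because the window is positional. The retained set
   provably contains no within-window pair at or above the threshold. The
   $r^2$ table is an input; the package never computes LD from genotypes,
   so clumped instrument counts depend on the reference panel supplied.
4. **Harmonization** — align the outcome record of each instrument to the
   exposure effect allele: identical alleles kept; swapped alleles flip the
   outcome sign (and reflect its frequency); strand complements are
   complemented first. Palindromic variants (A/T, C/G) carry no strand
   information in their alleles — a strand flip is textually identical to an
   allele swap — so orientation is decided purely by allele frequency: if
   both frequencies sit on the same side of 0.5 the record is kept,
   otherwise flipped, and the variant is dropped when either frequency is
   missing or falls in the ambiguity window $[0.42, 0.58]$ (policy
   `"infer"`; policy `"drop"` removes all palindromic variants). Indels are
   never treated as palindromic. Every candidate gets a logged action.

## MR-PRESSO-style pleiotropy detection

`mr_presso()` implements the residual-sum-of-squares battery. For each
variant the leave-one-out plain-IVW slope $\hat\beta_{-j}$ is computed in
closed form; the observed statistic is
$\mathrm{RSS} = \sum_j w_j(\hat\Gamma_j - \hat\beta_{-j}\hat\gamma_j)^2$.
The null distribution redraws
$\gamma^*_j \sim N(\hat\gamma_j, \sigma_{xj}^2)$ and
$\Gamma^*_j \sim N(\hat\beta_{-j}\hat\gamma_j, \sigma_{yj}^2)$ and recomputes
the statistic; empirical p-values use add-one smoothing,
$p = (1 + \#\{\mathrm{RSS}^* \ge \mathrm{RSS}\})/(n_\mathrm{sim}+1)$, so they
can never be zero. The per-variant outlier test compares each observed
squared residual with its simulated distribution, Bonferroni-adjusted by the
number of instruments; the distortion test compares raw and
outlier-corrected plain-IVW estimates against removals of the same number of
variants at random. Outlier removal is single-pass, and plain (non-robust)
IVW is used inside the procedure, matching its definition; robust IVW is
reserved for headline estimates.

The default is `n_sim = 1000`. This is not arbitrary: with add-one smoothing
the smallest attainable raw p is $1/(n_\mathrm{sim}+1)$, so with 28
instruments the smallest Bonferroni-adjusted p at $n_\mathrm{sim} = 500$
would be $28/501 \approx 0.056$ — no outlier could ever be declared at
$\alpha = 0.05$. Detecting outliers among $k$ instruments requires
$n_\mathrm{sim} > k/\alpha$; 1000 leaves headroom at the instrument counts
this package targets.

## The observational arm

Study effects (RR, OR or HR with 95% CI) are log-transformed;
the standard error is recovered as
$(\log \mathrm{CI}_u - \log \mathrm{CI}_l)/(2 \times 1.959964)$ — the full
97.5% normal quantile, not 1.96, so forward construction and inversion agree
exactly. HRs are pooled as-is with RRs; ORs are optionally converted via
$\mathrm{RR} = \mathrm{OR}/(1 - p_0 + p_0\,\mathrm{OR})$ but only when a
baseline risk $p_0$ is supplied (off by default — published corpora rarely
report per-study baseline risks, and a guessed $p_0$ is worse than an
honestly pooled OR). Stratified results reported by one article enter as
independent records; the shared-control correlation this ignores is a known,
documented limitation of the standard approach.

`meta_dl()` is the moment estimator:
$Q = \sum w_i (y_i - \hat\mu_F)^2$,
$\hat\tau^2 = \max\{0, (Q - (k-1))/(S_1 - S_2/S_1)\}$,
random-effects weights $1/(v_i + \hat\tau^2)$,
$I^2 = \max(0, (Q - df)/Q)\cdot 100$ (defined 0 when $Q=0$). With one study
the study itself is returned and $Q$ is reported as absent.

Publication-bias tests follow the conventional forms: Egger's regression of
$y_i/s_i$ on $1/s_i$ with a $t$-test on $k-2$ degrees of freedom for the
intercept, and Begg's rank correlation between variance and the
standardized deviates $(y_i - \hat\mu_F)/\sqrt{v_i - 1/\sum w}$ with the
tie-corrected normal approximation. When a study's variance does not exceed
the pooled variance the deviate denominator is floored with a warning; with
completely tied ranks the correlation is reported as 0 with p = 1.

## What the generators emulate — and what they do not

`gen_mr_dataset()` draws, per variant, a minor-allele frequency
$\mathrm{maf} \sim U(0.1, 0.5)$ and a true exposure effect of magnitude
$U(0.05, 0.15)$ with random sign, then adds sampling noise at GWAS-scale
standard errors. For a standardized quantitative trait the per-allele SE is
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$; for binary traits the
generator uses the log-OR analogue
$1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n\,\phi(1-\phi)}$ with case
fraction $\phi$, the standard variance approximation for case-control
summary statistics — using the quantitative formula unchanged on the
log-odds scale would understate binary-trait noise several-fold.

The default conditions are the study conditions the package validates
against: 28 instruments, causal effect $\log 1.26$ per mmol/L, exposure GWAS
$n = 133{,}010$ (quantitative), outcome GWAS $n = 296{,}525$ with
$\phi = 0.1165$ (a CAD-scale case-control panel), disease arm
$n = 898{,}130$, $\phi = 0.0825$ (a T2D-scale panel, used only for its
p-values). Pleiotropy regimes: `balanced` ($\alpha_j \sim N(0, sd^2)$,
InSIDE holds), `directional` ($N(sd, (sd/2)^2)$), and `inside_violating`
($\alpha_j$ correlated with $\gamma_j$). The default `pleiotropy_sd` of 0.01
makes a typical pleiotropic effect roughly 40% of the typical causal-path
effect $\beta\gamma \approx 0.023$ — moderate, not decorative. Outliers add
a stated multiple of $\sigma_{yj}$. Corruption (strand flips, allele swaps,
palindromic allele pairs) is applied to the outcome records only and
recorded in the truth, which also stores the pre-corruption observed pairs
in exposure-positive orientation so harmonization can be checked for exact
inversion. P-values are floored at $10^{-300}$ so very strong instruments
never emit a zero. One user seed drives deterministic per-component
sub-streams, so adding background variants does not shift the instrument
draws.

`gen_meta_studies()` draws study effects
$\theta_i \sim N(\mu, \tau^2)$, $\mathrm{se}_i \sim U(0.05, 0.30)$ — the
span from a large cohort to a small one — and observed
$y_i \sim N(\theta_i + b\,\mathrm{se}_i, \mathrm{se}_i^2)$, where $b$ plants
a small-study (publication-bias) signal. Defaults: $k = 21$ studies,
$\mu = \log 1.16$, $\tau = 0.05$. For the bias-test power check the package
uses $b = 2.0$ at $k = 20$: a pre-study power calculation (intercept SE
$\approx \sqrt{\sigma^2_\varepsilon\,(1/k + \bar{x}^2/S_{xx})} \approx 0.5$
under these conditions) puts 80% power near $b \approx 1.5$, so 2.0 gives a
clear margin without being fantastical.

What the generators do **not** emulate: real LD panels (the $r^2$ matrix is
idealized block-diagonal), winner's curse in instrument discovery, sample
overlap between exposure and outcome GWAS, allele-frequency differences
between cohorts, and genotype-level data of any kind. Passing the validation
suite therefore demonstrates that the estimators and the pipeline are
correct under their own assumptions — not that those assumptions hold in any
particular real dataset.

## Validation problem sizes and numerical choices

The validation suite checks: exact agreement (to $10^{-10}$) of plain
IVW/Egger with independent normal-equations fits on 100 random fixtures;
closed-form reductions (single-instrument IVW = Wald ratio, equal-weight
median = sample median, exact-fit Egger, the hand-worked DL example);
parameter recovery and 95% CI coverage over 500 replicates of the default MR
conditions; Egger-intercept type-I error over 1000 balanced-pleiotropy
replicates; weighted-median robustness with 30% invalid instruments over 500
replicates; outlier detection and null calibration of MR-PRESSO over 200
replicates at `n_sim = 1000`; exact inversion of planted corruption; and DL
recovery plus bias-test power over 500/200 replicates. The type-I check runs
at 74 instruments — the size of the unrestricted all-glucose instrument —
because the nominal-level property is evaluated with normal quantiles, whose
small-sample discrepancy is a function of instrument count, not of the
implementation; a deterministic variance calculation for the weighted
intercept under additive balanced pleiotropy puts the expected rejection
rate near 0.057 at that size.

Other numerical choices: clumping ties broken lexicographically by rsid;
duplicate rsids at load resolved by smallest p-value; empirical p-values
always add-one smoothed; all confidence intervals built and inverted with
1.959964; robust-fit non-convergence falls back to the plain fit with a
warning rather than failing the arm.

## Known limitations

* LD clumping depends entirely on the supplied $r^2$ table; with a different
  reference panel the retained instrument count will differ.
* The weighted-median bootstrap SE ignores the (small) correlation induced
  by re-using the weights.
* OR-to-RR conversion requires a baseline risk the user must supply.
* Ancestry restriction is the user's data-selection responsibility; the
  pipeline only records labels.
* Canalization — developmental compensation masking genetic effects — is an
  MR caveat no summary-statistic method can detect, this one included.
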