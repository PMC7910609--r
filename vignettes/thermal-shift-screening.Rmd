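---
title: "Proteome-wide enzyme substrate screening from thermal shift data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide enzyme substrate screening from thermal shift data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(meltscreen)
library(dplyr)
```

## The experimental idea

When a protein binds a ligand, is post-translationally modified, or
changes conformation, its thermal stability usually changes. Thermal
proteome profiling exploits this: aliquots of a lysate are heated across
a temperature gradient, aggregated protein is removed, and the soluble
remainder of every protein is quantified by multiplexed mass
spectrometry, one reporter channel per temperature. Each protein yields
a melting curve — soluble fraction versus temperature — and a melting
temperature `Tm`.

To find the substrates of an enzyme system-wide, the lysate is treated
in **four arms** before heating:

| arm           | contents                            |
|---------------|-------------------------------------|
| `vehicle`     | buffer only                         |
| `cosubstrate` | the cosubstrate alone (ATP, NAD(P)H, ...) |
| `enzyme`      | the recombinant enzyme alone        |
| `both`        | enzyme + cosubstrate                |

A protein whose `Tm` shifts whenever the cosubstrate is present is a
*cosubstrate binder*; one that shifts with the enzyme alone is an
*enzyme interactor*. A **substrate** is a protein that shifts only when
enzyme *and* cosubstrate are both present — the modification requires
the complete reaction. `meltscreen` implements this screen end to end:
reading and scaling the quantification table, curve normalization,
sigmoid fitting, quality control, the contrast statistics and class
criteria, a permutation estimate of the false discovery rate, and
multivariate (OPLS-DA) ranking of the candidates.

## The melting model

Every protein/sample curve is fit with a three-parameter sigmoid:

$$ I(T) = \frac{1 - Pl}{1 + e^{(T - T_m)/(b\,T)}} + Pl $$

* `Tm` — the melting temperature. The curve passes through
  `(1 + Pl)/2` at `T = Tm` exactly; this identity is tested to 1e-10.
* `b` — the slope parameter. In the default convention the exponent is
  `(T − Tm)/(b·T)`, so `b` is dimensionless and the transition width in
  degrees scales with the absolute temperature; setting
  `screen_config(slope_times_t = FALSE)` switches to the plain
  `(T − Tm)/b` convention where `b` is a width in °C. Both are in common
  use; fits are interconvertible but the fitted `b` values are not
  directly comparable between conventions.
* `Pl` — the high-temperature plateau, the residual soluble fraction
  that never aggregates.

Fitting is bounded Levenberg–Marquardt least squares with a
deterministic multi-start on `Tm` (grid minimum, median, maximum, and
the observed temperature closest to the half-transition — the last one
matters for very steep curves, which otherwise attract a flat-line
local optimum). Ties are broken by lowest SSE, then lowest `Tm`, so
fits are bit-reproducible.

## From reporter intensities to curves

`scale_fold_changes()` divides every abundance by the same protein's
abundance at the lowest (reference) temperature, giving a relative
solubility that starts at 1. One consequence worth knowing: a protein
whose true `Tm` sits close to the reference temperature is already
partially melted at the reference point, so its rescaled curve is not
exactly the model sigmoid and its fitted `Tm` carries a small
deterministic bias (a few tenths of a degree for `Tm` within ~10 °C of
the reference). This is a property of the field-standard scaling, not
of the optimizer; shifts (differences of `Tm` between arms) are much
less affected because the bias is shared.

`normalize_to_reference()` then removes sample-wide distortions
(labeling efficiency, loading). A normalization set of proteins
detected in every sample, with strongly decreasing curves (Spearman
correlation ≤ −0.8 between temperature and fraction) and a low final
soluble fraction (< 0.3), defines each sample's median melting
behavior. The across-sample median curve is itself fit with the
sigmoid, and each sample is corrected multiplicatively toward that
fitted reference, temperature by temperature; the reference temperature
is untouched. This is an approximation — it assumes distortions are
per-sample and per-temperature, not protein-specific — and it can be
switched off (`run_pipeline(normalize = FALSE)`).

## Quality control

Two gates, both configurable in `screen_config()`:

* **Fit quality** — `r2 > 0.7` in every sample entering a comparison.
* **Replicate consistency** — the per-treatment standard deviation of
  `Tm` across replicates must be below 2.5 °C.

A third flag marks **non-melters**: fits whose plateau is at or above
`pl_max` (default 0.5) have no measurable transition in the covered
range (some proteins retain most of their solubility even at the top
temperature), and their `Tm` is set to missing rather than propagated.

## Selection criteria

Per protein, `ΔTm` between two arms is tested with a two-sided t-test;
a two-sided F-test of variance equality at `f_alpha = 0.05` chooses
between the pooled (Student) and Welch forms. With two replicates per
arm the pooled test has two degrees of freedom — single-protein
p-values are intentionally blunt instruments here, which is why the
screen combines them with an effect-size cutoff and a global FDR
estimate rather than interpreting them individually.

* `cosubstrate_binder`: cosubstrate − vehicle, `p < 0.05`,
  `|ΔTm| > 1 °C`.
* `enzyme_interactor`: enzyme − vehicle, same thresholds.
* `substrate`: *both* contrasts both − enzyme and both − cosubstrate
  must pass — `min(p) < 0.05`, `max(p) < 0.1`, both `|ΔTm| > 1 °C`,
  and the two shifts must agree in sign (configurable).

The 1 °C minimum shift is motivated by the observed replicate
variation: the median replicate-to-replicate SD of `Tm` is around
0.4–0.6 °C, so 1 °C is roughly two replicate SDs.

## Permutation FDR

The selection above has many coupled thresholds, so its false-positive
behavior is estimated empirically. `estimate_fdr_permutation()`
shuffles, per protein, the observed `(Tm, r2)` pairs among the sample
positions where that protein was observed (destroying the treatment
structure while preserving each protein's value distribution and
missingness pattern), re-runs the *complete* selection — including the
replicate-SD gate — and reports

$$ \widehat{FDR} = \frac{\text{mean permuted hits}}{\text{observed hits}}. $$

`granularity = "column"` instead applies one common relabeling of the
sample columns per round, preserving protein-protein correlation. The
estimate is conservative when many true positives are planted (their
extreme values keep producing hits under shuffling), and it is
undefined (returned as `NA` with a warning) when nothing was observed.

## OPLS-DA ranking

Selection is univariate; ranking is multivariate.
`fit_oplsda()` treats samples as observations and proteins as
variables, codes the `both` arm against the `enzyme` and `cosubstrate`
arms as +1/−1, autoscales each protein's `Tm` column, removes
`n_ortho` orthogonal components, and extracts a single predictive
component (with `n_ortho = 0` this is exactly one-component PLS-DA).
Each protein's **VIP** (variable importance in projection) is
normalized so the mean squared VIP over the modeled proteins is 1;
`compute_vip()` adds approximate confidence bounds from a
leave-one-sample-out jackknife — approximate, because only 4–8
observations exist. Class *reference points* — the loading-space
positions of an ideal indicator variable for each class — are drawn on
the `autoplot()` loading plot, so proteins projecting toward the
`both` reference point are the coherent substrate candidates.
`rank_candidates()` merges VIP into the candidate table and ranks,
demoting candidates that could not enter the model.

## Simulated experiments and what they say about power

`simulate_experiment(sim_config(...))` generates a complete four-arm
experiment with planted ground truth: baseline `Tm ~ N(50, 4)`,
slopes `~ N(0.03, 0.005)`, plateaus `~ U(0, 0.15)`, planted binders /
substrates / interactors shifting in their defining arms, non-melters
with plateaus of 0.55–0.75, replicate `Tm` noise (0.5 °C by default),
log-normal reporter noise and per-temperature sample distortions (what
normalization removes), and optional whole-sample missingness
(`missing_rate`, 0 by default so that baseline benchmarks are about
statistics rather than missingness; raise it for stress tests).
`evaluate_against_truth()` scores any candidate table against the
planted classes.

One important honest limitation surfaced by these benchmarks: with two
replicates per arm, 0.5 °C replicate noise and a planted shift of
3 °C, the dual-contrast substrate criterion has a *statistical power
ceiling* of roughly 85–90% even with perfect curve fitting — the
`max(p) < 0.1` clause on two-degrees-of-freedom tests is the binding
constraint. Recovery above ~90% under those conditions should not be
expected from any implementation of these criteria; more replicates,
larger shifts, or relaxed secondary thresholds are the levers.

## Validation helpers

Orthogonal follow-up experiments have their own small computations,
implemented in the same strict, testable style:

* `filter_phosphopeptides()` — site localization probability
  strictly > 0.75, score > 40, delta score > 8; channel totals for
  normalization are computed *before* filtering, then log2.
* `normalize_and_impute_lfq()` — total normalization, log2, exclusion
  of proteins missing in more than `max_missing` samples, then
  imputation from a down-shifted normal,
  `N(mean − 1.8·SD, (0.25·SD)²)` per sample; observed values are never
  altered.
* `select_enriched_pulldown()` — mean log2 fold change ≥ 0.5 with
  `p < 0.05` on the same F-gated t-test used by the screen.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(
  n_proteins = 200, frac_substrate = 0.05,
  dtm_mean = 3, seed = 11
)
run <- run_pipeline(sim = cfg, seed = 11, n_perm = 50)
run
evaluate_against_truth(run$candidates$substrate, run$truth)
head(run$ranked)
glance(run$opls)
autoplot(run$opls, highlight = run$candidates$substrate$protein_id)
```

With measured data, replace `sim` by a quant table: write a YAML config
with the sample map (`write_config()` gives a template), then

```{r, eval = FALSE}
cfg <- load_config("config.yml")
quant <- read_protein_quant("protein_groups.tsv", cfg)
run <- run_pipeline(cfg, quant = quant, out_dir = "results", seed = 1)
```

The same pipeline is available from the command line via the installed
`exec/meltscreen` script (`simulate`, `run`, `screen`, `fdr`, `opls`
subcommands).
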