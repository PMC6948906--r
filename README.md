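# dcetofts

Quantitative and semi-quantitative analysis of dynamic contrast-enhanced
MRI (DCE-MRI) enhancement curves for characterizing adnexal masses (and
lesions with similar perfusion behavior). The package implements, as a
single tested pipeline:

* the **extended Tofts** tracer-kinetic model with automatic bolus-lag
  selection, fitted per curve or voxelwise against a calibrated
  **Weinmann population arterial input function** (AIF);
* the standard **semi-quantitative curve descriptors** (relative
  enhancement, time to peak, wash-in/wash-out rates, initial area under
  the curve over 60 s);
* automated **hot-spot ROI** selection on Ktrans maps with per-lesion
  aggregation;
* **group comparisons** (ANOVA; Shapiro–Wilk-gated t / Mann–Whitney) and
  **ROC analysis** with Youden-optimal cutoffs and full confusion-matrix
  metrics;
* a **synthetic cohort generator** with known per-lesion ground truth,
  so the whole pipeline runs end-to-end with no external data.

## The model

Tissue contrast concentration is modeled by the extended Tofts equation

```
Ct(t) = vp · Cp(t − δ) + Ktrans ∫₀ᵗ Cp(τ − δ) · exp(−kep (t − τ)) dτ
```

with `Ktrans` the volume transfer constant (min⁻¹), `kep` the efflux
rate constant (min⁻¹), `vp` the fractional plasma volume, and `δ` the
bolus lag between arterial and tissue enhancement onset, selected
automatically over whole-frame shifts by goodness of fit. The
extravascular extracellular volume fraction is the derived ratio
`ve = Ktrans / kep`. The plasma input `Cp = (1 − HCT) · Cb` (HCT 0.45)
comes from the biexponential Weinmann population blood curve, optionally
calibrated in amplitude and onset to measured arterial curves. Signal is
converted to concentration by the low-dose linearity assumption
`Ct ∝ (SI − SI₀)/SI₀`, so kinetic parameters are in relative
concentration units, comparable within one protocol.

At fixed `(kep, δ)` the model is linear in `(Ktrans, vp)`, and the fit
uses variable projection: a bounded 1-D search over `kep` with an exact
constrained linear solve inside — deterministic and exact in the linear
parameters. The convolution is evaluated exactly for the
piecewise-linear interpolant of `Cp` against the exponential kernel,
keeping discretization error ~0.003% even at 7.6 s frames and large
`kep`.

## Worked example

```r
library(dcetofts)
protocol <- dce_protocol()       # 50 frames x 7.6 s, injection at 10 s, 0.1 mmol/kg
aif <- cohort_aif(protocol)
cp <- blood_to_plasma(population_blood_curve(aif, protocol_times(protocol)), aif$hct)

set.seed(7)
truth <- pk_params(ktrans = 0.05, kep = 2.0, vp = 0.15, delta = 7.6)
curve <- simulate_lesion_curve(truth, aif, protocol, noise_sd = 0.01)
fit <- tofts_fit(signal_to_concentration(curve), cp)
print(fit)
#> Extended Tofts fit
#> Ktrans 0.08311 /min | Kep 2.726 /min | Ve 0.03048 | vp 0.1411 | delta 7.6 s
#>   SSE 0.02616 | R2 0.9949 | status ok
```

The fit recovers `vp` and the lag well and `Ktrans`/`kep` with the
scatter expected at 7.6 s sampling (they are jointly weakly identified;
their ratio `ve` is stable). The descriptors of the same curve:

```r
compute_descriptors(curve)
#> Semi-quantitative descriptors:
#>   SI0 101.3 | SImax 249.4 | SIpeak 247.4 | SIend 212.7
#>   SIrel 146.1% | TTP 73.6 s | WIR 2.012 /s | WOR 0.2478 | iAUC60 7094.44
```

`SIrel 146%` is the peak enhancement relative to baseline; `TTP` is
measured from injection; `WOR 0.25` means a quarter of the peak
enhancement has washed out by the end of the dynamic series.

A full synthetic study — 49 lesions (27 benign, 3 borderline, 19
malignant) in 43 patients, fitted, described, and evaluated with ROC
analysis of every parameter (borderline grouped with malignant as
positives):

```r
study <- run_study(run_config(seed = 0))
print(study)
#> DCE study: 49 lesions, 43 patients (seed 0)
#> Top discriminators (benign vs borderline/malignant):
#>  parameter   auc cutoff accuracy
#>    si_peak 0.788    222     77.6
#>     si_max 0.786    208     75.5
#>     iauc60 0.786   5730     75.5
#>     si_rel 0.783    111     75.5
```

`study$table_groups` and `study$table_roc` hold the full group-statistics
and diagnostic-performance tables; `write_study(study, dir)` persists
them as CSV with a JSON run manifest.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full default study from scratch at the given seed —
generating the synthetic cohort, fitting every lesion, computing the
descriptors and the ROC table — prints the diagnostic-performance table,
and writes the JSON report to `--out`.

## Vignette

`vignettes/dce-kinetics.Rmd` documents the model and its assumptions,
the AIF calibration, what the synthetic cohort does and does not
emulate, the numerical choices, and known limitations (in particular the
weak identifiability of `Ktrans`/`kep` at 7.6 s temporal resolution).
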