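---
title: "Pharmacokinetic and semi-quantitative DCE-MRI analysis with dcetofts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacokinetic and semi-quantitative DCE-MRI analysis with dcetofts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcetofts)
```

## The problem

Dynamic contrast-enhanced MRI acquires a T1-weighted volume every few
seconds while a gadolinium bolus passes through the tissue. Malignant
lesions recruit leaky, disorganized neovasculature, so contrast
extravasates faster and the enhancement curve rises higher and earlier
than in benign tissue. Two complementary readouts quantify this:
tracer-kinetic (pharmacokinetic) parameters from a compartment model,
and semi-quantitative descriptors of the raw signal-time curve. This
package implements both, plus the hot-spot ROI workflow, the group and
ROC statistics used to evaluate diagnostic performance, and a synthetic
cohort generator that provides ground truth for end-to-end validation.

The default acquisition protocol is 50 frames at 7.6 s per frame
(380 s), with the bolus injected 10 s into the scan and a dose of
0.1 mmol/kg — `dce_protocol()`.

## The kinetic model

Tissue concentration follows the extended Tofts model

$$C_t(t) = v_p\,C_p(t-\delta) + K^{trans}\int_0^t C_p(\tau-\delta)\,
  e^{-k_{ep}(t-\tau)}\,d\tau$$

with three free kinetic parameters — $K^{trans}$ (volume transfer
constant, min$^{-1}$), $k_{ep}$ (efflux rate constant, min$^{-1}$) and
$v_p$ (fractional plasma volume) — plus a bolus lag $\delta$ between
arterial and tissue onset. $v_e = K^{trans}/k_{ep}$ is always reported
as the derived ratio: the extended Tofts model has exactly three free
kinetic parameters, so fitting $v_e$ independently would be redundant.

**Arterial input.** $C_p = (1-\mathrm{HCT})\,C_b$ with HCT 0.45.
$C_b$ is the biexponential Weinmann population model
$s\,D\,(a_1 e^{-m_1 t} + a_2 e^{-m_2 t})$ with the published constants
$a_1 = 3.99$, $a_2 = 4.78$ kg/L, $m_1 = 0.144$, $m_2 = 0.0111$
min$^{-1}$ as overridable defaults. The constants are non-critical
because `calibrate_aif()` rescales the curve to measured arterial data:
it estimates a single multiplicative `scale` (least squares, profiled
analytically) and the bolus `onset_time`. Onset detection thresholds at
baseline mean + 3 SD — a conventional choice — which quantizes the
arrival to the frame grid; the onset is therefore refined continuously
within the one frame preceding the detected arrival by minimizing the
residual sum of squares. No shape refit is attempted: amplitude and
delay are the only quantities a 10-patient average can support. When
several measured curves are supplied they are combined as the
frame-wise mean before calibration (an assumption; per-patient fits
would be an alternative).

**Units.** The signal-to-concentration map is the low-dose linear
approximation $C_t \propto (SI - SI_0)/SI_0$ with the proportionality
constant set to 1. All concentrations (and hence $K^{trans}$, $v_p$ in
part) are in *relative* units, comparable within one protocol but not
absolute molar values. The default cohort AIF (`cohort_aif()`) carries
`scale = 18.5`, fixed once so that a lesion with benign-template
kinetics ($K^{trans} = 0.03$, $k_{ep} = 1.89$, $v_p = 0.10$) reaches a
relative enhancement near the benign group mean (~97%); because both
$C_t$ and $C_p$ scale together, this choice cancels out of the kinetic
fit.

## Numerical choices

**Convolution.** The exponential-kernel convolution is evaluated
*exactly for the piecewise-linear interpolant* of $C_p$ (a standard
recursion). Plain trapezoidal quadrature of the product was measured at
0.46% relative error at $k_{ep} = 2$ min$^{-1}$ and 3.1% at 5 min$^{-1}$
on the 7.6 s grid — unacceptable across the $k_{ep}$ range the cohort
generates — whereas the exact piecewise-linear scheme stays near 0.003%
independent of $k_{ep}$. No upsampling is needed.

**Fitting.** At fixed $(k_{ep}, \delta)$ the model is linear in
$(K^{trans}, v_p)$, so `tofts_fit()` uses variable projection: a bounded
1-D optimization over $k_{ep}$ (coarse log grid then golden-section
refinement) with an exact box-constrained $2\times2$ linear solve
inside. This is deterministic — no random multi-starts — and exact in
the linear parameters; bounds are $K^{trans} \in [0, 5]$,
$k_{ep} \in [0, 50]$ min$^{-1}$, $v_p \in [0, 1]$. The lag $\delta$ is
scanned over whole frames (default 0–5): the data are discrete at frame
resolution, so "one unit" of lag is one frame (7.6 s) and sub-frame lags
are not identifiable. The reported $\delta$ minimizes SSE over the grid.
An all-zero tissue curve short-circuits to zero parameters with a
`"zero"` status flag; voxels that fail outright keep a `"failed"` flag
in `fit_voxelwise()` maps rather than being silently zeroed.

**Degenerate inputs.** Flat enhancement curves return zero TTP/WIR/WOR
with a flag; a zero baseline makes relative enhancement undefined and is
an error; constant values in the ROC return AUC 0.5 with a flag;
all-tied groups return a Mann-Whitney p of 1.

## Semi-quantitative descriptors

From a signal-time curve with baseline $SI_0$ (mean of pre-injection
frames): maximum signal $SI_{max}$; relative enhancement
$SI_{rel} = (SI_{max}-SI_0)/SI_0 \times 100$; time to peak (TTP),
measured **from injection time** so the pre-injection lead does not bias
it; wash-in rate $WIR = (SI_{max}-SI_0)/TTP$; wash-out rate
$WOR = (SI_{max}-SI_{end})/(SI_{max}-SI_0)$ with $SI_{end}$ the final
dynamic frame (not any delayed post-dynamic acquisition); and
$iAUC_{60}$, the trapezoidal integral of baseline-subtracted signal over
the first 60 s after injection. $SI_{peak}$ has no universal definition;
it is implemented as the maximum of the 3-point moving-average smoothed
curve — a noise-robust peak that sits slightly below $SI_{max}$ on noisy
data — and documented as an interpretation.

## Hot-spot ROIs

`find_hotspots()` automates the radiologist's placement of three small
ROIs on the most enhancing part of a lesion: it greedily selects
`n_rois = 3` disjoint 6-connected regions of `roi_voxels = 9` voxels
maximizing mean Ktrans, growing a candidate region from every available
seed so that on maps with distinct hot spots the result matches the
exhaustive optimum (verified against brute-force enumeration in the
tests). Per-lesion values aggregate the three ROI means by unweighted
mean (configurable reading; the maximum would be an alternative), and
the descriptors are recomputed on the ROI-mean signal curve.

## Statistics

`compare_groups()` reproduces the three-group workflow: one-way ANOVA
across benign/borderline/malignant, then pairwise benign vs malignant
and benign vs (borderline + malignant) by two-tailed Student's t-test
when both groups pass Shapiro–Wilk at $\alpha = 0.05$, otherwise by
Mann–Whitney U (exact for small tie-free samples, tie-corrected normal
approximation otherwise). No multiple-testing correction is applied, by
design. `roc_with_cutoff()` computes AUC as the rank (Mann–Whitney)
statistic with ties counted one half, its p-value from the tie-corrected
normal approximation, and the operating point as the Youden-optimal
cutoff (ties resolved to the lower cutoff; an accuracy-maximizing
criterion is available). Orientation is fixed as "greater than cutoff =
positive", appropriate because every discriminative parameter here is
higher in malignancy. Borderline tumors are grouped with malignant as
positives.

## The synthetic cohort

No per-lesion data accompany the reference study, so
`generate_cohort()` builds a cohort matching its *statistical
structure*: 27 benign, 3 borderline and 19 malignant lesions, with 6
bilateral (two-lesion) malignant patients so 43 patients carry 49
lesions. Per class, $K^{trans}$, $k_{ep}$, $v_p$ and age are drawn from
distributions anchored to the study's group means/SDs; $\delta$ is
uniform on {0, 1, 2} frames. Curves are simulated through the forward
model as $SI = SI_0 (1 + C_t)$ plus Gaussian noise.

Two generator choices deserve explanation:

* **Distribution family.** The default is a moment-matched lognormal
  per parameter. The reported malignant $k_{ep}$ moments (mean 5.38, SD
  11.81 min$^{-1}$) can only come from a strongly right-skewed
  distribution: a zero-truncated normal with those moments places over
  half its mass above 10 min$^{-1}$ — time constants shorter than one
  frame, which no 7.6 s protocol can resolve — and would make the
  majority of malignant lesions kinetically unmeasurable, contradicting
  the study being emulated. The lognormal keeps the same mean/SD with a
  median of 2.2 min$^{-1}$. A truncated-normal family remains available
  (`family = "truncnorm"`).
* **Noise level.** The default curve noise is 1% of peak signal. The
  cohort's lesion curves stand for hot-spot-ROI-mean curves (3 ROIs of
  ~9 voxels); at the ~5% per-voxel noise used in the recovery
  experiments, a 27-voxel mean has ~1% noise. Independently, the
  study's within-class $K^{trans}$ SD of 0.01 bounds per-lesion
  measurement error far below what 5% curve noise would produce.

Semi-quantitative group differences are *induced* by the kinetic ground
truth (and the common $SI_0 = 100$), not drawn independently, so the
descriptor and kinetic stages always see internally consistent curves.
The generator does not emulate pelvic anatomy, motion, Rician magnitude
noise, or the joint correlation structure of real lesions — so a green
end-to-end test establishes that the pipeline preserves and detects the
group structure the generator encodes, not that it reproduces the
study's exact cohort statistics (its printed AUCs and cutoffs depend on
the unavailable per-lesion data and are out of reach by construction).

## Known limitations

* $K^{trans}$ and $k_{ep}$ are jointly weakly identified at 7.6 s
  sampling against a slowly-decaying population AIF: the SSE surface has
  a shallow ridge along which $K^{trans}/k_{ep}$ (i.e. $v_e$) is
  constant. Noiseless curves invert exactly (the round-trip tests
  demand < 1%), and the *median* of repeated noisy fits is nearly
  unbiased, but individual noisy estimates scatter widely — at 5%-of-
  peak noise, typical single-fit $K^{trans}$ errors are tens of percent.
  This is a property of the model/protocol combination, not of the
  optimizer (the fitted SSE is verified to be the global minimum along
  the ridge). Consequently, per-lesion fitted $K^{trans}$ discriminates
  classes much less well in the synthetic cohort than the ground-truth
  $K^{trans}$ does, and less well than the reference study reports —
  one end-to-end expectation (fitted-$K^{trans}$ AUC > 0.75 at seed 0)
  is knowingly not met and left failing rather than tuned around.
* Concentration units are relative; absolute $K^{trans}$ magnitudes are
  not comparable across protocols.
* $v_e = K^{trans}/k_{ep}$ as reported here need not match a source
  that fit or derived $v_e$ differently; the reference study's printed
  group $v_e$ means are not consistent with its $K^{trans}/k_{ep}$
  means, and the derived-ratio definition is used throughout.
* No NIfTI I/O: volumes are plain R arrays (no NIfTI reader is
  available in the supported dependency set); tables and curves persist
  as CSV.

## Reproducibility

Every stochastic step (cohort draws, noise, phantoms) flows from a
single integer seed; `generate_cohort()` and `run_study()` are
bit-reproducible given (spec, seed), and the run manifest records the
package version, seed and a hash of the configuration.
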