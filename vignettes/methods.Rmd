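---
title: "hrvnet: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hrvnet: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvnet)
```

This vignette documents the science inside `hrvnet`: what each stage
estimates, under which assumptions, which parameters matter and why their
defaults are what they are, and where a genuinely open design choice was
made.

## The analysis problem

Neurovisceral-integration studies record a single-lead ECG and a
multichannel resting EEG simultaneously (conventionally 5 minutes, eyes
closed) and ask three questions: whether a clinical group differs from
controls in cardiac autonomic indices (heart-rate variability, HRV),
whether it differs in the large-scale organisation of cortical coupling
(coherence networks summarised by graph metrics), and whether the two
domains covary differently across groups (correlation networks over the
per-subject summaries). `hrvnet` implements that full path plus a
synthetic cohort generator that makes each claim testable.

## Cardiac chain

**R-peak detection.** The Pan–Tompkins stages are implemented literally:
zero-phase Butterworth band-pass 5–15 Hz, five-point derivative,
squaring, 150 ms moving-window integration, adaptive dual thresholds with
a 200 ms refractory period and a search-back rescan (at half threshold)
of any gap exceeding 1.66 times the running R–R average. Detections are
then refined to the local maximum of the band-passed signal, because the
integrator peak lags the R wave by roughly the integration window; the
unit tests require beat-time errors below 10 ms and recall/precision of
at least 0.99 on clean synthetic ECG.

**Cleaning.** Two sequential screens produce the normal-to-normal (NN)
series: a physiological gate (intervals outside 200–3000 ms are detector
artifacts) and the 20 % ectopic filter. The filter is sequential — each
interval is compared with the *previous retained* interval, as in common
HRV software — which makes it idempotent and lets a single premature beat
be deleted without dragging its normal successor along. Deleted beats are
*not* replaced; the later spline interpolation bridges the gaps. A
cleaned series must retain at least four intervals, otherwise the record
is rejected as too short for any downstream estimate.

**Tachogram and spectrum.** The NN series is cubic-spline interpolated
onto a uniform 4 Hz grid (4 Hz comfortably oversamples the 0.4 Hz upper
HF edge while keeping AR fits short). Before the spectral fit the mean
and a linear trend are removed; slow drifts otherwise leak into the LF
band. The spectrum is parametric: Burg AR of order 16 — the convention of
widely used HRV toolboxes; the order is configurable — evaluated as

$$S(f) = \frac{2\sigma^2}{f_s\,\bigl|1 - \sum_k a_k e^{-2\pi i f k/f_s}\bigr|^2}$$

and integrated by the trapezoid rule over LF = [0.04, 0.15) Hz and
HF = [0.15, 0.4] Hz.

Two numerical points deserve emphasis. First, order-16 AR peaks can be
extremely narrow, so the default evaluation grid is fine (32769 points to
Nyquist); on coarse grids the integral of a sharp peak is badly wrong.
The tests require total integrated power to track the detrended variance
within 15 % and sinusoidal band power to match the closed form
$a^2/2$ within 10 %. Second, a noise-free sinusoid drives the Burg
innovation variance to zero and the spectrum degenerates to a point mass;
`ar_spectrum()` treats a numerically zero innovation variance as an error
("degenerate series") rather than returning spikes. Realistic tachograms
always carry beat-to-beat jitter, so this only affects pathological
fixtures.

**Time domain.** SDNN is the sample SD of all NN intervals; SDNNi is the
mean of per-segment SDs with segments defined on *elapsed time* (50 s),
not beat count, and a trailing partial segment admitted only when it
holds at least 10 beats; RMSSD and pNN50 follow their definitions; HR is
60000 divided by the mean NN interval.

## Cortical chain

**Windowed coherence.** Coherence is estimated from mean-removed,
Hann-tapered sliding windows. The printed estimator is the
magnitude-squared coherence built from per-window cosine/sine
coefficients: the squared modulus of the window-summed cross-spectrum
over the product of the summed auto-spectra. It is exactly 1 for
identical channels, exactly symmetric, and invariant to per-channel
rescaling (all asserted without tolerance in the tests). A bin with zero
power in either channel yields coherence 0 with a warning instead of a
NaN that would poison the band average.

Window parameters are a genuinely open choice and were fixed as: window
length 2 s (frequency resolution 0.5 Hz, which resolves the 1 Hz delta
edge — the shortest window that does), overlap 75 %, Hann taper. Band
averaging averages *per-bin coherence* across each band's bins; the
alternative (pool cross-spectra over the band, then form one coherence)
is deliberately not the default because the band-wise reading of the
estimator applies the coherence formula per frequency. Bands are
half-open $[low, high)$ except gamma, closed at 40 Hz, so the shared
edges 4, 8, 12, 25 and 30 Hz are counted exactly once.

With $N$ windows the coherence of truly independent channels is biased
upward by roughly $1/N_\mathrm{eff}$, where $N_\mathrm{eff}$ accounts for
window overlap (about one quarter of the window count at 75 % overlap
with a Hann taper). The tests bound the independent-channel floor at
$3/N_\mathrm{eff}$ plus a small margin, and the calibration suite checks
the analytic shared-source value: two channels $y_i = s + n_i$ with
independent band-limited noises of the source's variance have in-band
coherence $\sigma_s^4/(\sigma_s^2+\sigma_n^2)^2 = 0.25$, and the
estimator must land within ±0.05 of it.

**Artifact handling.** Interactive artifact editing is replaced by a
simple amplitude-threshold rejector: any 2-s block in which any channel
exceeds the threshold is excluded from spectral averaging, and at least 8
clean windows must survive. This models gross movement/electrode
transients only — see the honesty section below.

**Graph metrics.** Each band's coherence matrix (diagonal forced to
zero; self-coherence must not create self-loops) is a complete weighted
graph. Edge lengths are $1/w$ — the default convention for association
weights; $-\log w$ is available as an option. The characteristic path
length is the mean of shortest-path distances over *ordered* node pairs
(the $n(n-1)$ denominator of the printed double sum), with single-source
Dijkstra runs per node; a disconnected graph (possible only after
optional proportional thresholding, which is off by default) is an
error, not an infinite average. The weighted clustering coefficient uses
the cube-root geometric-mean triangle intensity
$t_i^w = \frac12\sum_{j,h}(w_{ij}w_{ih}w_{jh})^{1/3}$ — the convention of
the standard brain-connectivity toolbox, adopted because the bare
$C^w$ formula leaves $t_i^w$ undefined. Both metrics are validated
against exhaustive oracles: Floyd–Warshall all-pairs relaxation (exact to
1e-12 on random complete graphs up to 8 nodes) and hand-evaluated
triangles, plus exact invariances (inverse scale law
$L^w(cW) = L^w(W)/c$, permutation invariance, $C^w \in [0,1]$).

## Statistical layer

**Outlier screening** is cell-wise, not listwise: for each variable the
largest-magnitude studentized residual from a null model (group means
when a group factor exists, otherwise an intercept) is tested with a
Bonferroni-corrected two-sided p value; significant cells are masked and
the test repeats to convergence. Cell-wise masking is what produces the
differing effective n across variables that screened physiological
tables typically show. Losing more than 20 % of a variable's values
raises a heavy-tail warning.

**Model routing.** A response that rejects Shapiro–Wilk normality
(p < 0.05) *and* is strictly positive is analysed with a gamma GLM;
otherwise an ordinary linear model. The gamma link is log — the choice is
open in principle; the canonical inverse link has domain problems for
near-zero means, and the log link makes group effects multiplicative,
which matches how spectral powers behave. Non-normal responses containing
non-positive values fall back to the linear model with a warning.

**Effect sizes and collinearity.** Group contrasts report the group
coefficient's t (Wald t for the GLM) and
$\eta_p^2 = t^2/(t^2 + df_\mathrm{res})$; the GLM uses the same formula
with residual df, mirroring the linear case, since no separate GLM
effect-size recipe is established. The design matrix is screened by the
condition index (columns scaled to unit norm, square root of the
eigenvalue ratio of the cross-product matrix); an index above 30 refuses
the covariate set rather than silently reporting an unstable
coefficient.

**Correlation networks.** Spearman correlations (midranks for ties,
asymptotic p values) over all unique variable pairs, with
Benjamini–Hochberg adjustment *within one group's family of pairs* —
matching the per-group reporting of such studies; pooling families across
groups is possible but not the default. Constant variables are reported
with undefined r and excluded from the FDR family so they do not dilute
the correction. The type-I error of the contrast (0.05 ± 0.02 over 1000
null replicates) and exact agreement of the BH step with a brute-force
step-up implementation are asserted in the acceptance suite.

## The synthetic cohort: what it emulates, and what it does not

`generate_rr_series()` is a rate-modulation generator, not a cardiac
dynamics model: the instantaneous R–R interval is a mean plus one LF
(default 0.1 Hz) and one HF (default 0.25 Hz) sinusoid plus Gaussian
jitter, integrated into beat times. Only tachogram statistics matter
downstream, and this construction places the modulation frequencies
inside the analysis bands by design, with band powers known in closed
form ($a^2/2$). Ectopic beats are injected as premature contractions
(interval shortened by 25–40 % of its predecessor), guaranteeing each
violates the 20 % filter; ground-truth flags allow recall measurement.
The ECG renderer places a stylised QRS template at each beat time — no
P/T waves, by intent: it exists to exercise the detector against known
beat times.

`generate_eeg()` mixes band-limited common sources into channels with
fixed weights plus independent noise, giving closed-form coherence
targets. `generate_cohort()` draws per-subject parameters: control HR
around 64 ± 6 bpm with cases shifted by `effect_hr` (default +5 bpm);
log-normal LF/HF modulation amplitudes with the case HF amplitude scaled
by `sqrt(effect_hf)` (default power factor 0.5); theta source weights
scaled down for cases by `effect_theta_cpl` (default 0.25); and a latent
bivariate Gaussian copula linking each subject's overall R-R variability
scale to their theta coupling strength with correlation
`-rho_sdnn_cpl_case` in cases only (default target correlation −0.4,
mirroring the −0.37…−0.38 range reported for such effects). IQ is drawn
per group with the case group lower (means 104.78 vs 117.86), so the
IQ-adjusted contrasts are exercised under realistic covariate imbalance.

What passing tests on this cohort *do* show: the pipeline recovers
injected spectral suppression and coupling differences of realistic
magnitude through every stage, holds its nominal error rates on null
cohorts, and reproduces the sign of an injected cross-domain correlation
in the affected group only. What they do *not* show: robustness to real
ECG morphology variation (P/T waves, baseline wander), real EEG artifact
structure (ocular, myogenic), volume conduction (common sources here are
genuine couplings, whereas scalp coherence in real data is partly
conduction), non-sinusoidal respiratory modulation, or non-stationarity
within the 5-minute epoch.

## Problem sizes used in the validation suites

Simulation scales were chosen once, as the package's own desk-scale
validation conditions: single-subject fixtures use full 5-minute R-R
records; coherence calibration uses 2-channel, 120-s records at 250 Hz
over 20 seeds; cohort-level effect-recovery runs use the study-scale
group sizes (50/50) over 20 seeded cohorts with full-length (300 s) R-R
records — SDNNi needs several 50-s segments — and 60-s, 250 Hz EEG
records, which leave the coherence estimator with 117 windows per
subject, comfortably above its small-sample floor. Null-calibration of
the group contrast uses 1000 simulated subject tables. Generator
defaults themselves (300 s, 1000 Hz EEG, 19 channels) always reflect the
full recording protocol.

## Known limitations

- Coherence is plain magnitude-squared coherence; no volume-conduction
  correction (imaginary coherence), directed measures, or source-space
  analysis.
- The amplitude-threshold artifact rejector does not model ocular or
  myogenic artifacts; real recordings need proper editing upstream.
- Frequency-domain HRV omits the VLF band and respiration correction;
  nonlinear HRV indices are out of scope.
- The EDF reader/writer covers the continuous 16-bit subset (equal
  sampling rates across channels, no annotations) — sufficient for
  round-tripping this package's own exports and typical continuous
  resting recordings.
- Printed group-table t statistics that were covariate-adjusted in the
  original reports cannot be recomputed from unadjusted summary means and
  SDs; `pooled_t_from_summary()` reproduces exactly the unadjusted rows.
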