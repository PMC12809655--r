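---
title: "Isotopologue ratios from LC-coupled Orbitrap data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotopologue ratios from LC-coupled Orbitrap data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbidelta)
```

## The measurement problem

Compound-specific stable isotope analysis by electrospray Orbitrap mass
spectrometry reads the isotopic composition of an intact (fragment) ion
directly from the relative heights of its isotopologue peaks. Coupling
this measurement to liquid chromatography introduces two artifacts that
this package models, measures, and (through simulated data) lets you
study in isolation:

* **Chromatographic isotope fractionation.** Isotopologues of one
  analyte elute at slightly different retention times, so the
  instantaneous isotope ratio varies systematically *across* a peak.
* **Amount-dependent (nonlinear) ionization.** Measured delta values of
  some elements depend on analyte concentration, so the varying
  concentration across a peak biases isotope ratios even for perfectly
  co-eluting isotopologues.

The workflow under study captures the chromatographic peak after the
column — either in a plug-flow capillary loop that *preserves* the peak
shape, or in a stirred mixing chamber that *homogenizes* it — and then
infuses the capture device's contents into the source at low flow,
bracketed against a syringe reference for drift correction.

## From scan tables to delta values

### Ion counting

The pipeline starts from scan-level tables (one row per averaged
spectrum and isotopologue) carrying the signal intensity $S$, the peak
noise $N$, the resolving power $R$, the microscan count $\mu$, and the
charge $z$. The number of ions each reading represents is

$$N_{IO} = \frac{S}{N}\,\frac{C_N}{z}\sqrt{\frac{R_N}{R}}\sqrt{\mu},$$

with the empirical constant $C_N = 3$ and the reference resolving power
$R_N = 240{,}000$ (`processing_constants()`). `ions_observed()`
implements this relation and `sn_from_ions()` its exact inverse, which
the simulator uses to encode sampled ion counts back into intensities
(`peak_noise` is serialized as 1 so that the round-trip is exact to
better than $10^{-12}$).

### Blocks, ratios, and shot noise

Ion counts are summed over fixed processing windows (15 min by
default), and the block isotopologue ratio is the ratio of sums,
$R^i = \sum_j N_{IO}^i / \sum_j N_{IO}^{base}$, where the *basepeak* is
the isotopologue containing only the most abundant isotopes. Windows
are half-open $[t_0, t_1)$ so that consecutive blocks partition time
exactly; a block that would straddle a valve switch is an error rather
than being silently truncated. The predicted relative standard error of
a block ratio under Poisson counting is
$\sqrt{1/N_{rare} + 1/N_{base}}$ (`shot_noise_limit()`); covariance
between the separate mass peaks is neglected, which is an approximation
(the two isotopologues share the trap, but their image currents are
read from distinct m/z channels).

### Bracketing, drift correction, calibration

A run alternates reference (syringe) and sample (capture device)
segments on a fixed valve period (20 min by default, reference first: a
180-min run gives 5 reference and 4 sample segments). The first 2 min
after each switch are discarded as a guard time — the flow path needs
to settle; the value is configurable and the choice matters little as
long as blocks fit in the remaining window. Each sample block's ratio
is referenced to the *linear interpolation in time* between the two
bracketing reference-block ratios. Linear interpolation was chosen over
higher-order schemes because it makes an exact statement testable: any
ratio drift that is linear in time between consecutive reference blocks
is removed identically, and smooth slow drifts are removed to first
order. Deltas are kept on the ratio scale throughout and converted to
per mil once, at reporting.

Calibration to an assigned scale (VPDB/VCDT/air) is by one anchor
(offset) or two anchors (affine map, `delta_calibration()`); the
two-point form also inverts a multiplicative delta-scale distortion,
which the simulator can impose (`scale_distortion`) to emulate the
occasional "scale expansion" day.

### Uncertainty

The reported 95% half-width pools the scatter of the drift-corrected
sample blocks and of the reference blocks,
$SE = \sqrt{s_s^2/n_s + s_r^2/n_r}$, with Welch–Satterthwaite degrees
of freedom and a $t$ quantile (`combined_ci()`). The reference-side
scatter is taken about the reference blocks' *own linear drift trend*
(regression residuals, df-corrected), not about their raw mean:
bracketing removes the drift trend from the result, so leaving it in
the reference scatter would double-count it as uncertainty. A
2000-replicate shot-noise simulation in the test suite confirms the
interval covers the truth at 95% ± 3%.

`allan_deviation()` provides the standard non-overlapping Allan
deviation for choosing an integration time: under pure counting noise
it falls as $\tau^{-1/2}$; drift makes it rise again, and with the
default drift magnitudes the minimum falls in the 10–15 min range,
which is why 15-min processing blocks are the default.

## The forward simulator

The generator (`sim_config()`, `run_experiment()`) emulates the whole
chain with parameters fixed at the study conditions; they are defaults,
not tuning knobs.

* **Chromatography.** Each isotopologue is a Gaussian of common width
  ($\sigma = 15$ s) centered at the analyte retention time plus a
  per-isotopologue offset $\Delta t_R$ (positive = heavier more
  retained, the normal isotope effect). The log heavy/light flux ratio
  is then linear in time with slope $\Delta t_R/\sigma^2$; an offset of
  +0.075 s spans $1000 \cdot 4\sigma\,\Delta t_R/\sigma^2 = 20$ per mil
  across a $\pm 2\sigma$ window. Isotopologue abundances follow the
  stochastic (binomial) distribution — a singly substituted species at
  atom fraction $p$ with $n$ substitutable atoms has abundance
  $n\,p/(1-p)$ relative to the basepeak — shifted by the configured
  true enrichment.
* **Capillary capture** is plug flow: the captured window is eluted
  time-reversed (the end of the peak enters the source first) and
  stretched by the flow ratio (500/4 = 125×), with concentrations and
  moles conserved. The device capacity is enforced: an 80-s window at
  0.5 mL/min would need 667 µL and overflows the 540-µL capillary, so
  the capillary scenarios use a 60-s ($\pm 2\sigma$) window.
* **Chamber capture** homogenizes all captured analyte instantly
  (stirring), then washes it out as a dispersed plug:
  $C(t)/C_0 = \Phi((\tau - t)/\sigma_t)$ with $\tau = V/Q$ and
  $\sigma_t = \tau\sqrt{2/Pe}$. An ideal stirred tank would decay
  immediately, contradicting the observed multi-hour plateau; the
  dispersed-plug front with $Pe = 40$ leaves the 95% plateau after
  $\tau - \Phi^{-1}(0.95)\,\sigma_t \approx 180$ min ≈ 3 h
  (`chamber_plateau_time()`). The model's Gaussian front truncates a
  $\sim\Phi(-\sqrt{Pe/2}) \approx 4\times10^{-6}$ mass fraction; tests
  assert chamber mole conservation at $10^{-5}$ relative (capillary:
  $10^{-6}$).
* **Source bias** is a delta shift, not a response-curve model (the
  mechanism of the nonlinearity is out of scope):
  $\beta\,\ln(c/c_{lin})$ below the linear-range onset $c_{lin}$, zero
  above, continuous at the boundary. Defaults: carbon $c_{lin} = 10$ µM
  with $\beta$ sized so the bias magnitude at 0.5 µM is 65 per mil;
  sulfur $c_{lin} = 4$ µM with at most 9 per mil below it; nitrogen in
  between; all configurable. The 4-µM syringe reference carries its own
  bias, which cancels in bracketed $\Delta\delta$ exactly as in real
  linearity experiments.
* **Drift** is a multiplicative ratio factor
  $1 + (d_{lin}t + W(t))/1000$ shared by both channels; defaults 1 per
  mil/h linear plus a 0.3 per mil/√h random walk, the order of the
  slow drifts a bracketed run is designed to remove.
* **Ion statistics.** Per trap fill the expected charge is
  $\min(\text{AGC target},\ \text{rate} \times t_{max})$ with AGC
  $1.5\times10^5$, maximum injection 1000 ms, and a source rate of 1000
  ions ms⁻¹ µM⁻¹ (chosen so the AGC cap is active above ≈0.15 µM, as
  it is for all study concentrations); a spectrum accumulates 10
  microscan fills. The AGC target is applied per fill — whether the
  instrument's printed target applies per fill or per averaged spectrum
  is not documented, and per fill is the conservative reading. Counts
  are Poisson (seedable, or disabled entirely for transparency tests).
  Spectrum periods default to 2.0 s at resolving power 90,000 and
  0.75 s at 30,000 (transient length scales with resolution; plus
  fill/processing overhead).

Identical configuration and seed give byte-identical scan tables, and
every run's truth log records the configuration, seed, injected and
captured moles, so expected pipeline outputs are computable in closed
form.

### What the simulator does and does not emulate

It reproduces the *structure* of real scan data — AGC-capped Poisson
counting, concentration-dependent delta bias, slow common-mode drift,
capture-device-shaped concentration profiles, bracketing schedules —
but not electrospray physics, space-charge or coalescence effects,
isobaric interferences, real AGC prescan behavior, or analyte
speciation chemistry. Passing tests therefore demonstrate that the
*processing* is correct and that the workflow's claims follow from its
stated mechanisms; they do not certify accuracy on real instrument
data, where excess (non-Poisson) noise makes confidence intervals wider
than the shot-noise-limited ones simulated here.

## Problem sizes and numerical choices

Simulated study runs are 180 min at the real spectrum rates (5,400
spectra for a 90,000-resolution fragment; 14,400 at 30,000), which a
single run processes in well under a second. Replicate counts in tests
and in the acceptance script (10–20 replicates for stochastic
quantities, 2000 for the coverage simulation, which uses direct Poisson
draws rather than full runs) were chosen so Monte-Carlo error is small
against each tolerance. Degenerate inputs fail loudly: zero basepeak
sums, blocks straddling a valve switch, unbracketed sample blocks,
capture overflow, and singular (equal-anchor) calibrations are all
errors, while empty processing windows in an otherwise valid run are
skipped with a warning. Retention-offset sign convention: positive
means the heavier species is more retained; the capillary's time
reversal then makes the observed elution-time trend negative.

## Known limitations

* The drift random walk is a crude stand-in for real instrument state;
  bracketing removes most but not all of it, and the residual inflates
  simulated CIs slightly — conservatively, relative to the pure
  shot-noise floor.
* Shot-noise bookkeeping ignores inter-channel covariance.
* The chamber model stirs only once, at capture; continuous stirring
  during elution would sharpen the plateau edge (higher effective
  Péclet number).
* Nitrogen-15 in the aniline fragment is known to be sensitive to
  speciation effects that are reproducible here only phenomenologically
  via a large configured retention offset.
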