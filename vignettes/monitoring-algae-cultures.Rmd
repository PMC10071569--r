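---
title: "Monitoring microalgae cultivations from drift-time IMS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring microalgae cultivations from drift-time IMS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

driftwatch turns a time series of membrane-inlet ion mobility spectrometry
(MI-IMS) spectra, recorded every few minutes above a photobioreactor, into
process-state information and discrete control recommendations. This
vignette is the package's account of the underlying models, the choices we
made where the methodology was genuinely open, and what the bundled
simulator does and does not establish about real cultivations.

## The measurement model

A drift-tube IMS separates ions by their mobility $K$ in a weak electric
field $E = U/L$: an ion needs
$$t_d = \frac{L}{E\,K} = \frac{L^2}{U\,K}, \qquad
  K = K_0\,\frac{T}{T_0}\,\frac{p_0}{p}$$
to traverse the tube of length $L$ at drift voltage $U$. `drift_time()` and
`reduced_mobility()` implement this boundary; mobilities are stored in
cm$^2\,$V$^{-1}$s$^{-1}$ and converted to SI only inside the physics
functions. The default `instrument_config()` describes a compact
Tritium-source instrument: $L = 56$ mm, $U = 2470$ V, drift gas at 80 °C,
ambient pressure. Reference conditions for $K_0$ are not standardized
across instruments; we adopt the common convention $T_0 = 273.15$ K,
$p_0 = 1013.25$ hPa, and both are configurable.

Rather than relying on absolute drift times, every spectrum is normalized
to the **relative drift time**
$$t_{rel} = \frac{t_{d,\mathrm{Ion}}}{t_{d,\mathrm{RIP}}},$$
the ratio to the drift time of the reactant ion peak (RIP), the dominant
peak produced by ionized air constituents. All instrumental factors cancel
in the ratio, so peak positions become comparable across instruments and
days. `find_rip()` locates the RIP as the global intensity maximum,
refined to sub-sample precision with a three-point parabola through the
apex (the plain argmax is available via `refine = FALSE`, and an apex on
the first or last axis sample is returned unrefined and flagged).

## Peaks, noise and the limit of detection

The background noise level $\sigma$ is estimated in a configurable
peak-free window of the relative axis (default $t_{rel} \in [2.2, 2.9]$,
beyond all configured peaks — the instrument literature never states where
noise should be measured, so the window is exposed as a parameter). The
windowed trace is linearly detrended and $\sigma$ taken as the median
absolute deviation of the residuals scaled by 1.4826: consistent for
Gaussian noise, and a stray peak in the window perturbs it far less than a
standard deviation would. The limit of detection is defined as
$\mathrm{LOD} = 3\sigma$.

`detect_peaks()` keeps strict local maxima that exceed the local baseline
plus the LOD, lie after the RIP exclusion zone ($t_{rel} > 1.05$ by
default), and survive minimum-separation suppression (0.02 $t_{rel}$;
the more intense of two close maxima wins). The trace is pre-smoothed with
a cubic Savitzky–Golay filter (11-point window) before the local-maximum
rule: with more than a thousand samples per spectrum, a bare $3\sigma$
threshold on the raw trace crosses on pure noise roughly once per
spectrum, while on the smoothed trace the per-spectrum false-positive rate
stays well below 5% without attenuating peaks that are several samples
wide (the default peak width, $\sigma = 0.015\,t_{rel}$, spans about seven
axis samples). A relative epsilon of $10^{-9}$ of the trace maximum guards
the threshold against float-level ripples when the input is noise-free and
the LOD is exactly zero.

Detections are labelled against the configured peak set by
`match_known_peaks()`: nearest center within a tolerance of 0.02
$t_{rel}$, greedily by intensity, one detection per label. Unmatched
detections are flagged **novel** — the signal that new chemistry
(contamination, lysis, nutrient limitation) has appeared — unless they
fall within $3\sigma$ of a known center, in which case they are read as a
shoulder artifact of that peak rather than new chemistry.

Quantification uses the fixed-center Gaussian model: the spectrum is
modelled as a non-negative linear combination of unit Gaussians at the
configured centers and widths plus a constant term that absorbs the flat
detector baseline. Amplitudes solve the non-negative least-squares problem
(Lawson–Hanson, via pracma); unconstrained least squares is available
behind `nonneg = FALSE` for oracle comparisons. Non-negativity is a
physical constraint (intensities cannot be negative), not a fitting
convenience. Per-peak time series record both the apex intensity (maximum
baseline-corrected sample within the tolerance window, the quantity a
maximum-intensity trace plot shows) and the fitted amplitude; the
below-LOD flag is decided on the fitted amplitude, which averages over the
peak footprint and has roughly a quarter of the single-sample noise.

## The state model

For process monitoring we use all axis samples after the RIP rather than
seven peak maxima: each spectrum contributes the intensities at more than
a thousand relative drift times between 0.7 and 3. Spectra are
interpolated onto a common grid (1150 points by default), columns at
$t_{rel} \le 1.05$ are masked, each remaining column is centered and
scaled to unit variance, and the top four right singular vectors of the
scaled training matrix become the component loadings. Zero-variance
columns are scaled by 1 and recorded instead of dropped, so the grid stays
intact.

PCA loadings are defined only up to sign, which would make scores and
rules irreproducible across fits. Each component is therefore anchored to
a labelled peak through its contribution (loading $\times$ training mean
intensity, summed over the peak's $\pm 3\sigma$ window): PC1 so the
growth-marker peak d contributes positively, PC2 so the death-marker peak
g contributes positively, PC3 so the over-illumination marker peak f
contributes negatively (making the shading rule fire downward), and PC4 —
which no rule consumes — by the neutral convention that its
largest-magnitude loading element is positive. Two fits of the same matrix
return bit-identical loadings.

The model is fitted once on designated training cultures and frozen; new
spectra are only projected, never used to refit. The canonical training
design (`training_configs()`) combines standard reference cultures with
one culture run under the 60% → 200% illumination-step protocol, because a
component can only learn the over-illumination pattern (peak f) if that
pattern occurs in training. Whether the headline analysis should use raw
grid intensities or the Gaussian-model amplitudes is ambiguous in the
methodology this package operationalizes — both are legitimate
data-reduction strategies — so both are implemented; the raw grid is the
default feature matrix and the peak-amplitude route remains available
through `extract_time_series()`.

## Control rules

`classify_scores()` maps score trajectories to one recommendation per
spectrum with safety-first precedence
`SHADE > CHECK_SYSTEM > HARVEST_OR_CHECK_CONTAMINATION > HARVEST_OR_FEED >
DAY_NIGHT_DIP > CONTINUE`. The shading threshold, PC3 $< -5$, is the one
published rule; everything else had to be quantified here, was calibrated
once on the default simulator, and is exposed in `control_thresholds()`:

* trends are trailing least-squares slopes over 12 spectra (2 h at the
  10-min acquisition interval), in score units per hour;
* *PC2 rising* means slope $> 0.25$/h; *PC2 strongly negative* means a
  level below $-20$;
* *PC1 at maximum* is read from the running maximum of PC1: its trailing
  slope over 36 spectra (6 h) must fall below 0.15/h while the current
  score sits within 5 units of the running maximum, and a total rise of at
  least 10 units must have been observed first (the running maximum, not
  PC1 itself, is used so nightly dips of the growth peaks do not read as a
  plateau);
* a drop of the growth peaks c–e (mean apex slope below $-2$ intensity
  units/h) with no novel peak present is reported as `DAY_NIGHT_DIP` — the
  normal dark-phase signature, requiring no action.

When a peak table accompanies the scores, both harvest rules additionally
require the death-marker peak g to be above the LOD, and
`HARVEST_OR_CHECK_CONTAMINATION` requires PC1 to have fallen off its
running maximum: "cell concentration decreasing" is then supported by both
markers, and transient PC2 excursions at light/dark edges or at the sharp
onset of g cannot masquerade as decline. All statistics are causal
(trailing windows, running maxima), so batch classification and
one-spectrum-at-a-time streaming (`cmd_monitor()`) produce identical
sequences; the first 11 spectra return `INSUFFICIENT_DATA`.

Reference analytics live beside the rules: `od_to_dryweight()` applies the
linear calibration $c_x\,[\mathrm{g/L}] = 0.86 \cdot OD_{750}$;
`correlate_peak_with_od()` fits peak intensity against offline OD750 over
the growth phase (up to the OD maximum); `growth_phase_significance()`
compares phase windows against the start of the run with a two-sided
two-sample t-test. We use the Welch (unequal-variance) form: nothing
guarantees equal variances between a baseline window near the LOD and a
phase window of strong peaks.

## What the simulator emulates

No public spectrum set exists for this application, so the simulator is a
first-class module and defines the conditions everything else is tested
under:

* **Growth.** Logistic OD750 dynamics from an inoculation density of 0.11
  toward a carrying capacity of 1.0, integrated with a per-step exact
  logistic update on the 10-min grid; growth rate 0.042 h$^{-1}$ and death
  onset at day 5.5 place the OD maximum between day 5 and 6. After onset,
  OD declines exponentially (0.01 h$^{-1}$). The effective growth rate
  scales with illumination up to a saturation of 1.5× the reference level,
  so the 60% → 200% step protocol produces the expected growth-rate
  change. The trajectory itself is deterministic — noise enters only at
  the measurement layer — which is what makes parameter-recovery tests
  meaningful.
* **Light.** 16 h on / 8 h off per day. Illumination gates VOC emission
  (the growth peaks c–e are attenuated by a factor 0.4 in the dark, a
  chosen value exposed as `dark_attenuation`) but not the OD dynamics:
  dark respiration losses are neglected as small against the daily growth
  increment.
* **Emission.** Seven characteristic peaks at evenly spaced relative drift
  times in $[1.2, 1.6]$ (graphical sources show the range but never print
  numeric centers; all centers are configurable). c, d, e scale with OD —
  so peak d culminates exactly when growth does; a and b are low,
  medium-associated constants; f appears only above 1.5× reference
  illumination; g follows a saturating function of the OD decline
  fraction, $1 - e^{-(1 - OD/K)/0.15}$, rising sharply at stationary onset
  and monotonically through death — the sharp onset is deliberate, because
  the death marker is described as rising sharply once maximum cell
  concentration is reached, and an early version with a proportional ramp
  produced a death signature too weak to classify in its first day. A
  Chlorella variant maps all signal peaks below $t_{rel} = 1.2$ to emulate
  the species-distinct pattern.
* **Rendering.** Spectra are sums of Gaussians — RIP (reduced mobility
  2.1 cm$^2$V$^{-1}$s$^{-1}$, amplitude 1000) at $t_{rel} = 1$, a small
  pre-RIP artifact at 0.9 with 5% of the RIP amplitude, and the emission
  peaks — on a constant detector offset (10 a.u.) with i.i.d. Gaussian
  noise (sd 1) and clipping at zero. The offset is deliberate: real traces
  sit on a detector baseline, and without it the zero-clip would truncate
  the noise distribution and collapse the MAD estimate, making the
  3$\sigma$ LOD meaningless. The default axis spans $t_{rel}$ 0.65–3.1
  with 1200 samples, 1126 of them between 0.7 and 3.
* **Offline OD.** Five samplings per day, placed inside a daily working
  window (hours 1–15, within the lit phase) because offline photometry is
  a manual operation performed while the culture is lit; six replicate
  reads with a 2% coefficient of variation.

What passing tests therefore show: the pipeline recovers what this
generative model puts in — peak positions, amplitudes, phase structure,
the illumination response — at realistic noise. What they do not show:
robustness to membrane aging and drift-gas humidity excursions, RIP
depletion at high analyte load (the simulated RIP amplitude is constant),
peak-shape asymmetry, instrument-to-instrument transfer beyond what
relative-drift-time normalization removes, or the actual VOC chemistry of
any organism. Score magnitudes depend on the grid size and training-set
composition, so thresholds calibrated here must be recalibrated for real
instruments.

## Numerical choices and degenerate inputs

Interpolation onto the common grid is linear; grid points outside a
spectrum's range are filled with 0 under a warning (blank regions carry no
signal). Non-monotonic axes, mismatched lengths, zero RIP drift times,
all-zero spectra, empty trajectories, singular Gaussian designs (duplicate
center/width pairs) and grid mismatches against a frozen model are all
explicit errors rather than silent repairs. A constant peak series makes
$R^2$ undefined and errors; two phase windows with zero variance and equal
means return $t = 0$, $p = 1$. Config files round-trip through YAML with
15-digit precision and unknown keys are rejected by name.

Test and acceptance workloads run the default problem sizes — 8-day
cultivations at the 10-min interval (1152 spectra), a three-culture
training matrix of 3456 spectra on a 975-point masked grid, and ten
simulated cultivations for the correlation check — which we consider the
realistic scale for this application; the full suite completes in about a
minute on one core.

## Known limitations

The rule engine's non-published thresholds are simulator-calibrated
defaults, not validated setpoints. The day/night-dip rule fires on the
dusk transition, not throughout the dark phase (deep-night slopes are
flat), so dark-phase spectra between transitions read as `CONTINUE`.
Streaming recomputes the causal statistics per spectrum in quadratic total
time, which is irrelevant at six spectra per hour but would matter for
kilohertz streams. The serialization format is a package-specific CSV
matrix with a JSON sidecar; established mass-spectrometry interchange
formats with ion-mobility extensions were judged overkill for a 1-D trace
and are out of scope.
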