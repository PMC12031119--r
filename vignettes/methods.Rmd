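---
title: "Methods: persistence-homology range-bin selection for FMCW vital signs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: persistence-homology range-bin selection for FMCW vital signs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(radarvitals)
```

## The problem

A frequency-modulated continuous-wave (FMCW) radar placed lateral to a
sleeping person maps different body parts onto different range bins of width
$\Delta R = c/(2B)$ (5 cm at the default 3 GHz sweep). The phase of a bin's
complex reflection tracks sub-millimeter motion inside that bin through
$\phi(t) = 4\pi\, d(t)/\lambda$, so torso bins carry breathing
(millimeter scale) and leg bins can carry ballistic heartbeat motion
(tens of micrometers) unmasked by breathing. `radarvitals` selects, per
15-second window and per bin, every bin showing breathing and every bin
showing heartbeat, then pools the per-bin rate estimates by the median.
Using all informative bins instead of a single "best" bin is the core
design: the median over several noisy estimates of the same physiological
rate is more accurate and more robust than any individual one.

## Signal path

1. **Range FFT** (cube input): Hanning window along fast time, FFT, keep the
   positive-frequency half; spectra are divided by the window's coherent
   gain so a unit tone has unit magnitude. FFT length equals the fast-time
   sample count (no zero padding); bins are 0-based with center range
   $k \cdot \Delta R$.
2. **Chirp median**: the 12 chirps of a 50 ms frame span only 4.8 ms, far
   below vital-sign time scales, so they are 12 noisy measurements of the
   same state. We take the median per frame — separately over per-chirp
   magnitudes and per-chirp phases, the phases first re-wrapped around their
   circular mean so a frame straddling the $\pm\pi$ branch cut cannot
   corrupt the median. A `first`-chirp mode exists to reproduce
   with/without comparisons. The median of 12 i.i.d. Gaussian phases has
   std $\approx \sqrt{\pi/24}\,\sigma \approx 0.36\,\sigma$, the basis of
   the denoising check in the acceptance suite.
3. **Demodulation**: per-bin phase is `atan2(Im, Re)` unwrapped with
   threshold $\pi$, per bin independently; displacement is
   $d = \phi \lambda / 4\pi$.
4. **Bin restriction**: only bins with centers in 0.4–3 m are analyzed
   (TX/RX crosstalk below 40 cm; multipath beyond 3 m).

## Topological machinery

Both detectors rest on persistence diagrams:

* **Sublevel-set H0** of a 1-D window: a level sweeps upward; each local
  minimum births a component, merges follow the elder rule, and the
  essential component is closed at the global maximum (so every local
  minimum yields exactly one finite pair). Plateaus are processed
  left-to-right; a flat minimum births once. Each oscillation of a periodic
  signal contributes one point whose lifespan is roughly its peak-to-peak
  amplitude — the "one point per breath/beat" reading used by the counting
  criteria below.
* **Vietoris–Rips H0/H1** of the time-delay embedding
  $x(t) \mapsto (x(t), x(t-\tau), x(t-2\tau))$ with $\tau = 10$ samples
  (0.5 s at 20 Hz) and $m = 3$: a periodic window traces a loop, which
  appears as one long-lived H1 class. Scale convention: **distance units**
  (an edge enters at the pairwise distance, i.e. the diameter $2r$ of the
  ball radius $r$), matching common software output; this is documented
  prominently because a factor-2 drift here silently rescales every
  criterion. The Rips H0 essential class is dropped from criteria; "maximal
  H0 value/lifespan" always means the largest *finite* H0 death.
  The engine (Rcpp) computes H0 by Kruskal union-find (deaths = MST edge
  lengths) and H1 by boundary-matrix reduction over bitset columns,
  truncated at the enclosing radius, beyond which the complex is a cone and
  carries no further homology.
* **Diagram spread**: the DBSCAN scale $\varepsilon$ is derived from the
  diagram itself as the largest finite H0 death of a secondary Rips
  filtration on the diagram points — the single-linkage connection scale
  (equivalently the longest MST edge). The plain diameter is available via
  `spread_method = "diameter"` for sensitivity analysis; the connection
  scale is the default because the diameter grows with the outliers we are
  trying to isolate. DBSCAN uses the strict inequality `dist < eps`
  (coincident points always neighbors) — with $\varepsilon$ equal to the
  connection scale, a non-strict comparison would absorb every outlier by
  construction. `min_samples` counts the point itself (sklearn convention).

## Selection criteria

**Breathing** (5 Hz low-pass first) combines two branches:

* *Rips branch*: embed, compute H0/H1, convert to birth–lifespan, run
  DBSCAN (`minSamp = 2`, lone-outlier search) on the H1 points. An outlier
  is breathing evidence if (birth close to the maximal finite H0 death
  within `birth_proximity_tol = 0.2` relative, **or** birth inside the
  noise cluster's birth range) **and** lifespan at least
  `lifespan_dominance_factor = 2` times the larger of the noise cluster's
  maximal lifespan and the maximal finite H0 death.
* *Sublevel branch*: DBSCAN on the sublevel H0 diagram
  (`minSamp = floor(10 BPM × 15 s / 60) = 2`, $\varepsilon$ = diagram
  spread). The cluster with the highest mean lifespan is the signal
  cluster, the lowest is noise (intermediate clusters are ignored); a
  single cluster means no decision. Criteria: signal point count within the
  physiologic window count band for 10–22 BPM in 15 s — $[3, 6]$, with the
  lower bound rounded *up* (a genuine 10 BPM signal shows at least 2.5
  oscillations per window; rounding down would admit slower-than-band
  phenomena such as the two deepest excursions of a gross-motion burst) —
  and signal median lifespan at least twice the noise cluster's maximum
  **and** at least `signal_amp_fraction = 0.6` of the window's amplitude
  range.
* *Combination*: breathing is declared if both branches agree, or one
  branch passes all its criteria tightened uniformly by
  `strict_factor = 1.5`.

**Heartbeat** (0.65–5 Hz band-pass first) uses only the sublevel branch
with `minSamp = floor(40 × 15/60) = 10`, count band $[10, 50]$ (40–200 BPM),
and an empirical $\varepsilon$ = `heartbeat_eps_fraction = 0.15` of the
window's amplitude range — the data-driven spread is unreliable here
because band-passed windows have no clean two-cluster geometry.

All thresholds live in `selection_criteria()` so a sensitivity analysis is
a loop over configurations (`radarvitals sensitivity`).

### Where the numeric defaults come from

The bands, minSamp rates, $\tau$, $m$, window geometry and bin restriction
are published values. The remaining thresholds are package defaults chosen
once on labeled desk fixtures *before* the acceptance run: 0.2 / 2.0 / 1.5
follow the suggested starting points; `heartbeat_eps_fraction` was moved
from a suggested 0.1 to 0.15 because at 0.1 the beat cluster fails to form
in roughly 15% of clean pulse windows (single-linkage chains break), while
0.15 detects ~97% of clean pulse trains with no white-noise false positives
across probe seeds; `signal_amp_fraction = 0.6` is the observed separation
point between band-passed white noise (signal-cluster median lifespan
$\lesssim 0.65 \times$ range) and pulse trains ($\gtrsim 0.59$, almost
always $> 0.7$). The minSamp rates are interpreted per window
(`minsamp_mode = "per_window"`); the literal-count reading is switchable.

## Epoching and rates

Selection runs on 15 s windows stepping 5 s. For every run of 10
consecutive windows, a bin selected at least 7 times is selected in the
corresponding 60 s rate window ($(10-1)\cdot 5 + 15 = 60$); the 60 s
windows advance on the same 5 s grid. Runs crossing the recording end are
skipped.

Rates per 60 s window and selected bin: breathing by the highest
autocorrelation peak over lags in the 10–22 BPM period band (parabolic lag
refinement; undefined below a 0.3 correlation floor); heartbeat by peak
finding with a 0.3 s refractory period after amplitude normalization — the
published normalization is cited but not specified, so the package uses a
documented stand-in (division by the smoothed analytic-signal envelope,
which equalizes beat amplitudes) behind a replaceable interface. The window
rate is the median over bins; `*_single` columns carry the
highest-autocorrelation single-bin rate for baseline comparisons. Reference
rates: belt windows use the same autocorrelation estimator; ECG uses an
undecimated (à trous) Symlet-4 SWT, summing squared detail coefficients of
the levels covering ~10–25 Hz, peak finding with the same refractory rule,
and $60/\mathrm{median}(\text{interval})$. Agreement is summarized by MAE,
MAPE, the share of windows within ±1 BPM, and Bland–Altman mean difference
(reference − radar) with $\pm 1.96$ SD limits.

## Artifact metrics

Per 15 s window, on magnitudes over restricted bins: the 90th percentile
(linear interpolation between order statistics) of per-bin standard
deviations, and per-bin moment skewness / *excess* kurtosis averaged over
bins (zero-variance bins excluded). Excess kurtosis is the deliberate
convention: with Pearson kurtosis the normal distribution itself sits at 3
and the $|\kappa| > 3$ exceedance flag would be vacuous; a switch restores
the Pearson reading. Windows are grouped by "no bin selected" vs "at least
one bin selected" and each group reports std quartiles and the share of
windows with $|$skew$| > 1$ and $|$kurt$| > 3$.

## The synthetic world

The study's recordings are private, so validation runs on a simulator that
emulates the statistical structure the selection algorithm assumes — and
states its world once:

* **Breathing**: sinusoid + 2nd/3rd harmonics (20%/10%) at 11–18 BPM with
  slow sinusoidal drift, amplitudes 0.6–1.2 mm across eight torso bins
  (2.0–2.35 m), and 20% breath-to-breath depth variability (a smooth
  multiplicative envelope). The variability matters: real tidal volumes are
  not phase-locked, and it is exactly this irregularity that lets the
  amplitude-range-based heartbeat criteria reject breathing-harmonic
  leakage on torso bins.
* **Heartbeat**: Gaussian-windowed pulse trains (σ = 50 ms) at 55–80 BPM
  with 5% per-beat amplitude jitter, amplitudes 30–60 µm across five leg
  bins (0.6–0.8 m) — heterogeneous on purpose, since the benefit of median
  pooling only exists when bins differ in quality.
* **Noise**: i.i.d. complex Gaussian per sample, default σ = 0.02 per
  component at unit reflectivity (≈ 8 µm phase-equivalent displacement
  noise at 60 GHz, conservative against the micrometer phase accuracy
  reported for such sensors). All other restricted bins hold weak static
  clutter so their phase behaves like measurement noise.
* **Artifacts**: ~10 s whole-body posture shifts (one per 6 minutes of
  scene), modeled as Hann-windowed broadband bursts — a slow random-walk
  component plus dominant white displacement jitter, 8 mm scale — across
  *all* restricted bins, with accompanying amplitude modulation (gross
  motion changes radar cross-sections). Three earlier burst models failed
  to produce the phenomenon the artifact metrics measure: band-limited
  bursts left distant torso bins selectable, short bursts honestly leave
  most of a 15 s window full of detectable breathing, and smooth
  random-walk bursts are literally two giant breath-like swings that pass
  the breathing criteria. Jerky whole-body motion is both the realistic
  reading and the one that empties artifact windows.
* Two fidelity levels: `matrix` emits the complex range–time matrix
  directly (fast; unit tests), `cube` emits fast-time samples and runs the
  range FFT (exercises the full front end). Within a frame all 12 chirps
  share one displacement value (the frame spans 4.8 ms) with independent
  noise. A fixed seed makes every output bit-identical.

What a green test does *not* establish: the simulator has no
electromagnetic multipath, antenna patterns, I/Q imbalance, posture-
dependent geometry, or real inter-subject variability; clean-scene
sensitivities here are upper bounds on real-data behavior, and the
agreement numbers are not comparable to overnight-recording results.

## Numerical choices and degenerate inputs

* Filters: zero-phase (forward–backward) 4th-order Butterworth via bilinear
  transform, band-pass as high-pass/low-pass cascade, odd-reflection
  padding scaled to the lowest cutoff. (No signal-processing package is
  assumed; design and application are self-contained.)
* Sublevel ties: equal values are processed left-to-right; the left of two
  equal minima is the elder.
* Rips point budget: windows are farthest-point subsampled to
  `vr_max_points = 80` before the H1 filtration (the subsampling route to
  affordability); oracle tests run unsubsampled. Clouds above 10⁴ points
  are rejected outright.
* Degenerate windows (constant series, too-short series, diagrams with
  fewer than two points or clusters) yield "not selected" with a recorded
  reason rather than an error; pipeline errors per bin-window degrade to
  non-selection.
* Rate definedness floors (correlation ≥ 0.3, at least half the minimum
  physiologic beat count) are package defaults, config-exposed.
* The recording container is a plain-text layout (JSON header + CSV
  matrices) rather than HDF5 — no HDF5 binding is available in the target
  R stack; the layout is documented in `write_recording()`.

## Known limitations

* The heartbeat interval estimator quantizes peak positions to the 20 Hz
  frame grid; at 70 BPM this bounds single-window accuracy near ±1 BPM
  (visible as the ~1 BPM heart-rate MAE on clean scenes).
* The amplitude normalization before heartbeat peak finding (division by
  the smoothed analytic-signal envelope) is validated by parameter
  recovery, not by equivalence to any particular published equalization
  scheme; it sits behind a replaceable interface.
* The strict-criteria construction ("stricter versions") is a uniform
  threshold multiplication; other tightenings are conceivable.
* Breathing-harmonic rejection in the heartbeat branch relies on breath
  variability; perfectly metronomic breathing with strong harmonics can
  still masquerade as a pulse train.
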