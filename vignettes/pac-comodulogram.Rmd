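---
title: "Gamma phase-amplitude coupling grids: model, surrogates, and the cluster permutation contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma phase-amplitude coupling grids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacgrid)
```

## The measurement problem

Gamma-band activity (30–40 Hz) in resting, non-invasive recordings is far
below the 1/f background and is effectively invisible to ordinary spectral
power estimates. What survives is its *coupling*: in many cortical circuits
the amplitude of the gamma oscillation waxes and wanes with the phase of a
slower theta/alpha rhythm (4–12 Hz), because the slow phase gates the
excitability of the local population. pacgrid quantifies that
phase-amplitude coupling (PAC) per brain region and compares it between two
cohorts.

## The estimator

For one regional time series and one band pair, the package computes

* $\Phi_L(t)$ — the instantaneous phase of the low-frequency band (Hilbert
  phase of the band-passed signal), and
* $A_H(t)$ — the instantaneous amplitude envelope of the gamma band,

and forms the composite signal $Z(t) = A_H(t)\,e^{i\Phi_L(t)}$. Its time
average $M_{raw} = \langle Z(t) \rangle$ is the *mean vector*: with no
coupling, the points $Z(t)$ are circularly symmetric around the origin and
the mean vector shrinks to zero; when the envelope depends on phase, the
cloud is skewed and the mean vector points at the phase of maximal
amplitude.

The raw length $|M_{raw}|$ has units and a bias that depend on the envelope
scale, the recording length, and the marginal distributions of $A_H$ and
$\Phi_L$ alone. It is therefore normalized against time-lag surrogates
$Z(t,\tau) = A_H(t+\tau)\,e^{i\Phi_L(t)}$: lagging the envelope against the
phase destroys any phase-amplitude dependence while leaving both marginals
untouched. With $\mu$ and $\sigma$ the mean and standard deviation of the
surrogate lengths (200 surrogate lags by default),

$$M_{norm} = \frac{|M_{raw}| - \mu}{\sigma},$$

a z-score that is dimensionless, scale-invariant, and *signed* — values
below zero (an observed vector shorter than typical surrogates) are
meaningful and are never clipped. The preferred phase
$\Phi_{norm} = \arg M_{raw}$ is reported in degrees on $[0, 360)$.

Surrogate lags are drawn uniformly from $[\tau_{min}, T - \tau_{min}]$
(default $\tau_{min}$ = 1 s) and applied as circular shifts, which preserve
the envelope's marginal distribution exactly. The lag means for all shifts
are obtained at once through an FFT circular cross-correlation, which is
numerically identical to shifting and averaging directly (a unit test holds
the two routes to within $10^{-10}$).

## The comodulogram grid

The default grid crosses eight 1 Hz phase bins ($[4,5), \dots, [11,12)$ Hz)
with ten 1 Hz amplitude bins ($[30,31), \dots, [39,40)$ Hz): 80 cells per
subject per region, each carrying $M_{norm}$ and $\Phi_{norm}$.

Two numerical choices here deserve explanation.

**Filtering.** Band-passing uses a zero-phase spectral (FFT-domain) filter
with raised-cosine transitions of 0.25 Hz. Working at 1 Hz granularity
makes the filter's transition width part of the scientific contract: an IIR
design run forward-backward has transitions of the same order as the bins
themselves, so neighbouring bins see substantially overlapping content and
the grid loses its meaning. The spectral filter keeps band edges sharp, is
exactly zero-phase (no phase/envelope misalignment), and merges band-pass
and Hilbert transform into one FFT pair. A 4th-order Butterworth
(`method = "butterworth"`) is available for sensitivity checks. Filter and
Hilbert edge transients are removed by trimming 1 s (configurable) from
each end of the phase and envelope series before any averaging; the
analytic transform itself always sees the full signal.

**Amplitude bandwidth.** A modulated carrier at $f_A$ whose envelope varies
at $f_P$ has spectral sidebands at $f_A \pm f_P$. An amplitude filter only
1 Hz wide therefore *cannot* carry theta-range modulation: the envelope of
a 1 Hz-wide band is itself band-limited to 1 Hz and cannot oscillate at
6 Hz. The grid's 1 Hz amplitude bins are labels for where the gamma carrier
lives, not viable filter bandwidths for detecting theta-gamma coupling.
`amp_band_expand` controls the actual filter band: `0` (the default)
filters the literal bin, and `"match"` widens each amplitude band by the
centre frequency of the phase bin it is paired with — the standard
"amplitude bandwidth of at least twice the phase frequency" rule. All
coupling-recovery and group-contrast analyses in this package's tests use
`"match"`; the literal bins remain available for structural checks and for
studying exactly this sensitivity question.

Each cell's surrogate stream is seeded by a stable hash of
(seed, subject, region, phase bin, amplitude bin), so any single cell can
be recomputed in isolation, bit-identically, in any evaluation order.

## Group comparison

Per region, cohorts are compared cell-wise with equal-variance two-sample
t-tests ($df = n_A + n_B - 2$; group A minus group B). Cells with
two-sided $p <$ 0.05 (the cluster-forming threshold) are grouped into
connected components of equal sign under 4-neighbour adjacency — one step
along the phase axis or the amplitude axis; diagonals do not connect
(8-connectivity is available). A cluster's mass is the signed sum of its
member t-values.

Family-wise error over the 80 cells is controlled by a max-statistic
permutation test: group labels are reassigned at the whole-subject level
(preserving group sizes and the within-subject correlation structure of the
grid), the t-map and clusters are recomputed, and the null statistic of
each permutation is its maximum absolute cluster mass (0 when nothing
crosses the threshold). With 1024 permutations by default, an observed
cluster's p-value is $(1 + \#\{\text{null} \ge |mass|\}) / (1 + n_{perm})$
— never exactly zero. Pooling both signs into one max-|mass| null controls
error across both directions of effect.

Phase is summarised over the cells of significant clusters: for each
subject the complex $M_{raw}$ values of those cells are averaged and the
angle of the resultant is taken (averaging complex values, never angles, so
wraparound is handled correctly; by default the raw complex values are
averaged, `normalize = TRUE` weights all cells equally). Group preferred
phases are compared with an unpaired equal-variance t-test on the
per-subject angles in degrees, with each group's circular mean reported
alongside. A linear test on wrapped angles is the reference behaviour;
note the hazard that two angle samples straddling 0°/360° can appear far
apart linearly while being circularly close — the circular means printed
next to the test make such cases visible.

## The synthetic cohort generator

No public regional MEG time series accompany the analyses this package is
designed for, so validation runs on synthetic cohorts with known ground
truth. One signal is

$$x(t) = A_L \cos\theta(t) + A_H\,
  \frac{1 + \kappa\cos(\theta(t) - \phi_{pref})}{1+\kappa}\,
  \cos(2\pi f_A t + \psi_0) + \varepsilon(t),$$

where $\theta(t)$ is the low-frequency phase, $\kappa \ge 0$ the coupling
depth, $\phi_{pref}$ the preferred phase, and $\varepsilon$ Gaussian
$1/f^{\alpha}$ noise synthesized by spectral shaping. The cosine modulation
kernel was chosen over a von Mises kernel for its closed-form envelope,
which makes test oracles analytic: at $\kappa = 0$ the envelope is constant
and independent of phase; the gamma envelope peaks exactly at
$\theta = \phi_{pref}$; and $\arg M_{raw} \to \phi_{pref}$.

**Stochastic phase.** $\theta(t)$ is the Hilbert phase of a narrowband
Gaussian process centred on $f_P$ (default bandwidth 0.8 Hz), not a
deterministic sinusoid. This is deliberate and load-bearing: for a strictly
periodic oscillation, lagging the envelope against the phase merely
*rotates* the mean vector without shortening it, so time-lag surrogates
would not destroy the coupling they are meant to null out, and the
estimator could never separate real coupling from its surrogate
distribution. Resting-field oscillations drift in phase, which is exactly
the property the surrogate construction relies on; the generator reproduces
it with a phase-coherence time of roughly 1/bandwidth ≈ 1 s.
`lf_bandwidth = 0` recovers the deterministic sinusoid for filter-level
tests.

**Default levels.** `lf_amplitude = 1`, `hf_amplitude = 0.25`,
`noise_sd = 0.8`, `noise_exponent = 1` mirror the salient features of
resting M/EEG: a prominent theta/alpha rhythm, gamma far below the 1/f
background, and an overall 1/f spectrum. The gamma-to-noise ratio matters
for more than realism: when the gamma tone dominates its analysis band, the
surrogate spread is itself set by the modulation and $M_{norm}$ saturates
at a ceiling fixed by the number of independent phase epochs, flattening
the comodulogram across amplitude bins. At the default levels the surrogate
spread is noise-dominated and $M_{norm}$ tracks the modulation actually
captured by each filter band, which is what localizes the coupled cell.
These defaults were frozen from a design study of that operating regime and
are not tuned per analysis.

Cohorts attach per-subject random phase offsets ($\psi_0$, and the LF
process itself) so that group phase statistics are exercised nontrivially.
Per-signal seeds derive from (cohort seed, subject, region) by the same
stable hash as the grid cells; the same spec and seed reproduce a cohort
bit-identically across sessions.

**What the generator does not emulate.** Real source-reconstructed MEG has
waveform asymmetries (which can produce spurious PAC), inter-regional
leakage, artefacts, non-stationary noise levels, and coupling that drifts
over a recording. Passing the package's tests shows the estimator and the
inference machinery behave correctly under a clean, controllable signal
model — it does not certify robustness to those real-data complications.

## Problem sizes and tunables

| parameter | default | meaning |
|---|---|---|
| `fs` | 600 Hz (generator) | acquisition-matched sampling rate; analyses in tests run at 200 Hz, comfortably above Nyquist for 40 Hz |
| `duration` | 60 s | one resting epoch |
| `n_surrogates` | 200 | surrogate lags per cell |
| `min_lag` | 1 s | shortest surrogate lag; beyond the LF phase-coherence time |
| `trim` | 1 s | edge trim before averaging |
| `transition` | 0.25 Hz | spectral filter transition width |
| `amp_band_expand` | 0 | amplitude filter widening; `"match"` for coupling detection |
| `cluster_alpha` | 0.05 | cluster-forming per-cell threshold (two-sided) |
| `n_perm` | 1024 | permutations; tests use 200 for speed |
| `alpha` | 0.05 | family-wise significance level |

The validation suite scales the study design down to run in minutes on one
CPU: 200 Hz sampling, 20 s signals and 50 surrogates for null calibration
and power runs, 60 s signals and 200 surrogates for single-cell recovery
checks, 200 permutations, and exchangeable iid-normal subject maps for the
100-replicate family-wise-error calibration (the estimator-level null is
covered separately by the uncoupled-signal simulations). These sizes are
the package's validation choices; the defaults above remain the
recommendation for real analyses.

## Degenerate inputs and edge behaviour

* A constant (or zero) envelope makes every surrogate identical; the
  resulting `sigma = 0` raises an explicit degenerate-surrogate error with
  the offending cell's coordinates rather than returning an infinite
  z-score.
* Signals shorter than 10 s are rejected: too few low-frequency cycles for
  a stable mean vector.
* Band edges at or above Nyquist, misaligned sub-grid ranges, non-finite
  samples, and group sizes below 2 are rejected with informative errors.
* Angles are reported on the half-open $[0, 360)$; the floating-point
  wrap at exactly 360 folds to 0.

## A worked contrast

```{r example, eval = FALSE}
spec <- cohort_spec(
  n_group_a = 15, n_group_b = 15, regions = "left_parahippocampal",
  coupling_a = coupling_spec(kappa = 0.8, preferred_phase = pi / 2),
  coupling_b = coupling_spec(kappa = 0.2, preferred_phase = pi / 2),
  fs = 200, duration = 20, seed = 1
)
grids <- generate_cohort(spec) |>
  compute_cohort_grids(grid_spec(n_surrogates = 50,
                                 amp_band_expand = "match", seed = 1))
test <- permutation_cluster_test(grids, "A", "B", n_perm = 200, seed = 2)
tidy(test)
autoplot(test)

angles <- subject_mean_phase(grids, significant_cells(test))
phase_angle_contrast(angles$angle_deg[angles$group == "A"],
                     angles$angle_deg[angles$group == "B"])
```

## Known limitations

* The mean-vector-length index is the only estimator provided; KL-based
  modulation indices, GLM-PAC and phase-locking alternatives are out of
  scope, as is any correction for waveform-shape artefacts.
* Static, resting-state grids only; no event-related or time-resolved PAC.
* The phase contrast is a linear t-test on wrapped degrees (the reference
  behaviour for this pipeline); it loses power or misleads when group
  angle distributions straddle the wrap point.
* Regions are tested independently; no cross-region multiplicity
  correction is applied.
* Grid cells are computed serially; the per-cell hash seeding makes the
  computation embarrassingly parallel if a caller wants to distribute it.
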