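---
title: "Models and methods behind eegfmri"
author: "eegfmri authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eegfmri}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfmri)
```

# The problem

Scalp EEG resolves neural events at the millisecond scale but localises
them poorly; BOLD fMRI localises at the millimetre scale but observes
neural activity only through the slow hemodynamic response function
(HRF). Simultaneous EEG–fMRI recordings — the workhorse design in
epilepsy research, where interictal discharges visible in the EEG must
be traced to their hemodynamic correlates — therefore need an analysis
chain that (i) conditions the 4D BOLD series, (ii) summarises
resting-state activity voxelwise, (iii) extracts scalar features from
the EEG, and (iv) fuses the two modalities statistically. `eegfmri`
implements that chain as a scriptable library with a thin command-line
driver, together with seeded generators that produce every input with
known ground truth.

# BOLD conditioning

**Nuisance regression.** Confounds are removed per voxel by ordinary
least squares. Motion confounds follow the standard expansions of the
six rigid-body series $R = [X, Y, Z, \mathrm{pitch}, \mathrm{yaw},
\mathrm{roll}]$: 6 ($R$), 12 ($[R, \dot R]$ with the backward
difference and first row zero), 24 ($[R, R^2, R_{t-1}, R^2_{t-1}]$) and
36 (adding the lag-2 blocks). Lagged blocks are zero-padded at the
start; replicating the first row was rejected because zero-padding
makes the columns exactly testable against a shift oracle. Tissue
means, a centred linear trend, and an optional global-signal regressor
(off by default — its use is contentious) can be appended. The voxel's
temporal mean is added back to the residual so later grand-mean scaling
remains meaningful. Rank-deficient designs fall back to the
pseudoinverse with a warning naming the dependent columns.

**Ideal bandpass.** The resting-state filter (default 0.01–0.08 Hz)
zeroes DFT coefficients outside the closed band; DC is removed unless
the low edge is 0. Being a projection it is exactly idempotent, and
disjoint bands partition the demeaned signal's energy — both properties
are tested. For volumes, the voxel mean is re-added after filtering by
default. The resting-state path applies nuisance regression first, then
the bandpass; both orders are reachable through the library since the
two steps are separate functions.

**Drift.** For the GLM path, low-frequency drift is modelled as
unit-normalised DCT-II columns with period above 128 s (the column
count is $\lfloor 2 T \cdot \mathrm{TR} / 128 \rfloor - 1$), kept as
confound columns rather than pre-filtered so degrees of freedom stay
exact. Before model fitting the volume is scaled to grand mean 100
(`data = 100 * data / grand mean`).

# Resting-state measures

**Functional connectivity density.** For threshold $\theta$, a voxel's
global FCD is the number of other in-mask voxels whose Pearson
correlation with it exceeds $\theta$ (strict inequality, self
excluded). Local FCD is the size (minus the seed) of the cluster grown
from the voxel by repeatedly adding voxels that are spatially adjacent
to a current member *and* correlate with the seed above $\theta$;
correlation is seed-anchored, the classic growing-algorithm convention.
Long-range FCD is their difference. Adjacency defaults to the 26-voxel
neighbourhood (the full 27-voxel cube), with 6 and 18 available. Each
map is divided by its in-mask mean; zero-variance voxels get measure 0,
a warning, and are excluded from that denominator. Sliding-window
dynamics recompute the static measure on windows starting at $0, s, 2s,
\dots$ (default window 40 TRs, step 1 — the literature's common
choices; window count $\lfloor (T - w)/s \rfloor + 1$). The
implementation is verified *exactly* (integer equality) against an
independent brute-force oracle — full correlation matrix plus
morphological dilation — on dozens of seeded volumes.

**Spatio-temporal consistency (FOCA).** Over each voxel's 27-voxel cube
intersected with the mask (at least 9 members), temporal consistency
$t_i$ is the mean pairwise correlation of the member time series and
spatial consistency $s_i$ is the mean correlation between the
neighbourhood's spatial patterns at consecutive time points. The
default combiner is the rectified product $\max(0, t_i)\max(0, s_i)$,
which keeps the published $[0, 1]$ range; it is pluggable because the
exact published combination lives outside the sources this package was
built from, so the default is documented as a stand-in. Degenerate
neighbourhoods (too small, or containing a zero-variance series or
pattern) are flagged to 0 and excluded from the normalisation mean.

**Dynamic-series indices.** A series $v_t$ of measures is summarised by
mean, sample SD, coefficient of variation $\mathrm{sd}/\mathrm{mean}$,
mean point-by-point change $\mathrm{mean}_t\,|1 - v_t/v_{t-1}|$ and
mean relative ratio $\mathrm{mean}_t\, v_t/v_{t-1}$; ratio indices are
flagged NA when a predecessor is zero, the moments are still returned.

# EEG conditioning and features

Re-referencing subtracts the per-sample mean of all channels (average
reference) or of a named channel set; it is idempotent and invariant to
common offsets. Filtering is zero-phase: a windowed-sinc FIR of order
about $3 \cdot \mathrm{srate}/f_\mathrm{edge}$ (forced even) applied
forward–backward, or the exact Fourier mask. Events can be added and
deleted programmatically; bad blocks are half-open $[s, e)$ intervals
that *clip* features but never shift time, so downstream regressors
keep absolute alignment.

Three feature families feed the fusion models: event **onsets** (unit
values, bad-block events dropped on request); windowed **band power**
using the one-sided convention $p_k = 2|Y_k|^2/L$ with DC and Nyquist
bins undoubled — under it a sinusoid of amplitude $A$ at a bin
frequency yields band power $A^2 L / 2$, and disjoint bands sum to the
total one-sided power; and **ERP amplitudes** (baseline-corrected mean
or signed extremum in a measurement window; both offered since sources
differ, default baseline $[-200, 0]$ ms). Setting window = step = TR
locks a power series to the fMRI grid, one value per volume, with
bad-block windows flagged NA and later linearly interpolated — never
zero-filled, because zero is a meaningful power.

# HRF models and EEG-informed GLMs

Three kernel families, each sampled on $[0, 32]$ s and scaled to peak
magnitude 1: a single gamma with unit scale and shape $\mathrm{peak} +
1$ (so peak latency is its only free parameter), the canonical
double-gamma (delays 6/16 s, dispersions 1, undershoot ratio 1/6), and
Glover's two-gamma fit. Features are painted onto a microtime grid of
16 bins per TR (onsets with fractional-bin weight splitting so the
regressor converges as the grid is refined), convolved, and read out at
each volume's first bin — volume-start sampling, configurable, since
the slice-reference convention is a scanner-specific choice.

**GLM1** is voxelwise OLS with $t = c^\top\hat\beta /
\sqrt{\hat\sigma^2 c^\top (X^\top X)^{-1} c}$ and F tests by extra sum
of squares. **GLM2**, the epilepsy-oriented variant, fits one
single-gamma regressor per peak latency (default 3, 5, 7, 9 s) with
shared confounds and keeps the voxelwise maximal T and the winning
latency; because the implicit maximum over four fits inflates the
statistic, the per-peak maps and a joint F over all four regressors
(against the confound-only model) are also emitted so users can test
conservatively. Null calibration is verified by simulation: at
$\alpha = 0.05$ both the $t$ and the joint $F$ rejection rates over
2000 null voxels fall inside the exact binomial interval.

# Local multimodal serial analysis

A single canonical HRF can misrepresent patients' responses. LMSA
instead estimates the coupling per voxel: the TR-locked EEG feature is
expanded into a lagged matrix (columns = delays of $0..L$ TRs, default
$L = 6$, i.e. 12 s at TR 2 s — covering canonical HRF support), and
canonically correlated with the time series of the voxel's 27-voxel
neighbourhood ($\ge 9$ members, matching FOCA's rule for consistency).
The first canonical pair is computed by SVD of the whitened
cross-product; weights are scaled to unit-variance variates, and
rank-deficient sides are reduced by dropping dependent columns.

Significance of the association is tested through Wilks'
$\Lambda = \prod_i (1 - \rho_i^2)$ using **Rao's F approximation**.
The better-known Bartlett chi-square version of the same statistic was
implemented first and found measurably conservative at this problem's
dimensionality (empirical level ≈ 0.03 at nominal 0.05 for a
$7 \times 27$ system), which would break the package's own calibration
guarantee; Rao's F is uniform under the null in our checks (4000
replicates, KS p ≈ 0.9) and is therefore the gate, at $\alpha = 0.05$.

Where the gate passes, the EEG-side variate $v_i = X_\mathrm{lag} a$
(sign fixed so $\sum a \ge 0$, making estimated HRFs comparable across
voxels) is used to predict the voxel's own series in a regression with
nuisance and intercept; the reported map is the t of the $v_i$
coefficient, zero and flagged elsewhere. The weights $a$ over the lag
grid are the voxel's data-driven HRF estimate. The EEG-side variate is
used (not the fMRI-side) because the subsequent regression estimates
the voxel's activity *from* the EEG prediction; the fMRI-side option
remains available. With lag 0 and a single-voxel neighbourhood the
whole construction collapses to GLM1, and the package tests that the
two t values agree to 1e−8.

Calibration of the voxelwise gate is checked on white-noise volumes
over a mask of disjoint $3^3$ cubes evaluated only at full
neighbourhoods, so the tests are independent and the binomial reference
interval is exact; overlapping neighbourhoods on a solid mask would
correlate adjacent tests and invalidate a binomial comparison without
changing the per-test level.

# The synthetic-data generators

`simulateBold` produces AR(1)-plus-white noise (coefficient 0.3, a
typical single-voxel BOLD autocorrelation at TR 2 s) at a grand-mean
offset of 1000 so intensity masking and grand-mean scaling behave as on
real scanner data; hub clusters share a latent series mixed as
$\sqrt{r}\,z + \sqrt{1-r}\,\varepsilon$ so the expected within-hub
correlation is exactly the target $r$; activations add
$\beta \cdot (\text{onsets} \ast \text{gamma HRF})$. Defaults — 250
volumes at TR 2 s — mirror a standard ~8-minute clinical resting run.
`simulateEEG` produces $1/\sqrt{f}$-tilted background noise,
band-limited oscillations, and biphasic 250 ms spike templates whose
onsets are carried in the event table as type "GSWD". `simulateMotion`
produces smoothed random walks scaled to a chosen excursion.

What the generators do *not* emulate: spatial smoothness of real BOLD
(no point-spread function), physiological noise structure
(cardiac/respiratory cycles), scanner drift beyond AR(1), EEG artifacts
from the magnet (gradient, ballistocardiogram), and volume conduction.
Passing tests therefore demonstrate algorithmic correctness and
statistical calibration under the stated noise model, not end-to-end
performance on clinical recordings.

# Numerical choices and edge cases

- Voxel and time indices are 0-based in all user-facing coordinates and
  seconds-based for events; intervals are half-open.
- The NIfTI header time step is trusted for TR unless the caller
  overrides it (the override always wins; headers are unreliable);
  Analyze-style `.img/.hdr` pairs have no trustworthy TR field and
  require an explicit value.
- EDF signals are quantised to 16 bits over each channel's physical
  range on write; EEG units are normalised to µV on read.
- Strict `r > θ` thresholds; self-connections never counted.
- Zero-variance series: FCD/FOCA flag the voxel to 0 rather than
  propagating NaN; out-of-mask voxels are NA everywhere, never 0,
  because 0 is a valid statistic value.
- Statistic maps store degrees of freedom in a JSON sidecar; per-voxel
  HRFs in a TSV keyed by linear voxel index.
- All pipeline runs write a provenance record (resolved config, package
  version, input checksums) sufficient to re-run bit-identically; runs
  from one seed are byte-deterministic, which the test suite asserts
  end to end.

# Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic
data: FCD oracle equivalence on twenty volumes up to $8^3 \times 80$
across all connectivities and seven thresholds; GLM calibration on 2000
null voxels; peak-latency recovery on 50 seeded runs (SNR 1, 250
volumes); LMSA HRF recovery on 100 seeded runs and null calibration on
five independent white-noise volumes (1080 independent neighbourhood
tests). These sizes give the binomial and recovery checks enough
resolution to be meaningful while keeping a full run in a few minutes
on one core.

# Known limitations

- The FOCA combiner is a documented stand-in; results are comparable
  within this package but not guaranteed to equal other published FOCA
  implementations numerically.
- GLM2's max-T map is reported uncorrected for the maximum over peak
  latencies, as the construction prescribes; use the joint F or
  per-peak maps for conservative inference.
- OLS assumes white residuals: no AR(1) prewhitening is applied, so
  test statistics on strongly autocorrelated data are approximate
  (bandpassed resting data especially).
- LMSA supports a single scalar EEG feature; matrix-valued features and
  higher canonical pairs are out of scope.
- EEG readers cover EDF(+) and BrainVision; other vendor formats need
  conversion upstream.
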