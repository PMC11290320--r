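---
title: "Methods: functional map, coupling and arrest-behavior analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional map, coupling and arrest-behavior analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collimap)
```

collimap implements the computational analyses used to study how astroglial
gap-junction networks shape visual function in the mouse superior colliculus
(SC): Fourier-based retinotopic and orientation preference mapping from
periodic-stimulation intrinsic optical imaging, cross-animal map registration
with pixel-wise reproducibility statistics, spatial geometry of dye-coupled
astrocyte networks, and quantification of the light-induced locomotor arrest
reflex. This vignette describes the underlying models, the parameters that
matter, and the design decisions taken where the methodology left choices
open.

## Periodic-stimulation imaging model

A periodic stimulus (a bar sweeping across the screen every 8 s, or a grating
rotating at 2 rpm) drives, at every pixel of the camera image, a
hemodynamic response that is phase-locked to the stimulus:

$$x(t) = M \cos(2\pi f t - \Phi) + d(t) + \varepsilon(t),$$

where $f$ is the analysis frequency, $M$ the response magnitude, $\Phi$ the
response phase, $d(t)$ slow drift and $\varepsilon$ noise. The phase encodes
*where* in the stimulus cycle the pixel responds -- i.e. the visual-field
position (retinotopy) or the preferred orientation -- plus a hemodynamic
delay term $2\pi f \delta$ shared by all pixels of a session.

`extract_fourier_component()` computes the complex demodulate
$C = (2/N)\sum_n x_n e^{-i 2\pi f t_n}$ over the largest integer number of
stimulus cycles and returns $M = |C|$, $\Phi = -\arg C \bmod 2\pi$. Exact
demodulation at $f$ (rather than the nearest FFT bin) avoids spectral leakage
at awkward frequencies such as 1/15 Hz; restriction to integer cycles makes
the estimate unbiased for pure tones. Linearity, time-shift covariance and
magnitude invariance under phase are enforced by tests at the 1e-10 level.

`remove_slow_components()` removes signal unrelated to the stimulation before
demodulation: the temporal mean, a least-squares line, and a centered moving
average whose window is exactly one stimulation period. A one-period boxcar
contains no power at $f$, so its subtraction leaves the stimulus-locked
component untouched (preserved within 1% in tests) while suppressing drift
below $f/2$ by more than 20 dB on the drift model used by the generator.
Windows that would run past the movie are replaced by the nearest full-length
window so that every subtracted value remains a full-period mean. This
detrending fulfils the role of the generalized-indicator-function
preprocessing used with such recordings; since the downstream quantity is the
single-frequency component, any method honoring the contract above is
interchangeable, and a covariance-based variant could be added behind the
same interface.

## Retinotopy from opposite sweep directions

For two sessions with opposite sweep directions,
$\Phi_\text{fwd} = \phi_\text{pos} + 2\pi f \delta$ and
$\Phi_\text{rev} = -\phi_\text{pos} + 2\pi f \delta$ (mod $2\pi$), with
$\phi_\text{pos} = 2\pi \cdot \text{position}/\text{span}$ linear over the
printed screen spans (110 degrees azimuth, 60 degrees elevation). The
classical estimator -- half the difference of the two phase maps -- is
ambiguous modulo half the span once phases wrap. `retinotopy_from_pair()`
resolves the ambiguity by assuming the hemodynamic delay is below half the
stimulation period (less than 4 s at 1/8 Hz): the per-pixel delay phase is
$((\Phi_\text{fwd}+\Phi_\text{rev}) \bmod 2\pi)/2 \in [0,\pi)$ and the
position is read from the delay-corrected forward phase. This is equivalent
in intent to the half-difference and is validated by round-trip tests against
planted maps (noiseless recovery within 0.5 degrees at every pixel; with
amplitude SNR 3 at the analysis frequency, at least 95% of pixels within 5
degrees at 64 x 64 pixels).

One caveat is inherent to the convention: a delay of exactly 0 (or exactly
half the period) sits on the boundary of the $[0, \pi)$ representative and is
numerically unstable -- floating-point noise can flip the recovered delay
phase by $\pi$ and the position map by half a span. Delays strictly inside
the interval are recovered exactly; the delay-invariance tests therefore
sweep 0.1-3.9 s. Physiological hemodynamic delays (about 1-3 s) are far
from both boundaries.

## Orientation maps

A sine-wave grating is 180-degree periodic, so a rotation at 2 rpm (1/30 Hz)
cycles the stimulus orientation at **twice** the rotation frequency, 1/15 Hz;
that is the orientation analysis frequency
(`orientation_analysis_frequency()`). (Method descriptions sometimes label
this quantity "half the frequency of rotation" while printing 1/15 Hz; the
printed value is the physically consistent one and is what the package
uses.) The anticlockwise and clockwise sessions encode the preferred
orientation $\theta$ with opposite signs,
$\Phi_\pm = 2\pi f \delta \pm 2\theta$. `orientation_from_pair()` estimates
the shared delay phase as the magnitude-weighted circular mean (period
$\pi$) of $((\Phi_+ + \Phi_-) \bmod 2\pi)/2$ over valid pixels, subtracts it
from both maps, and averages the two delay-corrected orientation estimates on
the 180-degree circle. Pixels whose two estimates are antipodal on that
circle have an undefined mean and are flagged invalid rather than guessed.

## Cross-animal registration

Maps of different animals are aligned by a rigid transform (rotation plus
translation) per animal, minimizing the mean circular squared error
$1-\cos\Delta\phi$ summed over the azimuth and elevation phase maps on the
overlap of validity masks. The optimizer is a coarse grid over rotations
(default +/-15 degrees, 0.5-degree steps) with, for each rotation, an exact
FFT cross-correlation search over integer shifts (default +/-20 px) of the
cosine/sine phase fields, followed by local refinement of the angle and
parabolic sub-pixel refinement of the shift. The reference is the first
animal on the first pass and the pixel-wise circular mean of the registered
maps on the second; a pass that would increase the mean objective is
discarded, so the reported objective is non-increasing. Planted transforms
(5 degrees, 3 and -2 px) are recovered within 0.5 degrees and 0.5 px;
registering already-registered maps returns identity transforms.

Orientation sessions share each animal's coordinate frame with its
retinotopy sessions, so `apply_transforms()` reuses the retinotopy-derived
transforms for orientation maps.

## Pixel-wise reproducibility: the Moore-Rayleigh test

At every registered pixel the animals contribute weighted vectors (angle =
map value converted to its angular period, which angle-doubles orientations;
weight = response magnitude). The Moore-Rayleigh statistic replaces the
weights by their ranks $r_i$ (average ranks under ties) and normalizes the
rank-weighted resultant,

$$R^* = \frac{\sqrt{(\sum_i r_i\cos\theta_i)^2 +
(\sum_i r_i\sin\theta_i)^2}}{n^{3/2}}.$$

P-values come from a seeded, cached Monte-Carlo null (default 100,000 draws)
of independent uniform angles carrying the observed rank vector -- the exact
conditional permutation null, which coincides with the textbook "ranks
1..n" null whenever magnitudes are untied and remains exactly calibrated
under ties (e.g. unit weights). A Monte-Carlo null was chosen over printed
critical-value tables to support arbitrary $n$ and exact tie handling;
$p = (1 + \#\{R^*_\text{null} \ge R^*\})/(1 + n_\text{mc}) \in (0, 1]$.
Calibration tests verify the 0.05 level within +/-0.01 on 10,000 null pixels
with 5 animals, Kolmogorov-Smirnov uniformity of null p-values for
$n \in \{3, 5, 8\}$, and power above 0.99 for concentrated phases. Following
the per-pixel $p < 0.05$ convention, no multiple-testing correction is
applied (the threshold is configurable). Whether per-animal phases should be
centered before testing, and whether the weights should be the demodulated
magnitudes, are open choices; the defaults (no centering; demodulated
magnitudes) are exposed through the data handed to the test.

Selective domains are the significant pixels within the structure border --
itself the largest connected component of pixels whose average magnitude
exceeds half the maximum, morphologically closed -- expressed as a fraction
and as mm^2 via the 10.5 um/pixel camera pitch. Visual-field coverage bins
the averaged (azimuth, elevation) coordinates of pixels significant for both
axes into 5 x 5-degree cells.

## Dye-coupling geometry

Slice coordinates are micrometers, x medio-lateral, y increasing ventrally.
The direction frame at an injection is built from the surface polyline: the
dorsal axis points from the injection site toward its foot point on the
surface (i.e. toward the SC surface), and the medio-lateral axis is the
surface tangent, signed by a hemisphere flag since left/right cannot be
inferred from a slice image. Extents are statistics of the positive
projections of cell offsets on each axis; both the median (network spread)
and the maximum (maximal extent) are provided because both appear in
published quantifications. The isotropy ratio $a/(a+b)$ defaults to
dorsal vs lateral (the comparison used for the text's small-network isotropy
statement); figure legends elsewhere compare ventral vs medio-lateral, so the
directions are parameters. Extent-versus-depth relationships use ordinary
least squares with $R^2$, $F(1, n-2)$ and a two-sided p-value; group-level
hypothesis tests beyond these summaries are left to standard tools.

The synthetic generator draws cells from a bivariate Gaussian centered at
the injection site, rejection-truncated at the surface polyline. Deep
isotropic networks give a mean dorsal/lateral ratio of 0.5 (tested within
+/-0.02 over 200 networks); shallow injections truncate the dorsal direction,
reproducing the depth-limited dorsal extent relationship qualitatively
($R^2 \to 1$ across a depth sweep).

## Arrest behavior

Pose tables carry snout, barycenter and tail-base coordinates at 25
frames/s. Cleaning removes frames with likelihood below 0.9, bridges gaps up
to 0.5 s by linear interpolation (longer gaps stay missing), and smooths
positions with a 5-frame centered moving average. Speed is the Euclidean
norm of Savitzky-Golay first derivatives; window 7 and order 2 are defaults
chosen to suppress frame-to-frame jitter while keeping the 1-s analysis
windows sharp (the filter is exact for uniform motion), and both are
configurable since the original description fixes neither. The barycenter is
the analysis body part.

Around the first flash, $V_\text{baseline}$ is the mean speed over
$[t-1, t)$ s and $V_\text{arrest}$ over $[t+1, t+4)$ s; the speed-modulation
index is $(V_\text{baseline}-V_\text{arrest})/V_\text{baseline}$ -- 1 for a
full stop, 0 for no change, negative (unclipped) if the animal accelerates.
A trial whose baseline speed is below 2 cm/s (the animal was not "in
motion"; the threshold is a package default since no number is published) is
*rejected* with a distinct condition class rather than treated as an error.
The index is scale-invariant, so the px-to-cm conversion (from the 30 cm
arena) only matters for the inclusion threshold.

The trajectory generator moves the animal along a circular path inside the
arena at constant speed, drops the speed by the planted `arrest_fraction`
from 1 s after the flash onward, and by default keeps it dropped to the end
of the recording -- so the measurement window sits strictly inside the
arrest and only the leading edge of the speed step is smoothed by the
filters. Planted fractions are recovered within 0.02 noiselessly and within
0.1 in the mean over 50 noisy, dropout-afflicted trials.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure the analyses assume*:
stimulus-locked sinusoidal responses with a shared hemodynamic delay
(optionally passed through a gamma kernel, shape 4, scale 0.6 s, off by
default since the analysis only measures the single-frequency component),
slow drift (linear trend plus a 0.005 Hz sinusoid), additive Gaussian noise,
truncated Gaussian cell clouds, and speed steps with pose-estimation
dropouts (likelihoods uniform on [0, 0.9) for dropouts, [0.95, 1] for valid
frames). They do **not** model vascular artifacts, eye movements,
photobleaching, biophysical hemodynamics, or real pose-estimation failure
modes, so passing recovery tests demonstrates correctness of the analysis
chain, not robustness to every artifact of real recordings.

Signal-to-noise is parameterized as the time-domain amplitude ratio between
the stimulus-locked component and the noise standard deviation
(`noise_sd_for_snr()`); default nuisance levels (noise 0.3, drift 1.0 for
unit magnitude) represent a mid-quality recording. The camera acquisition
rate is not a stimulation constant and is exposed as a parameter; the
desk-scale defaults are 64 x 64 pixels at 5 Hz, with the full-scale
10.5 um/pixel pitch kept in the configuration for area conversions. Unit
tests run smaller grids and shorter sessions (16 x 16, 6 sweeps, 2
rotations) -- the estimators are per-pixel, so grid size affects only
runtime, and session length only the noise bandwidth.

## Numerical choices and degenerate inputs

* Phases are wrapped to $[0, 2\pi)$; positions to $[0, \text{span}]$ with the
  two endpoints identified (the generator keeps planted maps off the seam).
* Movies whose duration is not an integer number of analysis cycles are
  truncated to the largest integer-cycle prefix, with a message.
* Circular means with (numerically) vanishing resultants return `NaN` with a
  warning instead of an arbitrary angle; averaged-map pixels with antipodal
  contributions are flagged invalid; pixels with fewer than two contributing
  animals are invalid.
* Rank ties in the Moore-Rayleigh weights get average ranks, and the null is
  conditioned on the observed rank vector, keeping the test exact.
* An all-zero magnitude image yields an empty border mask with a warning.
* Registration masks are kept crisp: a resampled pixel is valid only when
  interpolated entirely from valid pixels, which costs a one-pixel rim per
  sub-pixel shift.

## Limitations

Registration searches rigid transforms only (no scaling or shear, matching
the fixed-magnification imaging geometry) over a bounded range (+/-15
degrees, +/-20 px). The reproducibility test treats pixels independently.
The coupling frame assumes a locally smooth, x-monotone surface polyline.
All acceptance-level numbers are computed on synthetic cohorts at desk
scale; headline biological effect sizes (e.g. coupled-cell counts of
specific genotypes) depend on unreleased experimental data and are outside
what synthetic recovery can establish.
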