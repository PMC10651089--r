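---
title: "Automated PSF analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated PSF analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psfqc)
```

## The measurement problem

A z-stack of a sub-resolution fluorescent bead is, to good approximation, an
image of the microscope's point spread function (PSF). Its lateral and axial
full width at half maximum (FWHM) quantify the instrument's resolution, and
their variation across the field of view reveals field-dependent aberrations.
Existing analysis tools require the user to set thresholds, box sizes and
pixel dimensions by hand; mis-set values silently bias the widths. `psfqc`
runs the whole chain — detection, thresholding, fitting, unit conversion,
reporting — without a single user-tuned parameter.

## Detection model

**Multi-scale representation.** The stack is blurred with isotropic Gaussian
kernels of increasing width $\sigma \in \{1, \sqrt2, 2, 2\sqrt2, 4, 4\sqrt2,
8, 8\sqrt2, 16\}$ pixels (`psf_scales()`), a geometric ladder with the
standard octave-subdivision ratio $\sqrt2$. Differences between copies
adjacent in kernel size act as a band-pass filter (difference of Gaussians,
DOG). For a fixed scale ratio $k$, $G_{k\sigma} - G_\sigma \approx
(k-1)\,\sigma^2 \nabla^2 G_\sigma$: the adjacent-scale DOG is already
proportional to the scale-normalised Laplacian, so the raw difference values
are comparable across scales and no extra normalisation factor is applied.
The **characteristic feature size** is reported as the geometric mean of the
scale pair holding the globally largest DOG value; for a Gaussian blob this
sits at roughly $0.8\times$ the blob sigma, within one ladder step, and it
seeds the fit initialisation, where only the order of magnitude matters.

The blurs are computed in the frequency domain with a Gaussian transfer
function and periodic boundaries. The transfer function is exactly one at
zero frequency, so each blurred copy conserves the total image intensity to
machine precision — the defining invariant of the representation. Periodic
wrap-around is harmless for bead fields, which sit on a uniform background.
Scales whose kernel support ($2\sigma$) exceeds the smallest stack dimension
are dropped rather than rejected outright; shallow experimental stacks
(often 15 planes) would otherwise be unanalysable. At least two usable
scales must remain.

**Thresholding.** The DOG maximum projection (over the scale axis) is
thresholded by Li's minimum cross-entropy criterion, implemented as the
fixed-point iteration
$t \leftarrow (\mu_{\le t} - \mu_{>t}) / (\ln\mu_{\le t} - \ln\mu_{>t})$
on the two class means, started from the global mean and iterated to a
relative update of $10^{-6}$ of the intensity range. The tests verify the
fixed point against exhaustive minimisation of the cross-entropy objective;
when the two intensity classes are separated by an empty gap the objective is
flat across the gap and any threshold inside it yields the same segmentation.

**Local maxima.** Candidate features are voxels that are maxima over their
full 26-neighbourhood and above threshold. On plateaus of equal values the
first voxel in (z, y, x) scan order wins, a deterministic tie-break. The list
is sorted by response and truncated to the 200 strongest, the design limit of
the report. Finally, any two peaks closer than 5 px in the lateral plane are
both removed: neither could be fitted cleanly inside its circular patch. Note
one consequence: two features at the same (y, x) separated axially are
detected as two 3D maxima, but the lateral exclusion rule then removes both —
their axial profiles through the shared column would each contain two lobes,
so no trustworthy axial width exists for either.

## Fitting model

A circular region of radius 5 px is cut from the peak's z-plane; pixels whose
centre lies beyond $r + 0.5$ px are masked, leaving 97 of the 11×11 pixels
(the +0.5 counts pixels whose area overlaps the circle). The lateral model is
a rotated elliptical Gaussian with offset,

$$I(u,v) = \text{offset} + A\exp\!\left(-\frac{u^2}{2\sigma_a^2}
  -\frac{v^2}{2\sigma_b^2}\right),$$

with $(u, v)$ the patch coordinates rotated by $\theta$; the axial model is a
1D Gaussian over the full z-profile through the peak column (a single column,
not a lateral average — the simplest reading of the axial distribution around
a feature). Both are solved by Levenberg–Marquardt (`minpack.lm::nls.lm`).
Initialisation: offset = median of the patch's outer rim, amplitude = peak
minus that median, centre = the detected voxel, sigmas = the characteristic
scale. Results are canonicalised so $\sigma_{major} \ge \sigma_{minor}$ with
$\theta \in (-\pi/2, \pi/2]$ the major-axis orientation.

Sigma bounds are $[0.5\ \text{px},\ \max(r, 3\,\sigma_{init})]$. The lower
bound stops collapse onto single hot pixels. The upper bound deliberately
exceeds the patch radius: on heavily oversampled data (10 nm pixels, true
lateral sigma ≈ 11.6 px) the patch samples only the top of the blob, which
still determines the width of an exactly-matching model, and clamping at the
radius would make such data unanalysable. A fit that converges onto any bound
is reported `fit_failed`, as is non-convergence; failed fits are counted and
excluded from averages, never imputed. $R^2 = 1 - SS_{res}/SS_{tot}$ uses the
unmasked pixels only, with $SS_{tot}$ about the patch mean.

**Units.** FWHM $= 2\sqrt{2\ln 2}\,\sigma \approx 2.35\,\sigma$, scaled by
the voxel size. Calibration is read from TIFF metadata (ImageJ-style
`spacing=`/`unit=` description plus X/Y resolution tags; only µm and nm are
interpreted) and can be overridden per call. Absent values stay `NA` and the
affected widths are reported in pixel units — never silently in nm.

## Ellipse projections

Tools that report axis-aligned spot widths cannot be compared directly with
an ellipse description (FWHM$_{max}$, FWHM$_{min}$, $\theta$); the naive
$a\cos\theta$ underestimates the true horizontal extent. `project_ellipse()`
finds the parametric angles of the extreme boundary points from the
vertex-gradient conditions ($\tan\varepsilon_x = -(b/a)\tan\theta$,
$\tan\varepsilon_y = (b/a)\cot\theta$), forms the centre chords through them,
and projects. The result equals the closed-form bounding box
$X' = 2\sqrt{a^2\cos^2\theta + b^2\sin^2\theta}$, which the tests use as an
independent oracle alongside a sampled-boundary brute force. Angles are first
folded into $[0, \pi/2]$ by the reflection $|\theta| \mapsto \pi - |\theta|$
above $\pi/2$ (projections are symmetric under both reflections); the circle
and the axis-aligned cases short-circuit before the $\cot/\tan$ poles.
The reverse mapping (X/Y widths to ellipse) is underdetermined and not
offered.

## Synthetic data and what it does (not) emulate

`synthetic_spec()` renders a 3D Gaussian spot — lateral FWHM 273 nm, axial
1036 nm (≈ a 1.15 NA water lens at 515 nm emission) — on a uniform background
of B = 100 counts, then optionally replaces every voxel by a Poisson draw
with that voxel's intensity as mean and variance (shot-noise-dominated
imaging). The signal-to-background ratio is SBR = (A + B)/B. The benchmark
sweep crosses lateral pixel sizes {10, 40, 80, 160} nm with eight amplitudes
{50, 100, 150, 200, 300, 500, 750, 1000} counts (SBR 1.5–11; the endpoints
fix the range, the intermediate rungs are an even ladder) — 32 datasets. The
axial step is the same for all datasets; the default of 100 nm gives about
ten samples across the axial FWHM. Stack dimensions default to odd sizes
covering ±4 lateral and ±3.5 axial sigmas (minimum 33), and a spot closer
than 3σ to a border is a placement error.

The model is deliberately the same family the analyzers fit, so the benchmark
isolates detection/estimation error from model mismatch. It does **not**
emulate Airy rings or aberrated PSFs, camera read noise or gain, sample
drift, or spectral bleed-through — passing the synthetic benchmark therefore
bounds algorithmic error, not total error on real acquisitions.

## Benchmark scoring

Lateral error is the RMS of the two axis errors as a percentage of truth,
$100\sqrt{((X_E - W)^2 + (Y_E - W)^2)/2}/W$ (the ÷2 makes it a true mean over
the axes; an un-averaged variant would differ by $\sqrt2$), axial error is
$100|Z_E - W_Z|/W_Z$. Both are capped at 100%, a failed or absent analysis
scores 100%, and cells are banded <10 / 10–20 / 20–30 / 30–40 / >40% for the
grid plot. With several spots per dataset the per-dataset estimate is the
mean over fitted features.

## Numerical and scope notes

* All voxel coordinates are 0-based; positions are reported at sub-pixel
  precision in pixels and, when calibrated, nm. Intensities are promoted to
  double at read time.
* TIFF writing is a minimal built-in baseline writer (float32, uncompressed,
  ImageJ-style tags) because the available TIFF bindings read, but cannot
  write, the calibration tags; files are verified by reading them back
  through the independent libtiff-based reader.
* Axis order is taken from the hyperstack metadata; ambiguous layouts
  (time-lapse `frames > 1`, inconsistent page counts) are errors rather than
  guesses — a silently swapped axis would corrupt every width.
* Non-square lateral pixels (dx ≠ dy) leave lateral widths in pixel units
  with a warning; an elliptical fit has no single lateral nm scale.
* Performance: test and validation runs use single-spot stacks of 33³ (40 nm
  sampling) to 33×95×95 voxels (10 nm) and a 200-spot field of 9×200×200;
  a full single-stack analysis takes well under two seconds, the 32-dataset
  sweep under a minute.

## Known limitations

* Below SBR ≈ 2.5 at 40 nm sampling, Poisson noise floods the DOG volume with
  spurious maxima; the mutual 5 px exclusion then removes everything and the
  analysis fails (scored as 100% error, the benchmark's failure convention).
  This matches the regime where parameter-free operation runs out of signal.
* Axially stacked features are lost to lateral exclusion (see above).
* The frequency-domain blur assumes periodic boundaries; features within a
  kernel support of the stack edge see slight wrap-around, and peaks within
  the patch radius of an edge are dropped before fitting anyway.
* The Gaussian spot model understates the tails of real PSFs; widths from
  strongly aberrated systems are fit-model-dependent.
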