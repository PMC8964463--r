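---
title: "Motion-compensated chemometric analysis of hyperspectral videos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-compensated chemometric analysis of hyperspectral videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A hyperspectral video is a time series of image cubes: at each of `K` time
points a camera records an `Ny x Nx` image whose every pixel carries a full
spectrum over `J` wavelength channels. Monitoring a drying, shrinking
specimen this way mixes three very different kinds of variation into one
four-way data set:

* **geometry** — the object moves and deforms (a drying piece of wood
  squeezes horizontally, the stage may bump sideways);
* **known physics and chemistry** — optical pathlength and light-scattering
  differences between pixels, smooth baseline drifts of the illumination,
  and the absorption signatures of known constituents (dry matter, water);
* **unknown systematic effects** — anything structured that the physical
  model does not anticipate (instrument drifts, thermodynamic state changes
  of water), on top of random measurement noise.

`hypercine` separates these three layers sequentially:

1. **Motion estimation and compensation.** Every frame is reduced to a
   greyscale image, dense optical flow against a reference frame is
   estimated, and every wavelength channel of every cube is *morphed back*
   so that all frames share the reference geometry. Displacements and
   intensity deviations each get a compact bilinear (scores x loadings)
   model: the frame-wise scores trace the motion history, the loadings
   are displacement images.
2. **Extended multiplicative signal correction (EMSC).** Each
   motion-compensated pixel spectrum `x` is decomposed by least squares as
   `x = b r + sum_i h_i s_i + a + d f + g f^2 + e`, with `r` a reference
   spectrum (dry matter), `s_i` known constituent spectra (water), `f` a
   linear ramp from -1 to 1 across the wavelength axis, `b` the effective
   relative pathlength and `h_i = b * dc_i` the abundance terms. The
   baseline polynomial absorbs smooth level/slope/curvature drifts.
3. **Streaming subspace modelling of the residuals.** The
   pathlength-corrected residuals `e / b` stream, frame by frame, through a
   self-expanding bilinear subspace model that projects each block, detects
   genuinely new directions of variation, isolates outlier rows, and
   periodically refines its basis — without ever retaining the raw stream.

The pipeline ends with temporal summaries (frame-averaged EMSC coefficient
and subspace-score trajectories), spatial summaries (per-pixel coefficient
and score maps with the motion-invalid fringe masked), and a PCA of the
frame-averaged pathlength-corrected reconstruction, whose score path makes
multi-phase process kinetics visible.

# Radiometric calibration

Raw camera counts `I` are converted per pixel and channel to reflectance
`R = (I - I_dark) / (I_white - I_dark)` against a dark and a white
(Spectralon-type) reference cube, then to apparent absorbance
`A = log10(1 / max(R, floor))`. The floor (default `1e-6`) makes the log
total; floored pixels are recorded. Channels where the two references
coincide are flagged invalid rather than divided. Line-scan instruments
often store a single-line reference; a `Ny = 1` reference cube is broadcast
across image rows as a documented convenience.

# Greyscale preparation for motion estimation

Optical flow assumes brightness constancy, which frame-wide baseline and
pathlength fluctuations violate. Three steps make the greyscale sequence
flow-friendly:

* **Frame-mean EMSC pre-correction**: coefficients are fitted once per
  frame on the frame-mean spectrum and the full correction
  `(x - a - d f - g f^2)/b - sum (h_i/b) s_i` is applied to every pixel.
  Fitting on the frame mean (not per pixel) removes only frame-wide
  fluctuations, leaving the per-pixel contrast that the flow needs. The
  correction subtracts the constituent term as `(h/b) s` — the same algebra
  as the full spectral correction — so that a pure-reference frame maps to
  itself and refitting a corrected frame returns identity coefficients.
* **Stable-band averaging**: the greyscale image is the per-pixel mean of
  the `n_bands` (default 3) channels whose frame-averaged absorbance varies
  least over time. The ranking is computed on the *uncorrected* absorbance
  video: after pre-correction every channel's frame mean is flat in time
  and the ranking would be noise. Ties resolve to the lower wavelength, and
  an explicit wavelength list can override the selection.
* **Level/range adjustment**: each grey frame is mapped to
  `(I - med_k) * (rms_ref / rms_k) + med_ref`, where `med` is the median
  over valid pixels and `rms = sqrt(median((I - med)^2))` the
  root-median-squared deviation (the robust spread statistic used here; it
  is affine-equivariant, so the adjustment is idempotent and collapses any
  affine distortion of the reference exactly).

The reference frame defaults to the last of the sequence — for a drying
scene, the geometrically most contracted state — and is configurable.

# Motion estimation, morphing, masking

Flow is a multi-scale Horn–Schunck-type global regularised estimator:
image pyramid (downsampling by 2 until the short side approaches 16 px),
and per level a few outer warp/linearisation iterations each running 100
Jacobi iterations of the classic update with smoothness weight
`alpha = 15`. Two implementation details matter:

* the image pair is contrast-normalised to an 8-bit-like joint range before
  differentiation, so `alpha` acts on a scale-free gradient magnitude;
* at each warp the residual global gain/bias between the warped frame and
  the reference is regressed out (`photometric = TRUE`). The median-based
  level/range adjustment necessarily leaves a few-percent amplitude
  mismatch whenever the object/background proportions change between
  frames; without compensation that mismatch masquerades as motion.

The estimated field `(du, dv)` lives on the reference grid and points from
reference coordinates to frame coordinates: back-morphing samples frame `k`
at `(x + du, y + dv)` with bilinear interpolation, and the identical field
is applied to all `J` channels of the cube. Samples falling outside the
frame are invalid — never extrapolated — producing the dark fringe around
motion-compensated frames. The downstream validity mask additionally drops
pixels whose displacement magnitude exceeds `max_disp` (default 10% of the
shorter image side); masked pixels take no part in the EMSC or subspace
stages.

Motions are summarised by uncentred truncated SVD models of the unfolded
fields (masked pixels imputed zero). Uncentred, the reference frame's score
row is exactly the origin, which makes the score trajectories directly
readable as "displacement relative to the reference". Horizontal and
vertical motions are additionally decomposed separately, because their
physics differ (structural squeeze vs stage/camera bumps). Frames are
rebuilt from the models by composing the reference image with the modelled
intensity deviation and displacing the result along the modelled field
(inverted by fixed-point iteration); at full rank the rebuild matches the
original frame to interpolation error.

# EMSC numerical choices

The design matrix `[r, s_1..s_I, 1, f, f^2]` is solved by QR decomposition
of the (weight-scaled) design — never by forming the normal-equation
inverse. The reference and constituent columns are max-normalised
internally for conditioning and the reported coefficients rescaled back, so
`b` and `h_i` always refer to the profiles supplied by the user. A
rank-deficiency check names the most collinear column pair. Channel
weights default to identity; only user-supplied diagonal weights are
supported. The polynomial order is fixed at two (offset, slope,
curvature). Pixels whose fitted `|b|` falls below `1e-3` are invalidated —
dividing by a near-zero pathlength would amplify noise without physical
meaning.

Frame-averaged coefficient trajectories are means of the pixel-wise
coefficients over each frame's valid pixels. The alternative — fitting the
frame-mean spectrum — is exposed (`average = "mean_spectrum"`) but not the
default: the mean of ratios is what the per-pixel maps integrate to, and an
all-invalid frame then yields an honest missing row instead of fabricated
zeros.

# The streaming subspace model

The residual stream is handled by a model that keeps only exact running
sufficient statistics (count, column sum, `J x J` second moment), the
current centre and orthonormal loadings, and per-block score rows. Three
rules govern it:

* **Detection.** After projecting a block, the residual's singular spectrum
  is examined; a direction is appended when its variance exceeds
  `max(3 * median eigenvalue, (1 - variance_target) * total variance,
  min_component_variance)`. The median-eigenvalue term is a robust
  noise-level estimate: on pure noise the leading eigenvalue of a block
  residual stays well below three times the bulk, so noise is compressed
  honestly rather than explained away (the model then carries a
  `target_unmet` flag). `min_component_variance` is an absolute floor the
  pipeline ties to the parent data's scale so that a numerically perfect
  upstream fit cannot seed components from rounding error.
* **Outlier isolation.** Rows whose residual norm exceeds `outlier_limit`
  (default 6) times the block's median residual norm are excluded from
  detection but kept in the stream and flagged. If more than 10% of a
  block's rows are "outliers" they are a pattern, not outliers, and are
  kept — a dense new variation source must never be discarded.
* **Refinement.** Every `refine_every` blocks (and once at the end of a
  stream) the centre and basis are re-estimated by an eigendecomposition of
  the exact covariance of everything seen — identical to batch PCA of the
  full stream, which is why the model matches a batch oracle to floating
  point after a final refine. The rank is the smallest count reaching the
  variance target among components above the noise floor, and never
  decreases: information about old observations is never lost. Stored
  score rows are mapped into the new basis through their blocks' low-rank
  reconstructions.

Everything is deterministic — there is no internal randomness, and each
loading's sign is fixed so its largest-magnitude element is positive. The
rank is capped at 32 to bound memory.

# The synthetic scene generator

Because realistic wood-drying recordings are not redistributable, the
package ships a fully ground-truthed generator. The default desk-scale
configuration is `64 x 48` pixels, `J = 60` channels over 930–2200 nm and
`K = 20` frames (the same structure as a real line-scan acquisition at
roughly 1/500 the volume). The scene is a single specimen whose pixels
follow the EMSC forward model exactly:

* constituent spectra are smooth Gaussian mixtures — a broad dry-matter
  reference and a water-like profile with bands near 1450 and 1940 nm
  (pairwise correlation above 0.95 is rejected as it would break the EMSC
  design);
* the water abundance is separable (a fixed textured spatial map times a
  two-phase trajectory: fast drop over the first 40% of the frames, slow
  decline afterwards — drying kinetics with a knee);
* the object contracts horizontally by 0.25% per frame (about 5% overall)
  toward the last frame's geometry, plus an optional small random vertical
  jitter (sd 0.1 px) emulating stage bumps; the last frame is the natural
  reference;
* the effective pathlength is a smooth ±15% textured field over the
  specimen, the per-frame baseline coefficients follow small smooth drifts
  (amplitudes 0.03/0.02/0.01), and one "unknown" systematic component — a
  narrow spectral feature between the water bands with its own spatial map
  and oscillating trajectory, amplitude 0.03 — exists precisely so the
  residual-subspace stage has a ground-truth target;
* i.i.d. Gaussian noise (sd 0.005 absorbance) is added, and the cube is
  converted to camera counts by inverting the calibration against
  structured synthetic dark/white references.

The specimen fills about 90% of the field of view, as a region of interest
cropped around a single sample would: this matters because the median-based
level/range statistics must sit inside the object's intensity mode.
Everything the pipeline estimates — displacement fields, pathlength map,
baseline and abundance trajectories, the unknown component — is stored in
the truth object, and regeneration from the same configuration is
bit-identical.

What the generator does *not* emulate: physics-based radiative transfer
(no Kubelka–Munk scattering model), wavelength-dependent noise, detector
nonlinearity, spectral misregistration, or deformations beyond a
horizontal affine squeeze. Passing tests on this scene therefore shows the
pipeline recovers its own model class under realistic noise and motion; it
does not certify behaviour under physics the model class excludes.

# Problem sizes and tolerances used in the checks

The test-suite uses the desk-scale scene above (and smaller 32 x 24 x 30 x 6
variants for contract tests); the acceptance script re-runs the full
pipeline on the default scene plus oracle comparisons on constructed
streams (10,000 x 60 for the subspace-vs-batch check, 96 x 128 images for
flow). Flow accuracy is asserted at 0.3 px RMS on interior pixels; EMSC
exactness at 1e-8 relative; subspace-vs-batch agreement at 1% relative
explained variance and 0.05 rad principal angles. The "residual energy
after the three models" summary reported in `report$energy` is computed
against the scatter-corrected (post-EMSC) signal energy about its grand
mean; with i.i.d. noise present the unexplained share can never drop below
the noise floor, so it is reported rather than thresholded.

On compression: the stored models comprise motion scores/loadings, five
per-pixel EMSC coefficient maps, and subspace scores/loadings. At the
desk-scale `J = 60` the coefficient maps alone are `5/60 = 8.3%` of the raw
scalars, so the total sits near 11%; at a realistic `J = 200` the identical
models are about 3%. The ratio is reported by `compression_summary()`.

# Known limitations

* Single-holon scenes only: no segmentation of independently moving
  objects, and no frame-to-frame tracking beyond direct-to-reference flow.
* No spectral resampling: constituent spectra must match the video's
  wavelength axis exactly (an error otherwise).
* The flow estimator is a global-smoothness method: it blurs motion
  discontinuities and needs spatial texture; texture-free regions inherit
  smoothly interpolated motion.
* EMSC here has no replicate-correction or interference-subtraction
  extensions, and the subspace stage has no forgetting factor, no
  downdating and no trilinear structure.
* File I/O covers ENVI header/raster directories and two-column text
  spectra; no HDF5 container support.
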