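---
title: "ChromaPlex: methods and design notes"
author: "ChromaPlex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ChromaPlex: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

ChromaPlex analyzes cyclic multiplexed immunofluorescence acquired on a
filterless-turret imager: five excitation LEDs (L385, L470, L567, L627,
L720 nm, each behind an in-line excitation filter) fired one at a time,
a single five-window ("penta") emission filter with passbands near
432/515/595/681/809 nm, and a color CMOS camera. Because the camera's
R, G and B channels weight every emission window differently, each
fluorochrome produces a characteristic pattern of responses across the
15 (LED, color-channel) combinations — its *fingerprint*.

Per pixel, the stacked signal vector $S \in \mathbb{R}^{15}$ (LED-major
order, channels R, G, B) is modeled as linear in the fluorochrome
abundances $F \in \mathbb{R}^{6}_{\ge 0}$:

$$ S = A\,F, \qquad
\hat F = \operatorname*{arg\,min}_{F \ge 0} \lVert A F - S \rVert_2 . $$

The non-negativity bound is physical — abundances are amounts of dye —
and is what distinguishes this inversion from ordinary least squares:
it suppresses the negative "overshoot" that plain unmixing produces in
channels adjacent to a bright fluorochrome. The solver is a
Lawson–Hanson active-set implementation in C++ (one small dense solve
per active-set change; a 2448 × 2048 frame unmixes in well under a
minute on one CPU). When the passive-set normal matrix is singular
(two fluorochromes with collinear fingerprints), the solver falls back
to the minimum-norm solution; this tie-break is fixed by test. An
optional noise floor (default: twice the dark-frame SD) lets
background pixels skip the solver entirely.

## Predicting the fingerprint matrix

Under LED-sequential illumination the entry of $A$ for LED $\ell$ and
channel $c$ factorizes into an excitation and an emission coupling:

$$ A_{(\ell,c),f} \;=\; \beta_f
\int E_\ell(\lambda)\, X_\ell(\lambda)\, \phi^{ex}_f(\lambda)\,
d\lambda \;\times\;
\int \phi^{em}_f(\lambda)\, P(\lambda)\, \sigma_c(\lambda)\, d\lambda $$

with $E_\ell$ the LED emission, $X_\ell$ its excitation filter,
$\phi^{ex}_f, \phi^{em}_f$ the fluorochrome spectra, $P$ the penta
transmission, $\sigma_c$ the sensor channel sensitivity and $\beta_f$ a
relative brightness. Columns are scaled to a maximum of 1, so
abundances carry the intensity scale; this normalization makes
predicted and experimentally estimated matrices directly comparable.
All curves are configuration data (CSV per curve, listed in a YAML
optics file); the shipped defaults are parametric approximations
(Gaussians for LEDs and fluorochromes, flat-top windows for filters,
visible peaks plus a shared near-infrared tail for the Bayer channels)
with centers taken from the nominal part specifications. Their
fingerprint matrix has 2-norm condition number ≈ 1.25, comfortably
invertible.

The experimental route mirrors practice: one slide per fluorochrome,
stained with that fluorochrome only. After dark subtraction, the
foreground is the set of pixels above the 0.95 quantile of the
brightest (LED, channel) plane — there is no canonical recipe for this
selection, so the quantile is exposed as `fgThresholdQuantile`,
supporting both cell-foreground and near-whole-field readings. Plane
averages over the foreground, column-scaled to max 1, reproduce the
generating matrix exactly on noiseless synthetic slides, and to within
2% (relative, for entries ≥ 0.05 on the max-1 scale) at the default
shot-noise level; entries below 0.05 are shot-noise dominated and are
held to 0.01 absolute instead — a relative bound on a near-zero entry
is not attainable at any realistic pixel count.

## Bleed-through accounting

Bleed-through per fluorochrome is reported by decomposing its emission
× penta × summed-sensor signal across the five passband windows; the
out-of-window share is the bleed-through fraction. The near-infrared
dye (CF750) is the notable leaker into the adjacent 681 nm window,
consistent with the broad red tails of cyanine-type emitters and the
convergence of Bayer channel sensitivities beyond ~800 nm.

# The cycle pipeline

Processing order is fixed and logged: **dark → align → quench-subtract
→ unmix**.

* **Dark subtraction.** A dark frame (no sample) is subtracted from
  every plane, clamped at zero. The clamp fraction is recorded; pixels
  whose difference magnitude lies below 3× the read-noise SD are not
  counted as clamping, since background flicker around zero always
  clamps ~50% of empty pixels and would render the statistic useless.
  A counted clamp fraction above 20% raises a QC warning.
* **Registration.** Cycles are aligned rigidly (rotation +
  translation) to cycle 1 using the DAPI counterstain, which is
  present in every cycle. The registration image is the raw
  (dark-subtracted) G/B composite under L385 — *raw* rather than
  unmixed, so unmixing always sees consistent geometry. Keypoints are
  intensity-weighted nucleus-blob centroids; an FFT cross-correlation
  provides the coarse translation and a trimmed iterative
  closest-point loop with a Kabsch fit refines rotation and
  translation while rejecting unmatched blobs. Fewer than 20
  detectable blobs or fewer than 8 inlier matches is a hard
  registration failure. Over 50 seeded transforms (|shift| ≤ 10 px,
  |rotation| ≤ 2°) the truth is recovered within 0.5 px and 0.1° in
  ≥ 95% of cases.
* **Quench subtraction.** The post-quench acquisition of cycle $n-1$
  is subtracted from the stained acquisition of cycle $n$ (clamped at
  zero); cycle 1 subtracts the cycle-0 autofluorescence reference.
  Because the quenched image contains exactly the quench-resistant
  carryover plus autofluorescence, this one step removes both. The
  cycle-0 reference contains no DAPI (it is acquired before the first
  stain, in the same mount as cycle 1), so it is warped with cycle 1's
  transform and cycle-1 DAPI survives subtraction.
* **Segmentation input.** The DAPI abundance images of all cycles are
  combined by pixel-wise maximum, so a nucleus dim in one cycle is
  still segmented.

# Segmentation, QC and quantification

Segmentation is a pluggable backend registry — learned segmenters can
be wrapped and registered under a name — with a classical built-in:
Gaussian smoothing, Otsu thresholding of the DAPI projection, hole
filling, distance-transform watershed to split touching nuclei, and
cell bodies grown from nucleus seeds by Voronoi propagation inside a
dilated (or cytoplasm-thresholded) mask. The built-in exists so the
pipeline is fully testable without heavyweight external models; it is
a reference implementation, not a claim about segmentation
state-of-the-art.

Cells with more than one nucleus, or with nucleus-to-cell area ratio
above 1, are excluded; nuclei without a cell and cells without a
nucleus are excluded and logged separately. The filter is idempotent
and its per-reason counts are part of the run's QC output.

Quantification is the mean unmixed abundance per retained cell —
whole-cell mask for membrane/cytoplasmic markers, nucleus mask for
nuclear markers (ER, PR, Ki67, GATA3 and DAPI by default; the panel
carries the flag). Normalization divides each marker's cell means by
its 10th percentile across cells and winsorizes above the 99th
percentile; both reference values are recorded. The percentile wording
admits several readings (divide vs subtract, winsorize vs truncate);
the divide-by-p10 / winsorize-at-p99 reading is the package's
documented interpretation, chosen because it makes the low-intensity
background population the unit of scale and keeps outliers bounded
without deleting cells. Bounded unmixing returns exact zeros in
background channels, whose 10th percentile can therefore be zero; a
small additive offset (default 1 count in the driver) regularizes
this, and a zero p10 without offset is a hard "degenerate baseline"
error.

Positivity per marker is strict: a cell is positive when its
normalized intensity exceeds mean + 3 SD of the IgG isotype control
cells of the marker's fluorochrome channel (ties are negative; the
paper does not fix the boundary convention, so the package does).
The default panel devotes cycle 4 to IgG controls on all five
non-DAPI channels, giving every channel its own null distribution. A
user-supplied constant threshold is accepted with a warning when no
IgG channel exists.

Phenotyping is ordered-rule evaluation over positivity columns
(first match wins, default label "other"), with two built-in rule
sets: immune (CD45+) versus tumor (any of HER2/EpCAM/MUC1/EGFR and
CD45−), and the five-way receptor/proliferation mosaic (multi-marker,
Ki67-only, HER2-only, ER/PR-only, quad-negative).

# The forward simulator

Every stage above is validated against a seeded forward model, so the
package is testable end to end without instrument data.

* **Scenes.** Elliptical cells with contained elliptical nuclei,
  placed by minimum-distance rejection sampling (default 640 × 640 px
  at 0.6 µm/px, 500 cells, 70/30 tumor/immune — the scale of a
  fine-needle-aspirate field). Marker abundances are log-normal per
  phenotype; tumor cells express the epithelial/receptor panel and no
  CD45, immune cells the reverse, and the IgG "markers" are expressed
  by nobody. Membrane markers are rendered on the cytoplasmic ring,
  nuclear markers on the nucleus.
* **Optics and noise.** Expected signal is $A F$ per pixel plus a
  cellular autofluorescence term (strongest under violet excitation),
  warped by the cycle's stage transform, then Poisson shot noise,
  Gaussian read noise (SD 6 counts) and a constant dark offset (100
  counts), clamped at zero. Default marker levels (~300 counts at the
  brightest fingerprint entry) against the ~6-count background SD put
  single-stain SNR near 50. Quenching leaves a 2% residual
  (`quenchResidual`), which compounds across cycles exactly as the
  quenched acquisitions record it — so quench subtraction is a
  meaningful, non-trivial correction in every simulated run.
* **Beads and focus.** Single-fluorochrome discs support SNR/CV and
  daily-calibration checks; defocus stacks blur a rendered field with
  a Gaussian whose width grows linearly with axial distance (7 planes,
  150 µm step by default).

What the simulator does *not* emulate: tissue architecture, 3D shape,
Bayer mosaic artifacts, photobleaching kinetics, illumination
flat-field error (the pipeline implements no flat-field correction),
and non-rigid deformation. Passing tests therefore demonstrate the
correctness of the computational chain under the stated optical and
noise model, not robustness to every property of real tissue.

# Numerical choices and problem sizes

* Unmixing tolerance: active-set pivoting uses a tolerance of
  $10\,\varepsilon \lVert A\rVert_1 \max(m,k)$; degenerate passive
  sets fall back to the minimum-norm solution.
* Warping is bilinear; out-of-frame pixels are zero-filled and masked.
  A transform discarding more than 20% of the frame is rejected.
* The focus score is gradient energy over variance after a 1 px
  Gaussian pre-filter; without the pre-filter, camera noise (white,
  hence gradient-rich) rewards defocused planes. Ties in plane
  selection resolve to the lower index.
* The registration ICP trims matches beyond 3× the median residual
  and stops when the update falls below 1e-4 px.
* Grid-oracle comparisons for the solver use an exhaustive coarse pass
  followed by a fine pass around the coarse minimum; because the
  residual is convex, a window scaled by the square root of the
  Hessian condition number is guaranteed to contain the fine-grid
  minimizer, and agreement is asserted to the same condition-scaled
  grid resolution.
* Validation problem sizes (chosen to exercise every code path at
  laptop scale): 200 random 3 × 2 systems for the solver oracle; a
  100-cell noiseless field for the forward–inverse identity; 60-cell
  noiseless and 500-cell noisy single-stain slides per fluorochrome
  for fingerprint estimation; 50 seeded transforms on a 150-cell field
  for registration; and the 500-cell default slide for end-to-end
  phenotype recovery.

# Known limitations

* The spectral defaults are parametric stand-ins, not measured curves;
  any analysis of real data should supply measured spectra via the
  optics YAML or estimate the fingerprint matrix from single-stain
  controls.
* Joint (stacked) inversion across all five LEDs is an interpretation:
  per-LED inversion would also be expressible in this framework but is
  not implemented.
* IgG thresholds are per fluorochrome channel; per-antibody thresholds
  would need one IgG per host species per channel, which the panel
  structure supports but the defaults do not populate.
* The divide-by-p10 normalization fails (by design, with an error) on
  markers whose low decile is truly zero; the offset is the supported
  escape hatch.
* Hardware concerns — LED drift, autofocus motor control, exposure
  calibration — are out of scope; the QC module scores images it is
  given.
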