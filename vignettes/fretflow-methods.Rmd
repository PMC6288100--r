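---
title: "Quantifying flow-induced FRET biosensor polarity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying flow-induced FRET biosensor polarity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretflow)
```

## The measurement problem

An intramolecular FRET biosensor reports a molecular interaction — here the
binding of RhoGDIα to the switch II domain of Rho GTPases — through the ratio
of its acceptor (FRET) to donor (ECFP) emission. Imaging a single adherent
cell once per minute while laminar flow is switched on yields two questions
that this package answers quantitatively:

1. **How much does the whole-cell ratio change after flow onset?** Reported
   as a baseline-normalized time course, where the baseline is the cell's own
   pre-stimulus mean.
2. **Does the response polarize along the flow axis?** The cell is divided
   into 50 equal-width bins along the flow direction (bin 1 at the
   downstream edge, bin 50 upstream), each bin's share of the total ratio
   signal is tracked over time, and the first and last five bins are
   averaged to give downstream and upstream summaries per cell. Across
   replicate cells, a two-tailed two-sample t-test at a fixed time point
   (30 min in the reference design) calls polarity at p < 0.05.

## Per-cell pipeline

`fret_analysis()` runs, per frame and per channel:

* **Background**: the mean over four square corner windows (default
  8 × 8 px each, `corner_window_px`). The corners are assumed cell-free —
  the synthetic generator enforces this with an explicit margin. Estimated
  per frame so slow illumination drift over a 30–60 min run is tracked.
  Pixels below background are clamped to zero after subtraction; leaving
  them negative would make downstream ratios undefined, and the clamp
  matches common ratio-imaging practice.
* **Despeckle**: a `(2r+1)²` median filter (default r = 1, i.e. 3 × 3),
  edge-replicated borders. The window always holds an odd number of samples,
  so the output is an exact order statistic of the input — no averaging, no
  quantization. This matters for validation: the filter is checked against a
  brute-force per-pixel sort at 1e-9.
* **Segmentation** ("edge recognition"): global Otsu threshold computed on
  the nonzero intensities (the clamped zeros would otherwise dominate the
  histogram), largest 4-connected component, interior holes filled. This
  deterministic, parameter-free chain was chosen over gradient-based edge
  detection, which needs tuning per dataset. Segmentation runs per frame on
  the donor channel by default (`segment_channel`); an optional
  `mask_propagation` flag reuses the previous frame's mask when a dim frame
  has no component above `min_cell_area_px` (default 200 px).
* **Ratio**: per-pixel FRET/donor division on the mask. Pixels whose donor
  signal falls below `donor_floor` are excluded and counted rather than
  allowed to blow up at dim cell edges; the default floor is twice the
  corner-pixel standard deviation of the frame, a noise-scale proxy that
  reduces to zero on noise-free data.
* **Whole-cell series**: the unweighted mean of the valid per-pixel ratios
  ("ratio of pixels"). The alternative — ratio of summed intensities —
  weights bright pixels more; it is not what "average ratio of the whole
  cell" means, but the intensity-weighted profile variant is available via
  `fret_control(weighting = "intensity")` for sensitivity checks. The
  baseline is the mean over *all* pre-stimulus frames.
* **Spatial profile**: each valid pixel is projected onto the flow axis and
  assigned to one of `n_bins = 50` equal-width intervals spanning that
  frame's projection range. A bin's value is its summed ratio as a
  percentage of the whole-cell sum, so every profile totals 100 exactly.
  Bin edges are recomputed per frame because cells deform under flow;
  `fret_control(edges = "fixed")` freezes frame 1's extent instead.
* **Per-bin normalization**: each bin's trace is divided by its own
  pre-stimulus mean, so post-stimulus values read as regional fold change.
  Bins with zero pre-stimulus signal are flagged invalid and carried as
  `NA` — never zero-filled, since zero is a meaningful percentage.

### Numerical conventions in the binning

Two conventions deserve explanation because they are invisible in typical
use but essential for exactness:

* **Canonical axis orientation.** On an integer pixel grid, pixels land
  *exactly* on bin edges at any flow angle (whenever a pixel's integer
  offset from the extreme pixel is a rational fraction of the extent
  vector). A naive half-open interval rule then assigns such pixels to
  different physical bins for flow directions `d` and `-d`, breaking the
  requirement that flipping the flow reverses the profile bin-for-bin. The
  implementation therefore applies the half-open convention along a
  canonical orientation of the axis (sign fixed so the first nonzero
  component is positive) and remaps bin indices afterwards: `d` and `-d`
  run the identical computation, and reversal is exact by construction.
* **Edge snap and canonical summation.** Projections within 1e-9 of a bin
  edge are snapped onto it (joining the downstream side), so that
  algebraically equivalent formulas cannot round an exact edge hit to
  opposite sides. Within each bin, values are summed in sorted order, which
  makes the profile bitwise invariant under joint 90° rotations of the
  image and the flow vector.

## Polarity testing across cells

Cells, not pixels, are the replication unit: pixels within a cell are
strongly correlated, whereas averaging the five edge regions per cell
("to decrease the discreteness" of any single thin bin) gives one
downstream and one upstream summary per cell. `polarity_test()` compares
the per-cell summaries with a two-tailed two-sample t-test; Welch's
unequal-variance form is the default because it is robust and costs almost
nothing, with the pooled-variance Student form selectable to mirror
spreadsheet-style analyses. Degenerate inputs are defined explicitly: two
constant groups with equal means give p = 1, with unequal means p = 0.
No multiple-testing correction is applied across conditions; p-values are
per-comparison, as in the reference design.

One caveat is built into the test's interpretation: the upstream and
downstream summaries come from the *same* cells, so any shared per-cell
random effect correlates the two groups, and compositional coupling (all
50 bins sum to 100) correlates them weakly in the other direction. The
two-sample test is exactly calibrated when the summaries are exchangeable
and independent across groups — which is how the null calibration study is
run (cells differing only in geometry and noise). With strong between-cell
heterogeneity the test tends to the conservative side.

## The synthetic generator

`generate_stack()` is the forward model used for validation: an elliptical
cell of uniform donor expression on a dark background, with ratio field

$$R(x,t) = R_0\,\bigl[1 - d\,E(t)\bigr]\,\bigl[1 + g\,u(x)\,G(t)\bigr],
\qquad E(t) = 1 - e^{-(t-t_0)/\tau}\ \text{for } t \ge t_0,$$

where $u(x) \in [-0.5, 0.5]$ is the normalized flow-axis coordinate
(+0.5 downstream) and $d$, $g$, $\tau$ are the plateau decay amplitude,
gradient slope and response time constant. Channels get a common additive
background offset, optional per-channel exponential photobleaching
(default off), Poisson shot noise (variance = mean, as for a photon-counting
detector) and additive Gaussian read noise, clamped at zero.

The defaults emulate the magnitudes of the live-cell experiments this
pipeline was designed around: $d = 0.25$ (a ~25% whole-cell decrease),
$\tau = 300$ s (response developing over minutes and stable well before
30 min), 60-s frames, 500-count donor signal over a 100-count offset with
3-count read noise — a realistic cooled-CCD regime in which shot noise
dominates.

**Gradient timing.** $G(t) = E(t)$ by default
(`gradient_mode = "stimulus"`): the spatial gradient develops with the
stimulus, which is the phenomenon of interest — a flow-*induced* polarized
response. The alternative `gradient_mode = "static"` ($G \equiv 1$) models
a pre-existing spatial pattern; baseline normalization cancels any
time-invariant spatial factor *exactly*, so a static gradient produces flat
unit normalized traces in every bin. That cancellation is itself used as a
validation oracle (below), but it also means a static gradient can never
register as polarity — which is the correct behavior of baseline-normalized
analysis, not a limitation of the generator.

**What the generator does not emulate:** optical blur (PSF), cell motility
and deformation under flow, channel crosstalk and bleed-through,
flat-field/illumination structure, multi-cell fields. Passing the recovery
tests therefore demonstrates that the *analysis* is correct and calibrated
under the stated noise model; it does not certify performance on real
recordings, where segmentation and mask stability are the dominant risks.

**Seeds.** Each acquisition derives per-frame RNG streams from its own seed
by fixed offsets, and `generate_cohort()` derives per-cell seeds from a
master seed the same way, so cohorts are reproducible piecewise: cell *i*
is bit-identical no matter how many cells are requested.

## Validation strategy and problem sizes

The test suite validates in five layers, all on synthetic data generated at
run time:

1. **Oracle equivalence** — background means, median filtering, ratio maps
   and flow-axis binning against exhaustive brute-force loops on 100 random
   32 × 32 instances each, at 1e-9.
2. **Conservation and symmetry** — profiles sum to 100 every frame; flow
   flips reverse profiles bitwise; joint 90° rotations leave them bitwise
   invariant.
3. **Noise-free recovery** — across $d \in \{0.1, 0.25, 0.4\}$ and
   $g \in \{-0.4, 0, 0.4\}$ (static mode, 96 × 96 px, 44 frames), the
   pipeline recovers the normalized plateau $1-d$ to ≤ 1e-3 relative error
   and flat unit per-bin traces to ≤ 1e-3; in stimulus mode the sign of the
   downstream-minus-upstream difference equals the sign of $g$.
4. **Noisy recovery** — at the default noise model and 500-count donor, the
   plateau estimate is within ±0.02 of $1-d$ (5 seeds).
5. **Statistical calibration** — on 1000 null cohorts of 8 cells
   (80 × 80 px, 4 frames; cells differ in geometry and noise only) the
   polarity test rejects within 0.05 ± 0.02; with the gradient sized so the
   up/down gap is three times the measured between-cell noise scale, power
   exceeds 0.95 at n = 8. The calibration images are deliberately small and
   short — the test statistic only needs one post-onset frame — so that a
   thousand full pipeline replicates remain a desk-scale computation.

Determinism is asserted end-to-end: identical seed and configuration give
byte-identical generated TIFFs and analysis CSV outputs.

## File formats

Images travel as multi-page TIFF, one file per channel, frames in page
order. Ingestion is value-preserving: integer TIFFs are *not* rescaled to
[0, 1] and float TIFFs pass through, so counts stay counts. Ratio maps are
written as 32-bit float TIFF with NaN outside the cell; because no
installed writer preserves float samples outside [0, 1], the package
carries a minimal uncompressed little-endian float32 TIFF writer, verified
against an independent reader in the tests. Acquisition metadata (flow
direction in image coordinates, stimulus onset frame, frame interval, pixel
size) travels in a flat YAML sidecar — TIFF tags for these fields are
nonstandard. Emission spectra are two-column text tables; the in-vitro FRET
readout `spectral_fret_ratio()` linearly interpolates the 475 nm and 515 nm
intensities (the spectrofluorometer readout pair; the 475/535 microscope
filter pair is selectable, and no conversion between the two readouts is
attempted).

## A worked example

```{r example, fig.width = 7, fig.height = 4}
truth <- fret_truth(decay_amplitude = 0.25, gradient_slope = 0.4,
                    gradient_mode = "stimulus", stimulus_onset_frame = 6,
                    seed = 42)
stack <- generate_stack(truth, n_frames = 36, dim = c(128, 128))
fit <- fret_analysis(stack)
print(fit)
plot(fit)
```

A cohort comparison at 30 min after onset:

```{r cohort}
stacks <- generate_cohort(truth, n_cells = 6, n_frames = 36,
                          dim = c(128, 128), between_cell_sd = 0.03)
cohort_polarity(lapply(stacks, fret_analysis), time_min = 30)
```

## Known limitations

* Single-cell fields only; no instance segmentation, drift correction or
  flat-field correction.
* The 50-bin geometric division assumes the mask spans comfortably more
  than 50 px along the flow axis; thinner cells yield empty bins, which are
  carried as invalid rather than interpolated.
* Ratio readouts are raw channel ratios; three-cube bleed-through
  correction and absolute FRET efficiency are out of scope.
* The polarity test treats cells as independent replicates of one
  condition; mixed-effects modeling across conditions is out of scope.
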