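---
title: "Phase-encoded cortical mapping: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-encoded cortical mapping: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topomapr)
```

# The problem

Topological (retinotopic, tonotopic, somatotopic) cortical maps are mapped
with *phase-encoded* stimulation: the stimulus cycles periodically through
a sensory dimension (a rotating polar-angle wedge, a frequency sweep, a
foot-to-face movement sequence), so that each responsive point on the
cortical surface responds periodically at the stimulus frequency, with a
response phase that encodes that point's preferred stimulus coordinate.
`topomapr` implements the full analysis chain on triangular surface
meshes — per-vertex Fourier statistics, combination of direction-reversed
runs, cross-subject complex averaging, phase-gradient fields, visual field
sign, and segmentation into labeled areas written in standard
annotation/color-table formats — together with a synthetic-cortex
generator that provides ground truth for every stage.

# The single-run model

A run is an $N \times T$ matrix of per-vertex signals sampled every
`trS` seconds, containing `nCycles` stimulus cycles ($T$ an integer
multiple of the cycle length). At the stimulus frequency index $k$ =
`nCycles`, the discrete Fourier coefficient gives, per vertex:

* **amplitude**, scaled by $2/T$ so a pure cosine of amplitude $a$
  returns $a$;
* **phase** $\phi$ in $(-\pi, \pi]$, with the convention that $\phi = 0$
  is a cosine peaking at $t = 0$ and a *later* response peak gives a
  *more positive* phase (so a hemodynamic delay $d$ adds
  $2\pi d / \mathrm{period}$);
* **significance**: $F$ = signal power at $k$ divided by the mean power
  over a noise band of $K$ frequencies, distributed as $F(2, 2K)$ under
  white noise.

The noise band is the conventional phase-encoded recipe: all indices
$4 \ldots T/2 - 1$, excluding the stimulus index, its second and third
harmonics, and one neighbor on each side of every excluded index
(indices 0–3 are slow drift). We additionally exclude the Nyquist index:
its periodogram ordinate has one rather than two degrees of freedom, and
keeping it would bias the $F(2, 2K)$ calibration that the test suite
verifies by Monte Carlo (type-I rate within $[0.04, 0.06]$ at
$\alpha = 0.05$, and Kolmogorov–Smirnov uniformity of the null
p-values).

Degenerate inputs are handled without exceptions where they arise
legitimately: a constant time series at a vertex is masked (undefined,
never a silent zero), and a noiseless periodic response yields the
$F = \infty$, $p = 0$ sentinel, which is routine in synthetic data.

# Direction-reversed runs and delay cancellation

Forward and time-reversed runs measure $\phi + \delta$ and
$-\phi + \delta$ respectively, where $\delta$ is the hemodynamic phase
delay. `combineReversed()` advances every run's phase by
$2\pi \cdot \mathtt{delayShiftS} / \mathrm{period}$ (compensating the
*estimated mean* delay, 5 s by default), negates the reversed runs, and
averages all runs as amplitude-weighted complex vectors (the average of
raw Fourier coefficients across scans). Because the residual delay then
enters the two directions with opposite signs, any delay *common* to
forward and reversed runs cancels exactly in the combined phase — the
test suite asserts exact cancellation (to 1e-9) for delays of 0, 3, 5
and 8 s against a 5-s shift. Phases are stored internally as complex
numbers throughout, so no averaging step can suffer wrap artifacts.

The combined map's F statistic is the mean of the per-run F values, kept
for display and single-subject masking; group inference uses the
statistic below.

# The cross-subject F-ratio

For group averages, each subject's per-vertex response is a bivariate
(real, imaginary) observation $z_i$. Under the isotropic bivariate
normal null, the statistic

$$F = (n-1)\,\frac{n\,|\bar z|^2}{\sum_i |z_i - \bar z|^2}
\;\sim\; F(2,\, 2(n-1))$$

is *exactly* F-distributed (it is the regression F-test of a complex
intercept). We use this form, with degrees of freedom $(2, 2(n-1))$,
because exact null calibration is a stated requirement of the pipeline
and is verified by Monte Carlo at $n = 6$ over 50,000 vertices. The
literature's complex-valued F-ratio for this masking step is described
in varying forms; we do not claim formula-level identity with any
particular implementation, only exact calibration under the stated
model. The combined phase is the angle of the mean vector; zero
dispersion again yields the $\infty$/$p = 0$ sentinel. At least three
subjects are required.

# Surface smoothing and its FWHM

`nnSmooth()` implements nearest-neighbor surface smoothing: each step
replaces every defined vertex value by the unweighted mean of itself and
its defined neighbors. Masks are frozen (a vertex stays defined iff it
started defined), undefined neighbors are simply omitted from the mean,
and complex values are averaged componentwise.

`smoothingFwhm()` expresses the cumulative kernel in mm by measuring the
impulse response at the center of a regular hexagonal patch and fitting
an isotropic 2D Gaussian *by moment matching*
($\sigma^2 = \tfrac12\,E[r^2]$). We deliberately do not fit by least
squares: the one- and two-step kernels are far from Gaussian (a
seven-point disk after one step), a least-squares fit overestimates
their width, and only the moment fit makes kernel variances add exactly
under convolution — which is the property (FWHM$^2$ additivity over
successive steps, $\sqrt{\text{steps}}$ growth) that the suite asserts.
On a patch with 0.9 mm vertex spacing, two smoothing steps correspond to
a kernel of about 2 mm FWHM; the width scales linearly with mesh
spacing, so a single printed millimeter value is meaningful only for a
specific mesh.

# Gradients, field sign and segmentation

`phaseGradient()` computes the tangential gradient
$\nabla\phi(\mathbf r)$ per vertex: neighbor displacements are projected
into the vertex's tangent plane (an orthonormal per-vertex frame built
from area-weighted face normals), neighbor phases are unwrapped relative
to the center phase, and the 2D gradient is the least-squares fit of
phase difference against tangent displacement — the steepest uphill
direction in phase, in rad/mm. Vertices with fewer than two
non-collinear defined neighbors are undefined. `meanGradientDirection()`
summarizes an area by the normalized vector mean of its gradients (the
atlas's "white arrow"); exact cancellation is flagged degenerate rather
than normalized.

The **visual field sign** at a vertex is the sign of the component along
the vertex normal of $\nabla\mathrm{ecc} \times \nabla\mathrm{polar}$:
$+1$ is declared non-mirror-image, $-1$ mirror-image. The field-sign
method fixes only the *relation* (mirror vs non-mirror alternates
between adjacent areas); the numeric assignment is this package's fixed
documented convention. A magnitude floor — by default 10% of each
field's median valid gradient norm — zeroes the sign where a gradient is
too weak to orient, which suppresses sign noise exactly at gradient
reversals. The suite checks the sign against analytic Jacobian
determinants of linear and curved diffeomorphic maps (≥ 99% interior
agreement).

`segmentFieldsign()` turns the field-sign map into a parcellation:
edge-connected components (two vertices are connected only through a
shared mesh edge, matching surface-filling of patches) of constant
nonzero sign within the significance mask. Components are discarded if
their surface area is below `minAreaMm2` (default 25 mm²) or if their
circular phase range — $2\pi$ minus the largest gap between sorted
phases — is below `minPhaseRangeRad` (default $\pi/4$). Both thresholds
are exposed because no published numeric criterion exists for "a range
of response phases"; the defaults are choices a mapper would consider
conservative at fMRI resolution. Surviving components get consecutive
ids by decreasing area, ties broken by lowest contained vertex index, so
output labeling is deterministic. An empty parcellation is valid.

# Mesh averaging and the inflation area bias

Registered subjects share mesh topology, so cross-subject surface
averaging is vertex-wise coordinate averaging. Because individual
folding crinkles are incoherent across subjects, averaging *folded*
surfaces cancels them and shrinks surface area, whereas averaging
*inflated* surfaces does not — so average-then-inflate yields less area
than inflate-then-average. Reproducing the *direction* of this bias
requires inflation to be nonlinear: plain neighbor-mean relaxation is a
linear operator and commutes with coordinate averaging exactly, making
both orders identical. `inflateMesh()` therefore rescales the mesh about
its centroid after every relaxation step to conserve total surface area
(a minimal stand-in for full metric-preserving inflation); with
`preserveArea = FALSE` it degenerates to plain relaxation, for which
area decreases monotonically. Only the ordering and monotonicity
properties are claimed — the magnitude of the bias depends on real
cortical geometry and is not asserted.

# The synthetic cortex

The generator provides ground truth for every stage:

* **Meshes**: regular hexagonal patches (`makeHexPatch`; interior
  vertices have six neighbors, vertex count $1 + 3n(n+1)$) and
  icospheres (`makeSphere`, $10 \cdot 4^s + 2$ vertices) for spherical
  resampling tests.
* **Visual specs** (`synthVisualSpec`): eccentricity linear along one
  axis; polar angle a continuous triangle wave along the perpendicular
  axis whose slope reverses at each stripe border — adjacent stripes
  carry opposite field sign and share duplicated phases at congruent
  borders (the V1/V2/V3 arrangement). Default gains 0.35 (polar) and
  0.2 (ecc) rad/mm keep the map within one phase cycle on the default
  patches.
* **1D specs** (`synth1dSpec`): a single linear phase coordinate
  (tonotopy analog); field sign undefined.
* **Somatotopic specs** (`synthSomatoSpec`): piecewise-linear phase with
  a recorded discontinuous jump at each patch border (the
  patchwork-quilt analog); gradients are anomalous exactly at borders.
* **Runs** (`synthRuns`): per subject, response
  $a \cos(2\pi k t / T - \phi - 2\pi d/\mathrm{period})$ for forward
  runs; reversed runs negate the stimulus phase before the delay.
  AR(1) noise (lag-1 coefficient 0.3 by default) approximates fMRI
  temporal autocorrelation. Every random draw derives deterministically
  from `cohort@seed`, the subject index and the run index, so identical
  specs give bit-identical runs.

**Cross-subject jitter.** Registration misalignment is emulated by a
smooth single-harmonic per-subject offset field (s.d. `jitterSd`, rad).
The offset is applied *through the map's own phase function* — cortical
position is displaced by `jitter/gain` along the map axis — which is an
additive phase offset in map interiors but reflects at folded congruent
borders. This distinction matters: a purely additive offset field would
slightly *inflate* the averaged map's phase range, whereas displacement
through the folds reproduces the well-known compression of averaged map
coordinates ("regression toward the horizontal meridian"): near a fold,
any displacement maps to a smaller phase, so the cross-subject average
is pulled toward mid-range, monotonically in jitter s.d. The suite
asserts exactly this monotone compression.

**Protocol defaults.** TR 1 s, 512 volumes per scan (8 min 32 s),
4 scans per modality (2 forward + 2 reversed), 3 modalities
(512 × 4 × 3 = 6144 volumes per subject), and 8 cycles per scan. The
cycle count is not a published quantity; 8 cycles give a 64-s stimulus
period, a conventional choice for phase-encoded designs, and it is
configurable. The 5-s delay shift and $\alpha = 0.05$ are defaults of
the same protocol.

# File formats

Three binary dialects are implemented bit-exactly, all big-endian:
triangle surfaces (3-byte magic `ff ff fe`, two comment lines, counts,
float32 coordinates, int32 0-based faces), annotations (per-vertex
packed `R + G·2⁸ + B·2¹⁶` colors with an embedded version-(-2)
colortable; packed 0 is the unlabeled sentinel on disk), and a
documented run container for time series. The color lookup table is
whitespace-delimited ASCII (`id name R G B A`), with the modality tag in
a trailing comment so that files remain readable by tools that ignore
comments; region names may contain commas (e.g. `7b-PICv,s`) but never
whitespace. Label content can also be exported as JSON (ids, names,
colors, per-vertex ids), the package's substitute for XML label formats.

The packaged 117-region atlas table (57 visual, 34 auditory, 20
somatosensory, 6 motor) reproduces the published region abbreviations
and modality grouping in annotation-file order. The distributed atlas
does not print RGB values, so the colors here are **synthetic**:
generated deterministically (a fixed internal linear-congruential
stream, never the global RNG) inside each modality's hue family —
visual areas blue/purple, auditory red/brown, somatomotor green/yellow —
with uniqueness of packed colors enforced. The same table ships as
`extdata/CsurfColorLUT_synthetic.txt`.

# Numerical choices and tie-breaks

* Vertex indices are 1-based inside R and converted at every file
  boundary (the on-disk dialects are 0-based).
* Spherical label resampling takes the nearest source vertex by
  great-circle distance; ties (e.g. midpoints of a subdivided mesh) go
  to the lowest source index, compared with a 1e-12 tolerance so
  floating-point summation order cannot flip the choice. Inputs must be
  spherical within 1% radial deviation.
* Tangent frames seed the first tangent from the global axis least
  aligned with the vertex normal and re-orthogonalize, so orthonormality
  holds to 1e-9 by construction.
* Circular phase range uses the largest-gap definition, which is
  rotation invariant and exact for noiseless maps.
* `significanceMask()` uses $p \le \alpha$, so the $p = 0$ sentinel of
  noiseless vertices passes any threshold, including $\alpha = 0$.

# Problem sizes and what the tests show

The test suite and the acceptance script use hexagonal patches of 6–34
rings (127–3,571 vertices), icospheres up to subdivision 3 (642
vertices), runs of 64–512 volumes, cohorts of 1–6 subjects, and
Monte-Carlo calibrations of 21,000 (single-run) and 50,000 (group)
null draws — sizes chosen so the whole suite completes in well under a
minute on one CPU while keeping binomial confidence intervals tight
enough to detect calibration errors of a fraction of a percentage
point.

Passing tests demonstrate correctness of the statistics, the geometry
and the formats under the generator's assumptions: sinusoidal responses,
AR(1) noise, smooth single-harmonic misalignment, shared mesh topology
across subjects, and maps that are piecewise-linear in cortical
coordinates. Real data violate all of these in degree — hemodynamic
responses are not perfectly sinusoidal, noise has spatial structure the
generator omits, registration errors are not single-harmonic, and real
map gradients vary. The suite therefore validates the machinery, not
the biology; published figures such as the fraction of neocortex
covered by topological maps (about 47%) or a specific millimeter FWHM
on the average surface depend on the authors' subject data and the real
average-mesh spacing, and are deliberately not asserted.

# Known limitations

* Inflation is relaxation plus area conservation, not full
  metric-preserving inflation; magnitude claims about the area bias are
  out of scope.
* The manual parcellation of a real atlas cannot be reproduced
  algorithmically; `segmentFieldsign()` is the principled automatic
  proxy and no per-area equivalence with any published figure is
  claimed.
* Spherical registration itself (driving meshes into a shared sphere)
  is out of scope; synthetic subjects share topology by construction.
* 1D (tonotopic) maps carry no field sign; their segmentation reduces
  to significance-mask components.
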