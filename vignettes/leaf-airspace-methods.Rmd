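---
title: "Quantifying leaf airspace and stomatal conductance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf airspace and stomatal conductance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafspace)
```

## The problem

Leaves trade water for carbon through stomatal pores, and the CO~2~ that
enters must diffuse through a network of intercellular airspace before it
reaches chloroplasts. X-ray computed microtomography (microCT) images this
airspace non-destructively at micrometre resolution, and a small set of
structural descriptors — mesophyll porosity, its depth profile from the
adaxial to the abaxial surface, the exposed mesophyll surface area, and the
presence of sub-stomatal cavities — can then be related to leaf-level gas
exchange (stomatal conductance $g_s$, assimilation $A_{400}$, intrinsic
water-use efficiency $A_{400}/g_s$) and to the theoretical maximum
conductance that stomatal anatomy permits.

`leafspace` implements that full analysis chain natively: segmentation of
grayscale volumes into leaf, tissue and airspace masks; voxel-counting
morphometry; a mesh-based surface-area estimator; the anatomical
$g_{s\max}$ model; and the statistical battery (Pearson correlation,
one-way ANOVA, Tukey HSD with compact letters) used to compare lines and
relate structure to function. Because raw leaf scans are large and rarely
redistributable, the package is built around a synthetic *phantom*
generator that produces seeded leaf volumes with exact voxel-level ground
truth, so that every downstream stage is testable end to end.

## The phantom: what it emulates and what it does not

A phantom is a full-width tissue slab (optionally masked to a cylindrical
leaf disc) with an airspace-free epidermis on each surface. Airspace is
carved as spherical pockets whose per-slice amount follows a parametric
porosity-versus-depth curve: porosity rises from `edge` (%) at each
epidermis to a mid-leaf `plateau` over `rise_length_um`, the shape real
depth profiles show. In `eudicot` mode the mesophyll is split at a
fractional depth into a denser palisade band and an airier spongy band
with separate plateaus. A roughly hemispherical sub-stomatal cavity is
carved beneath each stomatal site; setting `cavity_fraction < 1` emulates
arrested stomatal precursors that lack a cavity.

Pocket placement is closed-loop: candidate spheres (radius uniform in
`pocket_radius_um`) are stamped at the slice with the largest remaining
porosity deficit, and each sphere is shrunk until its per-slice
cross-sections fit the remaining deficits of every slice it touches, so
converged slices are not pushed past their target. Placement stops when
every slice is within 0.2 percentage points of its target or saturated.
On faces of 200 × 200 voxels and larger the realized mid-leaf profile
tracks the target well within ±2 pp. A requested plateau above ~90% is
rejected as unreachable with spherical pockets.

Key defaults and why:

* `voxel_size = 2.75` µm — the scan resolution the pipeline is designed
  around.
* `epidermis_thickness = 22` µm — a plausible epidermal depth (8 slices);
  the epidermis is airspace-free by construction, so thick epidermis
  dilutes whole-leaf porosity relative to the mesophyll plateau.
* `noise_sd = 10` on the 8-bit range with class means 30 (air/background)
  and 180 (tissue) — classes remain well separated (15 σ apart) while
  thresholding is genuinely exercised. Rendering refuses configurations
  with `|tissue_mean − air_mean| ≤ 4 noise_sd` as unseparable.
* `cavity_radius = 16.5` µm and pocket radii 5.5–16.5 µm — plausible
  magnitudes; no published cavity dimensions were available to fit, so
  these are defaults, not estimates.

The phantom does **not** emulate cell-wall-resolved geometry, vasculature,
anisotropic or tortuous airspace networks, beam hardening or ring
artefacts. Passing tests therefore demonstrate correctness of the
measurement chain on controlled geometry, not robustness to every
pathology of real scans.

## Segmentation

Thresholds are computed globally per volume on an exact 256-bin histogram
(restricted to the leaf mask for the tissue threshold). Two classic
algorithms are provided:

* **IsoData (Ridler–Calvard)** — the smallest intensity $t$ with
  $t = \mathrm{round}\big((\mu_{\le t} + \mu_{> t})/2\big)$ (round half
  up), found by an exhaustive scan of the 255 candidates; the scan makes
  the smallest-fixed-point tie rule exact, and equals the classical
  iteration from the histogram-mass midpoint on bimodal histograms.
* **Minimum** — repeated 3-point moving-average smoothing (mirrored ends)
  until exactly two local maxima survive (plateaus counted once, iteration
  cap 10,000), then the minimum bin strictly between them, lowest index on
  ties.

Both treat voxels strictly above the threshold as tissue (phantoms render
tissue bright); an inversion flag handles opposite-contrast data. Whether
a per-slice threshold would serve drifting illumination better is left as
a possible extension; the global choice is deterministic and matches how
single-scan stacks are usually processed.

The leaf mask is built from the thresholded foreground by morphological
closing (ball radius 2 voxels), per-slice hole filling (2D flood fill from
the slice border), and retention of the largest 26-connected component —
the minimal standard chain that yields a watertight leaf containing both
tissue and enclosed airspace. Erosion treats out-of-volume voxels as
foreground so that closing is border-preserving on full-field slabs. The
airspace mask is then exactly `leaf XOR tissue`, and the three-mask
algebra (disjointness, union) holds exactly by construction and is
asserted in tests.

## Morphometry

**Porosity** is pure voxel counting: per slice,
$100 \times \mathrm{airspace}/\mathrm{leaf}$; slices without leaf voxels
are reported absent (`NA`), not zero. The leaf-voxel-weighted mean of the
slice profile equals total porosity as an exact identity. The denominator
includes all leaf-mask voxels (epidermis included); restricting to a slice
band via the `slices` argument gives mesophyll-only figures when wanted.

**Surface area** of the tissue–airspace interface is estimated from a
triangulated iso-surface: the binary airspace mask is smoothed with a
3 × 3 × 3 box mean and the 0.5 iso-surface is triangulated by marching
tetrahedra with linear edge interpolation. Raw voxel-face counting
overestimates smooth interfaces by up to ~50% and is reported only as a
diagnostic; the smoothed mesh estimator is within 5% of the analytic area
of a radius-20-voxel sphere (measured: ~0.1%) and converges as resolution
increases. The tetrahedral decomposition has a slight orientational
anisotropy, so mesh area is reflection-invariant only to about 0.1%.
Mesh cells containing no tissue voxel are skipped, which excludes
airspace–background interfaces; whether published mesh-based descriptors
included the leaf-boundary interface is generally unstated, and this
explicit exclusion is the package's own convention. Normalisations are
per tissue volume (µm² µm⁻³) and per projected (paradermal) leaf area,
the only leaf-area notion available inside a volume.

**Sub-stomatal cavities** are 26-connected airspace components that reach
the sub-epidermal band of the chosen surface and exceed a minimum volume
(default 8,000 µm³, a sphere of radius ~12.4 µm, chosen to separate
cavities from interstitial channels at 2.75 µm voxels). Stoma matching is
lateral: a stoma is subtended when a cavity centroid lies within
`radius_um` (default 30 µm, about one stomatal complex length), each
cavity consumed by its nearest stoma.

**Layer slices.** The representative spongy slice is the porosity argmax
within a band (depth profiles consistently peak in the spongy mesophyll);
the representative palisade slice is an automated surrogate for visual
selection: the slice at a configured fractional position within the
palisade band among slices entirely within the mask.

## Anatomical maximum stomatal conductance

$$g_{s\max} \;=\; \frac{d \, D \, a_{\max}}
{v \,\bigl(l + \tfrac{\pi}{2}\sqrt{a_{\max}/\pi}\bigr)}$$

with $D$ stomatal density (mm⁻²), $a_{\max}$ mean maximum stomatal pore
area (µm²) and $l$ pore depth (µm, taken equal to guard-cell width at the
middle of the stoma); all quantities are converted to SI in one place and
round-trip-tested. The constants default to $d = 2.49\times10^{-5}$
m² s⁻¹ and $v = 2.424\times10^{-2}$ m³ mol⁻¹ (water vapour in air at
22 °C, 101.325 kPa). These standard values are configuration, not
measurements; analyses that used the rounded $\pi = 3.142$ can be
replicated via `physical_constants(pi_value = 3.142)` (the difference is
below 10⁻³ mol m⁻² s⁻¹ on realistic traits). Per-surface values are
summed to a total. When aggregating lines, density enters per leaf while
pore area and depth enter as line means (`aggregate_line_gsmax()`), the
convention used for trait tables of this kind.

## Statistics

The statistical battery is implemented natively, with base R distribution
functions (`pt`, `pf`, `pnorm`) as primitives and established
implementations (`cor.test`, `aov`, `TukeyHSD`, `ptukey`) used as
independent cross-checks in the test suite only.

* Pearson correlation uses the exact $t$ transform
  $t = r\sqrt{n-2}/\sqrt{1-r^2}$; `correlation_p_from_r2()` applies the
  same transform to a printed $r^2$ and $n$, which is how published
  correlation p-values can be re-derived without the underlying data.
* One-way ANOVA is the classical between/within decomposition.
* Tukey HSD uses the Tukey–Kramer statistic for unequal group sizes, with
  adjusted p from a studentized-range CDF computed by direct numerical
  integration (nested adaptive quadrature, relative tolerance 10⁻⁸, so the
  $k = 2$ reduction to the pooled t-test holds to ~10⁻⁶). The compact
  letter display uses insert-and-absorb over the significance graph:
  groups sharing no letter differ at the chosen α, groups sharing a letter
  do not.
* Box summaries use linear interpolation between order statistics
  (`quantile` type 7) and min/max whiskers, the convention of the figures
  this pipeline reproduces. The quartile rule is fixed because published
  figure legends rarely specify one.
* No multiplicity correction is applied across distinct reported
  correlations, mirroring common practice in this literature; within a
  Tukey family, the studentized-range adjustment applies.

## Numerical and design choices

* All volumes are `dim = c(depth, y, x)` with slice 1 at the adaxial
  surface; flipping the depth axis reverses profiles and leaves totals
  unchanged.
* Determinism: phantom generation and rendering are pure functions of
  `(config, seed)`; pipeline runs are pure functions of their `run_config`.
* Air pockets stay ≥1 voxel from lateral volume borders (and 2 voxels
  from a disc rim) so the leaf boundary is watertight and per-slice hole
  filling is exact; a consequence is that noiseless phantoms segment back
  to their truth labels *exactly*.
* Ties: argmax/argmin selections take the lowest index; IsoData takes the
  smallest fixed point; the palisade rule breaks ties toward the
  configured fractional position.
* Degenerate inputs error early with stage-tagged messages in the
  pipeline (`[sample | stage] ...`), and empty interfaces warn and return
  zeros rather than failing a whole cohort.

## Problem sizes

The test suite exercises phantoms from 40 × 50 × 50 up to
200 × 256 × 256 voxels, sphere phantoms up to radius 32, 10,000-replicate
null calibration of the ANOVA, and 100+ randomized histogram oracles;
the full suite runs in well under a minute on a single core. These sizes
were chosen as the smallest that make the tested properties
non-trivial — per-slice profile tracking needs a 200-voxel face, and the
surface-area bound is specified at sphere radius 20.

## Limitations

* The phantom's spherical-pocket airspace is isotropic and moderately
  connected; it does not reproduce the honeycomb anisotropy of real
  spongy mesophyll, so tortuosity-sensitive conclusions cannot be drawn
  from it.
* Global thresholding assumes a stationary intensity distribution within
  a scan; strong brightness gradients would need per-slice thresholds or
  flat-field correction upstream.
* Surface area is estimator-dependent at the voxel scale; comparisons
  across studies should fix the estimator, which is why results carry an
  `estimator` tag.
* Mesophyll conductance fitting, tortuosity/diffusion-path modelling and
  per-cell segmentation are out of scope.
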