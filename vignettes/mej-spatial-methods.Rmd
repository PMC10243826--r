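---
title: "Methods: spatial statistics for myoendothelial junctions en face"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial statistics for myoendothelial junctions en face}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

In resistance arteries, endothelial cells (ECs) reach through holes in the
internal elastic lamina (HIEL) to touch smooth muscle, forming myoendothelial
junctions (MEJs) — microdomains that concentrate vasodilatory signaling.
Viewed *en face* (the artery cut open, endothelium facing the objective),
HIEL appear as dark holes in a hydrazide-stained elastin sheet, and the
question is whether they sit in a particular spatial relationship to EC
signaling hubs (nuclei, endoplasmic reticulum, interendothelial junctions),
and which marker proteins or lipids (PS, Kir2.1, Cx40) occupy them.

`mejpattern` implements that analysis end to end: a synthetic field generator
with known ground truth, raster ingestion, Monte Carlo placement envelopes, a
minimum-distance statistic with a pattern verdict, marker-to-MEJ
colocalization, a stereology predictor for transverse sections, and the
pressure-myography quantification formulas.

## The core statistic and its verdict

For each HIEL center the statistic is the **minimum Euclidean distance to the
hub mask**, measured in micrometers from the center to the nearest foreground
pixel center. We compute it with an exact Euclidean distance transform
(EBImage's `distmap`, which we verified against brute-force scanning) plus a
windowed exact refinement for off-grid centers, so `min_distances()` equals
an exhaustive all-pairs scan to floating-point precision. Distance is from
the HIEL *center* to the nearest *mask pixel*, not hub centroids or HIEL
edges, because hub masks are irregular.

The observed distance distribution is compared against three simulated
envelopes that match the observed HIEL count per replicate:

* **PC** (positive control): every center within 1 µm of the hub;
* **NC** (negative control): every center between 1.5 and 4.5 µm;
* **RAND**: centers uniform over the field (complete spatial randomness).

PC/NC replicates use the mean observed diameter for every simulated HIEL;
RAND draws diameters uniformly over the observed range. Distances from all
replicates of a group are pooled into one sample per group, matching
single-box-plot-per-group reporting with HIEL-level n. The replicate count
is not fixed by the original description; the default is 100, and the
package's own recovery experiments use 20 (the pooled simulated sample then
already dwarfs the per-field observed n of ≈492, so test power is
insensitive to the choice).

Before testing, the real-world sample passes through robust outlier removal
(ROUT with Q = 1%). The published ROUT procedure is a robust regression
followed by an FDR-controlled test of the residual tail; adapted here to the
constant-location model, the robust fit is the median, the robust scale is
the 68.27th percentile of absolute residuals inflated by N/(N−1), each point
gets a t-ratio with a two-tailed p-value on N−1 df, and the ordered tail is
tested by a Benjamini–Hochberg pass at rate Q. Exact equivalence to the
proprietary implementation is not guaranteed; the procedure is oracle-tested
step by step, removed points are logged, and n is reported both before and
after removal.

Testing follows the original analysis: Welch's ANOVA across the four groups
(with the Brown–Forsythe F\* statistic reported alongside — there is no base
R implementation, so it is computed from its closed form with Satterthwaite
degrees of freedom), then pairwise Welch t-tests of REAL against each
simulated group adjusted by Holm–Šidák step-down, at α = 0.05. The verdict
label is driven by the adjusted pairwise tests:

| REAL vs RAND | REAL vs PC | REAL vs NC | label |
|---|---|---|---|
| not rejected | rejected | rejected | `random` |
| rejected | not rejected | rejected | `hub_associated` |
| rejected | rejected | not rejected | `hub_excluded` |
| anything else | | | `inconclusive` |

Only the `random` case is defined by the original analysis; the other two
labels are a documented extension, and degenerate zero-variance ties yield
p = 1 (identical groups are `inconclusive`, never spuriously labeled).

One subtlety is intrinsic to this design: when the real field truly follows
one of the mechanisms, the comparison against its own envelope is a true
null, so at α = 0.05 about 5% of fields land in `inconclusive` purely by
type-I error. The recovery experiments therefore check a ≥90% rate over
seeds rather than perfection.

```{r, eval = FALSE}
library(mejpattern)
spec <- field_spec(placement_mode = "PC", hub_kind = "nuclei", seed = 1)
field <- synthesize_field(spec)
d <- envelope_distances(field$hiel, field$hub,
                        sim_config(n_replicates = 20, seed = 2),
                        spec$px_size_um)
verdict <- compare_groups(d)
glance(verdict)
autoplot(verdict)
```

## The synthetic generator

No public imaging dataset accompanies this workflow, so the generator is
the package's test bed; its defaults are the study conditions stated with
the analysis, not tuning knobs:

* **Field**: 200 × 200 µm at 0.5 µm/pixel. A typical imaged region of
  interest is ≈1.4 × 10⁴ µm² with ≈17 ECs; a 4 × 10⁴ µm² field with 50
  cells gives the ~800 µm²-per-EC geometry of the quantified arteries while
  matching the "≈50 fully in-view ECs" unit of analysis.
* **Tessellation**: a seeded Voronoi tessellation rasterized to a label
  matrix (the manual claudin-5 tracing of real data is out of scope; Voronoi
  matches the cobblestone EC morphology). Every pixel belongs to exactly one
  cell, so areas sum to the field exactly, and point-in-cell assignment is a
  label lookup.
* **Hubs**: one nuclear ellipse (3.5 × 2.5 µm semi-axes, random orientation)
  per cell; ER as a 2 µm perinuclear annulus; junctions as rasterized cell
  borders including the field frame.
* **HIEL**: 9.83 per cell, realized as a fixed `round(n_cells × rate)` by
  default (Poisson optional) — fixed counts make envelope tests sharper.
  Diameters uniform in 0.5–2.5 µm; no numeric diameter range is available
  to reproduce, so the range is a configuration choice.
* **Placement**: PC/NC centers are drawn uniformly among the pixel centers
  whose exact distance-transform value lies in the band. This is the same
  distance-transform criterion as rejection sampling but with the band
  guarantee by construction and no rejection loop; the consequence — PC/NC
  centers sit at pixel centers while RAND centers are continuous — is
  immaterial at 0.5 µm pixels and is re-asserted element-wise in tests.
* **Puncta**: each marker occupies each HIEL Bernoulli-independently at its
  configured fraction (PS 13.8% by default). Pairwise co-occupancy
  (e.g. P(PS | Kir2.1-positive) = 5/6) is honored by conditional draws on
  the conditioning marker, with the draw on negative HIEL compensated so the
  marginal is preserved; configurations whose implied joint exceeds a
  marginal are rejected. Puncta are placed within half the assignment radius
  of their HIEL so detection recovers them. Background (non-MEJ) puncta
  default to 0 because only the MEJ-resident fraction is quantified.
* **Rendering**: Gaussian blobs (σ = diameter/4, floored at 0.35 µm so
  sub-pixel HIEL still rise above threshold) plus additive Gaussian noise
  (σ = 0.05 against unit blob amplitude). Everything is bit-reproducible
  from the field seed.

What the generator does *not* emulate: stitching artifacts, z-stacks,
non-convex cell shapes, uneven illumination, autofluorescence, or spatially
correlated noise. Passing tests show the statistics recover known truth
under idealized imaging; they do not validate thresholding choices on real
microscopy.

## Colocalization rules

A punctum belongs to an HIEL when its center lies within **0.75 µm** of the
HIEL center, read inclusively (a distance of exactly 0.75 counts). A punctum
within the radius of several HIEL goes to the nearest, with exact ties
broken by the lowest HIEL id, making assignment a deterministic function.
Occupancy is presence/absence per HIEL (multiple puncta of one marker in one
HIEL count once), and co-occupancy is directional: of the marker-A-positive
HIEL, the fraction also positive for B. Per-EC statistics use fully in-view
cells; synthetic Voronoi cells tile the frame and all count as in view,
while traced polygon inputs can carry an `in_view` flag for the
border-exclusion rule. The identity
`overall mean = conditional mean × fraction with ≥1` holds algebraically on
any dataset and is tested to machine precision.

## Stereology

With areal HIEL density ρ = N/A measured en face, a transverse section of
thickness t (70 nm) intersects a disc of diameter d lying in the lamina
plane whenever the disc center falls in a band of width d + t, so the
expected profile count per IEL length L is **ρ (d + t) L**. The package
returns the interval over the diameter range and checks an observed density
against it. The exact algebra of the original workbook is not available, so this
band-overlap form — the standard
profile-count derivation consistent with the stated symbol legend — is
validated against a Monte Carlo sectioning oracle (discs scattered on the
unrolled cylinder, sections spaced ≥5 µm apart per the double-counting
guard) within 3 SE over a 3 × 3 grid of (ρ, d). Curvature is ignored
(d ≪ C), and grazing incidence is not modeled. Reported bounds for this quantity derive
from measurements not available here, so they are not desk-reproducible;
the formula accepts any measured parameter set.

## Vasoreactivity

The adopted diameter formulas are the conventional ones consistent with
the standard variable definitions: tone = 100(D_pass − D_act)/D_pass; change vs 20 mmHg =
100(D_x − D_20)/D_20; dilation = 100(D_resp − D_pe)/(D_max − D_pe); lipid
response = 100(D_post − D_eq)/D_eq. Trace handling reports the extremum in
the observation window with time-to-peak rounded to the nearest half-minute,
and an optional filter excludes responses where the diameter re-constricts
below baseline after a transient peak. Dose-response assembly uses the
NS309 ladder (0.1, 0.3, 0.5, 0.6, 1, 2 µM) and excludes arteries lacking a
maximal diameter.

## Intensity quantification

Coverage is the percent of pixels above an explicit black cutoff; the
low/high split index replaces a display lookup-table boundary ("the last
blue bin") with explicit configuration, since the original cutoffs were
chosen visually and are not recorded. Empty pixels (index 0) are excluded
from the low bin, and the three bins always partition the image. Punctum
counts and areas are normalized to the control-group mean, which makes the
normalized control mean exactly 1.

## Numerical choices and problem sizes

Coordinates are 0-based pixels with centers at half-integer micrometer
offsets; all distances are in micrometers. Connected components default to
8-connectivity (4 available); EBImage's 4-connected labeling is extended to
8 by a union-find merge of diagonally touching labels. Flat images refuse
Otsu thresholding rather than returning a degenerate mask. The package's
own experiments run at: 200 random masks (≤128²) for distance-oracle
equality; 10 fields × 100 replicates for band assertions; 50 seeds × 3
mechanisms at 50 cells × 9.83 HIEL with 20 replicates for recovery; 5,000
HIEL for occupancy recovery; 10⁴ sections for the stereology check — sizes
chosen so the full suite completes on a laptop-class single core in a few
minutes while keeping every comparison well-powered.

## Known limitations

The verdict's `hub_associated`/`hub_excluded` labels extend the original
random-vs-not logic and should be read as such. ROUT here is a faithful
re-derivation, not a bit-match of the commercial implementation. The
stereology model treats HIEL as coplanar discs. The generator's noise model
is additive white Gaussian; detection behavior on real confocal noise will
differ and threshold choices remain per-image configuration, exactly as in
the original workflow.
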