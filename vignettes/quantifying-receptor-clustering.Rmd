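---
title: "Quantifying receptor–ligand clustering from DNA-PAINT localizations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor–ligand clustering from DNA-PAINT localizations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`paintnnd` turns drift-corrected, channel-aligned DNA-PAINT localization
tables into statements about molecular organization: whether receptors
dimerize or oligomerize, whether a labeled ligand co-localizes with its
receptor, and how receptor–ligand complexes rearrange during
internalization. This vignette explains the model behind each stage, the
parameters that matter, the numerical choices the package makes, and what
its synthetic-data tests do and do not demonstrate about real data.

## From localizations to protein positions

A DNA-PAINT channel records many localizations per target molecule, each
with a per-axis precision estimate (`lpx`, `lpy`, and for 3D data `lpz`,
all in nm). The package models a protein site as a circular cluster of
localizations and reduces it to a single position in three deterministic
steps.

**Local maxima.** Localization density is measured as the neighbor count
within a *detection scale* of `radius / 2`; a localization is a candidate
site when its count is at least `min_locs` and no localization within the
detection scale has a higher count (count ties go to the lower record
index, so results are reproducible). Detecting at half the grouping radius
is a deliberate choice: with the default `radius = 10` nm and 2 nm
localization scatter, the two members of a ligand pair 11 nm apart produce
a clearly bimodal localization density, and counting at the full radius
would always fuse them — the count is maximized *between* the two sites
and the single winner suppresses the other. Counting at 5 nm keeps each
site's own peak dominant while the 10 nm membership radius still collects
each site's full cloud. The exact local-maximum rule used by upstream
SMLM software is not standardized; the rule above is this package's
definition.

**Assignment.** Every localization within `radius` of at least one
maximum joins the nearest maximum (exact distance ties to the lower
cluster id); the rest stay unassigned. Groups that end with fewer than
`min_locs` members are dropped.

**Weighted center.** Each group collapses to the precision-weighted mean
per axis, with weights equal to the squared inverse precision of that
axis (`1/lpx²` for x, and so on). This is the minimum-variance combination
under independent Gaussian errors; with homogeneous precisions it reduces
to the arithmetic mean, and its error shrinks as `σ/√n` (both are tested).

Defaults: `radius = 10` nm (3–5× the 2–3 nm lateral precision typical of
DNA-PAINT), `min_locs = 10`. Both are arguments everywhere. Clustering
distances are lateral (x, y) by default because axial precision is
substantially worse than lateral on most 3D SMLM setups; `use_z = TRUE`
switches to 3D distances, and `z` is always carried through to the
weighted center. Multi-round re-localization averaging (RESI-style
sequential imaging) is out of scope: each channel is treated as one round.

## NND statistics and the CSR null

`first_nnd()` gives each protein position its distance to the nearest
*other* position in the same channel; `cross_nnd(query, reference)` gives
each query position its distance to the nearest reference position
(asymmetric, no self-exclusion — the channels are distinct molecules).
Both use an `Rcpp` uniform-grid index with expanding-ring search, so the
five-million-point null below is a seconds-scale computation; brute-force
`O(n²)` oracles exist only in the test suite.

The null model is complete spatial randomness (CSR): `simulate_csr()`
draws `n_molecules` uniform points in a square sized so the density
equals the *measured* density (positions inside an explicit region of
interest divided by its area). The default of 5 × 10⁶ molecules makes the
null curve essentially noise-free. No edge correction is applied to
either the experimental or the simulated NNDs: at that ensemble size the
boundary-affected fraction is negligible, and typical cell-scale ROIs
leave well under a percent of positions within 200 nm of the boundary.
The one place edge effects would genuinely bias a result — testing the
generator's all-monomer output against the closed-form CSR law
`p(r) = 2πρr·exp(−πρr²)` — is handled in the tests by restricting *query*
points to the region interior while keeping all points as neighbor
candidates, which removes the bias without correcting the pipeline.

ROIs are simple polygons in nm (JSON lists of `[x, y]` vertices on disk);
boundary points count as inside, for determinism. Because acquisition
software differs in what it exports, the package requires an explicit ROI
for density estimation rather than guessing a field of view; a bounding
rectangle of the data (`run_condition()`'s default) is the pragmatic
choice when no hand-drawn cell outline exists.

## The Δ-area statistic

Experimental and CSR NND values are histogrammed on identical bins
(default 5 nm, right-open, aligned to zero) and normalized to integrate
to 1 over the evaluation range (default 0–200 nm). The statistic is the
positive part of the experimental excess:

Δ area = Σ over bins in [0, 200] nm of max(0, h_exp − h_CSR) × bin size.

Two choices deserve comment:

* **Direction.** Δ area measures the experimental histogram's area
  *above* the CSR curve, i.e. excess short distances = clustering. The
  opposite sign order would measure anti-clustering; the adopted
  direction matches the orderings the statistic is meant to detect
  (untreated < treated, unbound label < bound label).
* **Normalization range.** Normalizing over the same 0–200 nm window that
  the sum runs over makes the bound Δ area ≤ 1 exact (a positive part of
  a difference of two unit densities) and makes the statistic insensitive
  to the long-distance tail, which depends on density rather than on
  molecular-scale structure. `norm_range = NULL` switches to full-range
  normalization when the tail is of interest.

Per-condition curves are summarized bin-wise by the mean and *population*
standard deviation across cells (the conventional "mean ± STD" band for
small-N per-condition summaries; `pop_sd` divides by n). Per-cell Δ areas
are compared across conditions with the classical one-way equal-variance
ANOVA (`stats::oneway.test(var.equal = TRUE)`), whose F statistic is
referred to its upper tail — the F test is inherently one-sided.
Post-hoc pairwise tests are deliberately absent. Stars: `***` p < 0.001,
`**` p < 0.01, `*` p < 0.05, `n.s.` otherwise.

For cross-NND the null needs both channels randomized: the package
simulates independent CSR ensembles at each channel's measured density in
a common frame and takes the cross-NND between them. Randomizing only one
channel would leave residual structure from the other and understate the
null's short-distance mass.

## Axial layers and internalization staging

For 3D data, `axial_profile()` histograms z (default 5 nm bins) and fits
a single Gaussian (amplitude, center, width) to the bin counts by
Levenberg–Marquardt least squares with moment-based starting values; if
the fit fails to converge the modal bin center is used, and an exactly
constant z column returns that value itself. A Gaussian fit was chosen
over the raw modal bin because it is insensitive to bin-edge placement at
the 5 nm bin width; the histogram peaks here are layer positions, and a
fitted center is stable to a fraction of a bin. `peak_separation()` is
the absolute difference of two fitted peaks — symmetric and
translation-invariant, recovering a 25 nm two-layer offset to well within
±2 nm at 2,000 positions per layer.

`region_nnd_series()` computes per-region 3D first-NND histograms on
shared bins with each region's modal bin center. Regions (membrane,
clustered membrane, vesicle) are user-supplied ROI labels, not detected
automatically — staging is a biological judgment the analyst makes.

## What the synthetic generator emulates

`generate_scene()` builds ground-truth membrane patches with the
statistical structure the analyses assume:

| parameter | default | meaning |
|---|---|---|
| `receptor_density` | 20 µm⁻² | surface density; an order-of-magnitude choice, real cells vary widely |
| `fractions` | all monomer | receptor share per group kind |
| `dimer_separation` | 11 nm | exact partner spacing, the structure-derived ligand-pair distance on a receptor dimer |
| `cluster_diameter` | 200–500 nm | oligomer cluster size range (disc-uniform members) |
| `vesicle_diameter` / `vesicle_depth` | 150 nm / 200 nm | sphere-surface groups below the membrane; ligands on an inner shell, pointing into the lumen |
| `ligand_offset_xy` | 17 nm | lateral label-to-label offset of a bound ligand, random orientation |
| `axial_offset` | 25 nm | ligand minus receptor z for membrane-bound pairs |
| `ligand_occupancy` | 1 | probability a receptor carries a bound ligand |
| `labeling_efficiency` | 0.4 | per-molecule Bernoulli labeling, the realistic efficiency of nanobody-based DNA-PAINT labeling |

`simulate_localizations()` is the forward model: per labeled molecule a
Poisson number of events (default mean 50), each at the true position
plus independent Gaussian noise whose σ is recorded verbatim as the
localization precision. Per-event precisions default to lognormal
(median 2 nm lateral / 5 nm axial, log-sd 0.3) to mimic photon-count
variation; fixed σ is available for controlled tests. Vesicle diameter,
depth and the lognormal constants are this package's own modeling
choices, not measured values.

Deliberately **not** emulated: imager blinking kinetics and frame
correlation (integrated out into the event count), detection background
and false localizations, drift and channel misalignment residuals,
multi-round merging, and camera-frame image formation. Passing the
end-to-end tests therefore shows the *analysis* chain is correct and
well-calibrated on clean forward-model data; it does not certify
robustness to uncorrected acquisition artifacts, which must be handled
upstream.

## Verification strategy and problem sizes

The test suite checks every operation against an independent route:
hand-computed examples, brute-force `O(n²)` and direct-arithmetic
oracles, closed-form limits (the CSR NND law), distributional bounds
(binomial, chi-square, CLT), and parameter-recovery runs through the full
stack. The standard batch uses scenes of 500–2,000 molecules with 30–50
events per site, CSR ensembles of 10⁴–2 × 10⁵ points, 20-seed null
calibrations and a 1,000-replication ANOVA type-I-error check — sizes
chosen so the whole suite completes in about a minute and a half while
leaving each statistical assertion with comfortable power. Key calibration
facts the tests establish: an all-monomer condition yields Δ area < 0.05
per cell; two independent 10⁵-point CSR samples give a median Δ area
below 0.02; Δ area increases strictly with dimer fraction; and the
pipeline recovers an 11 nm pair spacing, a 17 nm cross-channel offset
(each within one 5 nm bin) and a 25 nm axial offset (within 2 nm).

## Known limitations

* Proteins closer than about the detection scale (5 nm at defaults) fuse
  into one position; conversely, heavily over-sampled single sites are
  never split, but a site with fewer than `min_locs` events vanishes.
  Counts recovered from sparse labeling are *labeled*-molecule counts.
* Δ area conflates all forms of short-distance excess (dimerization,
  oligomer clustering, co-localization); it orders conditions but does
  not decompose mechanism.
* The CSR null assumes a homogeneous region; applying it to an ROI with
  large protein-free holes (organelles, membrane folds) inflates Δ area.
  Draw ROIs over homogeneous membrane.
* File exchange is CSV (with the conventional `frame, x, y, z, photons,
  lpx, lpy, lpz` columns) and JSON for ROIs and reports; binary
  localization containers from acquisition software should be exported to
  CSV upstream.
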