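# paintnnd

Quantification of membrane receptor–ligand oligomerization and
co-localization from DNA-PAINT single-molecule localization microscopy
(SMLM) data.

DNA-PAINT resolves individual membrane proteins — e.g. EGF ligands bound to
the EGF receptor — as clouds of repeated localizations a few nanometres
wide. To ask biological questions ("do receptors dimerize after ligand
treatment?", "does the labeled ligand actually sit on its receptor?"),
those clouds must be reduced to single protein positions and their spatial
arrangement compared against randomness. `paintnnd` implements that whole
chain:

1. **Protein positions** — localizations are grouped around local density
   maxima and collapsed to precision-weighted centers, with weights
   `w_i = 1 / lp_i²` (squared inverse localization precision, per axis).
2. **NND statistics** — first nearest-neighbor distances (NND) within a
   channel and cross-NND from a query channel (ligand) to a reference
   channel (receptor).
3. **CSR null** — complete spatial randomness simulated at the *measured*
   protein density (default 5 × 10⁶ molecules), giving the no-clustering
   reference NND curve.
4. **Δ area** — the headline statistic. With both NND histograms
   normalized to unit area over 0–200 nm (5 nm bins),

   ```
   Δ area = Σ_bins max(0, h_exp(b) − h_CSR(b)) · bin_size   ∈ [0, 1]
   ```

   the area of the experimental NND histogram lying *above* the CSR
   curve. 0 ⇒ random arrangement; larger ⇒ more
   clustering/co-localization.
5. **Condition comparison** — per-cell Δ areas summarized as mean ±
   population SD and compared across treatments by one-way ANOVA
   (upper-tail F test, stars at p < 0.001 / 0.01 / 0.05).
6. **3D analysis** — axial (z) histograms per channel with Gaussian-fitted
   peaks; the peak-to-peak distance separates e.g. an intracellular
   receptor-label layer from an extracellular ligand layer, and
   per-region 3D NND series stage receptor internalization.
7. **Synthetic ground truth** — a scene generator (monomers, exact-spacing
   dimers, 200–500 nm oligomer clusters, vesicles, partial labeling) and a
   DNA-PAINT forward model (Poisson event counts, Gaussian scatter at the
   recorded precision), so every stage is testable end to end without raw
   data.

Everything is data-frame first: localization tables, protein positions and
histograms are tibbles, results have `tidy()`/`glance()`/`autoplot()`
methods, and steps chain with the pipe.

## Worked example

A half-monomer, half-dimer membrane patch (10 receptors/µm² over
100 µm², 11 nm dimer spacing), imaged in silico and pushed through the
pipeline:

```r
library(paintnnd)

params <- scene_params(receptor_density = 10, area_um2 = 100,
                       fractions = c(monomer = 0.5, dimer = 0.5,
                                     cluster = 0, vesicle = 0),
                       labeling_efficiency = 1)
scene <- generate_scene(params, seed = 1)
locs <- simulate_localizations(
  scene, acquisition_model(mean_events = 30, sigma_xy = 2, sigma_z = 5),
  seed = 2)

receptors <- cluster_channel(dplyr::filter(locs, channel == "receptor"),
                             radius = 10, min_locs = 10)
nrow(receptors)
#> [1] 991

rho <- estimate_density(receptors, roi_rect(0, 1e4, 0, 1e4))
rho
#> [1] 9.91

obs  <- nnd_histogram(first_nnd(receptors)$nnd)
null <- nnd_histogram(first_nnd(simulate_csr(rho, 1e5, seed = 3))$nnd)
delta_area(obs, null, label = "dimer-rich")
#> <delta_area> dimer-rich: 0.5987 (bin 5 nm over [0, 200] nm)

modal_bin_center(obs)
#> [1] 12.5
```

1,000 ground-truth receptors come back as 991 positions; the measured
density matches; the NND mode lands in the 10–15 nm bin containing the
generating 11 nm spacing; and the Δ area of 0.60 reflects the strong
dimer excess over CSR (an all-monomer scene gives Δ area < 0.05).

For multi-cell, multi-condition studies see `run_condition()` and
`run_report()`, which produce per-cell Δ-area tables, mean ± SD curves,
the ANOVA table with significance stars, and a CSV/JSON report bundle.

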