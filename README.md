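# nucleotess

Delaunay-tessellation analysis of two-channel 3D single-molecule
localization microscopy (dSTORM) data of mitochondrial nucleoids: how
large are nucleoids, and how many mtDNA molecules does each one carry?

Mitochondrial DNA is packaged into nucleoids. Imaging a nucleoid stain
(anti-DNA) in one color and a sequence-specific mtDNA hybridization
probe (e.g. against the D-loop/7S region, one copy per mtDNA molecule)
in a second color yields two registered 3D point clouds of fluorophore
blinks. This package implements the full computational pipeline over
such point clouds, for microscopists and image analysts working with
localization tables rather than pixel images.

## Method core

* **Segmentation.** The point cloud is tetrahedralized (3D Delaunay,
  own Bowyer–Watson implementation in compiled code); tetrahedra with
  any edge ≥ `A_max` (default 80 nm) are culled, and connected surviving
  tetrahedra form one object with polyhedron volume `V_D`. Localizations
  outside all surviving tetrahedra form the exclusion set. Objects with
  ≤ 10 localizations are dropped.
* **Models.** Volume-equivalent spheres `d_D = (6 V_D / π)^{1/3}` (and
  `d_smooth` from the convexified polyhedron), plus a PCA rotational
  ellipsoid with `(π/6) d_max d_min² = V_D`, tilt
  `θ = arctan(√(a_x² + a_y²) / |a_z|)`, and an orientation filter at
  θ = 45°.
* **Loci counting (n_mtDNA).** A two-step procedure: mixed-channel
  segmentation at 80 nm, then per-channel re-tessellation inside each
  mixed object (nucleoid channel at the most frequent first-pass
  diameter, probe channel at the 80 nm probe extent). Probe components
  closer than 80 nm merge into one locus; each locus is assigned to the
  nearest refined nucleoid. Histograms report percentages over
  nucleoids with ≥ 1 locus and the weighted average restricted to
  n < 7.
* **Spatial statistics.** Cumulative pair counts `H(r)`, the unedged 3D
  Ripley estimator `K(r) = 2 V n⁻² H(r)`, `L(r) = (3K/4π)^{1/3}` with
  `L(r) − r` as the clustering score, ε-binned inter-distance histograms
  and their local maxima (MFDs), and two-sample histogram ratios.
* **Scene-level numbers.** Nucleoid spatial density ρ_nucl (per µm³ of
  the localization convex hull), condition fold-changes, and the qPCR
  copy number `C_N = mito / (nuclear/2)`.
* **Synthetic ground truth.** A generator for two-channel scenes —
  nucleoids along tubules at ~1 µm spacing, 20 nm antibody shells,
  10–500 localizations per nucleoid, σ_xy = 15 / σ_z = 30 nm noise,
  probes carrying a label every 40 nt (6 labels at 250 bp, 27 at
  1100 bp) — with per-localization parent labels as the recovery
  oracle.

## Worked example

```r
library(nucleotess)

sp <- scene_spec(stain_fill = "volume", background_density = 0,
                 loci_min_gap = 160, diameter_meanlog = log(220),
                 diameter_sdlog = 0.3, diameter_range = c(100, 400),
                 n_tubules = 3, box = c(8000, 8000, 3000), seed = 42L)
sim <- simulate_scene(sp)
ch  <- split_channels(sim$table)
ov  <- count_overlaps(ch[["1"]], ch[["2"]])
print(ov)
count_histogram(ov)
recovery_rate(ov, sim$truth)
nucleoid_density(ov, sim$table)
```

prints

```
overlap_result: 4 nucleoid(s) (4 with >=1 locus), 0 orphan loci
  second-pass A_max = 255 nm; dispositions: excluded_mixed=3, locus=87, nucleoid=1665
count_histogram: 4 nucleoid(s) with overlaps (= 100%), 0 with none
  n = 1:  75.0% (3)
  n = 2:  25.0% (1)
  weighted average (n < 7): 1.25
recovery_result: 100.0% exact (4/4 true nucleoids; 4 records)
density_result: 4 nucleoid(s) in 2.368 um^3 (hull) -> rho_nucl = 1.689 /um^3
```

Reading it: the mixed segmentation found 4 nucleoids; every one of the
1755 localizations has a recorded disposition (nucleoid body, probe
locus, or excluded); three nucleoids contained one probe locus and one
contained two, giving a weighted average of 1.25 mtDNA molecules per
nucleoid; all counts match the generator's ground truth exactly; and
the nucleoid density over the imaged (hull) volume is 1.7 /µm³.

The numbered scripts under `analysis/` run the same machinery as a
narrative workflow — `01` simulates and archives a reference scene,
`02` segments and models nucleoids, `03` counts loci per nucleoid,
`04` computes the Ripley/inter-distance statistics with a CSR control,
`05` derives densities, fold changes and copy numbers — each writing
its tables under `results/`. Run them from the repository root, e.g.
`Rscript analysis/03_count_overlaps.R`.

The methods vignette (`vignettes/nucleoid-tessellation.Rmd`) documents
the model, the parameter defaults and their units, the generator's
assumptions, numerical tie-breaks, and known limitations.

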