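#!/usr/bin/env Rscript
# Generate the reference synthetic two-channel dSTORM scene and archive
# it (localization CSV per channel + ground-truth JSON). Downstream
# scripts re-derive everything from these files or from the same spec.

source("analysis/common.R")
out <- results_dir("scene")

sp <- default_scene()
sim <- simulate_scene(sp)
print(sim$table)
print(sim$truth)

ch <- split_channels(sim$table)
write_localizations(ch[["1"]], file.path(out, "channel1_nucleoids.csv"))
write_localizations(ch[["2"]], file.path(out, "channel2_probes.csv"))
write_ground_truth(sim$truth, file.path(out, "ground_truth.json"))
write_vtk_points(sim$table, file.path(out, "scene.vtk"))

per <- table(sim$truth$parent$parent)
cat(sprintf(
  "\nScene (seed %d): %d nucleoids, %d planted loci.\n", sp$seed,
  nrow(sim$truth$nucleoids), nrow(sim$truth$loci)))
cat(sprintf(
  "Localizations: %d nucleoid-stain, %d probe, %d background.\n",
  per[["nucleoid"]], per[["locus"]],
  if ("background" %in% names(per)) per[["background"]] else 0L))
cat("Wrote channel CSVs, ground truth and a VTK point cloud to",
    out, "\n")
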