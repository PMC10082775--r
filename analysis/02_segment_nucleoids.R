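#!/usr/bin/env Rscript
# Single-channel nucleoid segmentation: Delaunay tessellation of the
# nucleoid-stain channel, A_max culling, sphere/ellipsoid modeling, and
# the diameter distribution with its most frequent value (MFD).

source("analysis/common.R")
out <- results_dir("segmentation")

scene_dir <- file.path("results", "scene")
tb <- if (file.exists(file.path(scene_dir, "channel1_nucleoids.csv"))) {
  read_localizations(file.path(scene_dir, "channel1_nucleoids.csv"))
} else {
  split_channels(simulate_scene(default_scene())$table)[["1"]]
}

a_max <- 80  # first-pass culling threshold (nm)
cx <- delaunay_tessellate(tb)
cx <- cull_tetrahedra(cx, a_max)
seg <- segment(cx)
print(seg)

objs <- filter_min_localizations(seg$objects, 10)
cat(sprintf("%d objects survive the >10-localization filter (of %d).\n",
            length(objs), length(seg$objects)))

rows <- do.call(rbind, lapply(seq_along(objs), function(i) {
  o <- objs[[i]]
  sm <- sphere_model(o, cx)
  em <- ellipsoid_model(o, cx)
  data.frame(id = i, n_localizations = o$n_localizations,
             v_d = o$volume_vd, d_d = sm$d_d, d_smooth = sm$d_smooth,
             d_max = em$d_max, d_min = em$d_min, theta = em$theta)
}))
write.csv(rows, file.path(out, "nucleoid_models.csv"), row.names = FALSE)

dd <- diameter_distribution(rows$d_d, bin_width = 10)
print(dd)
write.csv(data.frame(bin_start = dd$bin_edges[-length(dd$bin_edges)],
                     bin_end = dd$bin_edges[-1], count = dd$counts),
          file.path(out, "diameter_distribution.csv"), row.names = FALSE)

kept <- orientation_filter(lapply(objs, ellipsoid_model, complex = cx))
cat(sprintf(
  "Orientation filter (theta >= 45 deg kept): %d of %d models remain.\n",
  length(kept), length(objs)))
cat(sprintf("First-pass diameter MFD: %g nm (this MFD is the second-pass",
            dd$mfd), "A_max of the overlap analysis).\n")
write_vtk_tetrahedra(cx, file.path(out, "culled_tetrahedra.vtk"), seg)
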