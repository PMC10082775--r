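# Shared scene definitions for the analysis scripts. Everything is a pure
# function of the seeds fixed here, so each script can be run on its own
# from the repository root.

library(nucleotess)

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# the reference acquisition: shell-stained nucleoids along tubules with
# realistic noise, blinking and background
default_scene <- function(seed = 101L)
  scene_spec(seed = seed)

# scene for loci counting: volume staining (probes hybridize throughout
# the mtDNA volume), loci separated beyond the noise-broadened merge
# radius so that counts are identifiable
counting_scene <- function(seed = 201L)
  scene_spec(stain_fill = "volume", background_density = 0,
             loci_min_gap = 160,
             diameter_meanlog = log(220), diameter_sdlog = 0.3,
             diameter_range = c(100, 400), n_tubules = 6, seed = seed)
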