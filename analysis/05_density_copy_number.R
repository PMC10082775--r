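#!/usr/bin/env Rscript
# Scene-level quantities: nucleoid spatial density rho_nucl for two
# conditions differing in true nucleoid abundance, their fold change, and
# the qPCR-ratio mtDNA copy number.

source("analysis/common.R")
out <- results_dir("density")

run_density <- function(n_tubules, seed) {
  sim <- simulate_scene(scene_spec(n_tubules = n_tubules,
                                   background_density = 0.5, seed = seed))
  ch <- split_channels(sim$table)
  ov <- count_overlaps(ch[["1"]], ch[["2"]])
  list(density = nucleoid_density(ov, sim$table),
       n_true = nrow(sim$truth$nucleoids))
}

hi <- run_density(5, 401L)  # condition with more nucleoids
lo <- run_density(3, 402L)  # reference condition
print(hi$density)
print(lo$density)
fc <- fold_change(hi$density, lo$density)
cat(sprintf("Density fold change: %.2f (true count ratio %.2f).\n",
            fc, hi$n_true / lo$n_true))

# qPCR ratio: mitochondrial amplicon over half the (diploid) nuclear one
cn_a <- copy_number(mito_amount = 1500, nuclear_amount = 2)
cn_b <- copy_number(mito_amount = 300, nuclear_amount = 2)
print(cn_a); print(cn_b)
cat(sprintf("Copy-number ratio between conditions: %.2f.\n",
            cn_b$c_n / cn_a$c_n))

jsonlite::write_json(
  list(rho_hi = hi$density$rho_nucl, rho_lo = lo$density$rho_nucl,
       fold_change = fc, true_count_ratio = hi$n_true / lo$n_true,
       c_n_a = cn_a$c_n, c_n_b = cn_b$c_n),
  file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
cat("Wrote", file.path(out, "summary.json"), "\n")
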