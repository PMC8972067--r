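#!/usr/bin/env Rscript

# Simulate the four study groups (nondysplastic BE, BE before a later
# dysplasia diagnosis, BE adjacent to dysplasia, post-esophagectomy neo-BE)
# under the gland-fission model and write the gland/variant tables plus the
# ground-truth genealogy that the downstream analyses consume.

suppressPackageStartupMessages(library(begland))
suppressPackageStartupMessages(library(readr))

seed <- 20260922
out_dir <- file.path("results", "cohorts")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

presets <- scenario_presets()
for (i in seq_along(presets)) {
  name <- names(presets)[i]
  sim <- simulate_cohort(presets[[name]], seed = seed + i)
  write_gland_table(sim$glands, file.path(out_dir, paste0(name, "_glands.tsv")))
  write_variant_table(sim$variants,
                      file.path(out_dir, paste0(name, "_variants.tsv")))
  write_tsv(sim$genealogy, file.path(out_dir, paste0(name, "_genealogy.tsv")),
            na = "NA")
  write_tsv(sim$truth_clones,
            file.path(out_dir, paste0(name, "_truth_clones.tsv")), na = "NA")
  writeLines(sim$polymorphisms,
             file.path(out_dir, paste0(name, "_polymorphisms.txt")))
  message(sprintf(
    "%-18s %2d patients, %3d biopsied glands, %4d variant rows (seed %d)",
    name, presets[[name]]$n_patients, nrow(sim$glands),
    sum(sim$variants$var_class != "none"), seed + i))
}
message("cohort tables written to ", out_dir)
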