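#!/usr/bin/env Rscript

# Classify the simulated nondysplastic cohort from marker profiles and
# summarise the phenotype landscape: per-phenotype gland frequencies and
# the distribution of phenotypes-per-biopsy (most biopsies carry one or two
# phenotypes; three is rare).

suppressPackageStartupMessages(library(begland))
suppressPackageStartupMessages(library(readr))

in_dir <- file.path("results", "cohorts")
out_dir <- "results"
if (!file.exists(file.path(in_dir, "nondysplastic_glands.tsv"))) {
  stop("run analysis/01_simulate_cohorts.R first")
}

glands <- read_gland_table(file.path(in_dir, "nondysplastic_glands.tsv"))
glands <- classify_glands(glands[, setdiff(names(glands), "phenotype")])

freq <- as.data.frame(table(glands$phenotype))
names(freq) <- c("phenotype", "n_glands")
freq$percentage <- round(100 * freq$n_glands / sum(freq$n_glands), 2)
write_tsv(freq, file.path(out_dir, "phenotype_frequencies.tsv"))

div <- diversity_by_specimen(glands)
summary <- phenotype_count_summary(div$richness)
write_tsv(summary, file.path(out_dir, "phenotypes_per_biopsy.tsv"))

message("phenotype frequencies (nondysplastic cohort):")
for (i in seq_len(nrow(freq))) {
  message(sprintf("  %-18s %4d glands (%5.2f%%)", freq$phenotype[i],
                  freq$n_glands[i], freq$percentage[i]))
}
message("phenotypes per biopsy:")
for (i in seq_len(nrow(summary))) {
  message(sprintf("  %d phenotype(s): %3d biopsies (%5.2f%%)",
                  summary$n_phenotypes[i], summary$n_specimens[i],
                  summary$percentage[i]))
}
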