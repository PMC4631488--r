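#!/usr/bin/env Rscript
# Step 1: generate the synthetic study population.
#
# Emulates the breeding design behind the HSP70 immune-response study:
# 20 sires each mated to 3 dams (60 full-sib families), 5-10 measured
# offspring per family, every offspring measured as a young adult (year 1)
# and ~73% of them again near harvest (year 2), on both haemolymph
# fractions. Writes pedigree/phenotypes/truth CSVs for the later steps.

suppressPackageStartupMessages(library(immunoQG))

seed <- 2015L
cfg <- sim_config(seed = seed)
ds <- simulate_dataset(cfg)

outdir <- file.path("results", "data")
paths <- write_dataset(ds, outdir)

phen <- ds$phenotypes
cat("Simulated study population (seed", seed, ")\n")
cat(sprintf("  families: %d, animals: %d, phenotype records: %d\n",
            length(unique(phen$family)), nrow(ds$pedigree), nrow(phen)))
for (fr in unique(phen$fraction)) {
  for (yr in 1:2) {
    v <- phen$value[phen$fraction == fr & phen$year == yr]
    cat(sprintf("  %-14s year %d: n = %3d, mean = %5.2f, SD = %5.2f\n",
                fr, yr, length(v), mean(v), sd(v)))
  }
}
cat("written:", paste(basename(paths), collapse = ", "), "->", outdir, "\n")
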