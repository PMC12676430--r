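#!/usr/bin/env Rscript
# Simulate the default eight-population cohort (kdr haplotype classes paired
# under Hardy-Weinberg, neutral background sites, detox-gene copy numbers)
# and write the VCF, metadata, annotation, CN table and ground truth.
source("analysis/00_common.R")

cfg <- default_cohort_config()
cohort <- simulate_kdr_cohort(cfg$specs, seed = SEED,
                              class_private_sites = cfg$class_private_sites)
cn <- simulate_cn_table(cfg$specs, cfg$annotation, seed = SEED,
                        metadata = cohort$metadata)
paths <- write_cohort(cohort, cn, cfg$annotation, COHORT_DIR)

cat(sprintf("simulated %d samples x %d variants across %d populations\n",
            dim(cohort$genotypes$calls)[1], dim(cohort$genotypes$calls)[2],
            length(cfg$specs)))
cat(sprintf("files written under %s:\n  %s\n", COHORT_DIR,
            paste(basename(paths), collapse = "\n  ")))
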