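#!/usr/bin/env Rscript
# Vgsc diversity statistics per population: segregating sites, multiallelic
# fraction, theta-pi, Watterson's theta and Tajima's D.
source("analysis/00_common.R")

d <- load_cohort()
dv <- diversity_stats(d$variants, d$genotypes, d$metadata)
write_result_table(dv, file.path(TABLE_DIR, "diversity.tsv"))

print(dv, digits = 3)
cat(sprintf("\nmean theta-pi %.4g; mean Tajima's D %+.3f (positive values point\n",
            mean(dv$theta_pi), mean(dv$tajima_d, na.rm = TRUE)))
cat("to an excess of intermediate-frequency alleles, as expected when\n")
cat("resistance haplotype classes segregate at intermediate frequencies)\n")
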