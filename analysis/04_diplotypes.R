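#!/usr/bin/env Rscript
# Diplotype-group classification at the 995/402/1527 panel, group frequencies
# per population, UPGMA genotype clustering and Patterson-scaled PCA.
source("analysis/00_common.R")

d <- load_cohort()
panel <- kdr_panel()
calls <- classify_diplotypes(d$variants, d$genotypes, panel)
write_result_table(calls, file.path(TABLE_DIR, "diplotype_calls.tsv"))
freqs <- diplotype_frequencies(calls, d$metadata)
write_result_table(freqs, file.path(TABLE_DIR, "diplotype_frequencies.tsv"))

cat("diplotype group counts:\n")
print(table(calls$group))

cl <- genotype_clustering(d$genotypes)
write_dendrogram_newick(cl, file.path(TABLE_DIR, "diplotype_dendrogram.nwk"))

dos <- dosage_matrix(d$variants, d$genotypes)
pc <- pca_dosage(dos, maf_min = 0.01)
write_result_table(
  data.frame(sample_id = rownames(pc$scores), round(pc$scores[, 1:4], 6)),
  file.path(TABLE_DIR, "pca_coordinates.tsv"))
cat(sprintf("\nPCA explained-variance fractions (PC1-4): %s\n",
            paste(sprintf("%.3f", pc$explained[1:4]), collapse = ", ")))
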