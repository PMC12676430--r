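#!/usr/bin/env Rscript
# Copy-number states of the detoxification genes, amp/del frequencies per
# population and gene-level family x arm summaries.
source("analysis/00_common.R")

d <- load_cohort()
calls <- classify_cnv(d$cn_table, d$metadata, d$annotation)
write_result_table(calls, file.path(TABLE_DIR, "cnv_calls.tsv"))
freqs <- cnv_frequencies(calls, d$metadata)
write_result_table(freqs, file.path(TABLE_DIR, "cnv_frequencies.tsv"))
summ <- cnv_gene_summary(calls, d$annotation)
write_result_table(summ$total, file.path(TABLE_DIR, "cnv_gene_totals.tsv"))
write_result_table(summ$by_group, file.path(TABLE_DIR, "cnv_gene_by_group.tsv"))
write_result_table(cnv_scatter_export(calls, d$metadata, d$annotation),
                   file.path(TABLE_DIR, "cnv_scatter.tsv"))

cat("genes with >=1 amplification / deletion / any CNV:\n")
print(summ$total)
top <- freqs[order(-freqs$amp_freq_pct), ][1:5, ]
cat("\nhighest amplification frequencies:\n")
print(top, digits = 3)
cat(sprintf("\nmax modal copy number observed: %d\n", max(calls$cn)))
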