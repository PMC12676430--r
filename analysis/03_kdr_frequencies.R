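#!/usr/bin/env Rscript
# kdr allele frequencies per population, the cumulative triallelic 402L row,
# and the cluster-map ordering of the variant x population frequency matrix.
source("analysis/00_common.R")

d <- load_cohort()
panel <- kdr_panel()
ft <- allele_frequencies(d$genotypes, d$variants, d$metadata,
                         min_freq = 0.05, apply_filter = TRUE, panel = panel)
write_result_table(ft, file.path(TABLE_DIR, "allele_frequencies.tsv"))

pos402 <- panel$loci[["402"]]$pos
cum <- ft[ft$effect_label %in% "V402L_cumulative", ]
t1527 <- ft[ft$pos == panel$loci[["1527"]]$pos, ]
cat("cumulative 402L frequency vs 1527T frequency per population:\n")
print(merge(cum[, c("population", "frequency")],
            t1527[, c("population", "frequency")],
            by = "population", suffixes = c("_402L_cum", "_1527T")),
      digits = 3)

base <- ft[!ft$effect_label %in% "V402L_cumulative", ]
key <- paste0(base$pos, "_", base$alt)
mat <- tapply(base$frequency, list(key, base$population), mean)
mat[is.na(mat)] <- 0
ord <- cluster_map_order(mat)
write_result_table(
  data.frame(axis = c(rep("variant", nrow(mat)), rep("population", ncol(mat))),
             name = c(rownames(mat)[ord$row_order], colnames(mat)[ord$col_order]),
             rank = c(seq_len(nrow(mat)), seq_len(ncol(mat)))),
  file.path(TABLE_DIR, "cluster_map_order.tsv"))
cat(sprintf("\nclustered frequency matrix: %d variants x %d populations\n",
            nrow(mat), ncol(mat)))
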