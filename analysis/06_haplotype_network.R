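#!/usr/bin/env Rscript
# Median-joining haplotype network over the kdr panel plus cross-population
# shared variation, coloured by diplotype group, exported as DOT.
source("analysis/00_common.R")

d <- load_cohort()
panel <- kdr_panel()
vidx <- kdrpopgen:::panel_variant_index(d$variants, panel)
shared <- kdrpopgen:::network_site_filter(d$variants, d$genotypes, d$metadata)
keep <- sort(union(vidx, which(shared)))
h <- haplotype_rows(d$genotypes, variant_idx = keep)
calls <- classify_diplotypes(d$variants, d$genotypes, panel)
ann <- data.frame(
  species = rep(d$metadata$species[match(d$genotypes$samples,
                                         d$metadata$sample_id)], each = 2),
  group = rep(calls$group, each = 2))
col <- collapse_haplotypes(h, ann)
net <- median_joining(col, epsilon = 0)
print(net)
writeLines(network_to_dot(net, color_by = "group"),
           file.path(TABLE_DIR, "haplotype_network.dot"))
cat(sprintf("network written over %d sites; %d sampled haplotype nodes\n",
            length(keep), sum(!net$inferred)))
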