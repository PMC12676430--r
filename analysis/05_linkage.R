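#!/usr/bin/env Rscript
# EM maximum-likelihood linkage disequilibrium between each 402L mutant allele
# and 1527T, per site and pooled over the An. coluzzii cohort.
source("analysis/00_common.R")

d <- load_cohort()
col_md <- d$metadata[d$metadata$species == "An_coluzzii", ]
lt <- ld_table(d$variants, d$genotypes, col_md, pooled_label = "An_coluzzii")
write_result_table(lt, file.path(TABLE_DIR, "ld_table.tsv"))

wide <- reshape(lt[, c("population", "allele_pair", "n", "r2")],
                idvar = c("population", "n"), timevar = "allele_pair",
                direction = "wide")
print(wide, digits = 3)
pooled <- lt[lt$population == "An_coluzzii", ]
cat(sprintf("\npooled r2: 402L(g>t) vs 1527T = %.3f; 402L(g>c) vs 1527T = %.3f\n",
            pooled$r2[pooled$allele_pair == "402L(g>t) vs 1527T"],
            pooled$r2[pooled$allele_pair == "402L(g>c) vs 1527T"]))
cat("the g>t allele travels with 1527T; the rare g>c allele does not\n")
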