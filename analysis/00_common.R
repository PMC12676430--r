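# shared settings for the analysis scripts: run from the repository root with
#   Rscript analysis/01_simulate_cohort.R   (then 02..07 in any order)
suppressMessages(library(kdrpopgen))

SEED <- 2022
COHORT_DIR <- "results/cohort"
TABLE_DIR <- "results/tables"
dir.create(TABLE_DIR, recursive = TRUE, showWarnings = FALSE)

load_cohort <- function() {
  vcf <- file.path(COHORT_DIR, "cohort.vcf")
  if (!file.exists(vcf))
    stop("cohort not found; run analysis/01_simulate_cohort.R first")
  loaded <- read_genotype_vcf(vcf)
  list(variants = loaded$variants, genotypes = loaded$genotypes,
       metadata = read_metadata(file.path(COHORT_DIR, "metadata.tsv")),
       annotation = read_gene_annotation(file.path(COHORT_DIR, "annotation.tsv")),
       cn_table = read_cn_table(file.path(COHORT_DIR, "cn_table.tsv")))
}
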