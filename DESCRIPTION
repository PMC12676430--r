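Package: kdrpopgen
Title: Population Genomics of Insecticide Target-Site Resistance in Anopheles gambiae s.l.
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for analysing insecticide-resistance variation in Anopheles
    gambiae sensu lato cohorts: nucleotide diversity statistics (segregating
    sites, multiallelic accounting, theta-pi, Watterson's theta, Tajima's D) in
    the voltage-gated sodium channel gene, codon-level effect annotation and
    kdr allele frequencies including the triallelic V402L locus, diplotype-group
    classification at the 995/402/1527 panel, EM maximum-likelihood haplotype
    frequencies and linkage disequilibrium r-squared from unphased diploid
    genotypes, median-joining haplotype networks, and copy-number-variation
    frequency summaries for detoxification gene families. Includes a seeded
    synthetic-cohort generator with retained ground truth and a deterministic
    end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    Biostrings,
    ape,
    igraph,
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
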