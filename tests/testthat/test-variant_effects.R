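toy_tx <- function(strand = "+") {
  # CDS ATG CTG TAA at positions 1-9, padded reference
  transcript_model("toy", strand, data.frame(start = 1, end = 9),
                   paste0("ATGCTGTAA", strrep("A", 11)), 1)
}

test_that("codon annotation labels missense, synonymous and intronic alleles", {
  v <- variant_table(rep("2L", 3), c(5, 6, 15), c("T", "G", "A"),
                     list("A", "A", "C"))
  av <- annotate_effects(v, toy_tx())
  expect_equal(unlist(av$effect_labels), c("L2Q", "synonymous", "intronic"))
})

test_that("reference mismatches are reported with their position", {
  v <- variant_table("2L", 5, "C", list("A"))
  expect_error(annotate_effects(v, toy_tx()), "2L:5")
})

test_that("multiallelic sites are annotated per alternate allele", {
  v <- variant_table("2L", 5, "T", list(c("A", "G")))
  av <- annotate_effects(v, toy_tx())
  expect_equal(av$effect_labels[[1]], c("L2Q", "L2R"))
})

test_that("annotation is strand-involutive", {
  # reverse-complement construction of the same toy CDS placed at 1-9:
  # revcomp(ATGCTGTAA) = TTACAGCAT read on the minus strand
  fwd <- toy_tx("+")
  rev_seq <- paste0(strrep("T", 0), "TTACAGCAT", strrep("T", 11))
  rev <- transcript_model("toy_rev", "-", data.frame(start = 1, end = 9),
                          rev_seq, 1)
  # position 5 on the forward toy (codon 2 pos 2) maps to position 5 on the
  # reverse construction (9 - 5 + 1 = 5); T>A forward is A>T on the plus
  # strand of the reverse-complemented layout
  v_fwd <- variant_table("2L", 5, "T", list("A"))
  v_rev <- variant_table("2L", 5, "A", list("T"))
  expect_equal(annotate_effects(v_fwd, fwd)$effect_labels[[1]],
               annotate_effects(v_rev, rev)$effect_labels[[1]])
})

test_that("allele frequencies count alt alleles over non-missing calls", {
  v <- variant_table("2L", 10, "A", list("T"))
  calls <- array(0L, c(10, 1, 2))
  calls[1, 1, 2] <- 1L    # one heterozygote among 10 diploids
  g <- genotype_matrix(calls, samples = sprintf("S%d", 1:10))
  md <- data.frame(sample_id = sprintf("S%d", 1:10), species = "An_coluzzii",
                   site = "Bana", zone = "Sudanian", sex = "F")
  ft <- allele_frequencies(g, v, md, apply_filter = FALSE)
  expect_equal(ft$frequency, 0.05)
  expect_equal(ft$count, 1)
  expect_equal(ft$total, 20)
})

test_that("all-reference populations report zero frequency and zero-call cells are flagged", {
  v <- variant_table("2L", 10, "A", list("T"))
  calls <- array(0L, c(4, 1, 2))
  calls[3:4, 1, ] <- -1L
  g <- genotype_matrix(calls, samples = sprintf("S%d", 1:4))
  md <- data.frame(sample_id = sprintf("S%d", 1:4), species = "An_coluzzii",
                   site = c("Bana", "Bana", "Gama", "Gama"),
                   zone = "Sudanian", sex = "F")
  ft <- allele_frequencies(g, v, md, apply_filter = FALSE)
  expect_equal(ft$frequency[ft$population == "Bana"], 0)
  expect_true(is.na(ft$frequency[ft$population == "Gama"]))
  expect_false(ft$defined[ft$population == "Gama"])
})

test_that("the cumulative 402L row sums the two mutant-allele frequencies", {
  panel <- kdr_panel()
  co <- simulate_kdr_cohort(small_specs(n1 = 50, n2 = 10), seed = 44)
  ft <- allele_frequencies(co$genotypes, co$variants, co$metadata,
                           apply_filter = FALSE, panel = panel)
  l402 <- panel$loci[["402"]]
  for (p in unique(ft$population)) {
    sub <- ft[ft$population == p & ft$pos == l402$pos, ]
    cum <- sub$frequency[sub$effect_label %in% "V402L_cumulative"]
    per <- sub$frequency[!sub$effect_label %in% "V402L_cumulative"]
    expect_equal(cum, sum(per))
  }
  # strict linkage in the generator: cumulative 402L equals the 1527T frequency
  l1527 <- panel$loci[["1527"]]
  for (p in unique(ft$population)) {
    cum <- ft$frequency[ft$population == p & ft$pos == l402$pos &
                        ft$effect_label %in% "V402L_cumulative"]
    t_freq <- ft$frequency[ft$population == p & ft$pos == l1527$pos]
    expect_equal(cum, t_freq, tolerance = 1e-12)
  }
})

test_that("panel-locus frequencies equal generator truth exactly", {
  co <- simulate_kdr_cohort(small_specs(n1 = 50, n2 = 10), seed = 45)
  panel <- kdr_panel()
  ft <- allele_frequencies(co$genotypes, co$variants, co$metadata,
                           apply_filter = FALSE)
  tr <- co$truth$haplotypes
  for (p in c("Bana", "Po-Dongo")) {
    drawn <- c(tr$hap1[tr$population == p], tr$hap2[tr$population == p])
    f995F <- mean(substr(drawn, 1, 1) == "F")
    got <- ft$frequency[ft$population == p &
                        ft$pos == panel$loci[["995"]]$pos & ft$alt == "T"]
    expect_equal(got, f995F, tolerance = 1e-12)
  }
})

test_that("the reporting filter keeps rows passing the threshold in any population", {
  v <- variant_table(rep("2L", 2), c(10, 20), c("A", "C"), list("T", "G"))
  calls <- array(0L, c(4, 2, 2))
  calls[1, 1, ] <- 1L                     # site 1: frequency 0.5 in Bana
  calls[3, 2, 1] <- 1L                    # site 2: frequency 0.25 in Gama
  g <- genotype_matrix(calls, samples = sprintf("S%d", 1:4))
  md <- data.frame(sample_id = sprintf("S%d", 1:4), species = "An_coluzzii",
                   site = c("Bana", "Bana", "Gama", "Gama"),
                   zone = "Sudanian", sex = "F")
  ft <- allele_frequencies(g, v, md, min_freq = 0.3, apply_filter = TRUE)
  expect_setequal(unique(ft$pos), 10)
})

test_that("effect-class site summary reports multiallelic and non-synonymous percentages", {
  v <- variant_table(rep("2L", 4), c(10, 20, 30, 40), c("A", "C", "G", "T"),
                     list("T", "G", c("T", "C"), "A"),
                     effect_labels = list("L2Q", "synonymous",
                                          c("V3L", "V3L"), "intronic"))
  calls <- array(0L, c(2, 4, 2))
  calls[1, 1, 1] <- 1L
  calls[1, 2, 1] <- 1L
  calls[, 3, 1] <- c(1L, 2L)
  g <- genotype_matrix(calls, samples = c("S1", "S2"))
  s <- effect_site_summary(v, g)
  expect_equal(s$S, 3)
  expect_equal(s$n_nonsynonymous, 2)
  expect_equal(s$nonsynonymous_pct, 100 * 2 / 3)
  expect_equal(s$n_multiallelic, 1)
})

test_that("label aliases rename transcript-numbered effects to community names", {
  expect_equal(apply_label_aliases(c("L1014F", "synonymous"),
                                   c(L1014F = "L995F")),
               c("L995F", "synonymous"))
})
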