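test_that("degenerate haplotype mixtures give all-wild-type cohorts", {
  sp <- population_spec("P", "An_coluzzii", "Bana", "Sudanian", 50,
                        c(LVI = 1.0))
  co <- simulate_kdr_cohort(list(sp), seed = 1)
  vidx <- kdrpopgen:::panel_variant_index(co$variants, kdr_panel())
  expect_true(all(co$genotypes$calls[, vidx, ] == 0L))
  expect_true(all(co$truth$haplotypes$hap1 == "LVI"))
})

test_that("the generator is deterministic for a fixed seed", {
  a <- simulate_kdr_cohort(small_specs(), seed = 9, class_private_sites = 1)
  b <- simulate_kdr_cohort(small_specs(), seed = 9, class_private_sites = 1)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$haplotypes, b$truth$haplotypes)
  d <- simulate_kdr_cohort(small_specs(), seed = 10, class_private_sites = 1)
  expect_false(identical(a$genotypes$calls, d$genotypes$calls))
})

test_that("haplotype-class frequencies follow the binomial sampling model", {
  sp <- population_spec("P", "An_coluzzii", "Bana", "Sudanian", 1000,
                        c(FVI = 0.5, LL1T = 0.5))
  co <- simulate_kdr_cohort(list(sp), seed = 21)
  drawn <- c(co$truth$haplotypes$hap1, co$truth$haplotypes$hap2)
  p_hat <- mean(drawn == "FVI")
  se <- sqrt(0.5 * 0.5 / 2000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("frequencies must sum to one before any sampling happens", {
  expect_error(population_spec("P", "An_coluzzii", "Bana", "Sudanian", 10,
                               c(FVI = 0.6, LVI = 0.6)), "sum to 1")
})

test_that("neutral sites are polymorphic by construction and S=0 is allowed", {
  H <- simulate_neutral_sites(20, 0, seed = 1)
  expect_equal(dim(H), c(20, 0))
  H <- simulate_neutral_sites(12, 300, seed = 2)
  counts <- colSums(H)
  expect_true(all(counts >= 1 & counts <= 11))
  # low-frequency classes dominate under the 1/k spectrum
  expect_gt(mean(counts <= 3), mean(counts >= 9))
})

test_that("copy-number generation respects baselines and amp/del frequencies", {
  ann <- data.frame(gene_id = c("G_AUTO", "G_X"), gene_name = c("a", "x"),
                    family = c("CYP", "CYP"), contig = c("2R", "X"),
                    start = c(1L, 1L), end = c(10L, 10L))
  sp <- population_spec("P", "An_coluzzii", "Bana", "Sudanian", 500,
                        c(LVI = 1.0), sex_ratio = 0.5,
                        cn_specs = list(
                          G_AUTO = list(amp_freq = 0.8, del_freq = 0),
                          G_X = list(amp_freq = 0, del_freq = 0)))
  cn <- simulate_cn_table(list(sp), ann, seed = 3)
  auto <- cn$cn_table[cn$cn_table$gene_id == "G_AUTO", ]
  amp_hat <- mean(auto$cn > 2)
  expect_lt(abs(amp_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 500))
  expect_true(all(auto$cn[auto$cn <= 2] == 2))
  # X baseline is hemizygous in males, diploid in females
  xg <- cn$cn_table[cn$cn_table$gene_id == "G_X", ]
  expect_true(all(xg$cn %in% c(1L, 2L)))
  expect_true(any(xg$cn == 1L) && any(xg$cn == 2L))
})

test_that("classifying emitted phased genotypes recovers the truth pairs exactly", {
  co <- simulate_kdr_cohort(small_specs(n1 = 60, n2 = 20), seed = 13,
                            class_private_sites = 2)
  calls <- classify_diplotypes(co$variants, co$genotypes, kdr_panel())
  tr <- co$truth$haplotypes
  ok <- mapply(function(h1, h2, g1, g2)
    (h1 == g1 && h2 == g2) || (h1 == g2 && h2 == g1),
    calls$hap1, calls$hap2, tr$hap1, tr$hap2)
  expect_true(all(ok))
})

test_that("phased-count r2 from drawn haplotypes approaches the mixture-implied value", {
  # haplotype classes: T occurs on LL1T (with L1) and LL2T (with L2)
  freqs <- c(LVI = 0.35, FVI = 0.30, LL1T = 0.32, LL2T = 0.03)
  sp <- population_spec("P", "An_coluzzii", "Bana", "Sudanian", 10000, freqs)
  co <- simulate_kdr_cohort(list(sp), seed = 17)
  p_L1 <- unname(freqs["LL1T"])
  p_T <- unname(freqs["LL1T"] + freqs["LL2T"])
  D <- p_L1 - p_L1 * p_T
  r2_expected <- D^2 / (p_L1 * (1 - p_L1) * p_T * (1 - p_T))
  r2_obs <- co$truth$r2$r2[co$truth$r2$population == "Bana" &
                           co$truth$r2$allele_pair == "402L(g>t) vs 1527T"]
  expect_lt(abs(r2_obs - r2_expected), 0.02)
})

test_that("the default cohort configuration loads and matches the study layout", {
  cfg <- default_cohort_config()
  expect_length(cfg$specs, 8)
  species <- vapply(cfg$specs, `[[`, "", "species")
  expect_true(all(c("An_coluzzii", "An_gambiae_ss", "An_arabiensis") %in% species))
  zones <- vapply(cfg$specs, `[[`, "", "zone")
  expect_setequal(unique(zones), c("Sudanian", "Sudano_Sahelian", "Sahelian"))
  # gambiae s.s. fixed for FVI; arabiensis carries SVI
  gam <- cfg$specs[[which(species == "An_gambiae_ss")[1]]]
  expect_equal(unname(gam$kdr_hap_freqs["FVI"]), 1.0)
  ara <- cfg$specs[[which(species == "An_arabiensis")[1]]]
  expect_true("SVI" %in% names(ara$kdr_hap_freqs))
})
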