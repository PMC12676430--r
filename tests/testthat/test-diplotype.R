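panel <- kdr_panel()

test_that("haplotype labelling is a pure table lookup over the panel", {
  expect_equal(label_haplotype(c(0, 0, 0), panel), "LVI")
  expect_equal(label_haplotype(c(1, 0, 0), panel), "FVI")
  expect_equal(label_haplotype(c(0, 1, 1), panel), "LL1T")
  expect_equal(label_haplotype(c(0, 2, 1), panel), "LL2T")
  expect_equal(label_haplotype(c(2, 0, 0), panel), "SVI")
  expect_error(label_haplotype(c(3, 0, 0), panel), "not in panel map")
})

# build a genotype fixture holding given phased haplotype pairs at the panel
panel_cohort <- function(pairs, phased = TRUE) {
  v <- variant_table(
    rep("2L", 3),
    sort(vapply(panel$loci, `[[`, 1L, "pos")),
    vapply(panel$loci, `[[`, "", "ref")[order(vapply(panel$loci, `[[`, 1L, "pos"))],
    lapply(panel$loci, `[[`, "alts")[order(vapply(panel$loci, `[[`, 1L, "pos"))])
  ord <- order(vapply(panel$loci, `[[`, 1L, "pos"))
  n <- length(pairs)
  calls <- array(-1L, c(n, 3, 2))
  for (s in seq_len(n)) {
    h1 <- kdrpopgen:::label_to_alleles(pairs[[s]][1], panel)
    h2 <- kdrpopgen:::label_to_alleles(pairs[[s]][2], panel)
    calls[s, , 1] <- h1[ord]
    calls[s, , 2] <- h2[ord]
  }
  g <- genotype_matrix(calls, phased = phased, samples = sprintf("S%d", seq_len(n)))
  list(variants = v, genotypes = g)
}

test_that("phased diplotype pairs map to the named groups and OD", {
  fx <- panel_cohort(list(c("FVI", "FVI"), c("FL1T", "LVI"), c("FVI", "SVI"),
                          c("LL1T", "LL2T"), c("FL2T", "LVI"), c("LVI", "LVI")))
  calls <- classify_diplotypes(fx$variants, fx$genotypes, panel)
  expect_equal(calls$group,
               c("FVI/FVI", "FL1T/LVI", "OD", "LL1T/LL2T", "FL2T/LVI", "OD"))
  expect_false(any(calls$ambiguous))
})

test_that("the unphased triple heterozygote resolves by the coupling rule, flagged ambiguous", {
  fx <- panel_cohort(list(c("FL1T", "LVI")), phased = FALSE)
  calls <- classify_diplotypes(fx$variants, fx$genotypes, panel, phased = FALSE)
  expect_equal(calls$group, "FL1T/LVI")
  expect_true(calls$ambiguous)
  # the same genotype arises from the FVI/LL1T phase: identical call
  fx2 <- panel_cohort(list(c("FVI", "LL1T")), phased = FALSE)
  calls2 <- classify_diplotypes(fx2$variants, fx2$genotypes, panel, phased = FALSE)
  expect_equal(calls2$group, "FL1T/LVI")
  expect_true(calls2$ambiguous)
})

test_that("missing panel calls yield OD with the missing flag, not an exception", {
  fx <- panel_cohort(list(c("FVI", "FVI")))
  fx$genotypes$calls[1, 2, 1] <- -1L
  calls <- classify_diplotypes(fx$variants, fx$genotypes, panel)
  expect_equal(calls$group, "OD")
  expect_true(calls$missing)
})

test_that("unphased classification agrees with phased whenever unambiguous", {
  co <- simulate_kdr_cohort(small_specs(n1 = 60, n2 = 20), seed = 51)
  ph <- classify_diplotypes(co$variants, co$genotypes, panel, phased = TRUE)
  un <- classify_diplotypes(co$variants, co$genotypes, panel, phased = FALSE)
  agree <- ph$group[!un$ambiguous] == un$group[!un$ambiguous]
  expect_true(all(agree))
})

test_that("diplotype frequencies partition each population", {
  co <- simulate_kdr_cohort(small_specs(), seed = 52)
  calls <- classify_diplotypes(co$variants, co$genotypes, panel)
  freqs <- diplotype_frequencies(calls, co$metadata)
  for (p in unique(freqs$population)) {
    expect_equal(sum(freqs$frequency[freqs$population == p]), 1,
                 tolerance = 1e-9)
  }
  # invariant to sample order
  perm <- sample(nrow(calls))
  freqs2 <- diplotype_frequencies(calls[perm, ], co$metadata)
  m <- merge(freqs, freqs2, by = c("population", "group"))
  expect_equal(m$frequency.x, m$frequency.y)
})

test_that("a single-sample population yields frequencies in {0,1}", {
  fx <- panel_cohort(list(c("FVI", "FVI")))
  md <- data.frame(sample_id = "S1", species = "An_gambiae_ss", site = "Po-Dongo",
                   zone = "Sudanian", sex = "F")
  calls <- classify_diplotypes(fx$variants, fx$genotypes, panel)
  freqs <- diplotype_frequencies(calls, md)
  expect_equal(freqs$frequency, 1)
})

test_that("UPGMA genotype clustering merges identical samples at height zero", {
  fx <- panel_cohort(list(c("FVI", "FVI"), c("FVI", "FVI"), c("LL1T", "LL1T")))
  cl <- genotype_clustering(fx$genotypes)
  expect_equal(min(cl$hclust$height), 0)
  expect_true(all(cl$dist == t(cl$dist)))
  expect_true(all(diag(cl$dist) == 0))
})

test_that("cutting the tree at k recovers generated diplotype structure", {
  specs <- list(
    population_spec("A", "An_coluzzii", "Bana", "Sudanian", 20, c(LVI = 1.0)),
    population_spec("B", "An_coluzzii", "Gama", "Sudano_Sahelian", 20, c(FL1T = 1.0)),
    population_spec("C", "An_arabiensis", "Nassan", "Sudano_Sahelian", 20, c(SVI = 1.0)))
  co <- simulate_kdr_cohort(specs, seed = 61, class_private_sites = 2)
  cl <- genotype_clustering(co$genotypes)
  k3 <- stats::cutree(cl$hclust, k = 3)
  truth <- rep(1:3, each = 20)
  expect_gte(rand_index(k3[co$genotypes$samples], truth), 0.95)
})

test_that("dosage PCA separates divergent haplotype classes and reports sane variance fractions", {
  specs <- list(
    population_spec("A", "An_coluzzii", "Bana", "Sudanian", 50, c(LVI = 1.0)),
    population_spec("B", "An_coluzzii", "Gama", "Sudano_Sahelian", 50, c(LL1T = 1.0)))
  co <- simulate_kdr_cohort(specs, seed = 62, class_private_sites = 3)
  dos <- dosage_matrix(co$variants, co$genotypes)
  pc <- pca_dosage(dos, maf_min = 0.01)
  grp <- rep(1:2, each = 50)
  pc1 <- pc$scores[, 1]
  expect_true(max(pc1[grp == 1]) < min(pc1[grp == 2]) ||
              max(pc1[grp == 2]) < min(pc1[grp == 1]))
  expect_true(all(diff(pc$explained) <= 1e-9))
  expect_lte(sum(pc$explained), 1 + 1e-9)
})

test_that("PCA degenerate inputs raise errors", {
  expect_error(pca_dosage(matrix(1, 5, 3)), "zero-variance")
  expect_error(pca_dosage(matrix(0, 5, 3)), "maf")
  expect_error(pca_dosage(matrix(1, 1, 3)), ">= 2")
})

test_that("cluster-map ordering separates block structure and keeps duplicates adjacent", {
  expect_equal(cluster_map_order(matrix(1:4, 1))$row_order, 1)
  # two variant blocks private to two population blocks
  m <- rbind(c(0.9, 0.8, 0.0, 0.0),
             c(0.0, 0.0, 0.7, 0.9),
             c(0.8, 0.9, 0.0, 0.0),
             c(0.0, 0.0, 0.8, 0.8))
  ord <- cluster_map_order(m)
  ro <- ord$row_order
  block <- c(1, 2, 1, 2)[ro]
  expect_true(all(diff(which(block == 1)) == 1))
  # duplicated rows end up adjacent
  m2 <- rbind(c(1, 0, 0), c(0, 1, 1), c(1, 0, 0))
  ro2 <- cluster_map_order(m2)$row_order
  expect_equal(abs(diff(which(ro2 %in% c(1, 3)))), 1)
})
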