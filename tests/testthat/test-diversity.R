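worked_haplotypes <- matrix(c(0, 0, 0,
                              0, 0, 1,
                              0, 1, 1,
                              1, 1, 1), 4, 3, byrow = TRUE)

test_that("segregating-site counting handles monomorphic and triallelic cases", {
  # 3 variants: monomorphic, biallelic, triallelic observed
  v <- variant_table(rep("2L", 3), c(10, 20, 30), c("A", "C", "G"),
                     list("T", "G", c("T", "C")))
  calls <- array(0L, c(2, 3, 2))
  calls[, 2, 1] <- c(0L, 1L)              # het + hom-ref: segregating
  calls[, 3, 1] <- c(0L, 2L)              # three observed alleles
  calls[, 3, 2] <- c(1L, 2L)
  g <- genotype_matrix(calls, phased = FALSE, samples = c("S1", "S2"))
  seg <- count_segregating(v, g)
  expect_equal(seg$S, 2)
  expect_equal(seg$multiallelic_fraction, 0.5)
  # identical homozygous samples: S = 0, fraction undefined
  g0 <- genotype_matrix(array(0L, c(2, 3, 2)), samples = c("S1", "S2"))
  seg0 <- count_segregating(v, g0)
  expect_equal(seg0$S, 0)
  expect_true(is.na(seg0$multiallelic_fraction))
  expect_error(count_segregating(v, g, samples = character(0)), "empty")
})

test_that("nucleotide diversity matches hand-enumerated pairwise differences", {
  expect_equal(nucleotide_diversity(matrix(0L, 3, 5), 5), 0)
  two <- rbind(rep(0, 100), c(1, rep(0, 99)))
  expect_equal(nucleotide_diversity(two, 100), 0.01)
  # all 6 pairs of the worked 4-haplotype instance: 1+2+3+1+2+1 = 10
  expect_equal(nucleotide_diversity(worked_haplotypes, 3), 10 / 6 / 3)
  expect_error(nucleotide_diversity(worked_haplotypes[1, , drop = FALSE], 3),
               ">= 2")
})

test_that("Watterson's estimator uses the harmonic-number constant", {
  expect_equal(watterson_theta(5, 2, 10), 0.5)
  expect_equal(watterson_theta(3, 4, 3), 3 / ((1 + 1/2 + 1/3) * 3))
  expect_equal(watterson_theta(0, 10, 100), 0)
})

test_that("Tajima's D agrees with an independent constant-by-constant computation", {
  td <- tajimas_d(worked_haplotypes, 3)
  # independent oracle: recompute every constant from scratch
  n <- 4; S <- 3; Pi <- 10 / 6
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D_oracle <- (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(td$D, D_oracle, tolerance = 1e-12)
  expect_equal(td$D, 0.1677, tolerance = 1e-3)
})

test_that("S = 0 yields an undefined (not zero) Tajima's D", {
  td <- tajimas_d(matrix(0L, 6, 4), 4)
  expect_false(td$defined)
  expect_true(is.na(td$D))
  expect_equal(td$theta_pi, 0)
})

test_that("an excess of intermediate-frequency alleles gives positive D", {
  H <- matrix(0L, 10, 30)
  H[1:5, ] <- 1L   # every site at derived frequency n/2
  expect_gt(tajimas_d(H, 30)$D, 0)
})

test_that("diversity statistics are invariant to haplotype order", {
  set.seed(4)
  H <- simulate_neutral_sites(14, 80, seed = 4)
  td <- tajimas_d(H, 100)
  perm <- sample(nrow(H))
  td2 <- tajimas_d(H[perm, ], 100)
  expect_equal(td$D, td2$D, tolerance = 1e-12)
  expect_equal(td$theta_pi, td2$theta_pi, tolerance = 1e-12)
})

test_that("theta estimates on neutral matrices match per-column brute force", {
  H <- simulate_neutral_sites(10, 60, seed = 8)
  L <- 60
  # brute force over all haplotype pairs
  n <- nrow(H); tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(H[i, ] != H[j, ])
  pi_brute <- tot / choose(n, 2) / L
  expect_equal(nucleotide_diversity(H, L), pi_brute, tolerance = 1e-12)
  expect_equal(tajimas_d(H, L)$theta_w, watterson_theta(60, 10, L),
               tolerance = 1e-12)
})

test_that("unphased allele-frequency diversity matches the haplotype form without missingness", {
  co <- simulate_kdr_cohort(small_specs(), seed = 30, class_private_sites = 1)
  dp <- diversity_stats(co$variants, co$genotypes, co$metadata, phased = TRUE)
  du <- diversity_stats(co$variants, co$genotypes, co$metadata, phased = FALSE)
  # the (n/(n-1))(1 - sum p^2) estimator equals mean pairwise differences
  expect_equal(dp$theta_pi, du$theta_pi, tolerance = 1e-12)
  expect_equal(dp$S, du$S)
})
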