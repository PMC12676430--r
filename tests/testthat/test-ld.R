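test_that("triallelic collapsing pools every non-focal allele", {
  calls <- rbind(c(1L, 2L),   # g>t / g>c
                 c(0L, 0L),   # ref / ref
                 c(2L, 2L),   # g>c / g>c
                 c(-1L, 1L))  # missing
  expect_equal(collapse_to_biallelic(calls, 1L), c(1L, 0L, 0L, NA))
  expect_equal(collapse_to_biallelic(calls, 2L), c(1L, 0L, 2L, NA))
  expect_error(collapse_to_biallelic(calls, 0L), "reference")
})

test_that("two-locus counts exclude pairwise-incomplete individuals", {
  cnt <- two_locus_counts(c(0, 1, 2, NA, 2), c(0, 1, 2, 1, NA))
  expect_equal(sum(cnt), 3)
  expect_equal(cnt[1, 1], 1L)
  expect_equal(cnt[2, 2], 1L)
  expect_equal(cnt[3, 3], 1L)
})

test_that("perfect-coupling homozygote counts give r2 = 1 in at most two iterations", {
  cnt <- matrix(0L, 3, 3)
  cnt[3, 3] <- 2L
  cnt[1, 1] <- 2L
  em <- em_haplotype_frequencies(cnt)
  expect_equal(em$r2, 1)
  expect_equal(em$D, 0.25)
  expect_equal(unname(em$f), c(0.5, 0, 0, 0.5))
  expect_lte(em$iterations, 2)
  expect_true(em$converged)
})

test_that("monomorphic loci are flagged undefined rather than zero", {
  cnt <- matrix(0L, 3, 3)
  cnt[1, ] <- c(3L, 2L, 1L)    # locus 1 all g=0
  em <- em_haplotype_frequencies(cnt)
  expect_false(em$defined)
  expect_true(is.na(em$r2))
})

test_that("all-double-heterozygote data returns the documented saddle", {
  cnt <- matrix(0L, 3, 3)
  cnt[2, 2] <- 8L
  em <- em_haplotype_frequencies(cnt)
  expect_true(em$saddle)
  expect_true(em$converged)
  expect_equal(em$D, 0)
})

test_that("EM equals the closed-form count solution when no double heterozygotes exist", {
  set.seed(3)
  for (rep in 1:10) {
    cnt <- matrix(rpois(9, 3), 3, 3)
    cnt[2, 2] <- 0L
    n <- sum(cnt)
    if (n == 0) next
    em <- em_haplotype_frequencies(cnt)
    closed <- c(2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
                2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
                2 * cnt[1, 3] + cnt[2, 3] + cnt[1, 2],
                2 * cnt[1, 1] + cnt[2, 1] + cnt[1, 2]) / (2 * n)
    expect_equal(unname(em$f), closed, tolerance = 1e-12)
  }
})

test_that("EM log-likelihood never decreases and margins match the data exactly", {
  set.seed(11)
  for (rep in 1:100) {
    cnt <- matrix(rpois(9, 2), 3, 3)
    if (sum(cnt) == 0) cnt[2, 2] <- 1L
    em <- em_haplotype_frequencies(cnt)
    expect_true(all(diff(em$loglik) >= -1e-8))
    g <- matrix(0:2, 3, 3); h <- t(g)
    expect_equal(unname(em$f[1] + em$f[2]), sum(g * cnt) / (2 * sum(cnt)),
                 tolerance = 1e-12)
    expect_equal(unname(em$f[1] + em$f[3]), sum(h * cnt) / (2 * sum(cnt)),
                 tolerance = 1e-12)
    expect_equal(sum(em$f), 1, tolerance = 1e-9)
  }
})

test_that("EM on unphased genotypes converges to the phased-count r2", {
  f <- c(0.4, 0.1, 0.1, 0.4)
  diffs <- vapply(1:20, function(s) {
    d <- draw_two_locus(10000, f, seed = 100 + s)
    em <- em_haplotype_frequencies(two_locus_counts(d$dosA, d$dosB))
    pr <- phased_r2(d$A, d$B)
    abs(em$r2 - pr$r2)
  }, numeric(1))
  expect_true(all(diffs < 0.02))
})

test_that("the LD table reproduces perfect-coupling and independence patterns", {
  # L1 strictly coupled with T, no recombinant classes
  sp <- population_spec("P", "An_coluzzii", "Bana", "Sudanian", 300,
                        c(LVI = 0.4, LL1T = 0.6))
  co <- simulate_kdr_cohort(list(sp), seed = 71)
  lt <- ld_table(co$variants, co$genotypes, co$metadata)
  pooled <- lt[lt$population == "pooled", ]
  expect_equal(pooled$r2[pooled$allele_pair == "402L(g>t) vs 1527T"], 1)

  # L2 assorting independently of T: f(L2 & T) = p_L2 * p_T by construction
  sp2 <- population_spec("P", "An_coluzzii", "Bana", "Sudanian", 5000,
                         c(LVI = 0.4, LL1T = 0.4, LL2I = 0.1, LL2T = 0.1))
  co2 <- simulate_kdr_cohort(list(sp2), seed = 72)
  lt2 <- ld_table(co2$variants, co2$genotypes, co2$metadata)
  pooled2 <- lt2[lt2$population == "pooled", ]
  expect_lt(pooled2$r2[pooled2$allele_pair == "402L(g>c) vs 1527T"], 0.05)
})

test_that("small populations are flagged low_n and zero-rendering is configurable", {
  sp <- population_spec("P", "An_coluzzii", "Degue-Degue", "Sudanian", 4,
                        c(LVI = 0.5, FVI = 0.5))
  co <- simulate_kdr_cohort(list(sp), seed = 73)
  lt <- ld_table(co$variants, co$genotypes, co$metadata, min_n = 5)
  expect_true(all(lt$low_n))
  expect_true(all(is.na(lt$r2)))    # 1527T absent: undefined, NA by default
  lt0 <- ld_table(co$variants, co$genotypes, co$metadata, min_n = 5,
                  zero_when_monomorphic = TRUE)
  expect_true(all(lt0$r2 == 0))
})
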