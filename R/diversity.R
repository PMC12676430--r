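#' Count segregating sites and the multiallelic fraction
#'
#' A site is segregating when at least two distinct non-missing alleles are
#' observed within the sample subset; the multiallelic fraction is the share of
#' segregating sites at which more than two alleles are observed.
#'
#' @param variants variant table.
#' @param genotypes genotype matrix.
#' @param samples subset of sample ids (default: all).
#' @return list with \code{S} and \code{multiallelic_fraction} (NA when S = 0).
#' @export
count_segregating <- function(variants, genotypes, samples = genotypes$samples) {
  idx <- match(samples, genotypes$samples)
  if (length(idx) == 0 || anyNA(idx)) stop("empty or unknown sample subset")
  calls <- genotypes$calls[idx, , , drop = FALSE]
  nv <- dim(calls)[2]
  n_obs <- vapply(seq_len(nv), function(j) {
    a <- as.vector(calls[, j, ])
    length(unique(a[a >= 0L]))
  }, integer(1))
  S <- sum(n_obs >= 2L)
  frac <- if (S == 0) NA_real_ else sum(n_obs > 2L) / S
  list(S = S, multiallelic_fraction = frac)
}

#' Per-site nucleotide diversity from a haplotype matrix
#'
#' Mean number of pairwise differences over all haplotype pairs, divided by the
#' region length L. Sites with a missing allele in a pair are dropped for that
#' pair; the denominator remains L (no per-pair renormalisation).
#'
#' @param haplotypes matrix (n haplotypes x sites) of allele codes; NA = missing.
#' @param L region length in bp (>= number of columns).
#' @return per-site nucleotide diversity.
#' @export
nucleotide_diversity <- function(haplotypes, L) {
  n <- nrow(haplotypes)
  if (is.null(n) || n < 2) stop("need >= 2 haplotypes")
  if (L < ncol(haplotypes)) stop("L smaller than number of sites")
  mean_pairwise_differences(haplotypes) / L
}

# Total differing pairs per site via allele counts: among m non-missing
# alleles with counts c_a, differing pairs = C(m,2) - sum_a C(c_a,2).
# Identical to looping over all haplotype pairs and skipping missing sites.
mean_pairwise_differences <- function(haplotypes) {
  n <- nrow(haplotypes)
  total <- 0
  for (j in seq_len(ncol(haplotypes))) {
    a <- haplotypes[, j]
    a <- a[!is.na(a)]
    m <- length(a)
    if (m < 2) next
    counts <- tabulate(a + 1L)
    total <- total + choose(m, 2) - sum(choose(counts, 2))
  }
  total / (n * (n - 1) / 2)
}

harmonic <- function(n, power = 1) sum(1 / seq_len(n)^power)

#' Watterson's estimator (per site)
#'
#' theta_w = S / (a1 * L), a1 = sum_{i=1}^{n-1} 1/i.
#'
#' @param S number of segregating sites.
#' @param n number of haplotypes (>= 2).
#' @param L region length in bp.
#' @return per-site Watterson theta.
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("need n >= 2")
  S / (harmonic(n - 1) * L)
}

#' Tajima's D from a haplotype matrix
#'
#' Standardised difference between the mean-pairwise-difference and
#' segregating-sites estimators of the population mutation rate, using the
#' classical constants (a1, a2, b1, b2, c1, c2, e1, e2). S = 0 yields an
#' undefined (flagged) result rather than an exception.
#'
#' @param haplotypes matrix (n haplotypes x sites) of allele codes.
#' @param L region length (only used for reporting theta values per site).
#' @return list with \code{D}, \code{defined}, \code{S}, \code{n},
#'   \code{theta_pi} and \code{theta_w} (per site when L is given).
#' @export
tajimas_d <- function(haplotypes, L = ncol(haplotypes)) {
  n <- nrow(haplotypes)
  if (is.null(n) || n < 2) stop("need >= 2 haplotypes")
  poly <- vapply(seq_len(ncol(haplotypes)), function(j) {
    a <- haplotypes[, j]
    length(unique(a[!is.na(a)])) >= 2L
  }, logical(1))
  S <- sum(poly)
  if (S == 0) {
    return(list(D = NA_real_, defined = FALSE, S = 0L, n = n,
                theta_pi = 0, theta_w = 0))
  }
  Pi <- mean_pairwise_differences(haplotypes)   # total, not per-site
  a1 <- harmonic(n - 1)
  a2 <- harmonic(n - 1, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, defined = TRUE, S = as.integer(S), n = n,
       theta_pi = Pi / L, theta_w = S / (a1 * L))
}

#' Extract phased haplotype rows for a sample subset
#'
#' Decomposes the diploid calls of phased samples into 2n haplotype rows of
#' allele indices (NA where missing).
#'
#' @param genotypes genotype matrix (phased).
#' @param samples sample ids to include.
#' @param variant_idx optional variant column subset.
#' @return matrix of 2 * length(samples) rows.
#' @export
haplotype_rows <- function(genotypes, samples = genotypes$samples,
                           variant_idx = seq_len(n_variants(genotypes))) {
  idx <- match(samples, genotypes$samples)
  if (anyNA(idx)) stop("unknown sample id")
  a1 <- genotypes$calls[idx, variant_idx, 1, drop = FALSE]
  a2 <- genotypes$calls[idx, variant_idx, 2, drop = FALSE]
  dim(a1) <- dim(a1)[1:2]; dim(a2) <- dim(a2)[1:2]
  h <- matrix(NA_integer_, 2 * length(idx), length(variant_idx))
  h[seq(1, 2 * length(idx), by = 2), ] <- a1
  h[seq(2, 2 * length(idx), by = 2), ] <- a2
  h[h < 0] <- NA_integer_
  rownames(h) <- paste0(rep(samples, each = 2), c("_1", "_2"))
  h
}

#' Diversity statistics per population
#'
#' Computes S, the multiallelic fraction, per-site theta-pi, Watterson's theta
#' and Tajima's D for each population over a region. Phased samples are
#' decomposed into 2n haplotypes; with \code{phased = FALSE} theta-pi uses the
#' unbiased allele-frequency form over 2n observed alleles,
#' pi = L^-1 sum_sites (n/(n-1)) (1 - sum_a p_a^2),
#' and Tajima's D is computed from S and that pi.
#'
#' @param variants variant table.
#' @param genotypes genotype matrix.
#' @param metadata sample metadata table.
#' @param group_by metadata column defining populations (default "site").
#' @param L region length in bp (default: variant span).
#' @param phased treat genotypes as phased haplotypes (default TRUE).
#' @return data.frame with one row per population.
#' @export
diversity_stats <- function(variants, genotypes, metadata, group_by = "site",
                            L = NULL, phased = TRUE) {
  if (is.null(L)) L <- max(variants$pos) - min(variants$pos) + 1L
  groups <- split(metadata$sample_id, metadata[[group_by]])
  rows <- lapply(names(groups), function(g) {
    ids <- intersect(groups[[g]], genotypes$samples)
    if (length(ids) == 0) return(NULL)
    seg <- count_segregating(variants, genotypes, ids)
    if (phased) {
      h <- haplotype_rows(genotypes, ids)
      td <- tajimas_d(h, L)
      data.frame(population = g, n = nrow(h), S = seg$S,
                 multiallelic_fraction = seg$multiallelic_fraction,
                 theta_pi = td$theta_pi, theta_w = td$theta_w,
                 tajima_d = td$D, variant_density = seg$S / L,
                 stringsAsFactors = FALSE)
    } else {
      up <- unphased_diversity(genotypes, ids, L)
      data.frame(population = g, n = up$n, S = seg$S,
                 multiallelic_fraction = seg$multiallelic_fraction,
                 theta_pi = up$theta_pi, theta_w = up$theta_w,
                 tajima_d = up$D, variant_density = seg$S / L,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

# allele-frequency form of pi plus D from (pi, S) for unphased input; the
# haplotype sample size is the modal number of non-missing alleles per site
unphased_diversity <- function(genotypes, samples, L) {
  idx <- match(samples, genotypes$samples)
  calls <- genotypes$calls[idx, , , drop = FALSE]
  nv <- dim(calls)[2]
  per_site <- vapply(seq_len(nv), function(j) {
    a <- as.vector(calls[, j, ])
    a <- a[a >= 0L]
    nj <- length(a)
    if (nj < 2) return(c(0, nj))
    p <- tabulate(a + 1L) / nj
    c((nj / (nj - 1)) * (1 - sum(p^2)), nj)
  }, numeric(2))
  het <- per_site[1, ]
  n_site <- per_site[2, ]
  n_modal <- if (nv == 0) 2L else as.integer(names(sort(table(n_site), decreasing = TRUE))[1])
  S <- sum(het > 0)
  Pi <- sum(het)
  if (S == 0 || n_modal < 2) {
    return(list(theta_pi = 0, theta_w = 0, D = NA_real_, n = n_modal))
  }
  a1 <- harmonic(n_modal - 1)
  a2 <- harmonic(n_modal - 1, 2)
  n <- n_modal
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(theta_pi = Pi / L, theta_w = S / (a1 * L), D = D, n = n)
}
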