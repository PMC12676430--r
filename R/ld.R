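#' Collapse a (possibly multiallelic) locus to focal-allele dosage
#'
#' Counts copies of one named mutant allele; every other allele at the locus
#' (including the other mutant at a triallelic site) is pooled as non-focal.
#'
#' @param calls n x 2 matrix of allele indices at the locus (-1 missing).
#' @param focal_alt index (>= 1) of the focal alternate allele.
#' @return integer vector of 0/1/2 dosages, NA where either call is missing.
#' @export
collapse_to_biallelic <- function(calls, focal_alt) {
  stopifnot(is.matrix(calls), ncol(calls) == 2L)
  if (focal_alt < 1L) stop("focal allele must be a named mutant allele, not the reference")
  d <- (calls[, 1] == focal_alt) + (calls[, 2] == focal_alt)
  d[calls[, 1] < 0L | calls[, 2] < 0L] <- NA_integer_
  as.integer(d)
}

#' Two-locus unphased genotype counts
#'
#' 3x3 table n[g+1, h+1] of individuals with g copies of the focal allele at
#' locus 1 and h copies at locus 2; individuals missing at either locus are
#' excluded (pairwise-complete deletion).
#'
#' @param dos1,dos2 0/1/2 dosage vectors (NA = missing).
#' @return 3x3 integer matrix.
#' @export
two_locus_counts <- function(dos1, dos2) {
  keep <- !is.na(dos1) & !is.na(dos2)
  tab <- matrix(0L, 3, 3, dimnames = list(g = 0:2, h = 0:2))
  if (any(keep)) {
    t0 <- table(factor(dos1[keep], levels = 0:2),
                factor(dos2[keep], levels = 0:2))
    tab[] <- as.integer(t0)
  }
  tab
}

# observed-data log-likelihood of a 3x3 genotype table under HWE given
# haplotype frequencies f = c(AB, Ab, aB, ab)
two_locus_loglik <- function(counts, f) {
  P <- matrix(0, 3, 3)
  fAB <- f[1]; fAb <- f[2]; faB <- f[3]; fab <- f[4]
  P[3, 3] <- fAB^2
  P[3, 2] <- 2 * fAB * fAb
  P[3, 1] <- fAb^2
  P[2, 3] <- 2 * fAB * faB
  P[2, 2] <- 2 * (fAB * fab + fAb * faB)
  P[2, 1] <- 2 * fAb * fab
  P[1, 3] <- faB^2
  P[1, 2] <- 2 * faB * fab
  P[1, 1] <- fab^2
  nz <- counts > 0
  sum(counts[nz] * log(P[nz]))
}

#' EM maximum-likelihood two-locus haplotype frequencies and r-squared
#'
#' Estimates the four haplotype frequencies from unphased diploid genotype
#' counts under Hardy-Weinberg. Only the double-heterozygote cell is
#' phase-ambiguous: the E-step splits it between coupling (AB/ab) and
#' repulsion (Ab/aB) in proportion to the current haplotype-frequency
#' products; the M-step sets each frequency to its expected haplotype count
#' over 2n. Initialisation is at linkage equilibrium. When either locus is
#' monomorphic the result is flagged undefined (r2 is not reported). When the
#' data consist solely of double heterozygotes, the likelihood is flat between
#' coupling and repulsion and the equilibrium start is stationary; the
#' estimate D = 0 is returned with a saddle flag.
#'
#' @param counts 3x3 genotype count table (see \code{two_locus_counts}).
#' @param tol convergence tolerance on max |delta f| (default 1e-10).
#' @param max_iter iteration cap (default 1000).
#' @return list with haplotype frequencies \code{f} (AB, Ab, aB, ab), allele
#'   frequencies \code{p_A}, \code{p_B}, \code{D}, \code{r2}, \code{n},
#'   \code{iterations}, \code{converged}, \code{defined}, \code{saddle},
#'   \code{loglik} (trace of the observed-data log-likelihood).
#' @export
em_haplotype_frequencies <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("no individuals in the count table")
  g <- matrix(0:2, 3, 3, byrow = FALSE)
  h <- matrix(0:2, 3, 3, byrow = TRUE)
  p_A <- sum(g * counts) / (2 * n)
  p_B <- sum(h * counts) / (2 * n)
  defined <- p_A > 0 && p_A < 1 && p_B > 0 && p_B < 1
  f <- c(p_A * p_B, p_A * (1 - p_B), (1 - p_A) * p_B, (1 - p_A) * (1 - p_B))
  n11 <- counts[2, 2]
  # fixed haplotype contributions from unambiguous cells
  base_AB <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3]
  base_Ab <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1]
  base_aB <- 2 * counts[1, 3] + counts[2, 3] + counts[1, 2]
  base_ab <- 2 * counts[1, 1] + counts[2, 1] + counts[1, 2]
  loglik <- two_locus_loglik(counts, f)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (n11 > 0 && denom > 0) f[1] * f[4] / denom else 0.5
    f_new <- c(base_AB + w * n11,
               base_Ab + (1 - w) * n11,
               base_aB + (1 - w) * n11,
               base_ab + w * n11) / (2 * n)
    loglik <- c(loglik, two_locus_loglik(counts, f_new))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  D <- f[1] - p_A * p_B
  r2 <- if (defined) D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B)) else NA_real_
  saddle <- n11 == n && n > 0
  list(f = setNames(f, c("AB", "Ab", "aB", "ab")),
       p_A = p_A, p_B = p_B, D = D, r2 = r2, n = n,
       iterations = iter, converged = converged, defined = defined,
       saddle = saddle, loglik = loglik)
}

#' Count-based r-squared from phased haplotypes (oracle estimator)
#'
#' Direct haplotype-count estimate of D and r2 from two phased allele-indicator
#' vectors; used as the independent cross-check for the EM estimator.
#'
#' @param hap_a,hap_b 0/1 indicator vectors over haplotypes (same length).
#' @return list with \code{f}, \code{p_A}, \code{p_B}, \code{D}, \code{r2},
#'   \code{defined}.
#' @export
phased_r2 <- function(hap_a, hap_b) {
  keep <- !is.na(hap_a) & !is.na(hap_b)
  a <- hap_a[keep]; b <- hap_b[keep]
  m <- length(a)
  if (m == 0) stop("no complete haplotypes")
  fAB <- sum(a == 1 & b == 1) / m
  fAb <- sum(a == 1 & b == 0) / m
  faB <- sum(a == 0 & b == 1) / m
  fab <- sum(a == 0 & b == 0) / m
  p_A <- fAB + fAb
  p_B <- fAB + faB
  defined <- p_A > 0 && p_A < 1 && p_B > 0 && p_B < 1
  D <- fAB - p_A * p_B
  r2 <- if (defined) D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B)) else NA_real_
  list(f = c(AB = fAB, Ab = fAb, aB = faB, ab = fab),
       p_A = p_A, p_B = p_B, D = D, r2 = r2, defined = defined)
}

#' Linkage-disequilibrium table for the 402/1527 allele pairs
#'
#' For each population and for the pooled cohort, estimates r2 between each
#' 402L mutant allele (g>t and g>c, each collapsed against all other alleles)
#' and 1527T by EM maximum likelihood from unphased genotypes. Pooling
#' concatenates all samples before counting. Populations below \code{min_n}
#' are flagged low_n. Undefined r2 (monomorphic allele) renders NA by default;
#' \code{zero_when_monomorphic = TRUE} renders 0 instead.
#'
#' @param variants variant table containing the panel loci.
#' @param genotypes genotype matrix.
#' @param metadata sample metadata.
#' @param panel kdr panel.
#' @param group_by metadata column defining populations (default "site").
#' @param pooled_label label for the pooled row (default "pooled").
#' @param min_n minimum population size before flagging (default 5).
#' @param zero_when_monomorphic render undefined r2 as 0 (default FALSE).
#' @return data.frame, one row per (population x allele pair), plus long-format
#'   haplotype-frequency diagnostics columns.
#' @export
ld_table <- function(variants, genotypes, metadata, panel = kdr_panel(),
                     group_by = "site", pooled_label = "pooled", min_n = 5L,
                     zero_when_monomorphic = FALSE) {
  vidx <- panel_variant_index(variants, panel)
  i402 <- vidx[2]; i1527 <- vidx[3]
  calls402 <- matrix(genotypes$calls[, i402, ], ncol = 2)
  calls1527 <- matrix(genotypes$calls[, i1527, ], ncol = 2)
  dosT <- collapse_to_biallelic(calls1527, 1L)
  pairs <- list("402L(g>t) vs 1527T" = 1L, "402L(g>c) vs 1527T" = 2L)
  groups <- split(metadata$sample_id, metadata[[group_by]])
  groups[[pooled_label]] <- metadata$sample_id
  rows <- list()
  for (g in names(groups)) {
    idx <- match(intersect(groups[[g]], genotypes$samples), genotypes$samples)
    if (length(idx) == 0) next
    for (pn in names(pairs)) {
      dosL <- collapse_to_biallelic(calls402, pairs[[pn]])
      cnt <- two_locus_counts(dosL[idx], dosT[idx])
      if (sum(cnt) == 0) next
      em <- em_haplotype_frequencies(cnt)
      r2 <- em$r2
      if (!em$defined && zero_when_monomorphic) r2 <- 0
      rows[[length(rows) + 1L]] <- data.frame(
        population = g, allele_pair = pn, n = em$n, r2 = r2,
        D = em$D, p_focal = em$p_A, p_1527T = em$p_B,
        f_AB = em$f[1], f_Ab = em$f[2], f_aB = em$f[3], f_ab = em$f[4],
        iterations = em$iterations, converged = em$converged,
        defined = em$defined, saddle = em$saddle,
        low_n = em$n < min_n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
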