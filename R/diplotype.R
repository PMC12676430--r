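#' The kdr three-locus panel
#'
#' Defines the 995 / 402 / 1527 voltage-gated-sodium-channel panel: locus
#' coordinates, alleles and allele-to-label maps. At 995 the reference is L and
#' the two alternates are F and S; at the triallelic 402 locus the g>t and g>c
#' alternates are labelled L1 and L2; at 1527 the alternate is T. Coordinates
#' are conventional defaults inside the Vgsc span on 2L and can be overridden.
#'
#' @param loci optional replacement locus list (same structure as the default).
#' @return list of class \code{kdr_panel} with elements \code{loci} (named
#'   list in the fixed order 995, 402, 1527) and \code{groups} (the five named
#'   diplotype groups).
#' @export
kdr_panel <- function(loci = NULL) {
  if (is.null(loci)) {
    loci <- list(
      "995" = list(contig = "2L", pos = 2422652L, ref = "A",
                   alts = c("T", "C"), labels = c("L", "F", "S")),
      "402" = list(contig = "2L", pos = 2391228L, ref = "G",
                   alts = c("T", "C"), labels = c("V", "L1", "L2")),
      "1527" = list(contig = "2L", pos = 2429617L, ref = "T",
                    alts = "C", labels = c("I", "T")))
  }
  stopifnot(identical(names(loci), c("995", "402", "1527")))
  for (l in loci) {
    stopifnot(length(l$labels) == 1L + length(l$alts),
              !anyDuplicated(l$labels))
  }
  groups <- list("FVI/FVI" = c("FVI", "FVI"),
                 "FL1T/LVI" = c("FL1T", "LVI"),
                 "FL2T/LVI" = c("FL2T", "LVI"),
                 "LL1T/LL1T" = c("LL1T", "LL1T"),
                 "LL1T/LL2T" = c("LL1T", "LL2T"))
  structure(list(loci = loci, groups = groups), class = "kdr_panel")
}

#' All haplotype labels expressible under a panel
#' @param panel kdr panel.
#' @return character vector of label triples (e.g. "FVI").
#' @export
panel_haplotype_labels <- function(panel) {
  g <- expand.grid(l995 = panel$loci[["995"]]$labels,
                   l402 = panel$loci[["402"]]$labels,
                   l1527 = panel$loci[["1527"]]$labels,
                   stringsAsFactors = FALSE)
  paste0(g$l995, g$l402, g$l1527)
}

# allele index triple (995, 402, 1527) for a haplotype label, or NULL
label_to_alleles <- function(label, panel) {
  for (a in seq_along(panel$loci[["995"]]$labels)) {
    for (b in seq_along(panel$loci[["402"]]$labels)) {
      for (d in seq_along(panel$loci[["1527"]]$labels)) {
        lab <- paste0(panel$loci[["995"]]$labels[a],
                      panel$loci[["402"]]$labels[b],
                      panel$loci[["1527"]]$labels[d])
        if (lab == label) return(c(a, b, d) - 1L)
      }
    }
  }
  NULL
}

#' Label one haplotype at the panel loci
#'
#' @param alleles integer vector of allele indices at (995, 402, 1527);
#'   0 = reference.
#' @param panel kdr panel.
#' @return haplotype label, e.g. "FVI".
#' @export
label_haplotype <- function(alleles, panel) {
  stopifnot(length(alleles) == 3L)
  out <- character(3)
  for (i in 1:3) {
    lab <- panel$loci[[i]]$labels
    a <- alleles[i]
    if (is.na(a) || a < 0L || a >= length(lab))
      stop(sprintf("allele index %s not in panel map at locus %s",
                   a, names(panel$loci)[i]))
    out[i] <- lab[a + 1L]
  }
  paste0(out, collapse = "")
}

# indices of the panel loci inside a variant table (995, 402, 1527 order)
panel_variant_index <- function(variants, panel) {
  idx <- vapply(panel$loci, function(l) {
    i <- which(variants$contig == l$contig & variants$pos == l$pos)
    if (length(i) != 1L)
      stop(sprintf("panel locus %s:%d absent from variant table", l$contig, l$pos))
    i
  }, integer(1))
  idx
}

match_named_group <- function(pair, groups) {
  for (g in names(groups)) {
    if (setequal_pair(pair, groups[[g]])) return(g)
  }
  NA_character_
}

setequal_pair <- function(a, b) {
  (a[1] == b[1] && a[2] == b[2]) || (a[1] == b[2] && a[2] == b[1])
}

#' Classify individuals into diplotype groups
#'
#' Phased samples: the unordered pair of haplotype labels is matched against
#' the five named groups; any other pair is OD (other diplotypes). Unphased
#' samples: all phase resolutions of the three-locus genotype are enumerated;
#' a resolution matching a named group assigns that group, and when several
#' named groups (or several resolutions) are compatible the coupling rule
#' places 995F, 402L and 1527T on the same haplotype and the call is flagged
#' ambiguous. A missing call at any panel locus yields OD with a missing flag.
#'
#' @param variants variant table containing the panel loci.
#' @param genotypes genotype matrix.
#' @param panel kdr panel.
#' @param phased NULL (use the matrix's phased flags), TRUE or FALSE.
#' @return data.frame (sample_id, hap1, hap2, group, ambiguous, missing).
#' @export
classify_diplotypes <- function(variants, genotypes, panel, phased = NULL) {
  vidx <- panel_variant_index(variants, panel)
  ns <- n_samples(genotypes)
  pref <- c("FL1T/LVI", "FL2T/LVI", "LL1T/LL1T", "LL1T/LL2T", "FVI/FVI")
  out <- data.frame(sample_id = genotypes$samples,
                    hap1 = NA_character_, hap2 = NA_character_,
                    group = "OD", ambiguous = FALSE, missing = FALSE,
                    stringsAsFactors = FALSE)
  ph_mat <- if (is.matrix(genotypes$phased)) genotypes$phased[, vidx, drop = FALSE]
            else matrix(genotypes$phased, ns, 3)
  for (s in seq_len(ns)) {
    a1 <- genotypes$calls[s, vidx, 1]
    a2 <- genotypes$calls[s, vidx, 2]
    if (any(a1 < 0L) || any(a2 < 0L)) {
      out$missing[s] <- TRUE
      next
    }
    is_phased <- if (is.null(phased)) all(ph_mat[s, ]) else phased
    if (is_phased) {
      h1 <- label_haplotype(a1, panel)
      h2 <- label_haplotype(a2, panel)
      out$hap1[s] <- h1; out$hap2[s] <- h2
      g <- match_named_group(c(h1, h2), panel$groups)
      out$group[s] <- if (is.na(g)) "OD" else g
    } else {
      res <- phase_resolutions(a1, a2, panel)
      named <- vapply(res, function(p) match_named_group(p, panel$groups),
                      character(1))
      hits <- unique(named[!is.na(named)])
      if (length(hits) == 0) {
        out$group[s] <- "OD"
        out$ambiguous[s] <- FALSE
      } else {
        g <- if (length(hits) == 1) hits else pref[match(TRUE, pref %in% hits)]
        out$group[s] <- g
        out$ambiguous[s] <- length(res) > 1
        p <- res[[match(g, named)]]
        out$hap1[s] <- p[1]; out$hap2[s] <- p[2]
      }
    }
  }
  out
}

# unordered phase resolutions of a three-locus genotype as label pairs
phase_resolutions <- function(a1, a2, panel) {
  het <- which(a1 != a2)
  if (length(het) == 0) {
    return(list(c(label_haplotype(a1, panel), label_haplotype(a2, panel))))
  }
  # fix the first het locus to avoid mirror duplicates
  rest <- het[-1]
  combos <- if (length(rest) == 0) data.frame(row.names = 1)
            else expand.grid(rep(list(c(FALSE, TRUE)), length(rest)))
  res <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    h1 <- pmin(a1, a2); h2 <- pmax(a1, a2)   # canonical start
    h1[het[1]] <- min(a1[het[1]], a2[het[1]])
    h2[het[1]] <- max(a1[het[1]], a2[het[1]])
    if (length(rest)) {
      flip <- unlist(combos[r, ])
      for (i in seq_along(rest)) {
        lo <- min(a1[rest[i]], a2[rest[i]])
        hi <- max(a1[rest[i]], a2[rest[i]])
        h1[rest[i]] <- if (flip[i]) hi else lo
        h2[rest[i]] <- if (flip[i]) lo else hi
      }
    }
    res[[r]] <- c(label_haplotype(h1, panel), label_haplotype(h2, panel))
  }
  unique(res)
}

#' Diplotype-group frequencies per population
#'
#' Frequency = group count / classified-sample count within each population.
#' Samples with a missing panel call are excluded from the denominator.
#'
#' @param calls output of \code{classify_diplotypes}.
#' @param metadata sample metadata.
#' @param group_by metadata column ("site" or "species").
#' @param drop_missing exclude missing-flagged calls (default TRUE).
#' @return data.frame (population, group, count, n, frequency).
#' @export
diplotype_frequencies <- function(calls, metadata, group_by = "site",
                                  drop_missing = TRUE) {
  m <- merge(calls, metadata, by = "sample_id", sort = FALSE)
  if (drop_missing) m <- m[!m$missing, , drop = FALSE]
  pops <- split(m, m[[group_by]])
  rows <- lapply(names(pops), function(p) {
    sub <- pops[[p]]
    if (nrow(sub) == 0) {
      warning(sprintf("empty population %s omitted", p))
      return(NULL)
    }
    tab <- table(sub$group)
    data.frame(population = p, group = names(tab),
               count = as.integer(tab), n = nrow(sub),
               frequency = as.numeric(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-site unordered genotype codes (missing gets its own code)
genotype_codes <- function(genotypes, samples = genotypes$samples,
                           variant_idx = seq_len(n_variants(genotypes))) {
  idx <- match(samples, genotypes$samples)
  a1 <- matrix(genotypes$calls[idx, variant_idx, 1], nrow = length(idx))
  a2 <- matrix(genotypes$calls[idx, variant_idx, 2], nrow = length(idx))
  lo <- pmin(a1, a2) + 1L    # -1..3 -> 0..4
  hi <- pmax(a1, a2) + 1L
  lo * 5L + hi
}

#' Hierarchical clustering of genotypes (UPGMA on Hamming distances)
#'
#' Pairwise distance between samples is the Hamming distance between their
#' per-site unordered allele-count vectors; linkage is UPGMA (average). All-
#' missing samples are excluded with a warning.
#'
#' @param genotypes genotype matrix.
#' @param samples sample subset (default all).
#' @param variant_idx variant column subset (default all).
#' @return list with \code{hclust} (stats::hclust object), \code{order}
#'   (leaf order as sample ids), and \code{dist} (the distance matrix).
#' @export
genotype_clustering <- function(genotypes, samples = genotypes$samples,
                                variant_idx = seq_len(n_variants(genotypes))) {
  codes <- genotype_codes(genotypes, samples, variant_idx)
  all_missing <- rowSums(codes != 0L) == 0L
  if (any(all_missing)) {
    warning(sprintf("excluding %d all-missing sample(s)", sum(all_missing)))
    samples <- samples[!all_missing]
    codes <- codes[!all_missing, , drop = FALSE]
  }
  if (nrow(codes) < 2) stop("need >= 2 samples to cluster")
  D <- hamming_distance_codes(codes)
  dimnames(D) <- list(samples, samples)
  hc <- hclust(stats::as.dist(D), method = "average")
  list(hclust = hc, order = samples[hc$order], dist = D)
}

# Hamming distance between rows of an integer code matrix via sparse one-hot
# crossproduct (sites - matches)
hamming_distance_codes <- function(codes) {
  ns <- nrow(codes); nv <- ncol(codes)
  col_code <- paste(rep(seq_len(nv), each = ns), as.vector(codes))
  f <- factor(col_code)
  X <- Matrix::sparseMatrix(i = rep(seq_len(ns), nv),
                            j = as.integer(f), x = 1,
                            dims = c(ns, nlevels(f)))
  M <- as.matrix(Matrix::tcrossprod(X))
  nv - M
}

#' Export a clustering as Newick text
#' @param clustering output of \code{genotype_clustering}.
#' @param path output path.
#' @export
write_dendrogram_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Genotype dosage matrix (one column per alternate allele)
#'
#' Multiallelic sites are collapsed to one 0/1/2 dosage column per alt, which
#' keeps the triallelic 402 signal visible to PCA and clustering.
#'
#' @param variants variant table.
#' @param genotypes genotype matrix.
#' @param samples sample subset.
#' @return numeric matrix samples x (variant, alt) with NA for missing calls.
#' @export
dosage_matrix <- function(variants, genotypes, samples = genotypes$samples) {
  idx <- match(samples, genotypes$samples)
  nv <- n_variants(genotypes)
  a1 <- matrix(genotypes$calls[idx, , 1], nrow = length(idx))
  a2 <- matrix(genotypes$calls[idx, , 2], nrow = length(idx))
  n_alt <- lengths(variants$alts)
  cols <- vector("list", sum(n_alt))
  nm <- character(sum(n_alt))
  c0 <- 0L
  for (j in seq_len(nv)) {
    for (k in seq_len(n_alt[j])) {
      c0 <- c0 + 1L
      d <- (a1[, j] == k) + (a2[, j] == k)
      d[a1[, j] < 0 | a2[, j] < 0] <- NA_real_
      cols[[c0]] <- d
      nm[c0] <- paste0(variants$contig[j], ":", variants$pos[j], "_",
                       variants$alts[[j]][k])
    }
  }
  m <- do.call(cbind, cols)
  dimnames(m) <- list(samples, nm)
  m
}

#' PCA of genotype dosages with Patterson scaling
#'
#' Each dosage column is centred by its mean and scaled by sqrt(p(1-p)) with
#' p the allele frequency (mean dosage / 2); missing entries are mean-imputed
#' before scaling. The sign convention makes each component's largest-magnitude
#' loading positive.
#'
#' @param dosage samples x variants dosage matrix.
#' @param maf_min minor-allele-frequency filter (default 0.01).
#' @return list with \code{scores}, \code{loadings}, \code{explained}
#'   (variance fractions).
#' @export
pca_dosage <- function(dosage, maf_min = 0.01) {
  if (nrow(dosage) < 2) stop("need >= 2 samples")
  p <- colMeans(dosage, na.rm = TRUE) / 2
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf_min & p > 0 & p < 1
  if (!any(keep)) stop("no sites pass the maf filter")
  X <- dosage[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    x[is.na(x)] <- 2 * p[j]
    X[, j] <- (x - 2 * p[j]) / sqrt(p[j] * (1 - p[j]))
  }
  if (all(abs(X) < 1e-12)) stop("zero-variance dosage matrix after filtering")
  pc <- prcomp(X, center = FALSE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  k <- min(10, length(pc$sdev))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = load,
       explained = (pc$sdev^2 / total_var)[seq_len(k)])
}

#' Cluster-map row and column orders
#'
#' UPGMA on Euclidean distances applied independently to the rows and columns
#' of a frequency matrix (variants x populations); single rows or columns give
#' the identity order.
#'
#' @param mat numeric matrix.
#' @return list with \code{row_order} and \code{col_order} (integer indices).
#' @export
cluster_map_order <- function(mat) {
  stopifnot(all(is.finite(mat)))
  ro <- if (nrow(mat) < 2) seq_len(nrow(mat))
        else hclust(dist(mat), method = "average")$order
  co <- if (ncol(mat) < 2) seq_len(ncol(mat))
        else hclust(dist(t(mat)), method = "average")$order
  list(row_order = ro, col_order = co)
}
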