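#' @importFrom stats dist hclust prcomp rgeom runif setNames
#' @importFrom utils read.delim write.table combn
#' @keywords internal
"_PACKAGE"

SPECIES_LEVELS <- c("An_coluzzii", "An_gambiae_ss", "An_arabiensis")
ZONE_LEVELS <- c("Sudanian", "Sudano_Sahelian", "Sahelian")
SEX_LEVELS <- c("F", "M")
FAMILY_LEVELS <- c("CYP", "COE", "GST", "other")
CONTIG_LEVELS <- c("2L", "2R", "3L", "3R", "X")

#' Construct a variant table
#'
#' One row per VCF-style record; multiallelic records are kept as a single row
#' with multiple alternate alleles (the triallelic 402 locus is first-class,
#' never split into biallelic rows).
#'
#' @param contig character vector of chromosome arms.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each contig.
#' @param ref character vector of single-nucleotide reference alleles.
#' @param alts list of character vectors (1-3 single nucleotides per site).
#' @param effect_labels optional list of per-alt effect labels (same shape as
#'   \code{alts}).
#' @return data.frame with list columns \code{alts} and (optionally)
#'   \code{effect_labels}.
#' @export
variant_table <- function(contig, pos, ref, alts, effect_labels = NULL) {
  stopifnot(length(contig) == length(pos), length(ref) == length(pos),
            length(alts) == length(pos))
  pos <- as.integer(unname(pos))
  alts <- unname(lapply(alts, as.character))
  contig <- unname(contig)
  ref <- unname(ref)
  nucs <- c("A", "C", "G", "T")
  for (i in seq_along(pos)) {
    a <- alts[[i]]
    if (!all(c(ref[i], a) %in% nucs))
      stop(sprintf("non-ACGT allele at %s:%d", contig[i], pos[i]))
    if (ref[i] %in% a)
      stop(sprintf("ref allele among alts at %s:%d", contig[i], pos[i]))
    if (anyDuplicated(a))
      stop(sprintf("duplicate alt alleles at %s:%d", contig[i], pos[i]))
    if (length(a) < 1L || length(a) > 3L)
      stop(sprintf("1-3 alt alleles required at %s:%d", contig[i], pos[i]))
  }
  for (ctg in unique(contig)) {
    p <- pos[contig == ctg]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on contig %s", ctg))
  }
  out <- data.frame(contig = as.character(contig), pos = pos,
                    ref = as.character(ref), stringsAsFactors = FALSE)
  out$alts <- alts
  if (!is.null(effect_labels)) {
    stopifnot(length(effect_labels) == length(pos))
    out$effect_labels <- lapply(effect_labels, as.character)
  }
  out
}

#' Construct a genotype matrix
#'
#' @param calls integer array of shape (n_samples, n_variants, 2) of allele
#'   indices; 0 = reference, k = k-th alternate, -1 = missing.
#' @param phased logical: either a single flag or an n_samples x n_variants
#'   matrix marking phased calls.
#' @param samples character vector of sample ids (length n_samples).
#' @return list of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(calls, phased = FALSE, samples = NULL) {
  stopifnot(is.array(calls), length(dim(calls)) == 3L, dim(calls)[3] == 2L)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) samples <- paste0("S", seq_len(dim(calls)[1]))
  stopifnot(length(samples) == dim(calls)[1])
  if (is.matrix(phased)) {
    stopifnot(nrow(phased) == dim(calls)[1], ncol(phased) == dim(calls)[2])
  } else {
    stopifnot(is.logical(phased), length(phased) == 1L)
  }
  structure(list(calls = calls, phased = phased, samples = as.character(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%s)\n",
              dim(x$calls)[1], dim(x$calls)[2],
              if (isTRUE(all(x$phased))) "phased" else "unphased/mixed"))
  invisible(x)
}

n_samples <- function(g) dim(g$calls)[1]
n_variants <- function(g) dim(g$calls)[2]

check_genotypes_consistent <- function(variants, genotypes) {
  stopifnot(nrow(variants) == n_variants(genotypes))
  n_alleles <- 1L + lengths(variants$alts)
  mx <- apply(genotypes$calls, 2, max)
  if (any(mx >= n_alleles))
    stop("allele index exceeds number of alleles at a variant")
  invisible(TRUE)
}

#' Read a genotype VCF
#'
#' Reads a VCF 4.x file with GT fields into a variant table and genotype
#' matrix. Multiallelic records are preserved as single rows. "|" genotype
#' separators mark phased calls, "/" unphased; "." alleles become -1.
#'
#' @param path path to a VCF (optionally gzipped).
#' @param region optional \code{"contig:start-end"} filter (1-based inclusive).
#' @return list with elements \code{variants}, \code{genotypes}, \code{samples}.
#' @export
read_genotype_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  contig <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(gt)
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    r <- parse_region(region)
    if (!r$contig %in% contig) {
      warning(sprintf("region contig %s absent from VCF", r$contig))
      keep <- rep(FALSE, length(pos))
    } else {
      keep <- contig == r$contig & pos >= r$start & pos <= r$end
    }
  }
  idx <- which(keep)
  nv <- length(idx)
  ns <- length(samples)
  calls <- array(-1L, dim = c(ns, nv, 2L))
  phased <- matrix(FALSE, ns, nv)
  if (nv > 0) {
    gts <- gt[idx, , drop = FALSE]
    # gts is variants x samples of strings like "0/1", "2|2", "./."
    flat <- as.character(t(gts))           # sample-major within each variant
    flat[is.na(flat)] <- "./."
    ph <- grepl("|", flat, fixed = TRUE)
    parts <- strsplit(flat, "[/|]")
    bad <- which(lengths(parts) != 2L)
    if (length(bad)) {
      # haploid or malformed entries: treat single-allele calls as homozygous-style
      for (b in bad) {
        p <- parts[[b]]
        if (length(p) == 1L) parts[[b]] <- c(p, p)
        else stop(sprintf("malformed GT '%s' at record %d", flat[b],
                          (b - 1L) %/% ns + 1L))
      }
    }
    a1 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    a2 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    a1[is.na(a1)] <- -1L
    a2[is.na(a2)] <- -1L
    calls[, , 1] <- matrix(a1, nrow = ns, ncol = nv)
    calls[, , 2] <- matrix(a2, nrow = ns, ncol = nv)
    phased <- matrix(ph, nrow = ns, ncol = nv)
  }
  variants <- variant_table(contig[idx], pos[idx], ref[idx], alts[idx])
  g <- genotype_matrix(calls, phased = phased, samples = samples)
  check_genotypes_consistent(variants, g)
  list(variants = variants, genotypes = g, samples = samples)
}

parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop(sprintf("bad region '%s' (want contig:start-end)", region))
  list(contig = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Write a genotype VCF
#'
#' Emits a minimal plain-text VCF 4.2 with GT-only genotypes; phased calls use
#' "|", unphased "/", missing ".".
#'
#' @param variants variant table.
#' @param genotypes genotype matrix.
#' @param path output path.
#' @export
write_genotype_vcf <- function(variants, genotypes, path) {
  check_genotypes_consistent(variants, genotypes)
  ns <- n_samples(genotypes)
  nv <- n_variants(genotypes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", genotypes$samples), collapse = "\t")),
             con)
  if (nv == 0) return(invisible(path))
  ph <- if (is.matrix(genotypes$phased)) genotypes$phased
        else matrix(genotypes$phased, ns, nv)
  a1 <- genotypes$calls[, , 1, drop = FALSE]; dim(a1) <- c(ns, nv)
  a2 <- genotypes$calls[, , 2, drop = FALSE]; dim(a2) <- c(ns, nv)
  s1 <- ifelse(a1 < 0, ".", as.character(a1))
  s2 <- ifelse(a2 < 0, ".", as.character(a2))
  sep <- ifelse(ph, "|", "/")
  gtstr <- matrix(paste0(s1, sep, s2), ns, nv)
  rows <- vapply(seq_len(nv), function(j) {
    paste(c(variants$contig[j], variants$pos[j], ".", variants$ref[j],
            paste(variants$alts[[j]], collapse = ","), ".", "PASS", ".", "GT",
            gtstr[, j]), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated text with header \code{sample_id, species, site, zone, sex}.
#' Species, zone and sex tokens are validated against the study enums; sample
#' ids must be unique and each site must map to exactly one zone.
#'
#' @param path path to the TSV file.
#' @return data.frame, row order preserved.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "species", "site", "zone", "sex")
  if (!all(need %in% names(md)))
    stop(sprintf("metadata header must contain: %s", paste(need, collapse = ", ")))
  md <- md[, need]
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  dup <- md$sample_id[duplicated(md$sample_id)]
  if (length(dup))
    stop(sprintf("duplicate sample_id: %s", paste(unique(dup), collapse = ", ")))
  for (col in c("species", "zone", "sex")) {
    lv <- switch(col, species = SPECIES_LEVELS, zone = ZONE_LEVELS, sex = SEX_LEVELS)
    bad <- which(!md[[col]] %in% lv)
    if (length(bad))
      stop(sprintf("invalid %s '%s' in metadata row %d", col, md[[col]][bad[1]], bad[1]))
  }
  z <- unique(md[, c("site", "zone")])
  multi <- z$site[duplicated(z$site)]
  if (length(multi))
    stop(sprintf("site mapped to multiple zones: %s", paste(unique(multi), collapse = ", ")))
  invisible(TRUE)
}

#' Read a gene annotation table
#'
#' Tab-separated text with header
#' \code{gene_id, gene_name, family, contig, start, end}.
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
read_gene_annotation <- function(path) {
  an <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "gene_name", "family", "contig", "start", "end")
  if (!all(need %in% names(an)))
    stop(sprintf("annotation header must contain: %s", paste(need, collapse = ", ")))
  an <- an[, need]
  if (anyDuplicated(an$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(an$family %in% FAMILY_LEVELS)) stop("invalid gene family in annotation")
  if (!all(an$contig %in% CONTIG_LEVELS)) stop("invalid contig in annotation")
  if (any(an$start > an$end)) stop("gene start > end in annotation")
  an$start <- as.integer(an$start); an$end <- as.integer(an$end)
  an
}

#' Read a modal copy-number table
#'
#' Tab-separated text with header \code{sample_id, gene_id, cn}. Sparse entries
#' are allowed; absent (sample, gene) pairs are "no call" and are excluded from
#' frequency denominators downstream.
#'
#' @param path path to the TSV file.
#' @param annotation optional gene annotation; if given, unknown gene ids error.
#' @return data.frame with integer \code{cn}.
#' @export
read_cn_table <- function(path, annotation = NULL) {
  cn <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "cn")
  if (!all(need %in% names(cn)))
    stop(sprintf("CN table header must contain: %s", paste(need, collapse = ", ")))
  cn <- cn[, need]
  cn$cn <- as.integer(cn$cn)
  if (nrow(cn) && any(is.na(cn$cn))) stop("non-integer copy number in CN table")
  if (nrow(cn) && any(cn$cn < 0)) stop("negative copy number in CN table")
  if (!is.null(annotation)) {
    bad <- setdiff(unique(cn$gene_id), annotation$gene_id)
    if (length(bad))
      stop(sprintf("unknown gene_id in CN table: %s", paste(bad, collapse = ", ")))
  }
  cn
}

#' Write a result table as tab-separated text
#'
#' Floating-point columns are printed with 6 significant digits so that
#' repeated runs produce byte-identical files.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_result_table <- function(x, path) {
  y <- x
  for (j in seq_along(y)) {
    if (is.double(y[[j]])) y[[j]] <- signif(y[[j]], 6)
    if (is.list(y[[j]])) y[[j]] <- vapply(y[[j]], paste, "", collapse = ",")
  }
  write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{write_result_table}
#' @param x path to the TSV file.
#' @return data.frame.
#' @export
read_result_table <- function(x) read.delim(x, stringsAsFactors = FALSE)
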