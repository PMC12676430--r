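#' Construct a transcript model
#'
#' Minimal coding-transcript model used for codon-level effect annotation:
#' ordered exons (treated as CDS segments), a strand, and the reference
#' sequence covering the region.
#'
#' @param transcript_id transcript identifier.
#' @param strand "+" or "-".
#' @param exons data.frame with \code{start}, \code{end} (1-based inclusive,
#'   genomic coordinates, non-overlapping).
#' @param ref_seq reference sequence (character, A/C/G/T) for the covered span.
#' @param ref_offset genomic position of the first base of \code{ref_seq}.
#' @return list of class \code{transcript_model}.
#' @export
transcript_model <- function(transcript_id, strand, exons, ref_seq, ref_offset = 1L) {
  stopifnot(strand %in% c("+", "-"))
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap")
  cds_len <- sum(exons$end - exons$start + 1L)
  if (cds_len %% 3L != 0L) stop("CDS length not divisible by 3")
  ref_seq <- toupper(ref_seq)
  if (min(exons$start) < ref_offset ||
      max(exons$end) > ref_offset + nchar(ref_seq) - 1L)
    stop("reference sequence does not cover all exons")
  structure(list(transcript_id = transcript_id, strand = strand,
                 exons = exons, ref_seq = ref_seq,
                 ref_offset = as.integer(ref_offset)),
            class = "transcript_model")
}

#' Read a transcript model from GFF-like text plus a FASTA reference
#'
#' The GFF-like file is tab-separated with the standard 9 columns; rows of type
#' \code{CDS} define the exon set. The FASTA record name is either the contig
#' (sequence starts at position 1) or \code{contig:start-end}.
#'
#' @param gff_path path to the GFF-like file.
#' @param fasta_path path to the FASTA reference.
#' @param transcript_id transcript to extract (matched in column 9); default:
#'   use all CDS rows.
#' @return a \code{transcript_model}.
#' @export
read_transcript_model <- function(gff_path, fasta_path, transcript_id = NULL) {
  gff <- read.delim(gff_path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(gff) < 9) stop("GFF-like file needs 9 columns")
  names(gff)[c(1, 3, 4, 5, 7, 9)] <-
    c("seqid", "type", "start", "end", "strand", "attributes")
  cds <- gff[gff$type == "CDS", ]
  if (!is.null(transcript_id))
    cds <- cds[grepl(transcript_id, cds$attributes, fixed = TRUE), ]
  if (nrow(cds) == 0) stop("no CDS rows found")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(seqs)[1]
  offset <- 1L
  m <- regmatches(nm, regexec("^(\\S+):([0-9]+)-([0-9]+)", nm))[[1]]
  if (length(m) == 4) offset <- as.integer(m[3])
  tid <- if (is.null(transcript_id)) {
    m2 <- regmatches(cds$attributes[1], regexec("ID=([^;]+)", cds$attributes[1]))[[1]]
    if (length(m2) == 2) m2[2] else "transcript"
  } else transcript_id
  transcript_model(tid, cds$strand[1],
                   data.frame(start = as.integer(cds$start),
                              end = as.integer(cds$end)),
                   as.character(seqs[[1]]), offset)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# 1-based CDS index (5'->3' on the coding strand) for a genomic position,
# or NA when the position is not exonic
cds_index <- function(tx, pos) {
  ex <- tx$exons
  cum <- c(0L, cumsum(ex$end - ex$start + 1L))
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  fwd <- cum[hit] + (pos - ex$start[hit] + 1L)
  if (tx$strand == "+") fwd else sum(ex$end - ex$start + 1L) - fwd + 1L
}

cds_sequence <- function(tx) {
  pieces <- substring(tx$ref_seq,
                      tx$exons$start - tx$ref_offset + 1L,
                      tx$exons$end - tx$ref_offset + 1L)
  s <- paste(pieces, collapse = "")
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Annotate SNP effects against a transcript model
#'
#' Each alternate allele is labelled \code{"intronic"} (outside all exons),
#' \code{"synonymous"}, or \code{"<refAA><codon><altAA>"} (e.g. "L2Q") from
#' standard-genetic-code translation of the affected codon. On reverse-strand
#' transcripts alleles are complemented. Multiallelic sites are annotated per
#' alt independently.
#'
#' @param variants variant table.
#' @param tx transcript model.
#' @return the variant table with an \code{effect_labels} list column.
#' @export
annotate_effects <- function(variants, tx) {
  cds <- cds_sequence(tx)
  labels <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]
    ref <- variants$ref[i]
    alts <- variants$alts[[i]]
    ci <- cds_index(tx, pos)
    if (is.na(ci)) {
      labels[[i]] <- rep("intronic", length(alts))
      next
    }
    ref_coding <- if (tx$strand == "+") ref else COMPLEMENT[[ref]]
    if (substring(cds, ci, ci) != ref_coding)
      stop(sprintf("reference mismatch at %s:%d (VCF ref %s, transcript %s)",
                   variants$contig[i], pos, ref, substring(cds, ci, ci)))
    codon_no <- (ci - 1L) %/% 3L + 1L
    codon_pos <- (ci - 1L) %% 3L + 1L
    codon <- substring(cds, 3L * (codon_no - 1L) + 1L, 3L * codon_no)
    ref_aa <- translate_codon(codon)
    labels[[i]] <- vapply(alts, function(alt) {
      alt_coding <- if (tx$strand == "+") alt else COMPLEMENT[[alt]]
      mut <- codon
      substring(mut, codon_pos, codon_pos) <- alt_coding
      alt_aa <- translate_codon(mut)
      if (identical(alt_aa, ref_aa)) "synonymous"
      else paste0(ref_aa, codon_no, alt_aa)
    }, character(1), USE.NAMES = FALSE)
  }
  variants$effect_labels <- labels
  variants
}

is_nonsynonymous_label <- function(lab) {
  !(lab %in% c("synonymous", "intronic")) & grepl("^[A-Z*][0-9]+[A-Z*]$", lab)
}

#' Summarise effect classes over segregating sites
#'
#' Counts segregating sites within a sample subset and reports how many are
#' multiallelic and how many carry at least one non-synonymous (amino-acid
#' changing) alternate allele, with the corresponding percentages.
#'
#' @param variants annotated variant table (with \code{effect_labels}).
#' @param genotypes genotype matrix.
#' @param samples sample subset (default all).
#' @return list with \code{S}, \code{n_multiallelic}, \code{multiallelic_pct},
#'   \code{n_nonsynonymous}, \code{nonsynonymous_pct}.
#' @export
effect_site_summary <- function(variants, genotypes, samples = genotypes$samples) {
  idx <- match(samples, genotypes$samples)
  if (length(idx) == 0 || anyNA(idx)) stop("empty or unknown sample subset")
  calls <- genotypes$calls[idx, , , drop = FALSE]
  nv <- dim(calls)[2]
  n_obs <- vapply(seq_len(nv), function(j) {
    a <- as.vector(calls[, j, ])
    length(unique(a[a >= 0L]))
  }, integer(1))
  seg <- n_obs >= 2L
  S <- sum(seg)
  nonsyn <- vapply(variants$effect_labels, function(l) any(is_nonsynonymous_label(l)),
                   logical(1))
  n_multi <- sum(n_obs > 2L)
  n_ns <- sum(seg & nonsyn)
  list(S = S,
       n_multiallelic = n_multi,
       multiallelic_pct = if (S > 0) 100 * n_multi / S else NA_real_,
       n_nonsynonymous = n_ns,
       nonsynonymous_pct = if (S > 0) 100 * n_ns / S else NA_real_)
}

#' Per-population allele frequencies
#'
#' Alt-allele frequency = alt-allele count / non-missing allele count, per
#' population and per alternate allele. Rows whose frequency is below
#' \code{min_freq} in every population are dropped when the filter is enabled
#' (the aggregation rule is max over populations). When a kdr panel is
#' supplied, a derived cumulative row for the triallelic 402 locus (sum of the
#' two 402L alt frequencies) is appended per population.
#'
#' @param genotypes genotype matrix.
#' @param variants variant table (effect labels used when present).
#' @param metadata sample metadata.
#' @param group_by metadata column defining populations (default "site").
#' @param min_freq frequency threshold (default 0.05).
#' @param apply_filter drop rows below threshold in all populations.
#' @param panel optional kdr panel for the cumulative 402 row.
#' @return data.frame (population, contig, pos, alt, effect_label, count,
#'   total, frequency, defined).
#' @export
allele_frequencies <- function(genotypes, variants, metadata, group_by = "site",
                               min_freq = 0.05, apply_filter = TRUE,
                               panel = NULL) {
  groups <- split(metadata$sample_id, metadata[[group_by]])
  groups <- groups[vapply(groups, length, 1L) > 0]
  nv <- n_variants(genotypes)
  has_eff <- !is.null(variants$effect_labels)
  n_alt <- lengths(variants$alts)
  vj <- rep(seq_len(nv), n_alt)                    # variant row per output row
  kk <- unlist(lapply(n_alt, seq_len))             # alt index per output row
  alt_chr <- unlist(variants$alts)
  eff_chr <- if (has_eff) unlist(variants$effect_labels) else rep(NA_character_, length(vj))
  rows <- list()
  for (g in names(groups)) {
    ids <- intersect(groups[[g]], genotypes$samples)
    if (length(ids) == 0) next
    idx <- match(ids, genotypes$samples)
    A <- rbind(matrix(genotypes$calls[idx, , 1], ncol = nv),
               matrix(genotypes$calls[idx, , 2], ncol = nv))
    total <- colSums(A >= 0L)
    cnt_k <- vapply(1:3, function(k) colSums(A == k), numeric(nv))
    if (nv == 1) cnt_k <- matrix(cnt_k, nrow = 1)
    count <- cnt_k[cbind(vj, kk)]
    rows[[g]] <- data.frame(
      population = g, contig = variants$contig[vj], pos = variants$pos[vj],
      alt = alt_chr, effect_label = eff_chr,
      count = count, total = total[vj],
      frequency = ifelse(total[vj] > 0, count / total[vj], NA_real_),
      defined = total[vj] > 0, stringsAsFactors = FALSE)
  }
  ft <- do.call(rbind, rows)
  if (is.null(ft)) return(ft)
  if (apply_filter) {
    key <- paste(ft$contig, ft$pos, ft$alt)
    mx <- tapply(ifelse(is.na(ft$frequency), 0, ft$frequency), key, max)
    ft <- ft[mx[key] >= min_freq, , drop = FALSE]
  }
  if (!is.null(panel)) {
    l402 <- panel$loci[["402"]]
    cum <- lapply(names(groups), function(g) {
      sub <- ft[ft$population == g & ft$contig == l402$contig & ft$pos == l402$pos, ]
      if (nrow(sub) == 0) return(NULL)
      data.frame(population = g, contig = l402$contig, pos = l402$pos,
                 alt = paste(l402$alts, collapse = "+"),
                 effect_label = "V402L_cumulative",
                 count = sum(sub$count), total = sub$total[1],
                 frequency = sum(sub$frequency),
                 defined = all(sub$defined), stringsAsFactors = FALSE)
    })
    ft <- rbind(ft, do.call(rbind, cum))
  }
  rownames(ft) <- NULL
  ft
}

#' Rename codon-index effect labels to community names
#'
#' Community numbering of kdr codons (e.g. 995 for the codon historically
#' numbered 1014) differs from transcript-internal numbering; this applies a
#' configured alias map to the effect labels of a frequency table or variant
#' table.
#'
#' @param labels character vector of effect labels.
#' @param aliases named character vector, e.g. \code{c(L1014F = "L995F")}.
#' @return relabelled character vector.
#' @export
apply_label_aliases <- function(labels, aliases) {
  hit <- labels %in% names(aliases)
  labels[hit] <- unname(aliases[labels[hit]])
  labels
}
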