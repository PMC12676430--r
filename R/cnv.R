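#' Classify copy-number states against sex-aware baselines
#'
#' The baseline is 2 on autosomes and, on the X chromosome, 2 for females and
#' 1 for males; a call above baseline is an amplification, below a deletion
#' (copy number 0 is a complete deletion), equal is normal.
#'
#' @param cn_table data.frame (sample_id, gene_id, cn).
#' @param metadata sample metadata (sex required for X-linked entries).
#' @param annotation gene annotation table.
#' @return data.frame (sample_id, gene_id, cn, baseline, state).
#' @export
classify_cnv <- function(cn_table, metadata, annotation) {
  if (nrow(cn_table) == 0) {
    return(data.frame(sample_id = character(0), gene_id = character(0),
                      cn = integer(0), baseline = integer(0),
                      state = character(0)))
  }
  gi <- match(cn_table$gene_id, annotation$gene_id)
  if (anyNA(gi)) stop("CN table gene absent from annotation")
  contig <- annotation$contig[gi]
  si <- match(cn_table$sample_id, metadata$sample_id)
  sex <- metadata$sex[si]
  xlinked <- contig == "X"
  if (any(xlinked & (is.na(sex) | !sex %in% c("F", "M")))) {
    bad <- cn_table$sample_id[xlinked & (is.na(sex) | !sex %in% c("F", "M"))][1]
    stop(sprintf("unknown sex for sample %s with X-linked entry", bad))
  }
  baseline <- ifelse(xlinked, ifelse(sex == "F", 2L, 1L), 2L)
  state <- ifelse(cn_table$cn > baseline, "amp",
                  ifelse(cn_table$cn < baseline, "del", "normal"))
  data.frame(sample_id = cn_table$sample_id, gene_id = cn_table$gene_id,
             cn = cn_table$cn, baseline = as.integer(baseline), state = state,
             stringsAsFactors = FALSE)
}

#' Amplification and deletion frequencies per gene and population
#'
#' Frequency denominators are samples with a call for the gene in the
#' population (no-call pairs are excluded). Frequencies are reported on the
#' percentage scale.
#'
#' @param calls output of \code{classify_cnv}.
#' @param metadata sample metadata.
#' @param group_by metadata column defining populations (default "site").
#' @return data.frame (population, gene_id, n, amp_freq_pct, del_freq_pct).
#' @export
cnv_frequencies <- function(calls, metadata, group_by = "site") {
  if (nrow(calls) == 0) {
    return(data.frame(population = character(0), gene_id = character(0),
                      n = integer(0), amp_freq_pct = numeric(0),
                      del_freq_pct = numeric(0)))
  }
  m <- merge(calls, metadata, by = "sample_id", sort = FALSE)
  key <- interaction(m[[group_by]], m$gene_id, drop = TRUE)
  rows <- lapply(split(m, key), function(sub) {
    data.frame(population = sub[[group_by]][1], gene_id = sub$gene_id[1],
               n = nrow(sub),
               amp_freq_pct = 100 * mean(sub$state == "amp"),
               del_freq_pct = 100 * mean(sub$state == "del"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$population, out$gene_id), , drop = FALSE]
}

#' Gene-level CNV counts by family and chromosome arm
#'
#' Counts distinct genes with at least one amplification call, at least one
#' deletion call, and at least one CNV of either kind, overall and broken down
#' by gene family and contig. The union identity (amp-genes union del-genes =
#' CNV-genes) holds by construction.
#'
#' @param calls output of \code{classify_cnv}.
#' @param annotation gene annotation table.
#' @return list with \code{total} (single-row data.frame) and \code{by_group}
#'   (family x contig breakdown).
#' @export
cnv_gene_summary <- function(calls, annotation) {
  amp_genes <- unique(calls$gene_id[calls$state == "amp"])
  del_genes <- unique(calls$gene_id[calls$state == "del"])
  cnv_genes <- union(amp_genes, del_genes)
  total <- data.frame(n_genes_amp = length(amp_genes),
                      n_genes_del = length(del_genes),
                      n_genes_cnv = length(cnv_genes))
  gi <- match(cnv_genes, annotation$gene_id)
  if (anyNA(gi)) stop("CNV gene absent from annotation")
  grp <- expand.grid(family = FAMILY_LEVELS, contig = CONTIG_LEVELS,
                     stringsAsFactors = FALSE)
  by_group <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    sel <- annotation$gene_id[annotation$family == grp$family[i] &
                              annotation$contig == grp$contig[i]]
    data.frame(family = grp$family[i], contig = grp$contig[i],
               n_genes_amp = length(intersect(amp_genes, sel)),
               n_genes_del = length(intersect(del_genes, sel)),
               n_genes_cnv = length(intersect(cnv_genes, sel)),
               stringsAsFactors = FALSE)
  }))
  by_group <- by_group[by_group$n_genes_cnv > 0 | by_group$n_genes_amp > 0 |
                       by_group$n_genes_del > 0, , drop = FALSE]
  rownames(by_group) <- NULL
  list(total = total, by_group = by_group)
}

#' Long-format CNV export for genome-position scatter plots
#'
#' One row per (sample, gene) call with the gene midpoint position, copy
#' number, state, gene family and species, mirroring per-gene copy-number
#' scatter displays.
#'
#' @param calls output of \code{classify_cnv}.
#' @param metadata sample metadata.
#' @param annotation gene annotation table.
#' @return data.frame.
#' @export
cnv_scatter_export <- function(calls, metadata, annotation) {
  gi <- match(calls$gene_id, annotation$gene_id)
  si <- match(calls$sample_id, metadata$sample_id)
  data.frame(gene_id = calls$gene_id,
             gene_name = annotation$gene_name[gi],
             family = annotation$family[gi],
             contig = annotation$contig[gi],
             position = (annotation$start[gi] + annotation$end[gi]) %/% 2L,
             sample_id = calls$sample_id,
             species = metadata$species[si],
             site = metadata$site[si],
             cn = calls$cn, baseline = calls$baseline, state = calls$state,
             stringsAsFactors = FALSE)
}
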