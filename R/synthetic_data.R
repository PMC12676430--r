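VGSC_SPAN <- c(2358158L, 2431617L)   # conventional Vgsc gene span on 2L

#' Define a synthetic population
#'
#' @param name population label.
#' @param species one of the three An. gambiae s.l. species enums.
#' @param site collection site.
#' @param zone ecological zone.
#' @param n_samples number of diploid individuals (> 0).
#' @param kdr_hap_freqs named numeric vector of haplotype-class frequencies
#'   (labels like "FVI", "LL1T"); must sum to 1.
#' @param sex_ratio fraction of females (default 0.5).
#' @param n_background_sites neutral segregating sites private to this
#'   population (default 0).
#' @param cn_specs named list gene_id -> list(amp_freq, del_freq,
#'   amp_geom_prob) for the copy-number generator.
#' @return list of class \code{population_spec}.
#' @export
population_spec <- function(name, species, site, zone, n_samples,
                            kdr_hap_freqs, sex_ratio = 0.5,
                            n_background_sites = 0L, cn_specs = NULL) {
  stopifnot(species %in% SPECIES_LEVELS, zone %in% ZONE_LEVELS,
            n_samples > 0, sex_ratio >= 0, sex_ratio <= 1,
            n_background_sites >= 0)
  if (abs(sum(kdr_hap_freqs) - 1) > 1e-9)
    stop(sprintf("kdr_hap_freqs must sum to 1 (got %.12f) for population %s",
                 sum(kdr_hap_freqs), name))
  if (!is.null(cn_specs)) {
    for (g in names(cn_specs)) {
      cs <- cn_specs[[g]]
      if (cs$amp_freq + cs$del_freq > 1)
        stop(sprintf("amp_freq + del_freq > 1 for gene %s in population %s", g, name))
    }
  }
  structure(list(name = name, species = species, site = site, zone = zone,
                 n_samples = as.integer(n_samples),
                 sex_ratio = sex_ratio,
                 kdr_hap_freqs = kdr_hap_freqs,
                 n_background_sites = as.integer(n_background_sites),
                 cn_specs = cn_specs),
            class = "population_spec")
}

random_ref_alt <- function(n) {
  nucs <- c("A", "C", "G", "T")
  ref <- sample(nucs, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1L), character(1),
                USE.NAMES = FALSE)
  list(ref = ref, alt = alt)
}

#' Simulate a kdr cohort with retained ground truth
#'
#' Each individual's two haplotypes are drawn i.i.d. from the population's
#' haplotype-class frequencies (random union of gametes, i.e. Hardy-Weinberg
#' pairing). Genotypes at the three panel loci encode the drawn labels.
#' Optionally, each haplotype class carries \code{class_private_sites} fixed
#' marker mutations (making haplotype networks non-degenerate), and each
#' population contributes \code{n_background_sites} neutral segregating sites
#' drawn from the standard neutral site-frequency spectrum, polymorphic within
#' that population and reference elsewhere. Deterministic for a fixed seed.
#'
#' @param specs list of \code{population_spec}.
#' @param seed integer seed.
#' @param panel kdr panel (default \code{kdr_panel()}).
#' @param class_private_sites marker mutations per haplotype class (default 0).
#' @param region 1-based inclusive span for simulated positions.
#' @return list with \code{variants}, \code{genotypes} (phased),
#'   \code{metadata}, \code{truth}.
#' @export
simulate_kdr_cohort <- function(specs, seed, panel = kdr_panel(),
                                class_private_sites = 0L,
                                region = VGSC_SPAN) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  for (sp in specs) {
    if (abs(sum(sp$kdr_hap_freqs) - 1) > 1e-9)
      stop("haplotype frequencies must sum to 1")
  }
  set.seed(seed)
  N <- sum(vapply(specs, `[[`, 1L, "n_samples"))
  pop_of <- rep(seq_along(specs), vapply(specs, `[[`, 1L, "n_samples"))
  sample_id <- unlist(lapply(specs, function(sp)
    sprintf("%s_%03d", sp$name, seq_len(sp$n_samples))))
  sex <- unlist(lapply(specs, function(sp)
    ifelse(runif(sp$n_samples) < sp$sex_ratio, "F", "M")))
  metadata <- data.frame(
    sample_id = sample_id,
    species = rep(vapply(specs, `[[`, "", "species"),
                  vapply(specs, `[[`, 1L, "n_samples")),
    site = rep(vapply(specs, `[[`, "", "site"),
               vapply(specs, `[[`, 1L, "n_samples")),
    zone = rep(vapply(specs, `[[`, "", "zone"),
               vapply(specs, `[[`, 1L, "n_samples")),
    sex = sex, stringsAsFactors = FALSE)
  # draw haplotype class labels, two per individual
  hap_labels <- matrix(NA_character_, N, 2)
  for (p in seq_along(specs)) {
    sp <- specs[[p]]
    idx <- which(pop_of == p)
    hap_labels[idx, ] <- sample(names(sp$kdr_hap_freqs), 2 * length(idx),
                                replace = TRUE, prob = sp$kdr_hap_freqs)
  }
  classes <- sort(unique(as.vector(hap_labels)))
  class_alleles <- lapply(classes, label_to_alleles, panel = panel)
  names(class_alleles) <- classes
  if (any(vapply(class_alleles, is.null, TRUE)))
    stop("haplotype class label not expressible under the panel")
  # variant layout: panel loci + class-private sites + per-population background
  panel_pos <- vapply(panel$loci, `[[`, 1L, "pos")
  n_priv <- length(classes) * class_private_sites
  n_bg <- sum(vapply(specs, `[[`, 1L, "n_background_sites"))
  avail <- setdiff(seq.int(region[1], region[2]), panel_pos)
  if (n_priv + n_bg > length(avail)) stop("region too small for requested sites")
  extra_pos <- sort(sample(avail, n_priv + n_bg))
  priv_pos <- if (n_priv > 0) sort(sample(extra_pos, n_priv)) else integer(0)
  bg_pos_all <- setdiff(extra_pos, priv_pos)
  priv_class <- if (n_priv > 0) rep(classes, each = class_private_sites) else character(0)
  # shuffle private sites over their positions deterministically
  if (n_priv > 0) priv_class <- sample(priv_class)
  bg_pop <- if (n_bg > 0) {
    unlist(lapply(seq_along(specs), function(p)
      rep(p, specs[[p]]$n_background_sites)))
  } else integer(0)
  if (n_bg > 0) bg_pop <- sample(bg_pop)
  # assemble variant table (positions sorted)
  ra <- random_ref_alt(n_priv + n_bg)
  pos_all <- c(panel_pos, priv_pos, bg_pos_all)
  ref_all <- c(vapply(panel$loci, `[[`, "", "ref"), ra$ref)
  alts_all <- c(lapply(panel$loci, `[[`, "alts"), as.list(ra$alt))
  kind <- c(rep("panel", 3), rep("private", n_priv), rep("background", n_bg))
  meta_site <- c(names(panel$loci), priv_class, as.character(bg_pop))
  o <- order(pos_all)
  variants <- variant_table(rep(panel$loci[[1]]$contig, length(pos_all)),
                            pos_all[o], ref_all[o], alts_all[o])
  kind <- kind[o]; meta_site <- meta_site[o]
  # haplotype allele matrix (2N x nv)
  nv <- nrow(variants)
  H <- matrix(0L, 2 * N, nv)
  hap_class <- character(2 * N)
  hap_class[seq(1, 2 * N, 2)] <- hap_labels[, 1]
  hap_class[seq(2, 2 * N, 2)] <- hap_labels[, 2]
  hap_pop <- rep(pop_of, each = 2)
  for (j in seq_len(nv)) {
    if (kind[j] == "panel") {
      locus_i <- match(meta_site[j], names(panel$loci))
      H[, j] <- vapply(hap_class, function(cl) class_alleles[[cl]][locus_i],
                       integer(1), USE.NAMES = FALSE)
    } else if (kind[j] == "private") {
      H[, j] <- as.integer(hap_class == meta_site[j])
    } else {
      p <- as.integer(meta_site[j])
      rows <- which(hap_pop == p)
      nh <- length(rows)
      k <- sample(seq_len(nh - 1), 1L, prob = 1 / seq_len(nh - 1))
      H[sample(rows, k), j] <- 1L
    }
  }
  calls <- array(0L, dim = c(N, nv, 2))
  calls[, , 1] <- H[seq(1, 2 * N, 2), ]
  calls[, , 2] <- H[seq(2, 2 * N, 2), ]
  genotypes <- genotype_matrix(calls, phased = TRUE, samples = sample_id)
  truth <- cohort_truth(specs, pop_of, sample_id, hap_labels, panel)
  list(variants = variants, genotypes = genotypes, metadata = metadata,
       truth = truth)
}

# truth tables: per-sample haplotype pair, per-population haplotype
# frequencies (spec and drawn), and phased-count r2 per 402 allele vs 1527T
cohort_truth <- function(specs, pop_of, sample_id, hap_labels, panel) {
  haps <- data.frame(sample_id = sample_id,
                     population = vapply(specs, `[[`, "", "site")[pop_of],
                     hap1 = hap_labels[, 1], hap2 = hap_labels[, 2],
                     stringsAsFactors = FALSE)
  freq_rows <- list()
  r2_rows <- list()
  carries <- function(labels, locus_i, allele) {
    al <- vapply(labels, function(cl) label_to_alleles(cl, panel)[locus_i],
                 integer(1), USE.NAMES = FALSE)
    as.integer(al == allele)
  }
  pops <- c(split(seq_along(pop_of), pop_of), list(pooled = seq_along(pop_of)))
  names(pops) <- c(vapply(specs, `[[`, "", "site"), "pooled")
  for (pn in names(pops)) {
    idx <- pops[[pn]]
    drawn <- as.vector(hap_labels[idx, ])
    tab <- table(drawn) / length(drawn)
    spec_freq <- if (pn == "pooled") NULL else
      specs[[which(vapply(specs, `[[`, "", "site") == pn)]]$kdr_hap_freqs
    freq_rows[[pn]] <- data.frame(
      population = pn, label = names(tab),
      empirical_freq = as.numeric(tab),
      spec_freq = if (is.null(spec_freq)) NA_real_
                  else as.numeric(spec_freq[names(tab)]),
      stringsAsFactors = FALSE)
    hap_t <- carries(drawn, 3L, 1L)
    for (al in c(1L, 2L)) {
      hap_l <- carries(drawn, 2L, al)
      pr <- phased_r2(hap_l, hap_t)
      r2_rows[[paste(pn, al)]] <- data.frame(
        population = pn,
        allele_pair = sprintf("402L(g>%s) vs 1527T", c("t", "c")[al]),
        r2 = pr$r2, D = pr$D, defined = pr$defined, stringsAsFactors = FALSE)
    }
  }
  list(haplotypes = haps,
       hap_freqs = do.call(rbind, c(freq_rows, make.row.names = FALSE)),
       r2 = do.call(rbind, c(r2_rows, make.row.names = FALSE)))
}

#' Simulate unlinked neutral segregating sites
#'
#' Each site's derived-allele count k is drawn from the standard neutral
#' site-frequency spectrum, Pr(k) proportional to 1/k for k in 1..n-1, and a
#' uniformly random subset of k haplotypes carries the derived allele. Sites
#' are independent and every emitted column is polymorphic.
#'
#' @param n_haplotypes number of haplotypes (>= 2).
#' @param S number of segregating sites (>= 0).
#' @param seed integer seed.
#' @return 0/1 matrix of dimension n_haplotypes x S.
#' @export
simulate_neutral_sites <- function(n_haplotypes, S, seed) {
  stopifnot(n_haplotypes >= 2, S >= 0)
  set.seed(seed)
  H <- matrix(0L, n_haplotypes, S)
  if (S == 0) return(H)
  kprob <- 1 / seq_len(n_haplotypes - 1)
  ks <- sample(seq_len(n_haplotypes - 1), S, replace = TRUE, prob = kprob)
  for (j in seq_len(S)) {
    H[sample(n_haplotypes, ks[j]), j] <- 1L
  }
  H
}

#' Simulate a modal copy-number table
#'
#' Per sample and gene: deletion with probability del_freq (copy number drawn
#' uniformly below baseline, >= 0), amplification with probability amp_freq
#' (baseline + 1 + geometric), otherwise the baseline. The baseline is 2 on
#' autosomes and, on the X, 2 for females and 1 for males.
#'
#' @param specs list of \code{population_spec} (cn_specs fields used).
#' @param annotation gene annotation table.
#' @param seed integer seed.
#' @param metadata optional cohort metadata (sample ids and sexes reused); if
#'   NULL a cohort layout is generated from the specs.
#' @return list with \code{cn_table} (sample_id, gene_id, cn) and \code{truth}
#'   (sample_id, gene_id, state).
#' @export
simulate_cn_table <- function(specs, annotation, seed, metadata = NULL) {
  if (inherits(specs, "population_spec")) specs <- list(specs)
  set.seed(seed + 1L)
  if (is.null(metadata)) {
    sample_id <- unlist(lapply(specs, function(sp)
      sprintf("%s_%03d", sp$name, seq_len(sp$n_samples))))
    sex <- unlist(lapply(specs, function(sp)
      ifelse(runif(sp$n_samples) < sp$sex_ratio, "F", "M")))
    metadata <- data.frame(sample_id = sample_id, sex = sex,
                           site = rep(vapply(specs, `[[`, "", "site"),
                                      vapply(specs, `[[`, 1L, "n_samples")),
                           stringsAsFactors = FALSE)
  }
  pop_sizes <- vapply(specs, `[[`, 1L, "n_samples")
  pop_of <- rep(seq_along(specs), pop_sizes)
  rows <- list()
  for (p in seq_along(specs)) {
    sp <- specs[[p]]
    if (is.null(sp$cn_specs)) next
    bad <- setdiff(names(sp$cn_specs), annotation$gene_id)
    if (length(bad))
      stop(sprintf("cn_specs gene not in annotation: %s", paste(bad, collapse = ", ")))
    ids <- metadata$sample_id[pop_of == p]
    sexes <- metadata$sex[pop_of == p]
    for (g in names(sp$cn_specs)) {
      cs <- sp$cn_specs[[g]]
      contig <- annotation$contig[annotation$gene_id == g]
      baseline <- if (contig == "X") ifelse(sexes == "F", 2L, 1L)
                  else rep(2L, length(ids))
      u <- runif(length(ids))
      state <- ifelse(u < cs$del_freq, "del",
                      ifelse(u < cs$del_freq + cs$amp_freq, "amp", "normal"))
      gp <- if (is.null(cs$amp_geom_prob)) 0.5 else cs$amp_geom_prob
      cn <- baseline
      n_amp <- sum(state == "amp")
      if (n_amp) cn[state == "amp"] <- baseline[state == "amp"] + 1L +
          rgeom(n_amp, gp)
      n_del <- sum(state == "del")
      if (n_del) cn[state == "del"] <- vapply(baseline[state == "del"],
          function(b) sample.int(b, 1L) - 1L, integer(1))
      rows[[paste(p, g)]] <- data.frame(sample_id = ids, gene_id = g,
                                        cn = as.integer(cn), state = state,
                                        stringsAsFactors = FALSE)
    }
  }
  all <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(all)) {
    all <- data.frame(sample_id = character(0), gene_id = character(0),
                      cn = integer(0), state = character(0))
  }
  list(cn_table = all[, c("sample_id", "gene_id", "cn")],
       truth = all[, c("sample_id", "gene_id", "state")])
}

#' The default study-emulating cohort configuration
#'
#' Eight populations of ~100 mosquitoes across the three ecological zones:
#' An. gambiae s.s. fixed for FVI; An. coluzzii mixing LVI/FVI/LL1T with rare
#' LL2T; An. arabiensis mixing FVI and SVI. Each population carries 750
#' neutral background sites, and every haplotype class carries 3 private
#' marker mutations.
#'
#' @return list with \code{specs} (population specs), \code{class_private_sites},
#'   and \code{annotation} (detoxification gene table).
#' @export
default_cohort_config <- function() {
  path <- system.file("extdata", "default_cohort.yaml", package = "kdrpopgen")
  read_cohort_config(path)
}

#' Read a cohort configuration from YAML
#'
#' Schema: top-level keys \code{class_private_sites} (integer),
#' \code{annotation} (list of gene records: gene_id, gene_name, family,
#' contig, start, end) and \code{populations} (list of records with the
#' \code{population_spec} fields; \code{kdr_hap_freqs} and \code{cn_specs}
#' are maps).
#'
#' @param path path to the YAML file.
#' @return list with \code{specs}, \code{class_private_sites}, \code{annotation}.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  y <- yaml::read_yaml(path)
  ann <- do.call(rbind, lapply(y$annotation, function(g)
    data.frame(gene_id = g$gene_id, gene_name = g$gene_name,
               family = g$family, contig = g$contig,
               start = as.integer(g$start), end = as.integer(g$end),
               stringsAsFactors = FALSE)))
  specs <- lapply(y$populations, function(p) {
    cn <- NULL
    if (!is.null(p$cn_specs)) {
      cn <- lapply(p$cn_specs, function(cs)
        list(amp_freq = cs$amp_freq %||% 0,
             del_freq = cs$del_freq %||% 0,
             amp_geom_prob = cs$amp_geom_prob %||% 0.5))
      names(cn) <- names(p$cn_specs)
    }
    population_spec(name = p$name, species = p$species, site = p$site,
                    zone = p$zone, n_samples = p$n_samples,
                    kdr_hap_freqs = unlist(p$kdr_hap_freqs),
                    sex_ratio = p$sex_ratio %||% 0.5,
                    n_background_sites = p$n_background_sites %||% 0L,
                    cn_specs = cn)
  })
  list(specs = specs,
       class_private_sites = y$class_private_sites %||% 0L,
       annotation = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated cohort to files
#'
#' Emits the phased VCF, metadata, gene annotation, copy-number table and a
#' JSON ground-truth bundle into a directory.
#'
#' @param cohort output of \code{simulate_kdr_cohort}.
#' @param cn output of \code{simulate_cn_table} (or NULL).
#' @param annotation gene annotation table (or NULL).
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_cohort <- function(cohort, cn = NULL, annotation = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genotype_vcf(cohort$variants, cohort$genotypes, paths["vcf"])
  write.table(cohort$metadata, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- cohort$truth
  if (!is.null(cn)) {
    paths["cn_table"] <- file.path(dir, "cn_table.tsv")
    write.table(cn$cn_table, paths["cn_table"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    truth$cnv_states <- cn$truth
  }
  if (!is.null(annotation)) {
    paths["annotation"] <- file.path(dir, "annotation.tsv")
    write.table(annotation, paths["annotation"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
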