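#' Build an analysis configuration
#'
#' Exactly one of \code{synthetic} (a cohort configuration as returned by
#' \code{read_cohort_config}) or \code{inputs} (named paths vcf, metadata,
#' annotation, cn_table) must be supplied.
#'
#' @param synthetic cohort configuration list, or NULL.
#' @param inputs named list of input paths, or NULL.
#' @param seed integer seed used for simulation.
#' @param panel kdr panel.
#' @param region "contig:start-end" analysis region (default the Vgsc span).
#' @param min_freq allele-frequency reporting threshold (default 0.05).
#' @param ld_min_n minimum population size for LD rows (default 5).
#' @param pca_maf PCA minor-allele-frequency filter (default 0.01).
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(synthetic = NULL, inputs = NULL, seed = 1L,
                            panel = kdr_panel(),
                            region = sprintf("2L:%d-%d", VGSC_SPAN[1], VGSC_SPAN[2]),
                            min_freq = 0.05, ld_min_n = 5L, pca_maf = 0.01) {
  if (is.null(synthetic) == is.null(inputs))
    stop("exactly one of synthetic spec or real inputs must be configured")
  if (!is.null(inputs)) {
    need <- c("vcf", "metadata", "annotation", "cn_table")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop(sprintf("missing input paths: %s", paste(miss, collapse = ", ")))
    absent <- !vapply(unlist(inputs[need]), file.exists, TRUE)
    if (any(absent))
      stop(sprintf("input path does not exist: %s",
                   paste(unlist(inputs[need])[absent], collapse = ", ")))
  }
  structure(list(synthetic = synthetic, inputs = inputs, seed = as.integer(seed),
                 panel = panel, region = region, min_freq = min_freq,
                 ld_min_n = as.integer(ld_min_n), pca_maf = pca_maf),
            class = "analysis_config")
}

#' Run the full resistance-genomics analysis
#'
#' Runs all stages in dependency order: cohort simulation (or input loading),
#' diversity statistics, effect-level allele frequencies with the cluster-map
#' ordering, diplotype classification / frequencies / clustering / PCA, the
#' 402-vs-1527 LD table, the median-joining haplotype network, and CNV
#' summaries. Every output table is written with fixed precision and listed in
#' a manifest with content checksums, so an identical configuration and seed
#' reproduce identical manifests. Any stage failure aborts with the stage name
#' after writing a FAILED marker.
#'
#' @param config an \code{analysis_config}.
#' @param out_dir output directory.
#' @return invisible manifest list.
#' @export
run_full_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  timings <- c()
  logmsg <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }
  cfg_hash <- config_hash(config)
  logmsg("seed: %d", config$seed)
  logmsg("config_hash: %s", cfg_hash)
  outputs <- character(0)
  stage <- function(name, fun) {
    ts <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      writeLines("FAILED", file.path(out_dir, "FAILED"))
      logmsg("stage %s FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logmsg("stage %s: %.2fs", name,
           as.numeric(difftime(Sys.time(), ts, units = "secs")))
    res
  }

  env <- new.env()
  stage("inputs", function() {
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      cohort <- simulate_kdr_cohort(sc$specs, seed = config$seed,
                                    panel = config$panel,
                                    class_private_sites = sc$class_private_sites)
      cn <- simulate_cn_table(sc$specs, sc$annotation, seed = config$seed,
                              metadata = cohort$metadata)
      paths <- write_cohort(cohort, cn, sc$annotation,
                            file.path(out_dir, "input"))
      env$annotation <- sc$annotation
      env$truth_path <- unname(paths["truth"])
      loaded <- read_genotype_vcf(paths["vcf"], region = config$region)
      env$variants <- loaded$variants
      env$genotypes <- loaded$genotypes
      env$metadata <- read_metadata(paths["metadata"])
      env$cn_table <- read_cn_table(paths["cn_table"], env$annotation)
    } else {
      loaded <- read_genotype_vcf(config$inputs$vcf, region = config$region)
      env$variants <- loaded$variants
      env$genotypes <- loaded$genotypes
      env$metadata <- read_metadata(config$inputs$metadata)
      env$annotation <- read_gene_annotation(config$inputs$annotation)
      env$cn_table <- read_cn_table(config$inputs$cn_table, env$annotation)
    }
    env$vidx <- panel_variant_index(env$variants, config$panel)
    invisible(NULL)
  })

  emit <- function(x, name) {
    p <- file.path(out_dir, name)
    write_result_table(x, p)
    outputs <<- c(outputs, name)
    p
  }

  stage("diversity", function() {
    emit(diversity_stats(env$variants, env$genotypes, env$metadata), "diversity.tsv")
  })

  stage("frequencies", function() {
    # panel + class-marker sites stand in for the non-synonymous SNP set
    ft <- allele_frequencies(env$genotypes, env$variants, env$metadata,
                             min_freq = config$min_freq, apply_filter = TRUE,
                             panel = config$panel)
    env$freq_table <- ft
    emit(ft, "allele_frequencies.tsv")
    # cluster-map ordering of the variant x population frequency matrix
    base <- ft[ft$effect_label != "V402L_cumulative" | is.na(ft$effect_label), ]
    key <- paste0(base$contig, ":", base$pos, "_", base$alt)
    mat <- tapply(base$frequency, list(key, base$population), mean)
    mat[is.na(mat)] <- 0
    ord <- cluster_map_order(mat)
    emit(data.frame(axis = c(rep("variant", nrow(mat)), rep("population", ncol(mat))),
                    name = c(rownames(mat)[ord$row_order], colnames(mat)[ord$col_order]),
                    rank = c(seq_len(nrow(mat)), seq_len(ncol(mat)))),
         "cluster_map_order.tsv")
  })

  stage("diplotypes", function() {
    calls <- classify_diplotypes(env$variants, env$genotypes, config$panel)
    env$diplotype_calls <- calls
    emit(calls, "diplotype_calls.tsv")
    emit(diplotype_frequencies(calls, env$metadata), "diplotype_frequencies.tsv")
    cl <- genotype_clustering(env$genotypes)
    write_dendrogram_newick(cl, file.path(out_dir, "diplotype_dendrogram.nwk"))
    outputs <<- c(outputs, "diplotype_dendrogram.nwk")
    dos <- dosage_matrix(env$variants, env$genotypes)
    pc <- pca_dosage(dos, maf_min = config$pca_maf)
    emit(data.frame(sample_id = rownames(pc$scores),
                    round(pc$scores[, 1:min(4, ncol(pc$scores))], 6)),
         "pca_coordinates.tsv")
    emit(data.frame(component = seq_along(pc$explained),
                    explained = pc$explained), "pca_explained.tsv")
  })

  stage("ld", function() {
    emit(ld_table(env$variants, env$genotypes, env$metadata,
                  panel = config$panel, min_n = config$ld_min_n), "ld_table.tsv")
    # pooled per species as in the study's species-level row
    for (sp in unique(env$metadata$species)) {
      sub <- env$metadata[env$metadata$species == sp, ]
      lt <- ld_table(env$variants, env$genotypes, sub, panel = config$panel,
                     pooled_label = sp, min_n = config$ld_min_n)
      lt <- lt[lt$population == sp, , drop = FALSE]
      emit(lt, sprintf("ld_pooled_%s.tsv", sp))
    }
  })

  stage("network", function() {
    # network over the panel loci plus variation shared across populations;
    # population-private background sites would make every haplotype unique
    shared <- network_site_filter(env$variants, env$genotypes, env$metadata)
    keep <- sort(union(env$vidx, which(shared)))
    h <- haplotype_rows(env$genotypes, variant_idx = keep)
    ann <- data.frame(
      species = rep(env$metadata$species[match(env$genotypes$samples,
                                               env$metadata$sample_id)], each = 2),
      group = rep(env$diplotype_calls$group, each = 2),
      stringsAsFactors = FALSE)
    col <- collapse_haplotypes(h, ann)
    net <- median_joining(col, epsilon = 0L)
    dot <- network_to_dot(net, color_by = "group")
    writeLines(dot, file.path(out_dir, "haplotype_network.dot"))
    outputs <<- c(outputs, "haplotype_network.dot")
    jsonlite::write_json(net$tallies, file.path(out_dir, "network_tallies.json"),
                         digits = NA)
    outputs <<- c(outputs, "network_tallies.json")
  })

  stage("cnv", function() {
    calls <- classify_cnv(env$cn_table, env$metadata, env$annotation)
    emit(calls, "cnv_calls.tsv")
    emit(cnv_frequencies(calls, env$metadata), "cnv_frequencies.tsv")
    summ <- cnv_gene_summary(calls, env$annotation)
    emit(summ$total, "cnv_gene_totals.tsv")
    emit(summ$by_group, "cnv_gene_by_group.tsv")
    emit(cnv_scatter_export(calls, env$metadata, env$annotation), "cnv_scatter.tsv")
  })

  manifest <- stage("manifest", function() {
    files <- sort(outputs)
    sums <- as.character(tools::md5sum(file.path(out_dir, files)))
    manifest <- list(seed = config$seed, config_hash = cfg_hash,
                     files = as.list(setNames(sums, files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    manifest
  })
  logmsg("total: %.2fs", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(manifest)
}

# variants whose alt-allele carriers span at least two populations: selects
# haplotype-class-shared variation and drops population-private background
# sites, which would make every network haplotype unique
network_site_filter <- function(variants, genotypes, metadata, min_pops = 2L) {
  nv <- n_variants(genotypes)
  a1 <- matrix(genotypes$calls[, , 1], ncol = nv)
  a2 <- matrix(genotypes$calls[, , 2], ncol = nv)
  carrier <- a1 > 0 | a2 > 0
  pop <- metadata$site[match(genotypes$samples, metadata$sample_id)]
  vapply(seq_len(nv), function(j) {
    length(unique(pop[carrier[, j]])) >= min_pops
  }, logical(1))
}

config_hash <- function(config) {
  panel_min <- lapply(config$panel$loci,
                      function(l) l[c("contig", "pos", "ref", "alts")])
  s <- jsonlite::toJSON(list(seed = config$seed, region = config$region,
                             min_freq = config$min_freq,
                             ld_min_n = config$ld_min_n,
                             pca_maf = config$pca_maf, panel = panel_min,
                             synthetic = !is.null(config$synthetic)),
                        auto_unbox = TRUE)
  tf <- tempfile()
  writeLines(as.character(s), tf)
  h <- unname(tools::md5sum(tf))
  unlink(tf)
  h
}
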