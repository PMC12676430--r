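# shared fixture builders; everything is generated in code

# small two-population cohort spec used across tests
small_specs <- function(n1 = 40, n2 = 30,
                        freqs1 = c(LVI = 0.35, FVI = 0.30, LL1T = 0.32, LL2T = 0.03),
                        freqs2 = c(FVI = 1.0),
                        bg = 20) {
  list(
    population_spec("PopA", "An_coluzzii", "Bana", "Sudanian", n1, freqs1,
                    n_background_sites = bg),
    population_spec("PopB", "An_gambiae_ss", "Po-Dongo", "Sudanian", n2, freqs2,
                    n_background_sites = bg))
}

# genotype matrix fixture: one triallelic site, two samples 0/1 and 2|2
tiny_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("2L", "100", ".", "G", "T,C", ".", "PASS", ".", "GT",
            "0/1", "2|2"), collapse = "\t"),
    paste(c("2L", "120", ".", "A", "T", ".", "PASS", ".", "GT",
            "./.", "0/0"), collapse = "\t")), path)
  path
}

# metadata text fixture
write_metadata_fixture <- function(path, rows) {
  writeLines(c("sample_id\tspecies\tsite\tzone\tsex", rows), path)
  path
}

# brute-force minimal Steiner-network cost in the binary Hamming cube:
# minimum MST cost over the terminals plus up to max_extra added vertices
steiner_min_cost <- function(terminals, max_extra = 2) {
  ham <- function(x, y) sum(x != y)
  mst_cost <- function(mat) {
    n <- nrow(mat)
    if (n < 2) return(0)
    D <- as.matrix(dist(mat, method = "manhattan"))
    in_tree <- c(TRUE, rep(FALSE, n - 1))
    cost <- 0
    while (!all(in_tree)) {
      sub <- D[in_tree, !in_tree, drop = FALSE]
      m <- min(sub)
      cost <- cost + m
      j <- which(!in_tree)[which(sub == m, arr.ind = TRUE)[1, 2]]
      in_tree[j] <- TRUE
    }
    cost
  }
  L <- ncol(terminals)
  cand <- as.matrix(expand.grid(rep(list(0:1), L)))
  best <- mst_cost(terminals)
  if (max_extra >= 1) {
    for (i in seq_len(nrow(cand))) {
      best <- min(best, mst_cost(rbind(terminals, cand[i, ])))
    }
  }
  if (max_extra >= 2) {
    for (i in seq_len(nrow(cand) - 1)) {
      for (j in (i + 1):nrow(cand)) {
        best <- min(best, mst_cost(rbind(terminals, cand[i, ], cand[j, ])))
      }
    }
  }
  best
}

# adjusted-free Rand index between two partitions
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
  same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
  mean(same_a == same_b)
}

# diploid two-locus data from haplotype frequencies f = (AB, Ab, aB, ab);
# returns phased indicators and unphased dosages on the same draws
draw_two_locus <- function(n, f, seed) {
  set.seed(seed)
  hap <- sample(4, 2 * n, replace = TRUE, prob = f)
  A <- c(1, 1, 0, 0)[hap]
  B <- c(1, 0, 1, 0)[hap]
  list(A = A, B = B,
       dosA = A[seq(1, 2 * n, 2)] + A[seq(2, 2 * n, 2)],
       dosB = B[seq(1, 2 * n, 2)] + B[seq(2, 2 * n, 2)])
}
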