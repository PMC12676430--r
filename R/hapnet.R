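#' Collapse haplotypes to unique vectors with multiplicities
#'
#' Exact-match collapse of a haplotype matrix; optional per-haplotype
#' annotations (species, diplotype group, ...) are tallied per unique node for
#' network colouring. Unique haplotypes are ordered lexicographically so the
#' collapse is deterministic.
#'
#' @param haplotypes matrix (haplotypes x sites) of integer states.
#' @param annotations optional data.frame with one row per haplotype.
#' @return list with \code{haplotypes} (unique matrix), \code{multiplicity},
#'   and \code{tallies} (named list of count tables per annotation column).
#' @export
collapse_haplotypes <- function(haplotypes, annotations = NULL) {
  stopifnot(is.matrix(haplotypes))
  if (!is.null(annotations))
    stopifnot(nrow(annotations) == nrow(haplotypes))
  key <- apply(haplotypes, 1, paste, collapse = ",")
  ukey <- sort(unique(key))
  idx <- match(ukey, key)
  uh <- haplotypes[idx, , drop = FALSE]
  rownames(uh) <- NULL
  mult <- as.integer(table(key)[ukey])
  tallies <- NULL
  if (!is.null(annotations)) {
    tallies <- lapply(annotations, function(col) {
      tab <- table(node = factor(key, levels = ukey), value = col)
      matrix(as.integer(tab), nrow = length(ukey),
             dimnames = list(NULL, colnames(tab)))
    })
  }
  list(haplotypes = uh, multiplicity = mult, tallies = tallies)
}

hamming_matrix <- function(x, y = x) {
  nx <- nrow(x); ny <- nrow(y)
  D <- matrix(0L, nx, ny)
  for (j in seq_len(ncol(x))) {
    D <- D + outer(x[, j], y[, j], `!=`)
  }
  D
}

# minimax (bottleneck) path distances via Floyd-Warshall on max-composition
minimax_distances <- function(D) {
  M <- D
  n <- nrow(D)
  for (k in seq_len(n)) {
    Mk <- pmax(matrix(M[, k], n, n), matrix(M[k, ], n, n, byrow = TRUE))
    M <- pmin(M, Mk)
  }
  M
}

# minimum-spanning-network edges under relaxation epsilon:
# edge (u,v) kept iff d(u,v) <= minimax(u,v) + epsilon
msn_edges <- function(D, epsilon = 0L) {
  n <- nrow(D)
  if (n < 2) return(data.frame(from = integer(0), to = integer(0),
                               weight = integer(0)))
  M <- minimax_distances(D)
  keep <- which(upper.tri(D) & D <= M + epsilon, arr.ind = TRUE)
  data.frame(from = keep[, 1], to = keep[, 2],
             weight = D[keep], stringsAsFactors = FALSE)
}

majority_median <- function(u, v, w) {
  m <- u
  agree_vw <- v == w
  m[agree_vw] <- v[agree_vw]   # any value held by >= 2 of the 3; ties keep u
  m
}

#' Median-joining haplotype network
#'
#' Bandelt-style construction: (1) the minimum spanning network over the
#' current node set, keeping all links within \code{epsilon} of the minimal
#' connection cost; (2) for every node triplet in which two nodes share a
#' linked common neighbour, the majority-consensus median (Steiner) vector is
#' added; (3) steps 1-2 iterate to a fixed point; (4) obsolete median vectors
#' (degree <= 2 and not on any shortest path between sampled nodes) are
#' removed. Ties are broken by lexicographic vector order so the result is
#' deterministic given the input.
#'
#' @param collapsed output of \code{collapse_haplotypes} (or a bare matrix of
#'   unique haplotypes).
#' @param epsilon integer >= 0 relaxation parameter (default 0, parsimonious).
#' @param max_rounds safety cap on median-addition rounds.
#' @return list of class \code{haplotype_network}: \code{haplotypes} (node
#'   matrix, sampled nodes first), \code{multiplicity}, \code{inferred}
#'   (logical), \code{edges} (from, to, weight), \code{epsilon},
#'   \code{tallies}.
#' @export
median_joining <- function(collapsed, epsilon = 0L, max_rounds = 25L) {
  if (is.matrix(collapsed))
    collapsed <- collapse_haplotypes(collapsed)
  nodes <- collapsed$haplotypes
  n_sampled <- nrow(nodes)
  if (n_sampled < 1) stop("need at least one haplotype")
  mult <- collapsed$multiplicity
  inferred <- rep(FALSE, n_sampled)
  for (round in seq_len(max_rounds)) {
    D <- hamming_matrix(nodes)
    ed <- msn_edges(D, epsilon)
    if (nrow(ed) == 0) break
    adj <- vector("list", nrow(nodes))
    for (e in seq_len(nrow(ed))) {
      adj[[ed$from[e]]] <- c(adj[[ed$from[e]]], ed$to[e])
      adj[[ed$to[e]]] <- c(adj[[ed$to[e]]], ed$from[e])
    }
    new_medians <- list()
    for (u in seq_along(adj)) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      cmb <- combn(sort(nb), 2)
      for (c0 in seq_len(ncol(cmb))) {
        v <- cmb[1, c0]; w <- cmb[2, c0]
        m <- majority_median(nodes[u, ], nodes[v, ], nodes[w, ])
        new_medians[[length(new_medians) + 1L]] <- m
      }
    }
    if (length(new_medians) == 0) break
    cand <- unique(do.call(rbind, new_medians))
    key_nodes <- apply(nodes, 1, paste, collapse = ",")
    key_cand <- apply(cand, 1, paste, collapse = ",")
    fresh <- !(key_cand %in% key_nodes)
    if (!any(fresh)) break
    cand <- cand[fresh, , drop = FALSE]
    cand <- cand[order(apply(cand, 1, paste, collapse = ",")), , drop = FALSE]
    nodes <- rbind(nodes, cand)
    mult <- c(mult, rep(0L, nrow(cand)))
    inferred <- c(inferred, rep(TRUE, nrow(cand)))
  }
  # cleanup: drop obsolete medians, then rebuild the network
  repeat {
    D <- hamming_matrix(nodes)
    ed <- msn_edges(D, epsilon)
    if (nrow(nodes) == 1 || !any(inferred)) break
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$from, to = ed$to, weight = ed$weight),
      directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(nodes))))
    deg <- igraph::degree(g)
    sp <- igraph::distances(g, weights = igraph::E(g)$weight)
    sampled <- which(!inferred)
    on_path <- rep(FALSE, nrow(nodes))
    for (m in which(inferred)) {
      hit <- FALSE
      for (s in sampled) {
        if (hit) break
        for (t in sampled) {
          if (s < t && isTRUE(all.equal(sp[s, m] + sp[m, t], sp[s, t]))) {
            hit <- TRUE
            break
          }
        }
      }
      on_path[m] <- hit
    }
    drop <- which(inferred & deg <= 2 & !on_path)
    if (length(drop) == 0) break
    nodes <- nodes[-drop, , drop = FALSE]
    mult <- mult[-drop]
    inferred <- inferred[-drop]
  }
  D <- hamming_matrix(nodes)
  ed <- msn_edges(D, epsilon)
  structure(list(haplotypes = nodes, multiplicity = mult, inferred = inferred,
                 edges = ed, epsilon = as.integer(epsilon),
                 tallies = collapsed$tallies),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("haplotype_network: %d sampled + %d median nodes, %d edges (epsilon = %d)\n",
              sum(!x$inferred), sum(x$inferred), nrow(x$edges), x$epsilon))
  invisible(x)
}

#' Total edge weight of a spanning connection within the network
#'
#' Minimum spanning tree weight over the network's nodes using its edge set;
#' used to compare network cost against Steiner-optimal constructions.
#'
#' @param network a \code{haplotype_network}.
#' @return numeric total weight.
#' @export
network_spanning_cost <- function(network) {
  if (nrow(network$haplotypes) < 2) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = network$edges$from, to = network$edges$to,
               weight = network$edges$weight),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(network$haplotypes))))
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  sum(igraph::E(mst)$weight)
}

DOT_PALETTE <- c("#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd",
                 "#8c564b", "#e377c2", "#7f7f7f", "#bcbd22", "#17becf")

#' Render a haplotype network as DOT text
#'
#' One DOT node per network node with size proportional to the square root of
#' its multiplicity; median (inferred) nodes are rendered as small grey points;
#' one DOT edge per network edge labelled with its weight. Output is sorted
#' and stable for diffing.
#'
#' @param network a \code{haplotype_network}.
#' @param color_by optional annotation key (a name in the network's tallies);
#'   sampled nodes are filled with the colour of their majority category.
#' @return character scalar of DOT source.
#' @export
network_to_dot <- function(network, color_by = NULL) {
  nn <- nrow(network$haplotypes)
  fill <- rep("#cccccc", nn)
  if (!is.null(color_by)) {
    if (is.null(network$tallies) || !color_by %in% names(network$tallies))
      stop(sprintf("unknown annotation key '%s'", color_by))
    tal <- network$tallies[[color_by]]
    cats <- colnames(tal)
    pal <- rep(DOT_PALETTE, length.out = length(cats))
    maj <- apply(tal, 1, which.max)
    fill[!network$inferred] <- pal[maj]
  }
  node_lines <- vapply(seq_len(nn), function(i) {
    if (network$inferred[i]) {
      sprintf("  n%d [shape=point, width=0.08, color=\"#666666\", style=filled, inferred=true];", i)
    } else {
      w <- 0.3 + 0.15 * sqrt(network$multiplicity[i])
      sprintf("  n%d [shape=circle, width=%.3f, label=\"%d\", style=filled, fillcolor=\"%s\"];",
              i, w, network$multiplicity[i], fill[i])
    }
  }, character(1))
  ed <- network$edges
  if (nrow(ed)) {
    o <- order(ed$from, ed$to)
    ed <- ed[o, , drop = FALSE]
  }
  edge_lines <- if (nrow(ed) == 0) character(0) else
    sprintf("  n%d -- n%d [label=\"%d\", weight=%d];",
            ed$from, ed$to, ed$weight, ed$weight)
  paste(c("graph haplotype_network {", "  layout=neato;",
          node_lines, edge_lines, "}"), collapse = "\n")
}
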