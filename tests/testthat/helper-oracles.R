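# Test helpers: tiny graph fixtures, exhaustive enumeration of small
# connected graphs, and an exact bond-percolation oracle for the one-shot
# SIR model (its final informed set is the seed's percolation cluster).

# path graph on n nodes (1-2-3-...-n)
path_graph <- function(n) igraph::make_ring(n, circular = FALSE)

# star with `leaves` leaves; vertex 1 is the hub
star_graph <- function(leaves)
  igraph::make_star(leaves + 1, mode = "undirected", center = 1)

# attach a group attribute by index sets
with_groups <- function(g, minority_idx) {
  grp <- rep("majority", igraph::vcount(g))
  grp[minority_idx] <- "minority"
  igraph::V(g)$group <- grp
  g
}

# all connected labeled graphs on n nodes as edge matrices, deduplicated up
# to isomorphism via igraph canonical permutation
connected_graphs_upto_iso <- function(n) {
  pairs <- t(utils::combn(n, 2))
  ne <- nrow(pairs)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (mask in seq_len(2^ne) - 1L) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(ne) - 1L)) != 0L)
    if (length(sel) < n - 1) next                       # cannot be connected
    g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    if (!igraph::is_connected(g)) next
    cp <- igraph::canonical_permutation(g)$labeling
    cg <- igraph::permute(g, cp)
    el <- igraph::as_edgelist(cg)
    key <- paste(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
                       sep = "-")[order(pmin(el[, 1], el[, 2]),
                                        pmax(el[, 1], el[, 2]))],
                 collapse = ";")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1]] <- igraph::as_edgelist(g)
  }
  out
}

# Exact law of the seed's informed count under one-shot SIR with
# transmission probability lambda, by subset recursion over percolation
# clusters: P(cluster = S) = g(S) * (1-lambda)^{edges(S, V\S)} where g(S) is
# the probability that the open subgraph restricted to S connects all of S
# to the seed. Returns P(informed count = k), k = 1..n.
percolation_count_pmf <- function(edges, n, seed, lambda) {
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2)
  subsets <- 0:(2^n - 1)
  sbit <- bitwShiftL(1L, seed - 1L)
  # edge count between S and complement, and inside S, per subset
  e_inside <- integer(2^n)
  e_boundary_to <- function(S, A) {   # edges between A and S\A (within S)
    cnt <- 0L
    for (e in seq_len(nrow(edges))) {
      a <- bitwShiftL(1L, edges[e, 1] - 1L)
      b <- bitwShiftL(1L, edges[e, 2] - 1L)
      inA <- c(bitwAnd(A, a) != 0, bitwAnd(A, b) != 0)
      inS <- c(bitwAnd(S, a) != 0, bitwAnd(S, b) != 0)
      if (all(inS) && xor(inA[1], inA[2])) cnt <- cnt + 1L
    }
    cnt
  }
  gprob <- numeric(2^n)   # g(S): indexed by subset mask + 1
  masks <- subsets[bitwAnd(subsets, sbit) != 0L]
  masks <- masks[order(vapply(masks, function(m)
    sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L), numeric(1)))]
  popcount <- function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0L)
  for (S in masks) {
    if (popcount(S) == 1L) {
      gprob[S + 1] <- 1
      next
    }
    tot <- 0
    # proper sub-subsets of S containing the seed
    sub <- S
    repeat {
      sub <- bitwAnd(sub - 1L, S)
      if (bitwAnd(sub, sbit) != 0L && sub != S)
        tot <- tot + gprob[sub + 1] *
          (1 - lambda)^e_boundary_to(S, sub)
      if (sub == 0L) break
    }
    gprob[S + 1] <- 1 - tot
  }
  pmf <- numeric(n)
  full <- 2^n - 1L
  for (S in masks) {
    k <- popcount(S)
    # boundary edges between S and the rest of the whole graph
    bnd <- 0L
    for (e in seq_len(nrow(edges))) {
      a <- bitwShiftL(1L, edges[e, 1] - 1L)
      b <- bitwShiftL(1L, edges[e, 2] - 1L)
      if (xor(bitwAnd(S, a) != 0, bitwAnd(S, b) != 0)) bnd <- bnd + 1L
    }
    pmf[k] <- pmf[k] + gprob[S + 1] * (1 - lambda)^bnd
  }
  pmf
}
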