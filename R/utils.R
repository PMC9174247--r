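# internal helpers shared across modules

GROUPS <- c("minority", "majority")

# normalize user-supplied group labels ("m"/"M" are case-sensitive shorthands)
match_group <- function(x, several.ok = FALSE) {
  if (is.null(x)) stop("group label must not be NULL", call. = FALSE)
  map1 <- function(g) {
    if (is.na(g)) stop("group label must not be NA", call. = FALSE)
    if (g %in% c("m", "min", "minority")) return("minority")
    if (g %in% c("M", "maj", "majority")) return("majority")
    stop(sprintf("unknown group label '%s' (use 'minority'/'m' or 'majority'/'M')", g),
         call. = FALSE)
  }
  out <- vapply(as.character(x), map1, character(1), USE.NAMES = FALSE)
  if (!several.ok && length(out) != 1L)
    stop("expected a single group label", call. = FALSE)
  out
}

# group code used by the C++ core: minority = 1, majority = 0
group_code <- function(g) ifelse(match_group(g, several.ok = TRUE) == "minority", 1L, 0L)

# evaluate `code` under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

# vertex groups of an igraph, defaulting to all-majority when unlabelled
vertex_groups <- function(graph) {
  if ("group" %in% igraph::vertex_attr_names(graph)) {
    match_group(igraph::V(graph)$group, several.ok = TRUE)
  } else {
    rep("majority", igraph::vcount(graph))
  }
}

# compressed adjacency + 0/1 group codes for the C++ core
graph_csr <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  csr <- cpp_build_csr(n, el - 1L)
  grp <- ifelse(vertex_groups(graph) == "minority", 1L, 0L)
  list(ptr = csr$ptr, adj = csr$adj, groups = grp, n = n)
}

# resolve a vertex given by index or name to a 1-based index
resolve_vertex <- function(graph, v) {
  n <- igraph::vcount(graph)
  if (is.character(v)) {
    nm <- igraph::V(graph)$name
    idx <- match(v, nm)
    if (is.na(idx)) stop(sprintf("unknown node '%s'", v), call. = FALSE)
    return(idx)
  }
  v <- as.integer(v)
  if (length(v) != 1L || is.na(v) || v < 1L || v > n)
    stop(sprintf("seed node out of range (network has %d nodes)", n), call. = FALSE)
  v
}
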