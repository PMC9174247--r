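#' Draw binary group labels
#'
#' Assigns each of \code{n} nodes to the minority group independently with
#' probability \code{minority_fraction}, otherwise to the majority. One
#' uniform draw is consumed per label.
#'
#' @param n number of labels to draw.
#' @param minority_fraction probability of the minority group, in (0, 1).
#'   Values of 0.5 or above are accepted with a warning (the "minority" is
#'   then not the smaller group in expectation); values outside (0, 1) are
#'   rejected, except the degenerate boundaries which require
#'   \code{allow_degenerate = TRUE}.
#' @param allow_degenerate accept \code{minority_fraction} of exactly 0 or 1.
#' @return character vector of \code{"minority"} / \code{"majority"} labels.
#' @examples
#' table(assign_groups(1000, 0.2))
#' @export
assign_groups <- function(n, minority_fraction, allow_degenerate = FALSE) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  f <- minority_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f))
    stop("'minority_fraction' must be a single number", call. = FALSE)
  lo <- if (allow_degenerate) 0 else .Machine$double.xmin
  if (f < 0 || f > 1 || (!allow_degenerate && (f <= 0 || f >= 1)))
    stop("'minority_fraction' must lie strictly inside (0, 1)", call. = FALSE)
  if (f >= 0.5 && f < 1)
    warning("minority_fraction >= 0.5: the 'minority' group is not the smaller one")
  ifelse(stats::runif(n) < f, "minority", "majority")
}

#' Preferential-attachment weights under homophily
#'
#' Computes the attachment kernel for a new node of group
#' \code{entrant_group}: an existing node \code{j} of degree \code{k_j}
#' receives weight \code{h * k_j} if it shares the entrant's group and
#' \code{(1 - h) * k_j} otherwise. Weights are returned both raw and
#' normalized to a probability distribution.
#'
#' @param graph an igraph with a \code{group} vertex attribute.
#' @param entrant_group group of the arriving node (\code{"minority"} or
#'   \code{"majority"}, shorthands \code{"m"}/\code{"M"}).
#' @param homophily homophily parameter \code{h} in [0, 1]; \code{h = 0.5} is
#'   group-blind preferential attachment, \code{h = 1} never attaches across
#'   groups.
#' @return list with \code{weights} (normalized, named by vertex),
#'   \code{raw}, \code{degrees}, and a logical \code{degenerate} flag set when
#'   every weight is zero (then \code{weights} is all \code{NA}).
#' @examples
#' g <- bah_network(20, homophily = 0.7, seed = 1)
#' w <- attachment_weights(g, "minority", 0.7)
#' sum(w$weights)
#' @export
attachment_weights <- function(graph, entrant_group, homophily) {
  h <- check_probability(homophily, "homophily")
  eg <- match_group(entrant_group)
  grp <- vertex_groups(graph)
  k <- igraph::degree(graph)
  raw <- ifelse(grp == eg, h, 1 - h) * k
  nm <- if (!is.null(igraph::V(graph)$name)) igraph::V(graph)$name else
    as.character(seq_along(raw))
  names(raw) <- nm
  tot <- sum(raw)
  degenerate <- tot <= 0
  weights <- if (degenerate) raw * NA_real_ else raw / tot
  list(weights = weights, raw = raw, degrees = stats::setNames(k, nm),
       degenerate = degenerate)
}

#' Generate a homophilic scale-free network
#'
#' Grows a Barabasi--Albert-type network with a binary group attribute.
#' Each arriving node draws its group (minority with probability
#' \code{minority_fraction}) and attaches to \code{m_links} distinct existing
#' nodes sampled proportionally to degree times a homophily factor:
#' \code{h} for same-group candidates, \code{1 - h} across groups. With
#' \code{h > 0.5} the network is homophilic, with \code{h < 0.5} heterophilic,
#' and \code{h = 0.5} recovers group-blind preferential attachment.
#'
#' The growth starts from a two-node seed, one node per group (node 1
#' minority, node 2 majority). With \code{seed_mode = "bridged"} the seed pair
#' is joined by an edge, which guarantees every arrival has a same-group
#' candidate of positive degree and keeps the graph connected for
#' \code{m_links = 1} (exactly \code{n_nodes - 1} edges). With
#' \code{seed_mode = "isolated"} the pair is unlinked and, for
#' \code{m_links = 1}, the graph always has exactly two components —
#' the faithful fragmentation limit for \code{h = 1} studies. If every kernel
#' weight is zero (possible only with the isolated seed), attachment falls
#' back to a uniform pick among candidates whose group coefficient is
#' positive, and a warning reports how often this happened.
#'
#' @param n_nodes number of nodes (at least 3).
#' @param m_links edges added per arriving node (default 1, giving a tree
#'   under the bridged seed).
#' @param minority_fraction probability that an arrival is a minority node;
#'   see \code{\link{assign_groups}}.
#' @param homophily homophily parameter \code{h} in [0, 1].
#' @param seed_mode \code{"bridged"} (default) or \code{"isolated"}.
#' @param seed optional integer; when given, the generator runs under
#'   \code{set.seed(seed)} and restores the caller's RNG stream afterwards.
#' @return an undirected igraph whose vertices carry a \code{group} attribute
#'   (\code{"minority"}/\code{"majority"}); generator parameters are stored as
#'   graph attributes. Vertex ids follow arrival order.
#' @examples
#' g <- bah_network(70, minority_fraction = 0.2, homophily = 0.8, seed = 42)
#' igraph::ecount(g)           # 69: a tree
#' table(igraph::V(g)$group)
#' @export
bah_network <- function(n_nodes, m_links = 1, minority_fraction = 0.2,
                        homophily = 0.5,
                        seed_mode = c("bridged", "isolated"), seed = NULL) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 3,
            is.numeric(m_links), length(m_links) == 1L, m_links >= 1)
  h <- check_probability(homophily, "homophily")
  f <- minority_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f >= 1)
    stop("'minority_fraction' must lie strictly inside (0, 1)", call. = FALSE)
  if (f >= 0.5)
    warning("minority_fraction >= 0.5: the 'minority' group is not the smaller one")
  seed_mode <- match.arg(seed_mode)

  res <- with_seed(seed,
    cpp_generate_bah(as.integer(n_nodes), as.integer(m_links), f, h,
                     seed_mode == "bridged"))
  if (res$fallback > 0)
    warning(sprintf(
      "degenerate attachment weights: fell back to uniform choice %d time(s)",
      res$fallback))

  g <- igraph::make_empty_graph(n = as.integer(n_nodes), directed = FALSE)
  g <- igraph::add_edges(g, t(res$edges + 1L))
  igraph::V(g)$group <- ifelse(res$groups == 1L, "minority", "majority")
  g <- igraph::set_graph_attr(g, "model", "BAh")
  g <- igraph::set_graph_attr(g, "homophily", h)
  g <- igraph::set_graph_attr(g, "minority_fraction", f)
  g <- igraph::set_graph_attr(g, "m_links", as.integer(m_links))
  g <- igraph::set_graph_attr(g, "seed_mode", seed_mode)
  g
}

#' Per-group degree and mixing summary
#'
#' Exact node, edge, and degree statistics by group: group sizes, within- and
#' between-group edge counts, mean and maximum degree per group, and the group
#' of the global hub (the maximum-degree node; ties broken by smallest id).
#'
#' @param graph an igraph with a \code{group} vertex attribute.
#' @return list with a per-group data frame \code{groups}, the
#'   \code{between_edges} count, \code{total_edges}, \code{hub_group} and
#'   \code{hub_degree}, and \code{cross_fraction} (share of between-group
#'   edges).
#' @examples
#' g <- bah_network(200, homophily = 0.2, seed = 1)
#' group_degree_summary(g)$hub_group   # heterophilic hubs are minority nodes
#' @export
group_degree_summary <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("network is empty", call. = FALSE)
  grp <- vertex_groups(graph)
  k <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  g1 <- grp[el[, 1]]
  g2 <- grp[el[, 2]]
  within <- vapply(GROUPS, function(g) sum(g1 == g & g2 == g), numeric(1))
  between <- sum(g1 != g2)
  hub <- which.max(k)
  per_group <- data.frame(
    group = GROUPS,
    n_nodes = vapply(GROUPS, function(g) sum(grp == g), numeric(1)),
    within_edges = within,
    mean_degree = vapply(GROUPS, function(g)
      if (any(grp == g)) mean(k[grp == g]) else NA_real_, numeric(1)),
    max_degree = vapply(GROUPS, function(g)
      if (any(grp == g)) max(k[grp == g]) else NA_real_, numeric(1)),
    row.names = NULL)
  total <- nrow(el)
  list(groups = per_group, between_edges = between, total_edges = total,
       hub_group = grp[hub], hub_degree = unname(k[hub]),
       cross_fraction = if (total > 0) between / total else NA_real_)
}
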