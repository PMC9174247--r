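# Empirical attributed networks: reading, largest component, and a
# simulation-matching estimator of the homophily parameter.

#' Read an attributed network from edge-list and attribute files
#'
#' The edge file holds two whitespace- or tab-separated columns of node ids;
#' the attribute file holds node id and group label. Lines starting with
#' \code{#} are comments. The graph is made undirected and simple: reciprocal
#' and duplicate edges are collapsed and self-loops dropped (with a message).
#' Exactly two group values must remain after mapping; the one named by
#' \code{minority_label} (default: the less frequent one) becomes
#' \code{"minority"}.
#'
#' @param edge_file path to the edge list.
#' @param attribute_file path to the node-attribute table.
#' @param minority_label group value in the attribute file to treat as the
#'   minority.
#' @param directed_input ignored for the topology (links are always collapsed
#'   to undirected), kept to document intent.
#' @return an undirected simple igraph; vertex names hold the original ids,
#'   \code{group} holds \code{"minority"}/\code{"majority"}, and
#'   \code{raw_group} the original labels.
#' @examples
#' ef <- tempfile(); af <- tempfile()
#' writeLines(c("a b", "b c", "a b"), ef)
#' writeLines(c("a x", "b y", "c y"), af)
#' g <- read_attributed_network(ef, af, minority_label = "x")
#' igraph::ecount(g)   # duplicate collapsed: 2
#' @export
read_attributed_network <- function(edge_file, attribute_file,
                                    minority_label = NULL,
                                    directed_input = FALSE) {
  edges <- utils::read.table(edge_file, header = FALSE, comment.char = "#",
                             colClasses = "character",
                             col.names = c("from", "to"))
  attrs <- utils::read.table(attribute_file, header = FALSE,
                             comment.char = "#", colClasses = "character",
                             col.names = c("id", "group"))
  if (anyDuplicated(attrs$id))
    stop("duplicate node ids in attribute file", call. = FALSE)

  missing <- setdiff(unique(c(edges$from, edges$to)), attrs$id)
  if (length(missing))
    stop(sprintf("edge endpoints without attribute row: %s%s",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10)
                   sprintf(" (and %d more)", length(missing) - 10) else ""),
         call. = FALSE)

  values <- sort(unique(attrs$group))
  if (length(values) != 2)
    stop(sprintf("expected exactly 2 group values, found %d (%s)",
                 length(values),
                 paste(utils::head(values, 5), collapse = ", ")),
         call. = FALSE)
  if (is.null(minority_label)) {
    tab <- table(attrs$group)
    minority_label <- names(tab)[which.min(tab)]
  }
  if (!minority_label %in% values)
    stop(sprintf("minority_label '%s' not among group values (%s)",
                 minority_label, paste(values, collapse = ", ")),
         call. = FALSE)

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = attrs["id"])
  loops <- sum(igraph::which_loop(g))
  before <- igraph::ecount(g)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  dup <- before - loops - igraph::ecount(g)
  if (loops > 0) message(sprintf("dropped %d self-loop(s)", loops))
  if (dup > 0)
    message(sprintf("collapsed %d duplicate/reciprocal edge(s)", dup))

  raw <- attrs$group[match(igraph::V(g)$name, attrs$id)]
  igraph::V(g)$raw_group <- raw
  igraph::V(g)$group <- ifelse(raw == minority_label, "minority", "majority")
  g
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component. Ties in size are
#' broken by the component containing the smallest vertex index (a message
#' reports the tie).
#'
#' @param graph an igraph.
#' @return the induced subgraph (identity for a connected graph).
#' @examples
#' g <- igraph::make_graph(~ a-b, b-c, d-e)
#' igraph::vcount(largest_component(g))   # 3
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("network is empty", call. = FALSE)
  comp <- igraph::components(graph)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1) {
    first_vertex <- vapply(big, function(b)
      min(which(comp$membership == b)), numeric(1))
    big <- big[which.min(first_vertex)]
    message(sprintf(
      "component size tie: keeping the component containing vertex %d",
      min(which(comp$membership == big))))
  }
  igraph::induced_subgraph(graph, which(comp$membership == big))
}

#' Estimate the homophily parameter by simulation matching
#'
#' Estimates the homophily \code{h} of an attributed network by matching its
#' cross-group edge fraction against ensembles of generated networks with the
#' same size and minority fraction: a bisection over \code{h} solves
#' \code{E[cross-fraction of BAh(N, m = 1, f_a, h)] = observed cross-fraction}
#' (the expected cross-fraction is monotone decreasing in \code{h}).
#' The raw mixing statistics are returned alongside so users can substitute a
#' different estimator.
#'
#' @param graph an igraph with a \code{group} vertex attribute and both
#'   groups present.
#' @param n_matching_reps generated networks per bisection evaluation.
#' @param n_iter bisection iterations.
#' @param seed optional integer RNG seed.
#' @return object of class \code{homophily_fit}: \code{h_hat}, an
#'   \code{uncertainty} (Monte-Carlo SE propagated through the local slope),
#'   the observed \code{cross_fraction} and \code{minority_fraction}, and the
#'   matching settings.
#' @examples
#' g <- bah_network(300, homophily = 0.8, seed = 1)
#' fit <- estimate_homophily(g, n_matching_reps = 20, seed = 2)
#' fit$h_hat
#' @export
estimate_homophily <- function(graph, n_matching_reps = 50, n_iter = 12,
                               seed = NULL) {
  grp <- vertex_groups(graph)
  if (length(unique(grp)) < 2)
    stop("homophily estimation needs both groups present", call. = FALSE)
  if (igraph::ecount(graph) == 0)
    stop("homophily estimation needs at least one edge", call. = FALSE)
  n <- igraph::vcount(graph)
  fa <- mean(grp == "minority")
  obs <- group_degree_summary(graph)$cross_fraction

  mean_cross <- function(h, reps = n_matching_reps)
    mean(cpp_cross_fractions(n, 1L, fa, h, TRUE, as.integer(reps)))

  fit <- function() {
    lo <- 0; hi <- 1
    for (i in seq_len(n_iter)) {
      mid <- (lo + hi) / 2
      if (mean_cross(mid) > obs) lo <- mid else hi <- mid
    }
    h_hat <- (lo + hi) / 2
    # uncertainty: MC standard error of the matched cross-fraction divided by
    # the local slope of the response curve
    dh <- 0.05
    xs <- cpp_cross_fractions(n, 1L, fa, h_hat, TRUE,
                              as.integer(n_matching_reps))
    slope <- (mean_cross(min(1, h_hat + dh)) -
              mean_cross(max(0, h_hat - dh))) /
             (min(1, h_hat + dh) - max(0, h_hat - dh))
    se <- stats::sd(xs) / sqrt(length(xs))
    unc <- if (abs(slope) > 0) abs(se / slope) else NA_real_
    list(h_hat = h_hat, uncertainty = unc)
  }
  est <- with_seed(seed, fit())

  structure(list(h_hat = est$h_hat, uncertainty = est$uncertainty,
                 cross_fraction = obs, minority_fraction = fa,
                 n_nodes = n, n_matching_reps = as.integer(n_matching_reps),
                 n_iter = as.integer(n_iter)),
            class = "homophily_fit")
}

#' @export
print.homophily_fit <- function(x, ...) {
  cat(sprintf("Homophily estimate (simulation matching on cross-group edge fraction)\n"))
  cat(sprintf("  h_hat = %.3f +/- %.3f\n", x$h_hat, x$uncertainty))
  cat(sprintf("  observed cross-fraction = %.4f, minority fraction = %.4f, N = %d\n",
              x$cross_fraction, x$minority_fraction, x$n_nodes))
  invisible(x)
}
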