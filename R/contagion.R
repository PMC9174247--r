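# Contagion models. All three run from a single informed seed to the
# absorbing state; "informed" in all reported counts means informed OR
# recovered (recovered nodes know the information but no longer spread it).

cascade_result <- function(graph, states, steps, model, seed_node,
                           mechanism = NULL, infectivity = NA_real_,
                           threshold = NA_real_) {
  grp <- vertex_groups(graph)
  lv <- c("susceptible", "informed", "recovered")
  st <- factor(lv[states + 1L], levels = lv)
  knowing <- st != "susceptible"
  group_size <- vapply(GROUPS, function(g) sum(grp == g), numeric(1))
  informed <- vapply(GROUPS, function(g) sum(knowing & grp == g), numeric(1))
  res <- list(
    model = model,
    final_states = st,
    informed_count_per_group = informed,
    group_size = group_size,
    final_density = sum(informed) / length(st),
    final_density_per_group = ifelse(group_size > 0,
                                     informed / group_size, NA_real_),
    steps = steps,
    seed_node = seed_node,
    seed_group = grp[seed_node],
    mechanism = mechanism,
    infectivity = infectivity,
    threshold = threshold)
  class(res) <- "cascade"
  res
}

#' @export
print.cascade <- function(x, ...) {
  cat(sprintf("%s contagion cascade (seed node %d, %s group)\n",
              sub("^(.)", "\\U\\1", x$model, perl = TRUE),
              x$seed_node, x$seed_group))
  if (!is.na(x$infectivity))
    cat(sprintf("  infectivity lambda = %g\n", x$infectivity))
  if (!is.na(x$threshold))
    cat(sprintf("  threshold T = %g\n", x$threshold))
  cat(sprintf("  final density rho_f = %.4f  (minority %.4f, majority %.4f)\n",
              x$final_density, x$final_density_per_group["minority"],
              x$final_density_per_group["majority"]))
  cat(sprintf("  informed-or-recovered: %d of %d nodes; %d steps\n",
              sum(x$informed_count_per_group), length(x$final_states),
              x$steps))
  invisible(x)
}

run_cascade <- function(graph, seed_node, model, infectivity, threshold,
                        simple_group, seed) {
  v <- resolve_vertex(graph, seed_node)
  net <- graph_csr(graph)
  mcode <- match(model, c("simple", "complex", "hybrid")) - 1L
  sg <- if (is.null(simple_group)) -1L else group_code(simple_group)
  out <- with_seed(seed,
    cpp_cascade(net$ptr, net$adj, net$groups, v - 1L, mcode,
                infectivity, threshold, sg))
  mech <- NULL
  if (model == "hybrid") {
    sgrp <- if (is.null(simple_group)) vertex_groups(graph)[v]
            else match_group(simple_group)
    mech <- ifelse(vertex_groups(graph) == sgrp, "simple", "complex")
  }
  cascade_result(graph, out$states, out$steps, model, v, mech,
                 infectivity = if (model == "simple") infectivity else
                   if (model == "hybrid") 1 else NA_real_,
                 threshold = if (model != "simple") threshold else NA_real_)
}

#' Run Simple Contagion (one-shot SIR)
#'
#' The seed starts informed. Informed nodes are processed in FIFO order;
#' each attempts every currently susceptible neighbor exactly once (in
#' randomized order), succeeding independently with probability
#' \code{infectivity}, and then recovers. Each link carries at most one
#' meaningful attempt, so the final informed-or-recovered set is the seed's
#' cluster under bond percolation with occupation probability
#' \code{infectivity}.
#'
#' @param graph an igraph (a \code{group} vertex attribute is used for the
#'   per-group densities; unlabelled graphs count as all-majority).
#' @param seed_node seed vertex (index or name).
#' @param infectivity transmission probability \code{lambda} in [0, 1].
#' @param seed optional integer RNG seed (restored on exit).
#' @return a \code{cascade} object: final states, informed counts and
#'   densities per group, overall final density \code{rho_f}, and a step
#'   counter (processed informed nodes).
#' @examples
#' g <- bah_network(100, seed = 1)
#' run_simple(g, seed_node = 1, infectivity = 0.5, seed = 7)
#' @export
run_simple <- function(graph, seed_node, infectivity, seed = NULL) {
  lambda <- check_probability(infectivity, "infectivity")
  run_cascade(graph, seed_node, "simple", lambda, NA_real_, NULL, seed)
}

#' Run Complex Contagion (strict threshold dynamics)
#'
#' The seed starts informed. Susceptible nodes adopt when the fraction of
#' their neighbors that are informed or recovered strictly exceeds
#' \code{threshold}. Nodes are re-evaluated in randomized sweeps until a full
#' sweep changes nothing; because the strict-threshold update is monotone,
#' this absorbing state is unique and identical to the one reached by
#' selecting nodes uniformly at random forever.
#'
#' @inheritParams run_simple
#' @param threshold adoption threshold \code{T} in [0, 1]. \code{T = 0} gives
#'   a full cascade on a connected graph; \code{T >= 1} freezes everyone but
#'   the seed.
#' @return a \code{cascade} object; \code{steps} counts evaluation sweeps.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected", center = 1)
#' run_complex(g, seed_node = 2, threshold = 0.3)$final_density  # seed only
#' @export
run_complex <- function(graph, seed_node, threshold, seed = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("'threshold' must be a single nonnegative number", call. = FALSE)
  run_cascade(graph, seed_node, "complex", NA_real_, as.numeric(threshold),
              NULL, seed)
}

#' Run Hybrid Contagion
#'
#' Combines the two mechanisms by group: nodes in the seed's group follow
#' Simple Contagion with infectivity 1 (they adopt as soon as any neighbor is
#' informed, each link used at most once), while nodes of the other group
#' follow the strict threshold rule of Complex Contagion. Whenever any node
#' becomes informed the lambda-1 simple transmission is cascaded to
#' exhaustion, then complex nodes are re-evaluated in randomized sweeps until
#' a global absorbing state; the final set is invariant to the interleaving
#' order because the combined update is monotone.
#'
#' @inheritParams run_complex
#' @param simple_group override of the group that follows the simple
#'   mechanism (default: the seed's group, so the information's home group
#'   spreads it freely).
#' @return a \code{cascade} object whose \code{mechanism} field records which
#'   rule each node followed.
#' @examples
#' g <- bah_network(50, homophily = 0.7, seed = 3)
#' maj <- which(igraph::V(g)$group == "majority")[1]
#' run_hybrid(g, seed_node = maj, threshold = 0.2, seed = 9)
#' @export
run_hybrid <- function(graph, seed_node, threshold, simple_group = NULL,
                       seed = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("'threshold' must be a single nonnegative number", call. = FALSE)
  run_cascade(graph, seed_node, "hybrid", 1, as.numeric(threshold),
              simple_group, seed)
}

#' Check whether a state configuration is absorbing
#'
#' A configuration is absorbing when no susceptible node currently satisfies
#' its adoption condition and no simple-contagion attempt is pending (i.e. no
#' informed node still has a susceptible neighbor it could attempt).
#'
#' @param graph an igraph.
#' @param states factor or character vector over vertices with levels
#'   \code{susceptible}/\code{informed}/\code{recovered}.
#' @param model \code{"simple"}, \code{"complex"}, or \code{"hybrid"}.
#' @param threshold adoption threshold for the complex mechanism.
#' @param simple_group group following the simple mechanism under
#'   \code{"hybrid"} (required there).
#' @return \code{TRUE} iff no further adoption is possible.
#' @examples
#' g <- igraph::make_star(5, mode = "undirected", center = 1)
#' st <- c("susceptible", "informed", rep("susceptible", 3))
#' is_absorbing(g, st, "complex", threshold = 0.3)
#' @export
is_absorbing <- function(graph, states, model = c("simple", "complex", "hybrid"),
                         threshold = NULL, simple_group = NULL) {
  model <- match.arg(model)
  st <- as.character(states)
  n <- igraph::vcount(graph)
  stopifnot(length(st) == n)
  if (!all(st %in% c("susceptible", "informed", "recovered")))
    stop("states must be susceptible/informed/recovered", call. = FALSE)
  adj <- igraph::as_adj_list(graph)
  knowing <- st != "susceptible"
  frac_informed <- function(v) {
    nb <- as.integer(adj[[v]])
    if (!length(nb)) return(0)
    mean(knowing[nb])
  }
  pending_simple <- function(candidates) {
    any(vapply(candidates, function(v)
      st[v] == "informed" && any(st[as.integer(adj[[v]])] == "susceptible"),
      logical(1)))
  }
  can_adopt_complex <- function(candidates, T_) {
    any(vapply(candidates, function(v)
      st[v] == "susceptible" && frac_informed(v) > T_, logical(1)))
  }
  if (model == "simple") return(!pending_simple(seq_len(n)))
  if (model == "complex") {
    if (is.null(threshold)) stop("'threshold' required for complex model")
    return(!can_adopt_complex(seq_len(n), threshold))
  }
  if (is.null(simple_group) || is.null(threshold))
    stop("'simple_group' and 'threshold' required for hybrid model")
  grp <- vertex_groups(graph)
  sg <- match_group(simple_group)
  simple_nodes <- which(grp == sg)
  complex_nodes <- which(grp != sg)
  # pending simple attempt: any knowing node adjacent to a susceptible simple
  # node (lambda = 1 means such an attempt would succeed)
  pending <- any(vapply(which(st == "susceptible" & grp == sg), function(v)
    any(knowing[as.integer(adj[[v]])]), logical(1)))
  !pending && !can_adopt_complex(complex_nodes, threshold)
}

#' Replicate cascades on a fixed network
#'
#' Runs \code{n_realizations} independent cascades on one network, redrawing
#' the seed (uniformly within \code{source_group}, or over all nodes) and the
#' dynamics randomness each time. This is the fixed-network Monte-Carlo mode
#' used for empirical graphs.
#'
#' @inheritParams run_simple
#' @param model \code{"simple"}, \code{"complex"}, or \code{"hybrid"}.
#' @param n_realizations number of runs.
#' @param infectivity \code{lambda} for the simple model.
#' @param threshold \code{T} for the complex/hybrid models.
#' @param source_group draw seeds from this group (default: any node).
#' @param seed_node fix the seed node instead of drawing it.
#' @return data frame with one row per run: seed node and group, overall and
#'   per-group final densities, and step count.
#' @examples
#' g <- bah_network(100, seed = 1)
#' r <- replicate_cascades(g, "simple", 50, infectivity = 0.5, seed = 2)
#' mean(r$rho_f)
#' @export
replicate_cascades <- function(graph, model = c("simple", "complex", "hybrid"),
                               n_realizations, infectivity = 1,
                               threshold = 0, source_group = NULL,
                               seed_node = NULL, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_realizations >= 1)
  net <- graph_csr(graph)
  mcode <- match(model, c("simple", "complex", "hybrid")) - 1L
  src <- if (is.null(source_group)) -1L else group_code(source_group)
  fixed <- if (is.null(seed_node)) -1L else resolve_vertex(graph, seed_node) - 1L
  out <- with_seed(seed,
    cpp_ensemble_fixed(net$ptr, net$adj, net$groups, mcode,
                       check_probability(infectivity, "infectivity"),
                       as.numeric(threshold), src, fixed,
                       as.integer(n_realizations), -1L))
  grp <- vertex_groups(graph)
  data.frame(rep = seq_len(n_realizations),
             seed_node = out$seed_node + 1L,
             seed_group = grp[out$seed_node + 1L],
             rho_f = out$rho_all,
             rho_minority = out$rho_minority,
             rho_majority = out$rho_majority,
             steps = out$steps)
}
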