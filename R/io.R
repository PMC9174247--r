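# Writers and readers for networks and result objects. Result files carry
# their type so that read_results() can reconstruct the object, and
# divergent critical thresholds are serialized as the explicit string
# "divergent", never as NaN.

#' Write a network as an edge-list TSV
#'
#' Two tab-separated columns of node ids (vertex names when present,
#' otherwise 1-based indices). Optional header lines are written as
#' \code{#} comments.
#'
#' @param graph an igraph.
#' @param path output file.
#' @param header optional character vector of comment lines.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(graph, path, header = NULL) {
  el <- igraph::as_edgelist(graph, names = !is.null(igraph::V(graph)$name))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(el, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write node group attributes as a TSV
#'
#' Two tab-separated columns: node id and group, encoded \code{m} for the
#' minority and \code{M} for the majority.
#'
#' @inheritParams write_edge_list
#' @return the path, invisibly.
#' @export
write_node_attributes <- function(graph, path, header = NULL) {
  ids <- if (!is.null(igraph::V(graph)$name)) igraph::V(graph)$name
         else seq_len(igraph::vcount(graph))
  grp <- ifelse(vertex_groups(graph) == "minority", "m", "M")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(data.frame(ids, grp), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML (with the group attribute)
#'
#' @inheritParams write_edge_list
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network
#'
#' @param path a GraphML file (typically written by
#'   \code{\link{write_network_graphml}}).
#' @return an igraph.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

results_payload <- function(x) {
  if (inherits(x, "it_matrix")) {
    cfg <- NULL
    if (inherits(x$generator, "bah_config")) cfg <- unclass(x$generator)
    dyn <- if (inherits(x$dynamics, "dynamics_config")) unclass(x$dynamics)
    list(type = "it_matrix", it = as.list(x$it), se = as.list(x$se),
         M = x$n_realizations, config = c(cfg, dyn))
  } else if (inherits(x, "bias_vector")) {
    list(type = "bias_vector", biases = unclass(x))
  } else if (inherits(x, "homophily_fit")) {
    c(list(type = "homophily_fit"), unclass(x))
  } else if (inherits(x, "homophily_sweep")) {
    df <- x$results
    df$t_c <- ifelse(df$divergent, "divergent", as.character(df$t_c))
    list(type = "homophily_sweep", model = x$model,
         n_realizations = x$n_realizations, results = df)
  } else if (inherits(x, "density_pdf")) {
    list(type = "density_pdf", breaks = x$breaks, counts = x$counts,
         density = x$density, M = x$n_realizations)
  } else if (is.data.frame(x)) {
    list(type = "data.frame", results = x)
  } else {
    stop("no serializer for objects of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

#' Write results to CSV or JSON
#'
#' Serializes the package's result objects (\code{it_matrix},
#' \code{bias_vector}, \code{homophily_fit}, \code{homophily_sweep},
#' \code{density_pdf}) and plain data frames. JSON files embed the object
#' type and round-trip through \code{\link{read_results}}; CSV is available
#' for tabular payloads, with divergent critical thresholds written as the
#' string \code{"divergent"}.
#'
#' @param x a result object or data frame.
#' @param path output file.
#' @param format \code{"json"} or \code{"csv"}.
#' @param header optional comment lines (CSV only).
#' @return the path, invisibly.
#' @examples
#' b <- bias_decompose(c(1, 0, 0, 1))
#' f <- tempfile(fileext = ".json")
#' write_results(b, f)
#' read_results(f)$echo_chamber
#' @export
write_results <- function(x, path, format = c("json", "csv"), header = NULL) {
  format <- match.arg(format)
  payload <- results_payload(x)
  if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null", na = "string")
  } else {
    df <- payload$results
    if (is.null(df))
      stop(sprintf("'%s' objects have no tabular form; use format = \"json\"",
                   payload$type), call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# type: %s", payload$type), con)
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read results written by \code{\link{write_results}}
#'
#' JSON payloads are reconstructed into their original classes where
#' possible; CSV payloads come back as data frames (a \code{t_c} column is
#' parsed with \code{"divergent"} mapped to \code{NA} plus a
#' \code{divergent} flag).
#'
#' @param path file written by \code{\link{write_results}}.
#' @return the reconstructed object.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(trimws(first), "#")) {            # CSV with type comment
    df <- utils::read.table(path, header = TRUE, sep = ",",
                            comment.char = "#", stringsAsFactors = FALSE)
    if ("t_c" %in% names(df)) {
      df$divergent <- df$t_c == "divergent"
      df$t_c <- suppressWarnings(as.numeric(ifelse(df$divergent, NA, df$t_c)))
    }
    return(df)
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    it_matrix = new_it_matrix(unlist(obj$it), se = unlist(obj$se),
                              n_realizations = obj$M),
    bias_vector = structure(as.list(obj$biases), class = "bias_vector"),
    homophily_fit = structure(obj[setdiff(names(obj), "type")],
                              class = "homophily_fit"),
    homophily_sweep = {
      df <- obj$results
      df$divergent <- df$t_c == "divergent"
      df$t_c <- suppressWarnings(as.numeric(ifelse(df$divergent, NA, df$t_c)))
      structure(list(results = df, model = obj$model,
                     n_realizations = obj$n_realizations),
                class = "homophily_sweep")
    },
    density_pdf = structure(list(breaks = obj$breaks,
                                 mids = obj$breaks[-1] - diff(obj$breaks) / 2,
                                 counts = obj$counts, density = obj$density,
                                 n_realizations = obj$M),
                            class = "density_pdf"),
    data.frame = obj$results,
    stop(sprintf("unknown results type '%s'", obj$type), call. = FALSE))
}
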