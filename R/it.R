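# Group-to-group information-transmission observables and their bias
# decomposition. IT_ab is the probability that information seeded in group a
# reaches a random node of group b; for a single run this equals the final
# informed density of group b, so the Monte-Carlo estimate is a mean of
# per-run group densities.

IT_NAMES <- c("mm", "mM", "Mm", "MM")

#' Final informed density of one group
#'
#' Returns \code{I_g / N_g}: the fraction of nodes of \code{group} that are
#' informed or recovered in the absorbing state of a cascade. For a single
#' run this is exactly the run's contribution to the transmission probability
#' into that group.
#'
#' @param result a \code{cascade} object.
#' @param group \code{"minority"} or \code{"majority"}.
#' @return a number in [0, 1].
#' @examples
#' g <- bah_network(100, seed = 1)
#' r <- run_simple(g, 1, infectivity = 1)
#' final_group_density(r, "minority")   # 1: full cascade on a connected tree
#' @export
final_group_density <- function(result, group) {
  stopifnot(inherits(result, "cascade"))
  g <- match_group(group)
  if (result$group_size[[g]] == 0L)
    stop(sprintf("group '%s' is empty: density undefined", g), call. = FALSE)
  unname(result$final_density_per_group[[g]])
}

dyn_to_codes <- function(dynamics) {
  model <- dynamics$model
  list(mcode = match(model, c("simple", "complex", "hybrid")) - 1L,
       lambda = if (is.null(dynamics$infectivity)) 1 else dynamics$infectivity,
       threshold = if (is.null(dynamics$threshold)) 0 else dynamics$threshold)
}

#' Dynamics configuration
#'
#' Bundles the contagion model and its parameters. The hybrid model fixes
#' the infectivity at 1 (its only control parameter is the threshold); a
#' different value is rejected.
#'
#' @param model \code{"simple"}, \code{"complex"}, or \code{"hybrid"}.
#' @param infectivity \code{lambda} in [0, 1] (simple model).
#' @param threshold \code{T} in [0, 1] (complex/hybrid models).
#' @return a list of class \code{dynamics_config}.
#' @examples
#' dynamics_config("hybrid", threshold = 0.3)
#' @export
dynamics_config <- function(model = c("simple", "complex", "hybrid"),
                            infectivity = 1, threshold = 0) {
  model <- match.arg(model)
  lambda <- check_probability(infectivity, "infectivity")
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("'threshold' must be a single nonnegative number", call. = FALSE)
  if (model == "hybrid" && lambda != 1)
    stop("hybrid contagion requires infectivity = 1", call. = FALSE)
  structure(list(model = model, infectivity = lambda,
                 threshold = as.numeric(threshold)),
            class = "dynamics_config")
}

#' Network generator configuration
#'
#' Parameter bundle for \code{\link{bah_network}}, used by the Monte-Carlo
#' estimators that regenerate a fresh network per realization.
#'
#' @inheritParams bah_network
#' @return a list of class \code{bah_config}.
#' @examples
#' bah_config(1000, homophily = 0.7)
#' @export
bah_config <- function(n_nodes, m_links = 1, minority_fraction = 0.2,
                       homophily = 0.5, seed_mode = c("bridged", "isolated")) {
  seed_mode <- match.arg(seed_mode)
  stopifnot(n_nodes >= 3, m_links >= 1)
  f <- minority_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f <= 0 || f >= 1)
    stop("'minority_fraction' must lie strictly inside (0, 1)", call. = FALSE)
  if (f >= 0.5)
    warning("minority_fraction >= 0.5: the 'minority' group is not the smaller one")
  structure(list(n_nodes = as.integer(n_nodes), m_links = as.integer(m_links),
                 minority_fraction = f,
                 homophily = check_probability(homophily, "homophily"),
                 seed_mode = seed_mode),
            class = "bah_config")
}

# run one source-group ensemble; returns per-run densities for both targets
source_ensemble <- function(generator, dynamics, source_group, n_realizations) {
  d <- dyn_to_codes(dynamics)
  src <- group_code(source_group)
  if (inherits(generator, "bah_config")) {
    cpp_ensemble_generated(generator$n_nodes, generator$m_links,
                           generator$minority_fraction, generator$homophily,
                           generator$seed_mode == "bridged",
                           d$mcode, d$lambda, d$threshold, src,
                           as.integer(n_realizations), -1L)
  } else if (igraph::is_igraph(generator)) {
    net <- graph_csr(generator)
    if (!any(net$groups == src))
      stop("source group empty in the fixed network", call. = FALSE)
    cpp_ensemble_fixed(net$ptr, net$adj, net$groups, d$mcode, d$lambda,
                       d$threshold, src, -1L, as.integer(n_realizations), -1L)
  } else {
    stop("'generator' must be a bah_config or an igraph", call. = FALSE)
  }
}

#' Estimate one group-to-group transmission probability
#'
#' Monte-Carlo estimate of \code{IT_ab}: per realization a network is drawn
#' (fresh from the generator, or the fixed network reused), a seed is drawn
#' uniformly from the source group, the dynamics run to absorption, and the
#' final informed density of the target group is recorded. The estimate is
#' the mean over realizations, with a standard error \code{sd/sqrt(M)}.
#'
#' @param generator a \code{\link{bah_config}} (fresh network per
#'   realization) or an igraph (fixed-network mode).
#' @param dynamics a \code{\link{dynamics_config}}.
#' @param source_group,target_group group labels (source = seed's group,
#'   target = group whose final density is measured).
#' @param n_realizations number of Monte-Carlo realizations \code{M}.
#' @param seed optional integer RNG seed.
#' @return list with \code{estimate}, \code{se}, \code{n_realizations}, and
#'   the per-run densities \code{values}.
#' @examples
#' it <- estimate_it(bah_config(200), dynamics_config("simple", 1),
#'                   "minority", "majority", n_realizations = 20, seed = 1)
#' it$estimate   # 1: lambda = 1 floods a connected tree
#' @export
estimate_it <- function(generator, dynamics, source_group, target_group,
                        n_realizations, seed = NULL) {
  stopifnot(inherits(dynamics, "dynamics_config"), n_realizations >= 1)
  tg <- match_group(target_group)
  out <- with_seed(seed,
    source_ensemble(generator, dynamics, source_group, n_realizations))
  vals <- if (tg == "minority") out$rho_minority else out$rho_majority
  list(estimate = mean(vals),
       se = stats::sd(vals) / sqrt(length(vals)),
       n_realizations = as.integer(n_realizations),
       values = vals)
}

#' Estimate the full information-transmission matrix
#'
#' Estimates the four observables \code{IT_mm, IT_mM, IT_Mm, IT_MM} (first
#' subscript = source group, second = target). With \code{share_runs = TRUE}
#' (default) each source-group realization records the final densities of
#' both target groups, so the four entries cost two ensembles of
#' \code{n_realizations} runs; with \code{FALSE} each pair gets its own
#' independent ensemble.
#'
#' @inheritParams estimate_it
#' @param share_runs reuse each run for both target groups of its source.
#' @return an object of class \code{it_matrix}: named entries \code{it}
#'   (order \code{mm, mM, Mm, MM}), standard errors \code{se},
#'   \code{n_realizations}, and the configurations used.
#' @examples
#' m <- estimate_it_matrix(bah_config(200), dynamics_config("simple", 1),
#'                         n_realizations = 20, seed = 1)
#' m$it
#' @export
estimate_it_matrix <- function(generator, dynamics, n_realizations,
                               share_runs = TRUE, seed = NULL) {
  stopifnot(inherits(dynamics, "dynamics_config"), n_realizations >= 1)
  it <- se <- stats::setNames(numeric(4), IT_NAMES)
  run <- function() {
    if (share_runs) {
      for (src in c("m", "M")) {
        out <- source_ensemble(generator, dynamics,
                               ifelse(src == "m", "minority", "majority"),
                               n_realizations)
        for (tgt in c("m", "M")) {
          key <- paste0(src, tgt)
          vals <- if (tgt == "m") out$rho_minority else out$rho_majority
          it[key] <<- mean(vals)
          se[key] <<- stats::sd(vals) / sqrt(length(vals))
        }
      }
    } else {
      for (key in IT_NAMES) {
        est <- estimate_it(generator, dynamics,
                           ifelse(substr(key, 1, 1) == "m", "minority", "majority"),
                           ifelse(substr(key, 2, 2) == "m", "minority", "majority"),
                           n_realizations)
        it[key] <<- est$estimate
        se[key] <<- est$se
      }
    }
  }
  with_seed(seed, run())
  new_it_matrix(it, se = se, n_realizations = as.integer(n_realizations),
                generator = generator, dynamics = dynamics)
}

new_it_matrix <- function(it, se = NULL, n_realizations = NA_integer_,
                          generator = NULL, dynamics = NULL) {
  stopifnot(length(it) == 4)
  it <- stats::setNames(as.numeric(it), IT_NAMES)
  if (any(is.na(it)) || any(it < -1e-12) || any(it > 1 + 1e-12))
    stop("IT entries must lie in [0, 1]", call. = FALSE)
  structure(list(it = pmin(pmax(it, 0), 1),
                 se = if (is.null(se)) stats::setNames(rep(NA_real_, 4), IT_NAMES)
                      else stats::setNames(as.numeric(se), IT_NAMES),
                 n_realizations = n_realizations,
                 generator = generator, dynamics = dynamics),
            class = "it_matrix")
}

#' @export
print.it_matrix <- function(x, ...) {
  cat("Information-transmission matrix (source -> target)\n")
  m <- matrix(x$it, 2, 2, byrow = TRUE,
              dimnames = list(source = c("minority", "majority"),
                              target = c("minority", "majority")))
  print(round(m, 4))
  if (!all(is.na(x$se)))
    cat(sprintf("standard errors: %s\n",
                paste(sprintf("%s=%.4f", IT_NAMES, x$se), collapse = " ")))
  if (!is.na(x$n_realizations))
    cat(sprintf("M = %d realizations per source group\n", x$n_realizations))
  invisible(x)
}

#' @export
as.matrix.it_matrix <- function(x, ...) {
  matrix(x$it, 2, 2, byrow = TRUE,
         dimnames = list(source = c("minority", "majority"),
                         target = c("minority", "majority")))
}

it_values <- function(it) {
  if (inherits(it, "it_matrix")) return(it$it)
  v <- as.numeric(it)
  if (length(v) != 4)
    stop("expected an it_matrix or 4 values (mm, mM, Mm, MM)", call. = FALSE)
  if (is.null(names(it))) names(v) <- IT_NAMES else {
    if (!setequal(names(it), IT_NAMES))
      stop("IT vector names must be mm, mM, Mm, MM", call. = FALSE)
    v <- as.numeric(it)[IT_NAMES]
    names(v) <- IT_NAMES
  }
  v
}

#' Decompose an IT matrix into bias variables
#'
#' Linear change of variables from the four transmission probabilities to
#' interpretable biases:
#' \deqn{\bar{IT} = (IT_{mm}+IT_{mM}+IT_{Mm}+IT_{MM})/4}
#' \deqn{B_E = (-IT_{mm}-IT_{mM}+IT_{Mm}+IT_{MM})/2}
#' \deqn{B_R = (-IT_{mm}+IT_{mM}-IT_{Mm}+IT_{MM})/2}
#' \deqn{B_{EC} = (IT_{mm}-IT_{mM}-IT_{Mm}+IT_{MM})/2}
#' The mean transmission measures overall spreading; the emissivity bias
#' \code{B_E > 0} means majority-seeded information spreads better; the
#' receptivity bias \code{B_R > 0} means the majority receives more; the
#' echo-chamber bias \code{B_EC > 0} means within-group transmission
#' dominates between-group transmission (an echo chamber).
#'
#' @param it an \code{it_matrix} or a numeric vector of the four entries in
#'   order \code{mm, mM, Mm, MM}.
#' @return an object of class \code{bias_vector} with components
#'   \code{mean_it}, \code{emissivity}, \code{receptivity},
#'   \code{echo_chamber}.
#' @examples
#' bias_decompose(c(1, 0, 0, 1))   # perfect echo chamber: B_EC = 1
#' @export
bias_decompose <- function(it) {
  v <- it_values(it)
  b <- c(mean_it = sum(v) / 4,
         emissivity = (-v[["mm"]] - v[["mM"]] + v[["Mm"]] + v[["MM"]]) / 2,
         receptivity = (-v[["mm"]] + v[["mM"]] - v[["Mm"]] + v[["MM"]]) / 2,
         echo_chamber = (v[["mm"]] - v[["mM"]] - v[["Mm"]] + v[["MM"]]) / 2)
  structure(as.list(b), class = "bias_vector")
}

#' Reconstruct an IT matrix from bias variables
#'
#' Exact inverse of \code{\link{bias_decompose}}. Errors if the implied
#' transmission probabilities fall outside [0, 1] (an inconsistent bias
#' combination).
#'
#' @param b a \code{bias_vector} or numeric vector
#'   (mean_it, emissivity, receptivity, echo_chamber).
#' @param tol numerical tolerance on the [0, 1] bounds.
#' @return an \code{it_matrix}.
#' @examples
#' bias_invert(bias_decompose(c(0.9, 0.2, 0.3, 0.8)))$it
#' @export
bias_invert <- function(b, tol = 1e-9) {
  if (inherits(b, "bias_vector")) b <- unlist(b)
  v <- as.numeric(b)
  if (length(v) != 4)
    stop("expected 4 values (mean_it, emissivity, receptivity, echo_chamber)",
         call. = FALSE)
  it <- c(mm = v[1] + (-v[2] - v[3] + v[4]) / 2,
          mM = v[1] + (-v[2] + v[3] - v[4]) / 2,
          Mm = v[1] + (v[2] - v[3] - v[4]) / 2,
          MM = v[1] + (v[2] + v[3] + v[4]) / 2)
  if (any(it < -tol) || any(it > 1 + tol))
    stop(sprintf(
      "inconsistent bias vector: implied IT entries [%s] fall outside [0, 1]",
      paste(sprintf("%.4f", it), collapse = ", ")), call. = FALSE)
  new_it_matrix(pmin(pmax(it, 0), 1))
}

#' @export
print.bias_vector <- function(x, ...) {
  cat("Information-transmission biases\n")
  cat(sprintf("  mean IT        %+.4f\n", x$mean_it))
  cat(sprintf("  emissivity     %+.4f  (>0: majority sources spread better)\n",
              x$emissivity))
  cat(sprintf("  receptivity    %+.4f  (>0: majority targets receive more)\n",
              x$receptivity))
  cat(sprintf("  echo chamber   %+.4f  (>0: within-group flow dominates)\n",
              x$echo_chamber))
  invisible(x)
}
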