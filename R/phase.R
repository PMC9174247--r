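# Critical-threshold phase analysis: histograms of the final informed
# density over a threshold grid, and detection of the threshold T_c at which
# the global maximum of the pdf jumps from full contagion (rho_f = 1) to no
# contagion (rho_f = 0). When the contagion phase persists over the whole
# grid, T_c is reported as divergent.

#' Final-density histogram of a contagion ensemble
#'
#' Runs \code{n_realizations} cascades (fresh network and fresh seed per
#' realization when \code{generator} is a \code{\link{bah_config}}) and bins
#' the overall final densities \code{rho_f} into an area-normalized
#' histogram on [0, 1].
#'
#' @inheritParams estimate_it
#' @param source_group group from which seeds are drawn.
#' @param n_bins number of equal-width bins (at least 10; default 20, so the
#'   extreme bins are [0, 0.05) and [0.95, 1]).
#' @return object of class \code{density_pdf}: \code{breaks}, \code{mids},
#'   \code{counts}, \code{density} (integrating to 1), \code{n_realizations},
#'   and the raw densities \code{rho}.
#' @examples
#' p <- final_density_pdf(bah_config(100), dynamics_config("simple", 1),
#'                        "majority", n_realizations = 100, seed = 1)
#' sum(p$density * diff(p$breaks))   # 1
#' @export
final_density_pdf <- function(generator, dynamics, source_group,
                              n_realizations = 300, n_bins = 20,
                              seed = NULL) {
  stopifnot(n_bins >= 10, n_realizations >= 1)
  out <- with_seed(seed,
    source_ensemble(generator, dynamics, source_group, n_realizations))
  new_density_pdf(out$rho_all, n_bins, source_group)
}

new_density_pdf <- function(rho, n_bins, source_group = NA_character_) {
  breaks <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(floor(rho * n_bins) + 1L, n_bins)   # top edge closed
  counts <- tabulate(idx, nbins = n_bins)
  width <- 1 / n_bins
  structure(list(breaks = breaks,
                 mids = breaks[-1] - width / 2,
                 counts = counts,
                 density = counts / (sum(counts) * width),
                 n_realizations = length(rho),
                 source_group = source_group,
                 rho = rho),
            class = "density_pdf")
}

#' @export
print.density_pdf <- function(x, ...) {
  cat(sprintf(
    "Final-density pdf: %d realizations, %d bins; mass in [0,%.2f) = %.3f, mass in [%.2f,1] = %.3f\n",
    x$n_realizations, length(x$counts),
    x$breaks[2], x$counts[1] / x$n_realizations,
    x$breaks[length(x$breaks) - 1],
    x$counts[length(x$counts)] / x$n_realizations))
  invisible(x)
}

#' @export
plot.density_pdf <- function(x, ...) {
  graphics::barplot(x$density, width = diff(x$breaks),
                    space = 0, names.arg = NULL,
                    xlab = expression(rho[f]), ylab = "pdf", ...)
  graphics::axis(1, at = seq(0, length(x$counts), length.out = 6),
                 labels = seq(0, 1, 0.2))
  invisible(x)
}

#' Locate the critical threshold of a scan
#'
#' Given final-density pdfs on an ascending threshold grid, returns the
#' smallest grid threshold at which the global maximum of the pdf sits in
#' the bottom extreme bin (no contagion) rather than the top extreme bin
#' (full contagion). If the top bin stays the global maximum over the whole
#' grid, the critical threshold is reported as divergent: the contagion phase
#' persists for every threshold.
#'
#' Pdfs that are not all-or-nothing (global maximum in an interior bin at
#' some grid point, as for majority-source hybrid cascades whose
#' transmission mode sits below 1) are handled by comparing the masses of
#' the two phases instead of single bins: the no-contagion phase is the
#' bottom extreme bin and the transmission phase is all mass at
#' \code{rho_f > 0.5}. The critical threshold is then the first grid point
#' where the no-contagion mass outweighs the transmission mass, and the
#' result is flagged. For all-or-nothing pdfs the two rules coincide (the
#' transmission phase lives in the top bin).
#'
#' @param scan a \code{threshold_scan} object, or a list with numeric
#'   \code{thresholds} and a list \code{pdfs} of \code{density_pdf} objects
#'   sharing one binning.
#' @return object of class \code{critical_threshold}: \code{value} (numeric,
#'   \code{NA} when divergent), \code{divergent}, \code{flagged} (TRUE when
#'   the extreme-mass fallback decided), and \code{method}.
#' @examples
#' # all mass on top for T < 0.3, on bottom from 0.3 on -> T_c = 0.3
#' pdfs <- lapply(seq(0.1, 0.5, 0.1), function(T)
#'   echonet:::new_density_pdf(rep(if (T < 0.3) 1 else 0, 100), 20))
#' critical_threshold(list(thresholds = seq(0.1, 0.5, 0.1), pdfs = pdfs))
#' @export
critical_threshold <- function(scan) {
  th <- scan$thresholds
  pdfs <- scan$pdfs
  stopifnot(length(th) == length(pdfs), !is.unsorted(th))
  nb <- length(pdfs[[1]]$counts)
  cls <- vapply(pdfs, function(p) {
    stopifnot(length(p$counts) == nb)
    gm <- which.max(p$density)
    if (gm == 1L) "bottom" else if (gm == nb) "top" else "interior"
  }, character(1))
  bottom_mass <- vapply(pdfs, function(p) p$counts[1] / sum(p$counts), numeric(1))
  top_mass <- vapply(pdfs, function(p) p$counts[nb] / sum(p$counts), numeric(1))
  # transmission-phase mass: everything above rho_f = 0.5
  upper <- which(pdfs[[1]]$breaks[-length(pdfs[[1]]$breaks)] >= 0.5)
  trans_mass <- vapply(pdfs, function(p)
    sum(p$counts[upper]) / sum(p$counts), numeric(1))

  if (!any(cls == "interior")) {
    # all-or-nothing family: literal global-maximum-bin switch
    hit <- which(cls == "bottom")
    if (length(hit)) {
      res <- list(value = th[hit[1]], divergent = FALSE, flagged = FALSE,
                  method = "global_max")
    } else {
      res <- list(value = NA_real_, divergent = TRUE, flagged = FALSE,
                  method = "global_max")
    }
  } else {
    # broad transmission mode: compare the masses of the two phases
    cross <- which(bottom_mass > trans_mass)
    if (length(cross)) {
      res <- list(value = th[cross[1]], divergent = FALSE, flagged = TRUE,
                  method = "phase_mass")
    } else {
      res <- list(value = NA_real_, divergent = TRUE, flagged = TRUE,
                  method = "phase_mass")
    }
  }
  res$classification <- cls
  res$bottom_mass <- bottom_mass
  res$top_mass <- top_mass
  res$transmission_mass <- trans_mass
  res$thresholds <- th
  class(res) <- "critical_threshold"
  res
}

#' @export
print.critical_threshold <- function(x, ...) {
  if (x$divergent) {
    cat("Critical threshold: divergent (contagion phase persists over the grid)\n")
  } else {
    cat(sprintf("Critical threshold T_c = %g%s\n", x$value,
                if (x$flagged) " (extreme-mass rule; pdf not all-or-nothing)" else ""))
  }
  invisible(x)
}

#' Scan final-density pdfs over a threshold grid
#'
#' Builds a \code{\link{final_density_pdf}} for every threshold on the grid
#' (same generator, dynamics model, and source group throughout) and locates
#' the critical threshold.
#'
#' @inheritParams final_density_pdf
#' @param model \code{"complex"} or \code{"hybrid"} (the threshold models).
#' @param t_grid ascending grid of thresholds in (0, 1].
#' @return object of class \code{threshold_scan}: \code{thresholds},
#'   \code{pdfs}, \code{critical} (a \code{\link{critical_threshold}}), and
#'   the configurations.
#' @examples
#' sc <- threshold_scan(bah_config(100), "complex", "majority",
#'                      t_grid = seq(0.1, 0.5, 0.1), n_realizations = 100,
#'                      seed = 1)
#' sc$critical
#' @export
threshold_scan <- function(generator, model = c("complex", "hybrid"),
                           source_group, t_grid = seq(0.02, 1, by = 0.02),
                           n_realizations = 300, n_bins = 20, seed = NULL) {
  model <- match.arg(model)
  stopifnot(length(t_grid) >= 1, !is.unsorted(t_grid),
            all(t_grid > 0), all(t_grid <= 1))
  run <- function() {
    lapply(t_grid, function(T_)
      final_density_pdf(generator,
                        dynamics_config(model, threshold = T_),
                        source_group, n_realizations, n_bins))
  }
  pdfs <- with_seed(seed, run())
  out <- list(thresholds = t_grid, pdfs = pdfs,
              source_group = match_group(source_group),
              model = model, generator = generator,
              n_realizations = as.integer(n_realizations))
  out$critical <- critical_threshold(out)
  class(out) <- "threshold_scan"
  out
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("Threshold scan (%s contagion, %s source): %d thresholds x %d realizations\n",
              x$model, x$source_group, length(x$thresholds),
              x$n_realizations))
  print(x$critical)
  invisible(x)
}

#' Sweep the critical threshold against homophily
#'
#' For every combination of homophily value and source group, runs a
#' \code{\link{threshold_scan}} and records the critical threshold (or its
#' divergence). This reproduces the phase diagrams of the threshold models
#' as the network moves from heterophilic to homophilic.
#'
#' @inheritParams threshold_scan
#' @param generator a \code{\link{bah_config}} whose \code{homophily} field
#'   is overridden by each grid value.
#' @param h_grid homophily values to sweep.
#' @param source_groups one or both of \code{"minority"}, \code{"majority"}.
#' @param keep_scans retain the full scans (memory-heavy) in the result.
#' @return object of class \code{homophily_sweep} wrapping a data frame
#'   \code{results} with columns \code{h}, \code{source}, \code{t_c}
#'   (\code{NA} when divergent), \code{divergent}, \code{flagged}.
#' @examples
#' sw <- threshold_homophily_sweep(bah_config(100), "complex",
#'                                 h_grid = c(0.2, 0.7),
#'                                 t_grid = seq(0.05, 0.5, 0.05),
#'                                 n_realizations = 100, seed = 1)
#' sw$results
#' @export
threshold_homophily_sweep <- function(generator,
                                      model = c("complex", "hybrid"),
                                      h_grid,
                                      t_grid = seq(0.02, 1, by = 0.02),
                                      source_groups = c("minority", "majority"),
                                      n_realizations = 300, n_bins = 20,
                                      keep_scans = FALSE, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(generator, "bah_config"), length(h_grid) >= 1)
  source_groups <- match_group(source_groups, several.ok = TRUE)
  grid <- expand.grid(h = h_grid, source = source_groups,
                      stringsAsFactors = FALSE)
  scans <- vector("list", nrow(grid))
  run <- function() {
    for (i in seq_len(nrow(grid))) {
      gen <- generator
      gen$homophily <- grid$h[i]
      scans[[i]] <<- threshold_scan(gen, model, grid$source[i], t_grid,
                                    n_realizations, n_bins)
    }
  }
  with_seed(seed, run())
  crit <- lapply(scans, `[[`, "critical")
  results <- data.frame(
    h = grid$h, source = grid$source,
    t_c = vapply(crit, `[[`, numeric(1), "value"),
    divergent = vapply(crit, `[[`, logical(1), "divergent"),
    flagged = vapply(crit, `[[`, logical(1), "flagged"))
  structure(list(results = results, model = model, generator = generator,
                 t_grid = t_grid, n_realizations = as.integer(n_realizations),
                 scans = if (keep_scans) scans else NULL),
            class = "homophily_sweep")
}

#' @export
print.homophily_sweep <- function(x, ...) {
  cat(sprintf("Critical-threshold sweep (%s contagion), %d (h, source) points:\n",
              x$model, nrow(x$results)))
  df <- x$results
  df$t_c <- ifelse(df$divergent, "divergent", format(df$t_c))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.homophily_sweep <- function(x, ...) {
  df <- x$results
  finite <- df[!df$divergent, ]
  graphics::plot(NULL, xlim = range(df$h),
                 ylim = c(0, max(finite$t_c, 0.1, na.rm = TRUE) * 1.1),
                 xlab = "homophily h", ylab = expression(T[c]), ...)
  for (s in unique(df$source)) {
    d <- df[df$source == s, ]
    col <- if (s == "minority") "firebrick" else "steelblue"
    graphics::lines(d$h, d$t_c, col = col, type = "b", pch = 16)
    div <- d[d$divergent, ]
    if (nrow(div))
      graphics::points(div$h, rep(graphics::par("usr")[4], nrow(div)),
                       pch = 17, col = col)
  }
  graphics::legend("topleft", legend = unique(df$source), bty = "n",
                   col = c("firebrick", "steelblue")[
                     match(unique(df$source), c("minority", "majority"))],
                   pch = 16)
  invisible(x)
}
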