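# Top-level driver: powder-averaged decay simulation with engine
# selection, instability rejection, and optional averaging over the
# electron resonance-offset distribution.

#' Simulate a powder-averaged decoherence trace
#'
#' Runs the selected expansion engine for every orientation of a
#' hemispherical grid, flags orientations whose normalized signal leaves
#' `[0, 1.1]` within the rejection window, and returns the weighted
#' average over the surviving orientations. In dressed mode, setting
#' `offset_nodes > 1` additionally averages the assembled traces over the
#' Gaussian resonance-offset distribution of the system (Gauss-Hermite
#' quadrature with the system's `offset_sigma`).
#'
#' @param system A [spin_system()].
#' @param times Evolution times T, us.
#' @param engine One of "appa", "cce", "pcce", "cf".
#' @param mode "bare" or "dressed" (APPA is bare-only).
#' @param order CCE truncation order (engine "cce").
#' @param partition Disjoint cluster partition for "pcce"/"cf"; defaults
#'   to the methyl partition of the system.
#' @param u Superclusters combine `u` partition clusters (engine "pcce").
#' @param knots Orientation-grid knots (default 9, i.e. 145 orientations).
#' @param w1 Drive amplitude, MHz (dressed mode).
#' @param OmegaS Resonance offset, MHz (centre of the distribution).
#' @param offset_nodes Offset quadrature nodes (dressed mode; 1 = no
#'   offset averaging).
#' @param reject_window Time window for instability rejection, us;
#'   defaults to the full trace.
#' @param floor Division instability floor for the expansion engines.
#' @param settle_delay,pm_model,pm_amplitude See [sequence_spec()].
#' @param progress Print per-orientation progress?
#' @return Object of class `decoherence_sim` with elements `trace` (the
#'   averaged `cluster_trace`), `rejected_fraction`, `engine`, `mode`,
#'   `order`, `grid`, and per-orientation diagnostics in `orientations`.
#' @export
#' @examples
#' \donttest{
#' frag <- make_methyl(c(0, 0, 4.5), c(0, 0, 1), tunnel_kHz = 54.5)
#' sys <- spin_system(frag$protons, list(frag$methyl))
#' sim <- simulate_decoherence(sys, times = seq(0, 20, 2), engine = "cce",
#'                             order = 2, knots = 2)
#' print(sim)
#' }
simulate_decoherence <- function(system, times,
                                 engine = c("cce", "appa", "pcce", "cf"),
                                 mode = c("bare", "dressed"),
                                 order = 2L, partition = NULL, u = 2L,
                                 knots = 9L, w1 = 100, OmegaS = 0,
                                 offset_nodes = 1L, reject_window = NULL,
                                 floor = 1e-10, settle_delay = 0.996,
                                 pm_model = "ideal", pm_amplitude = 0.3,
                                 progress = FALSE) {
  stopifnot(inherits(system, "spin_system"))
  engine <- match.arg(engine)
  mode <- match.arg(mode)
  if (engine == "appa" && mode != "bare")
    stop("the analytical pair product approximation is bare-spin only")
  if (engine %in% c("pcce", "cf") && is.null(partition))
    partition <- methyl_partition(system)
  grid <- orientation_grid(knots)
  orientations <- grid_orientations(grid)
  offs <- OmegaS
  wts <- 1
  if (mode == "dressed" && offset_nodes > 1L && system$offset_sigma > 0) {
    gh <- pracma::gaussHermite(as.integer(offset_nodes))
    offs <- OmegaS + sqrt(2) * system$offset_sigma * gh$x
    wts <- gh$w / sqrt(pi)
  }
  traces <- vector("list", length(orientations))
  n_unstable_div <- 0L
  for (i in seq_along(orientations)) {
    ori <- orientations[[i]]
    acc <- NULL
    for (j in seq_along(offs)) {
      spec <- sequence_spec(mode, times, w1 = w1, OmegaS = offs[j],
                            settle_delay = settle_delay,
                            pm_model = pm_model,
                            pm_amplitude = pm_amplitude)
      res <- switch(engine,
        appa = appa_trace(couplings_for_orientation(system, ori), times),
        cce = cce_trace(system, order, spec, ori, floor),
        pcce = pcce_trace(system, partition, u, spec, ori, floor),
        cf = cf_trace(system, partition, spec, ori, floor))
      if (inherits(res, "expansion_result")) {
        if (res$unstable) n_unstable_div <- n_unstable_div + 1L
        res <- res$trace
      }
      acc <- if (is.null(acc)) wts[j] * res$values else acc + wts[j] * res$values
    }
    traces[[i]] <- .new_cluster_trace(times, acc, NA_real_, mode)
    if (progress)
      message(sprintf("orientation %d/%d done", i, length(orientations)))
  }
  reject <- vapply(traces, reject_unstable, logical(1),
                   window = reject_window)
  if (all(reject)) stop("all orientations rejected as unstable")
  avg <- powder_average(traces, grid, reject)
  structure(list(trace = avg,
                 rejected_fraction = attr(avg, "rejected_fraction"),
                 engine = engine, mode = mode,
                 order = if (engine == "pcce")
                   c(length(partition[[1]]), u * length(partition[[1]]))
                 else order,
                 grid = grid, orientations = data.frame(
                   theta = grid$theta, phi = grid$phi, rejected = reject),
                 n_unstable_divisions = n_unstable_div,
                 system = system),
            class = "decoherence_sim")
}

#' @export
print.decoherence_sim <- function(x, ...) {
  cat(sprintf("<decoherence_sim> %s-spin decay, engine %s\n",
              x$mode, x$engine))
  cat(sprintf("  %d protons, %d orientations (%.1f%% rejected)\n",
              length(x$system$protons), nrow(x$grid),
              100 * x$rejected_fraction))
  te <- decay_time(x)
  if (is.finite(te)) cat(sprintf("  1/e decay time: %.3g us\n", te))
  invisible(x)
}

#' @export
summary.decoherence_sim <- function(object, ...) {
  cat(sprintf("Powder-averaged %s-spin decoherence (engine %s, order %s)\n",
              object$mode, object$engine,
              paste(object$order, collapse = ",")))
  cat(sprintf("  protons: %d, methyl groups: %d\n",
              length(object$system$protons),
              length(object$system$methyls)))
  cat(sprintf("  grid: %d knots, %d orientations, rejected %.1f%%\n",
              attr(object$grid, "knots"), nrow(object$grid),
              100 * object$rejected_fraction))
  cat(sprintf("  time axis: %g .. %g us (%d points)\n",
              min(object$trace$times), max(object$trace$times),
              length(object$trace$times)))
  te <- decay_time(object)
  cat(sprintf("  1/e decay time: %s us\n",
              if (is.finite(te)) sprintf("%.3g", te) else "not reached"))
  invisible(object)
}

#' @export
plot.decoherence_sim <- function(x, ...,
                                 xlab = "T [us]",
                                 ylab = "normalized echo signal") {
  graphics::plot(x$trace$times, x$trace$values, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = exp(-1), lty = 3, col = "grey50")
  invisible(x)
}

#' First crossing time of a decay trace
#'
#' Linear interpolation of the first downward crossing of `level`
#' (default 1/e); `Inf` if the trace never falls below it.
#'
#' @param x A `cluster_trace`, `expansion_result` or `decoherence_sim`.
#' @param level Signal level defining the decay time.
#' @return Time of the first crossing, us.
#' @export
decay_time <- function(x, level = exp(-1)) {
  if (inherits(x, "decoherence_sim")) x <- x$trace
  if (inherits(x, "expansion_result")) x <- x$trace
  stopifnot(inherits(x, "cluster_trace"))
  v <- x$values
  tt <- x$times
  below <- which(v < level)
  if (!length(below)) return(Inf)
  i <- below[1]
  if (i == 1) return(tt[1])
  t0 <- tt[i - 1]; t1 <- tt[i]
  v0 <- v[i - 1]; v1 <- v[i]
  t0 + (v0 - level) / (v0 - v1) * (t1 - t0)
}
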