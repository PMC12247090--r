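# Deterministic hemispherical orientation grids and weighted powder
# averaging with rejection of unstable orientations.

#' Hemispherical orientation grid
#'
#' Builds a deterministic grid of field orientations on the upper
#' hemisphere: `k` rings at theta = 90 (i-1)/(k-1) degrees, with a single
#' point at the pole and 4 (i-1) equally spaced phi values on ring i, for
#' a total of 2 k (k-1) + 1 orientations (k = 9 gives 145, k = 23 gives
#' 1013). Each ring carries the solid angle of its latitude band, divided
#' equally among its points; weights are normalized to sum to 1.
#'
#' @param knots Number of rings k >= 2.
#' @return Object of class `orientation_grid`: data frame with columns
#'   `theta`, `phi` (degrees) and `weight`.
#' @export
#' @examples
#' nrow(orientation_grid(9))  # 145
orientation_grid <- function(knots) {
  knots <- as.integer(knots)
  if (is.na(knots) || knots < 2) stop("knots must be an integer >= 2")
  theta_ring <- 90 * (seq_len(knots) - 1) / (knots - 1)
  # band edges: midpoints between rings, clamped to [0, 90]
  edges <- c(0, (theta_ring[-knots] + theta_ring[-1]) / 2, 90)
  band <- cos(edges[-(knots + 1)] * pi / 180) - cos(edges[-1] * pi / 180)
  theta <- phi <- weight <- numeric(0)
  for (i in seq_len(knots)) {
    npts <- if (i == 1) 1L else 4L * (i - 1L)
    theta <- c(theta, rep(theta_ring[i], npts))
    phi <- c(phi, (seq_len(npts) - 1) * 360 / npts)
    weight <- c(weight, rep(band[i] / npts, npts))
  }
  grid <- data.frame(theta = theta, phi = phi, weight = weight / sum(weight))
  class(grid) <- c("orientation_grid", "data.frame")
  attr(grid, "knots") <- knots
  grid
}

#' @export
print.orientation_grid <- function(x, ...) {
  cat(sprintf("<orientation_grid> %d knots, %d orientations\n",
              attr(x, "knots"), nrow(x)))
  invisible(x)
}

#' Orientations of a grid as a list
#'
#' @param grid An [orientation_grid()].
#' @return List of [orientation()] objects carrying the grid weights.
#' @export
grid_orientations <- function(grid) {
  stopifnot(inherits(grid, "orientation_grid"))
  lapply(seq_len(nrow(grid)), function(i)
    orientation(grid$theta[i], grid$phi[i], grid$weight[i]))
}

#' Weighted powder average of per-orientation traces
#'
#' Averages traces over the grid with the grid weights, after removing
#' orientations flagged as rejected (weights are renormalized over the
#' surviving set). The fraction of rejected orientations is recorded on
#' the result.
#'
#' @param traces List of `cluster_trace` objects (or `expansion_result`s),
#'   one per grid orientation, on a common time axis.
#' @param grid An [orientation_grid()] with matching length.
#' @param reject Logical vector of rejection flags (default: none).
#' @return A `cluster_trace` with attribute `rejected_fraction`.
#' @export
powder_average <- function(traces, grid, reject = NULL) {
  stopifnot(inherits(grid, "orientation_grid"))
  traces <- lapply(traces, function(tr)
    if (inherits(tr, "expansion_result")) tr$trace else tr)
  if (length(traces) != nrow(grid))
    stop("need one trace per grid orientation")
  if (is.null(reject)) reject <- rep(FALSE, length(traces))
  if (length(reject) != length(traces))
    stop("reject mask length must match the number of traces")
  if (all(reject)) stop("all orientations were rejected")
  keep <- which(!reject)
  w <- grid$weight[keep]
  w <- w / sum(w)
  times <- traces[[keep[1]]]$times
  acc <- numeric(length(times))
  for (j in seq_along(keep)) {
    tr <- traces[[keep[j]]]
    if (!isTRUE(all.equal(tr$times, times)))
      stop("traces must share a common time axis")
    acc <- acc + w[j] * tr$values
  }
  out <- .new_cluster_trace(times, acc, NA_real_, traces[[keep[1]]]$mode)
  attr(out, "rejected_fraction") <- mean(reject)
  out
}
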