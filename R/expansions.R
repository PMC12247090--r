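# Decay-trace assembly engines: analytical pair product approximation
# (APPA), cluster correlation expansion (CCE-o), partial CCE over a
# disjoint partition (pCCE(s, o = u*s)), and plain cluster factorization
# (CF). All engines work per orientation; powder averaging is layered on
# top (see powder.R / simulate_decoherence).

#' Analytical pair product approximation (APPA)
#'
#' Bare-spin Hahn echo decay as the product over all proton pairs of the
#' analytical nuclear-pair ESEEM factor
#' `W_kl(T) = 1 - (3/2) l - (l/2) cos(w T) + 2 l cos(w T / 2)` with
#' modulation depth `l = (Ak - Al)^2 wnn^2 / ((Ak - Al)^2 + wnn^2)^2` and
#' nuclear zero-quantum frequency `w = sqrt((Ak - Al)^2 + wnn^2) / 2`,
#' where `wnn` is the tunnel-substituted flip-flop coupling.
#'
#' @param couplings A `coupling_set` from [couplings_for_orientation()].
#' @param times Evolution times T, us.
#' @return A `cluster_trace` (bare mode).
#' @export
appa_trace <- function(couplings, times) {
  stopifnot(inherits(couplings, "coupling_set"))
  n <- length(couplings$A)
  W <- rep(1, length(times))
  if (n > 1) {
    for (k in seq_len(n - 1)) for (l in (k + 1):n) {
      W <- W * pair_eseem(couplings$A[k], couplings$A[l],
                          couplings$wnn[k, l], times)
    }
  }
  .new_cluster_trace(times, W, 1, "bare")
}

#' Analytical two-proton Hahn echo modulation factor
#'
#' @param Ak,Al Secular hyperfine couplings of the two protons, MHz.
#' @param wnn_kHz Flip-flop coupling (tunnel-substituted), kHz.
#' @param times Evolution times, us.
#' @return Numeric vector `W_kl(T)`.
#' @export
pair_eseem <- function(Ak, Al, wnn_kHz, times) {
  dA <- Ak - Al                      # MHz
  wnn <- wnn_kHz / 1e3               # MHz
  lam <- pair_modulation_depth(Ak, Al, wnn_kHz)
  wZQ <- .MHz(0.5 * sqrt(dA^2 + wnn^2))  # rad/us
  1 - 1.5 * lam - 0.5 * lam * cos(wZQ * times) + 2 * lam * cos(wZQ * times / 2)
}

#' Modulation depth of the two-proton echo factor
#'
#' `lambda = (Ak - Al)^2 wnn^2 / ((Ak - Al)^2 + wnn^2)^2`; maximal at 1/4
#' when the hyperfine difference matches the flip-flop coupling.
#'
#' @inheritParams pair_eseem
#' @return Modulation depth in `[0, 1/4]`.
#' @export
pair_modulation_depth <- function(Ak, Al, wnn_kHz) {
  dA <- Ak - Al
  wnn <- wnn_kHz / 1e3
  den <- (dA^2 + wnn^2)^2
  if (den == 0) 0 else dA^2 * wnn^2 / den
}

# normalized trace values of one cluster under the sequence spec
.engine_cluster_values <- function(couplings, cluster, spec) {
  if (spec$mode == "bare") {
    if (length(cluster) == 0) return(rep(1, length(spec$times)))
    hahn_echo_trace(couplings, spec, cluster)$values
  } else {
    dressed_echo_trace(if (length(cluster)) couplings else NULL, spec,
                       cluster)$values
  }
}

# elementwise division with instability floor; returns values and a flag
.floor_divide <- function(num, den, floor) {
  list(values = num / den, flagged = any(abs(den) < floor))
}

.new_expansion_result <- function(times, values, mode, engine, order,
                                  n_signals, unstable_clusters,
                                  supercluster_count = NA_integer_) {
  structure(list(trace = .new_cluster_trace(times, values, 1, mode),
                 engine = engine, order = order, n_signals = n_signals,
                 unstable = length(unstable_clusters) > 0,
                 unstable_clusters = unstable_clusters,
                 supercluster_count = supercluster_count),
            class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  ord <- paste(x$order, collapse = ",")
  cat(sprintf("<expansion_result> engine %s(%s), %d cluster signal(s)%s\n",
              x$engine, ord, x$n_signals,
              if (x$unstable) sprintf(", %d unstable division(s)",
                                      length(x$unstable_clusters)) else ""))
  invisible(x)
}

#' Cluster correlation expansion trace for one orientation
#'
#' Enumerates all proton clusters up to size `order`, computes each cluster
#' signal by density-operator simulation, divides out all subcluster
#' contributions (memoized, in increasing cluster size) and assembles
#' `L(o) = W_empty * prod_c Ltilde_c`. Divisions by values smaller in
#' magnitude than `floor` flag the affected cluster; the result is then
#' marked unstable rather than patched.
#'
#' @param system A [spin_system()].
#' @param order CCE truncation order o >= 1.
#' @param spec A [sequence_spec()].
#' @param orientation An [orientation()].
#' @param floor Instability floor for divisions (default 1e-10).
#' @return An `expansion_result`.
#' @export
cce_trace <- function(system, order, spec, orientation, floor = 1e-10) {
  stopifnot(inherits(system, "spin_system"), order >= 1)
  N <- length(system$protons)
  if (order > N) stop("CCE order exceeds the number of protons")
  cpl <- couplings_for_orientation(system, orientation)
  w0 <- .engine_cluster_values(cpl, integer(0), spec)
  memo <- new.env(parent = emptyenv())
  unstable <- list()
  n_signals <- 1L
  key <- function(ids) paste(ids, collapse = ",")
  L <- w0
  for (size in seq_len(order)) {
    combos <- utils::combn(cpl$ids, size, simplify = FALSE)
    for (C in combos) {
      WC <- .engine_cluster_values(cpl, C, spec)
      n_signals <- n_signals + 1L
      den <- w0
      if (size > 1) {
        for (sub_size in seq_len(size - 1)) {
          subs <- utils::combn(C, sub_size, simplify = FALSE)
          for (S in subs) den <- den * get(key(S), envir = memo)
        }
      }
      div <- .floor_divide(WC, den, floor)
      if (div$flagged) unstable <- c(unstable, list(C))
      assign(key(C), div$values, envir = memo)
      L <- L * div$values
    }
  }
  .new_expansion_result(spec$times, L, spec$mode, "cce", order, n_signals,
                        unstable)
}

#' Validate a disjoint equal-size cluster partition
#'
#' @param partition List of integer vectors of proton ids; clusters must be
#'   disjoint and of equal size.
#' @param system Optional [spin_system()] to check ids against.
#' @return The partition, with sorted clusters.
#' @export
cluster_partition <- function(partition, system = NULL) {
  if (!is.list(partition) || !length(partition))
    stop("partition must be a non-empty list of id vectors")
  partition <- lapply(partition, function(x) sort(as.integer(x)))
  sizes <- lengths(partition)
  if (length(unique(sizes)) != 1L)
    stop("all clusters in a partition must have the same size")
  all_ids <- unlist(partition)
  if (anyDuplicated(all_ids)) stop("partition clusters must be disjoint")
  if (!is.null(system) && !all(all_ids %in% system$ids))
    stop("partition references unknown proton ids")
  partition
}

#' Partition a spin system by methyl-group membership
#'
#' @param system A [spin_system()] with methyl groups.
#' @return A partition (list of 3-proton id vectors).
#' @export
methyl_partition <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  if (!length(system$methyls)) stop("system has no methyl groups")
  cluster_partition(lapply(system$methyls, function(m) m$proton_ids), system)
}

#' Partial cluster correlation expansion trace for one orientation
#'
#' The bath is partitioned into M disjoint clusters of size s. Each
#' cluster signal is corrected for the empty-bath signal,
#' `Stilde_j = S_j / W_empty`; every supercluster formed from u clusters
#' contributes `Ltilde_k = S_k / (W_empty * prod_{j in k} Stilde_j)`; and
#' the assembled signal is
#' `L = W_empty * prod_j Stilde_j * prod_k Ltilde_k`. There are
#' choose(M, u) superclusters of size o = u s.
#'
#' @param system A [spin_system()].
#' @param partition List of disjoint equal-size id vectors (see
#'   [cluster_partition()]), e.g. from [methyl_partition()].
#' @param u Number of clusters combined into a supercluster (>= 1).
#' @inheritParams cce_trace
#' @return An `expansion_result` with the supercluster count in
#'   `supercluster_count`.
#' @export
pcce_trace <- function(system, partition, u, spec, orientation,
                       floor = 1e-10) {
  stopifnot(inherits(system, "spin_system"))
  partition <- cluster_partition(partition, system)
  M <- length(partition)
  u <- as.integer(u)
  if (u < 1 || u > M) stop("u must satisfy 1 <= u <= number of clusters")
  cpl <- couplings_for_orientation(system, orientation)
  w0 <- .engine_cluster_values(cpl, integer(0), spec)
  unstable <- list()
  n_signals <- 1L
  Stilde <- vector("list", M)
  L <- w0
  for (j in seq_len(M)) {
    Sj <- .engine_cluster_values(cpl, partition[[j]], spec)
    n_signals <- n_signals + 1L
    div <- .floor_divide(Sj, w0, floor)
    if (div$flagged) unstable <- c(unstable, list(partition[[j]]))
    Stilde[[j]] <- div$values
    L <- L * div$values
  }
  n_super <- 0L
  if (u > 1) {
    supers <- utils::combn(M, u, simplify = FALSE)
    n_super <- length(supers)
    for (ks in supers) {
      ids <- sort(unlist(partition[ks]))
      Sk <- .engine_cluster_values(cpl, ids, spec)
      n_signals <- n_signals + 1L
      den <- w0
      for (j in ks) den <- den * Stilde[[j]]
      div <- .floor_divide(Sk, den, floor)
      if (div$flagged) unstable <- c(unstable, list(ids))
      L <- L * div$values
    }
  } else {
    n_super <- M  # superclusters coincide with the clusters themselves
  }
  s <- length(partition[[1]])
  .new_expansion_result(spec$times, L, spec$mode, "pcce", c(s, u * s),
                        n_signals, unstable, n_super)
}

#' Cluster factorization trace for one orientation
#'
#' Product of the empty-bath-corrected signals of the disjoint clusters:
#' `L = W_empty * prod_j Stilde_j`. Identical to pCCE with u = 1; exact
#' when all inter-cluster couplings vanish.
#'
#' @inheritParams pcce_trace
#' @return An `expansion_result`.
#' @export
cf_trace <- function(system, partition, spec, orientation, floor = 1e-10) {
  res <- pcce_trace(system, partition, 1L, spec, orientation, floor)
  res$engine <- "cf"
  res
}

#' Flag a trace as numerically unstable
#'
#' A normalized echo trace is rejected if, at any time within the
#' inspection window, it becomes negative or exceeds 1.1 (the thresholds
#' used when discarding orientations from powder averages).
#'
#' @param trace A `cluster_trace` (or an `expansion_result`).
#' @param window Inspection window, us; defaults to the full time axis.
#' @param lower,upper Rejection thresholds.
#' @return TRUE if the trace is unstable within the window.
#' @export
reject_unstable <- function(trace, window = NULL, lower = 0, upper = 1.1) {
  if (inherits(trace, "expansion_result")) trace <- trace$trace
  stopifnot(inherits(trace, "cluster_trace"))
  if (is.null(window)) window <- max(trace$times)
  v <- trace$values[trace$times <= window]
  any(v < lower | v > upper)
}
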