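# Pulse-sequence engines. Bare mode: two-pulse Hahn echo
# (pi/2 - T/2 - pi - T/2 - echo) with ideal pulses. Dressed mode: spin lock
# along +x with a pi/2 - T/2 - pi - T/2 - pi/2 phase-modulation (PM) echo on
# the dressed spin; PM pulses are either ideal instantaneous dressed-frame
# rotations (exp(-i beta Sz)) or explicit propagation of the cosine
# phase-modulated drive.

#' Pulse-sequence specification
#'
#' @param mode "bare" (Hahn echo, no microwave drive during evolution) or
#'   "dressed" (spin-locked primary echo via PM pulses).
#' @param times Total evolution times T, us; non-negative, increasing.
#' @param w1 Microwave field amplitude, MHz; required > 0 in dressed mode.
#' @param OmegaS Electron resonance offset, MHz.
#' @param settle_delay Delay between the start of the spin lock and the
#'   first PM pulse, us (dressed mode). Default 0.996 us, mirroring the
#'   delay used experimentally.
#' @param pm_model "ideal" (instantaneous dressed rotations) or "explicit"
#'   (time-stepped propagation of the phase-modulated drive).
#' @param pm_amplitude PM modulation amplitude a_PM, rad (explicit model).
#' @return Object of class `sequence_spec`.
#' @export
sequence_spec <- function(mode = c("bare", "dressed"), times,
                          w1 = 100, OmegaS = 0, settle_delay = 0.996,
                          pm_model = c("ideal", "explicit"),
                          pm_amplitude = 0.3) {
  mode <- match.arg(mode)
  pm_model <- match.arg(pm_model)
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) || any(times < 0) ||
      is.unsorted(times, strictly = TRUE))
    stop("times must be non-negative and strictly increasing (us)")
  if (mode == "dressed" && (!is.finite(w1) || w1 <= 0))
    stop("dressed mode requires w1 > 0 (MHz)")
  structure(list(mode = mode, times = times, w1 = w1, OmegaS = OmegaS,
                 settle_delay = settle_delay, pm_model = pm_model,
                 pm_amplitude = pm_amplitude),
            class = "sequence_spec")
}

# minimal coupling set describing an empty bath
.empty_couplings <- function() {
  structure(list(A = numeric(0), Bx = numeric(0), By = numeric(0),
                 wdd = matrix(0, 0, 0), wzz = matrix(0, 0, 0),
                 wnn = matrix(0, 0, 0), ids = integer(0),
                 orientation = orientation(0, 0)),
            class = "coupling_set")
}

.new_cluster_trace <- function(times, values, raw0, mode) {
  structure(list(times = times, values = values, raw0 = raw0, mode = mode),
            class = "cluster_trace")
}

#' @export
print.cluster_trace <- function(x, ...) {
  cat(sprintf("<cluster_trace> %s mode, %d time points, range [%.4g, %.4g]\n",
              x$mode, length(x$times), min(x$values), max(x$values)))
  invisible(x)
}

# trace of operator product, tr(A %*% B), without forming the product
.trAB <- function(A, B) sum(A * t(B))

#' Bare-spin Hahn echo trace of one cluster
#'
#' Simulates pi/2 - T/2 - pi(x) - T/2 - echo with ideal pulses by full
#' density-operator propagation in the eigenbasis of the cluster
#' Hamiltonian, and returns the refocused electron coherence normalized to
#' its value at T = 0.
#'
#' @param couplings A `coupling_set` (or NULL for an empty bath).
#' @param spec A [sequence_spec()] with mode "bare".
#' @param cluster Proton ids forming the cluster; defaults to all.
#' @param include_pseudosecular Include pseudo-secular hyperfine terms.
#' @return A `cluster_trace`.
#' @export
hahn_echo_trace <- function(couplings, spec, cluster = couplings$ids,
                            include_pseudosecular = TRUE) {
  stopifnot(inherits(spec, "sequence_spec"), spec$mode == "bare")
  if (is.null(couplings)) { couplings <- .empty_couplings(); cluster <- integer(0) }
  ham <- build_cluster_hamiltonian(couplings, cluster, OmegaS = spec$OmegaS,
                                   w1 = 0,
                                   include_pseudosecular = include_pseudosecular)
  ns <- ham$nspins
  Sx <- spin_operator("x", 1L, ns)
  Vh <- Conj(t(ham$V))
  Ot <- Vh %*% Sx %*% ham$V
  rt0 <- -Ot
  Pt <- Vh %*% .pulse_matrix("x", pi, ns) %*% ham$V
  PtH <- Conj(t(Pt))
  raw <- vapply(spec$times, function(T) {
    ph <- exp(-1i * ham$lambda * T / 2)
    r1 <- (ph %o% Conj(ph)) * rt0
    r2 <- Pt %*% r1 %*% PtH
    r3 <- (ph %o% Conj(ph)) * r2
    .trAB(r3, Ot)
  }, complex(1))
  r0 <- .trAB(Pt %*% rt0 %*% PtH, Ot)   # T = 0 reference
  .check_real(raw / r0, "hahn_echo_trace")
  .new_cluster_trace(spec$times, Re(raw / r0), Re(r0), "bare")
}

.check_real <- function(z, where) {
  if (max(abs(Im(z))) > 1e-7)
    warning(sprintf("%s: imaginary residue %.2e in echo signal", where,
                    max(abs(Im(z)))))
}

#' Dressed-spin primary echo trace of one cluster
#'
#' Starting from the spin-locked state -Sx, evolves for the settle delay
#' under the full Hamiltonian (drive included), applies the PM echo
#' sequence pi/2 - T/2 - pi - T/2 - pi/2, and returns the expectation value
#' of Sx normalized to its value at the smallest T (set `normalize = FALSE`
#' to obtain raw amplitudes, used for offset averaging).
#'
#' @inheritParams hahn_echo_trace
#' @param normalize Normalize to the value at the smallest T?
#' @return A `cluster_trace`. In a raw (unnormalized) trace, `values` holds
#'   `<Sx>` scaled such that full locking of -Sx gives -1.
#' @export
dressed_echo_trace <- function(couplings, spec, cluster = couplings$ids,
                               include_pseudosecular = TRUE,
                               normalize = TRUE) {
  stopifnot(inherits(spec, "sequence_spec"), spec$mode == "dressed")
  if (is.null(couplings)) { couplings <- .empty_couplings(); cluster <- integer(0) }
  Amax <- if (length(cluster)) max(abs(couplings$A[match(cluster, couplings$ids)])) else 0
  if (Amax > spec$w1 / 5)
    warning("w1 is not much larger than the largest |A|; dressed-spin picture is marginal")
  ham <- build_cluster_hamiltonian(couplings, cluster, OmegaS = spec$OmegaS,
                                   w1 = spec$w1,
                                   include_pseudosecular = include_pseudosecular)
  ns <- ham$nspins
  d <- 2^ns
  Sx <- spin_operator("x", 1L, ns)
  Vh <- Conj(t(ham$V))
  Ot <- Vh %*% Sx %*% ham$V
  rt0 <- -Ot
  raw <- if (spec$pm_model == "ideal") {
    P90 <- Vh %*% .pulse_matrix("z", pi / 2, ns) %*% ham$V
    P180 <- Vh %*% .pulse_matrix("z", pi, ns) %*% ham$V
    phs <- exp(-1i * ham$lambda * spec$settle_delay)
    r1 <- P90 %*% ((phs %o% Conj(phs)) * rt0) %*% Conj(t(P90))
    Ofin <- Conj(t(P90)) %*% Ot %*% P90
    P180H <- Conj(t(P180))
    vapply(spec$times, function(T) {
      ph <- exp(-1i * ham$lambda * T / 2)
      r2 <- (ph %o% Conj(ph)) * r1
      r3 <- P180 %*% r2 %*% P180H
      r4 <- (ph %o% Conj(ph)) * r3
      .trAB(r4, Ofin)
    }, complex(1))
  } else {
    .dressed_explicit_raw(ham, couplings, cluster, spec, rt0, Ot)
  }
  .check_real(raw * 4 / d, "dressed_echo_trace")
  raw <- Re(raw) * 4 / d   # scale: full lock of -Sx -> -1
  if (normalize) .new_cluster_trace(spec$times, raw / raw[1], raw[1], "dressed")
  else .new_cluster_trace(spec$times, raw, NA_real_, "dressed")
}

# explicit cosine phase modulation: propagate the time-dependent drive
# w1 (cos(phi) Sx + sin(phi) Sy), phi(t) = a_PM cos(2 pi w1 t), in steps
# no longer than 1/(20 w1). Pulse lengths follow the first-harmonic
# (Bessel J1) dressed nutation frequency w1 J1(a_PM).
.dressed_explicit_raw <- function(ham, couplings, cluster, spec, rt0, Ot) {
  ns <- ham$nspins
  # static part without the drive
  ham0 <- build_cluster_hamiltonian(couplings, cluster, OmegaS = spec$OmegaS,
                                    w1 = 0, include_pseudosecular = TRUE)
  H0 <- ham0$H
  Sx <- spin_operator("x", 1L, ns)
  Sy <- spin_operator("y", 1L, ns)
  w1r <- .MHz(spec$w1)
  a <- spec$pm_amplitude
  f_nut <- spec$w1 * besselJ(a, 1)           # MHz
  t_pi <- 1 / (2 * f_nut)                    # us
  dt <- 1 / (20 * spec$w1)                   # us
  pulse_U <- function(t_start, t_len) {
    nstep <- max(1L, ceiling(t_len / dt))
    h <- t_len / nstep
    U <- diag(2^ns) + 0i
    for (k in seq_len(nstep)) {
      tm <- t_start + (k - 0.5) * h
      phi <- a * cos(.MHz(spec$w1) * tm)
      Hk <- H0 + w1r * (cos(phi) * Sx + sin(phi) * Sy)
      e <- eigen(Hk, symmetric = TRUE)
      U <- e$vectors %*% ((exp(-1i * e$values * h) %o% rep(1, 2^ns)) *
                            Conj(t(e$vectors))) %*% U
    }
    U
  }
  Vh <- Conj(t(ham$V))
  vapply(spec$times, function(T) {
    t0 <- spec$settle_delay
    U1 <- Vh %*% pulse_U(t0, t_pi / 2) %*% ham$V
    t1 <- t0 + t_pi / 2 + T / 2
    U2 <- Vh %*% pulse_U(t1, t_pi) %*% ham$V
    t2 <- t1 + t_pi + T / 2
    U3 <- Vh %*% pulse_U(t2, t_pi / 2) %*% ham$V
    phs <- exp(-1i * ham$lambda * spec$settle_delay)
    ph <- exp(-1i * ham$lambda * T / 2)
    r <- (phs %o% Conj(phs)) * rt0
    r <- U1 %*% r %*% Conj(t(U1))
    r <- (ph %o% Conj(ph)) * r
    r <- U2 %*% r %*% Conj(t(U2))
    r <- (ph %o% Conj(ph)) * r
    r <- U3 %*% r %*% Conj(t(U3))
    .trAB(r, Ot)
  }, complex(1))
}

#' Empty-bath reference signal
#'
#' The echo signal of the electron spin without a nuclear bath. In bare
#' mode this is identically 1. In dressed mode it is the dressed echo of
#' the driven two-level system averaged over the resonance-offset
#' distribution (Gauss-Hermite quadrature over a Gaussian of width
#' `offset_sigma`, or explicit `offset_samples`), capturing the
#' time-dependent loss of magnetization from the incomplete spin lock.
#'
#' @param spec A [sequence_spec()].
#' @param offset_sigma Gaussian offset width, MHz (ignored in bare mode).
#' @param offset_samples Optional explicit offsets, MHz. Equal weights.
#' @param n_nodes Number of Gauss-Hermite nodes when sampling the Gaussian.
#' @return A `cluster_trace`, normalized at the smallest T.
#' @export
w_empty <- function(spec, offset_sigma = 0, offset_samples = NULL,
                    n_nodes = 15L) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (spec$mode == "bare")
    return(.new_cluster_trace(spec$times, rep(1, length(spec$times)), 1,
                              "bare"))
  if (is.null(offset_samples)) {
    if (offset_sigma > 0) {
      gh <- pracma::gaussHermite(as.integer(n_nodes))
      offs <- spec$OmegaS + sqrt(2) * offset_sigma * gh$x
      wts <- gh$w / sqrt(pi)
    } else {
      offs <- spec$OmegaS
      wts <- 1
    }
  } else {
    offs <- as.numeric(offset_samples)
    wts <- rep(1 / length(offs), length(offs))
  }
  acc <- numeric(length(spec$times))
  for (i in seq_along(offs)) {
    sp <- spec
    sp$OmegaS <- offs[i]
    tr <- dressed_echo_trace(NULL, sp, integer(0), normalize = FALSE)
    acc <- acc + wts[i] * tr$values
  }
  .new_cluster_trace(spec$times, acc / acc[1], acc[1], "dressed")
}
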