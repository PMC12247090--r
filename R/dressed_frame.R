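# Analytical dressed-spin quantities: the hyperfine field of a nuclear
# spin configuration, the tilt angle of the effective field, the residual
# (decoupled) hyperfine splitting, and the slow (spin-locked) fraction of
# magnetization.

#' Hyperfine field of a nuclear spin configuration
#'
#' `dw_hfi = sum_n A_n m_n` for magnetic quantum numbers m_n = +-1/2.
#'
#' @param config Numeric vector of magnetic quantum numbers (+0.5 / -0.5).
#' @param A Secular hyperfine couplings, MHz, same length.
#' @return Hyperfine field, MHz.
#' @export
hyperfine_field <- function(config, A) {
  config <- as.numeric(config)
  A <- as.numeric(A)
  if (length(config) != length(A))
    stop("config and A must have the same length")
  if (length(config) && !all(abs(abs(config) - 0.5) < 1e-12))
    stop("magnetic quantum numbers must be +1/2 or -1/2")
  sum(A * config)
}

#' Tilt angle of the effective field in the dressed frame
#'
#' `theta_c = arctan(-w1 / (OmegaS + dw_hfi))`, with the branch chosen so
#' that theta lies in (0, 180) degrees and passes continuously through 90
#' degrees as the denominator crosses zero (two-argument arctangent of
#' (w1, OmegaS + dw_hfi)).
#'
#' @param OmegaS Resonance offset, MHz.
#' @param dw_hfi Hyperfine field, MHz.
#' @param w1 Drive amplitude, MHz, >= 0.
#' @return Tilt angle in degrees. Vectorized.
#' @export
#' @examples
#' 90 - tilt_angle(0, 10, 100)  # about 5.71 degrees
tilt_angle <- function(OmegaS, dw_hfi, w1) {
  den <- OmegaS + dw_hfi
  if (any(w1 == 0 & den == 0))
    stop("tilt angle undefined: both w1 and OmegaS + dw_hfi are zero")
  atan2(w1, den) * 180 / pi
}

#' Residual hyperfine splitting under microwave irradiation
#'
#' `A_eff = sqrt((OmegaS + dw)^2 + w1^2) - sqrt((OmegaS - dw)^2 + w1^2)`,
#' the splitting of the two electron-spin transitions of the four-level
#' system formed by a configuration and its complement. It vanishes for
#' on-resonant irradiation (complete hyperfine decoupling) and reduces to
#' `2 dw` in the limit `w1 = 0`, `OmegaS > dw > 0`.
#'
#' @inheritParams tilt_angle
#' @return Effective splitting, MHz. Vectorized.
#' @export
effective_splitting <- function(OmegaS, dw_hfi, w1) {
  sqrt((OmegaS + dw_hfi)^2 + w1^2) - sqrt((OmegaS - dw_hfi)^2 + w1^2)
}

#' Slow (spin-locked) fraction of electron magnetization
#'
#' `f_slow = sum_c sin(theta_c) / 2^N` over all nuclear spin
#' configurations; the complement symmetry of the configurations makes the
#' result invariant under flipping the signs of all couplings. For N up to
#' `max_exact` protons the sum is exact; beyond that, configurations are
#' Monte-Carlo sampled (requires `n_sample` and a seed set by the caller).
#'
#' @param A Secular hyperfine couplings, MHz.
#' @param OmegaS Resonance offset, MHz.
#' @param w1 Drive amplitude, MHz, > 0.
#' @param max_exact Largest N for exact enumeration (default 20).
#' @param n_sample Number of sampled configurations when N > max_exact.
#' @return The locked fraction, in (0, 1].
#' @export
#' @examples
#' 1 - slow_fraction(10, 0, 100)  # about 0.005
slow_fraction <- function(A, OmegaS = 0, w1 = 100, max_exact = 20L,
                          n_sample = NULL) {
  A <- as.numeric(A)
  N <- length(A)
  if (N == 0) return(sin(tilt_angle(OmegaS, 0, w1) * pi / 180))
  if (N <= max_exact) {
    # iteratively build all 2^N sums of +-A/2
    dw <- 0
    for (a in A) dw <- c(dw + a / 2, dw - a / 2)
  } else {
    if (is.null(n_sample))
      stop(sprintf("N = %d exceeds max_exact = %d; set n_sample for %s",
                   N, max_exact, "Monte-Carlo sampling"))
    m <- matrix(sample(c(-0.5, 0.5), N * n_sample, replace = TRUE),
                nrow = n_sample)
    dw <- drop(m %*% A)
  }
  mean(sin(tilt_angle(OmegaS, dw, w1) * pi / 180))
}
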