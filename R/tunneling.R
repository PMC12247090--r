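# Methyl-tunnel physics: the exchange-coupling substitution that folds the
# tunnel splitting into the nuclear pair couplings, and a hindered-rotor
# solver that converts a threefold rotation barrier into a tunnel splitting.

#' Combine dipolar and tunnel couplings for a proton pair
#'
#' For two protons of the same methyl group the tunnel splitting enters the
#' pair Hamiltonian as an exchange coupling, shifting the longitudinal
#' coupling to `wdd - 2 wt / 3` and the flip-flop coefficient to
#' `wdd + 4 wt / 3`; pairs in different groups keep the bare dipolar value.
#'
#' @param wdd_kHz Dipolar coupling(s), kHz. Vectorized (also over matrices).
#' @param wtunnel_kHz Tunnel splitting(s), kHz, >= 0.
#' @param same_methyl Logical: pair within one methyl group?
#' @return List with elements `wzz` and `wnn`, kHz, same shape as `wdd_kHz`.
#' @export
#' @examples
#' combine_couplings(10, 60, TRUE)   # wzz = -30, wnn = 90
#' combine_couplings(10, 60, FALSE)  # both 10
combine_couplings <- function(wdd_kHz, wtunnel_kHz, same_methyl) {
  if (any(wtunnel_kHz < 0)) stop("tunnel splitting must be non-negative")
  wt <- ifelse(same_methyl, wtunnel_kHz, 0)
  list(wzz = wdd_kHz - 2 * wt / 3, wnn = wdd_kHz + 4 * wt / 3)
}

#' Hindered methyl rotor model
#'
#' One-dimensional torsional Hamiltonian `H = -B d^2/dphi^2 +
#' V3 [cos(3 phi) + 1] / 2`. The fit phase of a barrier scan only shifts
#' the origin of phi and does not affect the splitting; the solver uses
#' phase zero.
#'
#' @param V3_kJmol Barrier height V3, kJ/mol, >= 0.
#' @param B_GHz Rotational constant, GHz; default from the standard methyl
#'   geometry (C-H 1.09 A, tetrahedral angles), about 158 GHz.
#' @param phi0_deg Phase of the barrier fit function, degrees (metadata).
#' @return Object of class `rotor_model`.
#' @export
rotor_model <- function(V3_kJmol, B_GHz = spindec_constants()$B_CH3_GHz,
                        phi0_deg = 0) {
  if (!is.finite(V3_kJmol) || V3_kJmol < 0) stop("V3 must be >= 0 (kJ/mol)")
  if (!is.finite(B_GHz) || B_GHz <= 0) stop("B must be > 0 (GHz)")
  structure(list(V3_kJmol = V3_kJmol, B_GHz = B_GHz, phi0_deg = phi0_deg),
            class = "rotor_model")
}

#' Ground-state tunnel splitting of a hindered methyl rotor
#'
#' Diagonalizes the torsional Hamiltonian in a free-rotor (plane-wave)
#' basis, partitioned by the threefold symmetry into the A block
#' (m = 0 mod 3) and an E block (m = 1 mod 3), and returns the A-E
#' splitting of the torsional ground state. The basis is grown until the
#' splitting changes by less than `tol` (relative) upon doubling.
#'
#' Because the splitting is a difference of two eigenvalues that are many
#' orders of magnitude larger than the splitting itself, convergence is
#' accepted when the change on doubling falls below either the relative
#' tolerance or the floating-point noise floor of the eigenvalue scale.
#'
#' @param model A [rotor_model()], or a barrier in kJ/mol.
#' @param tol Relative convergence tolerance on basis doubling.
#' @param mmax0 Initial plane-wave cutoff |m| of the basis.
#' @return Tunnel splitting in kHz (ordinary frequency). In the free-rotor
#'   limit V3 = 0 this is the rotational constant B.
#' @export
#' @examples
#' tunnel_splitting(rotor_model(15.8))  # tens of kHz
tunnel_splitting <- function(model, tol = 1e-6, mmax0 = 30L) {
  if (is.numeric(model)) model <- rotor_model(model)
  stopifnot(inherits(model, "rotor_model"))
  V3 <- model$V3_kJmol * .const$kJmol_to_GHz   # GHz
  B <- model$B_GHz
  block_min <- function(offset, mmax) {
    m <- seq(-mmax, mmax, by = 3) + offset
    nb <- length(m)
    H <- diag(B * m^2 + V3 / 2, nb)
    if (nb > 1) {
      i <- seq_len(nb - 1)
      H[cbind(i, i + 1)] <- V3 / 4
      H[cbind(i + 1, i)] <- V3 / 4
    }
    min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  }
  splitting <- function(mmax)
    (block_min(1L, mmax) - block_min(0L, mmax)) * 1e6  # GHz -> kHz
  mmax <- as.integer(mmax0)
  prev <- splitting(mmax)
  for (it in 1:8) {
    mmax <- 2L * mmax
    cur <- splitting(mmax)
    # eigenvalue noise floor: machine epsilon times the spectral scale of
    # the basis (GHz), expressed in kHz
    floor_kHz <- 64 * .Machine$double.eps * (B * mmax^2 + V3) * 1e6
    if (abs(cur - prev) <= max(tol * abs(cur), floor_kHz))
      return(cur)
    prev <- cur
  }
  stop(sprintf("tunnel splitting not converged at basis cutoff |m| <= %d",
               mmax))
}
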