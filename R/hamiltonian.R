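# Cluster Hamiltonians and density-operator propagation. Spin operators are
# built by Kronecker products with the electron first, each spin ordered
# |alpha>, |beta>. Propagation goes through the eigendecomposition of the
# (Hermitian) Hamiltonian, which is cached so that whole pulse sequences can
# be evaluated in the eigenbasis.

.sop <- list(
  x = matrix(c(0, 0.5, 0.5, 0), 2, 2),
  y = matrix(c(0, 0.5i, -0.5i, 0), 2, 2),
  z = diag(c(0.5, -0.5)),
  p = matrix(c(0, 0, 1, 0), 2, 2),   # |a><b| raising, S+ = Sx + i Sy
  m = matrix(c(0, 1, 0, 0), 2, 2),
  id = diag(2)
)

#' Single-spin operator embedded in a cluster product space
#'
#' @param which One of "x", "y", "z", "p" (raising), "m" (lowering), "id".
#' @param pos Position of the spin: 1 is the electron, 2..(c+1) the protons.
#' @param nspins Total number of spins (electron plus cluster protons).
#' @return Complex matrix of dimension `2^nspins`.
#' @export
spin_operator <- function(which, pos, nspins) {
  which <- match.arg(which, c("x", "y", "z", "p", "m", "id"))
  stopifnot(pos >= 1, pos <= nspins)
  out <- if (pos == 1L) .sop[[which]] else diag(2^(pos - 1))
  if (pos > 1L) out <- kronecker(out, .sop[[which]])
  if (pos < nspins) out <- kronecker(out, diag(2^(nspins - pos)))
  out + 0i
}

#' Build the Hamiltonian of an electron-proton cluster
#'
#' Assembles, in rad/us,
#' `H = OmegaS Sz + sum_n An Sz Inz (+ Bnx Sz Inx + Bny Sz Iny)
#'  + sum_kl wzz Ikz Ilz - sum_kl (wnn/4)(Ik+ Il- + Ik- Il+) + w1 Sx`
#' for the protons selected by `cluster`. The nuclear Zeeman term is
#' omitted: it commutes with every other term and with the initial states
#' used here. The empty cluster gives the driven two-level electron.
#'
#' @param couplings A `coupling_set` from [couplings_for_orientation()].
#' @param cluster Integer vector of proton ids (subset of `couplings$ids`);
#'   may be empty.
#' @param OmegaS Electron resonance offset, MHz.
#' @param w1 Microwave field amplitude, MHz (0 for bare-spin sequences).
#' @param include_pseudosecular Include the `Sz Inx`, `Sz Iny` terms?
#' @return Object of class `cluster_hamiltonian`: list with the matrix `H`
#'   (rad/us), eigenvalues `lambda`, eigenvectors `V`, and `nspins`.
#' @export
build_cluster_hamiltonian <- function(couplings, cluster = couplings$ids,
                                      OmegaS = 0, w1 = 0,
                                      include_pseudosecular = TRUE) {
  stopifnot(inherits(couplings, "coupling_set"))
  cluster <- as.integer(cluster)
  ii <- match(cluster, couplings$ids)
  if (anyNA(ii)) stop("cluster references unknown proton ids")
  c_sz <- length(ii)
  ns <- c_sz + 1L
  d <- 2^ns
  H <- matrix(0i, d, d)
  Sz <- spin_operator("z", 1L, ns)
  if (OmegaS != 0) H <- H + .MHz(OmegaS) * Sz
  if (w1 != 0) H <- H + .MHz(w1) * spin_operator("x", 1L, ns)
  for (a in seq_len(c_sz)) {
    k <- ii[a]
    H <- H + .MHz(couplings$A[k]) * Sz %*% spin_operator("z", a + 1L, ns)
    if (include_pseudosecular) {
      if (couplings$Bx[k] != 0)
        H <- H + .MHz(couplings$Bx[k]) * Sz %*% spin_operator("x", a + 1L, ns)
      if (couplings$By[k] != 0)
        H <- H + .MHz(couplings$By[k]) * Sz %*% spin_operator("y", a + 1L, ns)
    }
  }
  if (c_sz > 1) {
    for (a in seq_len(c_sz - 1)) for (b in (a + 1):c_sz) {
      k <- ii[a]; l <- ii[b]
      wzz <- .kHz(couplings$wzz[k, l])
      wnn <- .kHz(couplings$wnn[k, l])
      if (wzz != 0)
        H <- H + wzz * spin_operator("z", a + 1L, ns) %*%
          spin_operator("z", b + 1L, ns)
      if (wnn != 0) {
        ff <- spin_operator("p", a + 1L, ns) %*% spin_operator("m", b + 1L, ns)
        H <- H - wnn / 4 * (ff + Conj(t(ff)))
      }
    }
  }
  if (max(abs(H - Conj(t(H)))) > 1e-10 * max(1, max(abs(H))))
    stop("assembled Hamiltonian is not Hermitian")
  e <- eigen((H + Conj(t(H))) / 2, symmetric = TRUE)
  structure(list(H = H, lambda = e$values, V = e$vectors, nspins = ns),
            class = "cluster_hamiltonian")
}

#' @export
print.cluster_hamiltonian <- function(x, ...) {
  cat(sprintf("<cluster_hamiltonian> %d spins, dimension %d\n",
              x$nspins, 2^x$nspins))
  invisible(x)
}

#' Propagate a density operator under a cluster Hamiltonian
#'
#' Computes `rho(t) = U rho0 U'` with `U = V exp(-i Lambda t) V'` from the
#' cached eigendecomposition, which is numerically stabler than generic
#' matrix-exponential algorithms for the long evolution times needed here.
#'
#' @param H A `cluster_hamiltonian`.
#' @param rho0 Density operator (or any Hermitian operator) matching `H`.
#' @param t Evolution time, us.
#' @return The propagated operator.
#' @export
propagate <- function(H, rho0, t) {
  stopifnot(inherits(H, "cluster_hamiltonian"))
  rho0 <- as.matrix(rho0)
  if (max(abs(rho0 - Conj(t(rho0)))) > 1e-8 * max(1, max(abs(rho0))))
    stop("rho0 must be Hermitian")
  ph <- exp(-1i * H$lambda * t)
  rt <- Conj(t(H$V)) %*% rho0 %*% H$V
  rt <- (ph %o% Conj(ph)) * rt
  H$V %*% rt %*% Conj(t(H$V))
}

#' Ideal instantaneous pulse on the electron spin
#'
#' Applies `rho' = exp(-i angle S_axis) rho exp(+i angle S_axis)` with the
#' rotation acting on the electron only.
#'
#' @param rho Density operator of the cluster (electron first).
#' @param axis One of "x", "y", "z".
#' @param angle Flip angle, rad.
#' @return The rotated operator.
#' @export
ideal_pulse <- function(rho, axis = c("x", "y", "z"), angle = pi) {
  axis <- match.arg(axis)
  rho <- as.matrix(rho)
  d <- nrow(rho)
  ns <- as.integer(round(log2(d)))
  if (2^ns != d) stop("operator dimension must be a power of 2")
  U <- .pulse_matrix(axis, angle, ns)
  U %*% rho %*% Conj(t(U))
}

# electron rotation exp(-i angle S_axis) on a 2^ns space
.pulse_matrix <- function(axis, angle, ns) {
  u2 <- switch(axis,
    x = {
      c <- cos(angle / 2); s <- sin(angle / 2)
      matrix(c(c, -1i * s, -1i * s, c), 2, 2)
    },
    y = {
      c <- cos(angle / 2); s <- sin(angle / 2)
      matrix(c(c, s, -s, c), 2, 2)
    },
    z = diag(exp(-1i * angle * c(0.5, -0.5))))
  kronecker(u2, diag(2^(ns - 1)) + 0i)
}
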