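# Independent oracles and fixture builders used across the suite.

# Complex matrix exponential through the real 2n x 2n embedding
# [[Re, -Im], [Im, Re]] and Matrix::expm -- independent of the package's
# eigendecomposition propagator.
expm_complex_oracle <- function(M) {
  n <- nrow(M)
  R <- rbind(cbind(Re(M), -Im(M)), cbind(Im(M), Re(M)))
  E <- as.matrix(Matrix::expm(Matrix::Matrix(R)))
  E[seq_len(n), seq_len(n)] + 1i * E[seq_len(n) + n, seq_len(n)]
}

# Finite-difference Bloch-wave solver for the hindered-rotor torsional
# Schroedinger equation on the reduced cell [0, 2*pi/3): independent of
# the plane-wave implementation. Returns the A-E splitting in kHz.
tunnel_fd_oracle <- function(V3_kJmol, B_GHz = spindec_constants()$B_CH3_GHz,
                             n = 600) {
  V3 <- V3_kJmol * spindec_constants()$kJmol_to_GHz
  L <- 2 * pi / 3
  h <- L / n
  phi <- (0:(n - 1)) * h
  V <- V3 / 2 * (cos(3 * phi) + 1)
  block_min <- function(kappa) {
    H <- matrix(0 + 0i, n, n)
    diag(H) <- 2 * B_GHz / h^2 + V
    for (i in 1:(n - 1)) {
      H[i, i + 1] <- -B_GHz / h^2
      H[i + 1, i] <- -B_GHz / h^2
    }
    H[1, n] <- -B_GHz / h^2 * exp(-1i * kappa)
    H[n, 1] <- -B_GHz / h^2 * exp(1i * kappa)
    min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  }
  (block_min(2 * pi / 3) - block_min(0)) * 1e6
}

# Analytical two-proton Hahn echo modulation (written out directly from
# the pair formula, in MHz / kHz / us units).
eq_pair_oracle <- function(A1, A2, wnn_kHz, times) {
  dA <- A1 - A2
  wnn <- wnn_kHz / 1e3
  lam <- if (dA^2 + wnn^2 == 0) 0 else
    dA^2 * wnn^2 / (dA^2 + wnn^2)^2
  w <- 2 * pi * 0.5 * sqrt(dA^2 + wnn^2)
  1 - 1.5 * lam - 0.5 * lam * cos(w * times) + 2 * lam * cos(w * times / 2)
}

# A random spin system with isotropic hyperfine tensors (so that the
# pseudo-secular components vanish at every orientation) and optionally a
# methyl group over the first three protons.
make_secular_system <- function(n, seed, a_range = c(-3, 3),
                                with_methyl = FALSE, tunnel_kHz = 54.5) {
  set.seed(seed)
  pos <- matrix(stats::rnorm(3 * n, sd = 2.5), n, 3)
  pos <- pos + sign(pos) * 1.0  # keep protons apart
  protons <- lapply(seq_len(n), function(i) {
    a <- stats::runif(1, a_range[1], a_range[2])
    proton(i, pos[i, ], hyperfine_tensor(diag(rep(a, 3))))
  })
  methyls <- if (with_methyl && n >= 3)
    list(methyl_group(1:3, tunnel_kHz)) else list()
  spin_system(protons, methyls)
}

# Standard single-methyl fixture used in many tests.
methyl_system <- function(dist = 4.2, tunnel_kHz = 54.5) {
  frag <- make_methyl(c(0, 0, dist), c(0, 0, 1), tunnel_kHz = tunnel_kHz)
  spin_system(frag$protons, list(frag$methyl))
}

# Two separated two-proton clusters (weak but nonzero inter-cluster
# couplings unless far = TRUE).
two_pair_system <- function(far = FALSE) {
  gap <- if (far) 1e3 else 6
  p <- list(
    proton(1L, c(0, 0, 4.0), point_dipole_tensor(c(0, 0, 4.0))),
    proton(2L, c(1.5, 0, 4.3), point_dipole_tensor(c(1.5, 0, 4.3))),
    proton(3L, c(gap, 0.5, 4.1), hyperfine_tensor(diag(rep(0.8, 3)))),
    proton(4L, c(gap + 1.4, 0, 4.4), hyperfine_tensor(diag(rep(-0.5, 3)))))
  spin_system(p)
}
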