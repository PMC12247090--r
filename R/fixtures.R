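# Synthetic spin-system generators: single methyl groups, trityl-like
# rings of methyl groups around the electron, and random proton baths,
# all with point-dipole hyperfine tensors. These stand in for structures
# and tensors that would otherwise come from electronic-structure
# calculations.

# orthonormal pair perpendicular to unit vector n
.perp_basis <- function(n) {
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Point-dipole hyperfine tensor
#'
#' `T = d_eH (3 n n' - 1) / r^3` for the electron-to-proton vector
#' `r_vec`; traceless and axial with eigenvalues in ratio (2, -1, -1).
#' The point-dipole picture breaks down close to the electron, so
#' distances below 2 angstrom are rejected.
#'
#' @param r_vec Electron-to-proton vector, angstrom, |r_vec| >= 2.
#' @return A [hyperfine_tensor()], MHz.
#' @export
point_dipole_tensor <- function(r_vec) {
  r_vec <- as.numeric(r_vec)
  r <- sqrt(sum(r_vec^2))
  if (!is.finite(r) || r < 2)
    stop("proton closer than 2 angstrom to the electron: point-dipole invalid")
  n <- r_vec / r
  hyperfine_tensor(.const$d_eH_MHz_A3 * (3 * (n %o% n) - diag(3)) / r^3)
}

#' Build a methyl-group fragment
#'
#' Places three protons around `center` (the methyl carbon) with C-H bond
#' length `r_CH`, tetrahedral H-C-axis angles and 120 degree spacing about
#' `axis`, and registers them as one methyl group with the given tunnel
#' splitting. Hyperfine tensors are point-dipole with respect to
#' `electron_position`.
#'
#' @param center Carbon position, angstrom.
#' @param axis Methyl symmetry axis (direction from carbon towards the
#'   rest of the molecule); need not be normalized.
#' @param r_CH C-H bond length, angstrom, in `[0.9, 1.3]`.
#' @param tunnel_kHz Tunnel splitting, kHz.
#' @param first_id Id assigned to the first proton (then consecutive).
#' @param electron_position Electron position for the point-dipole tensors.
#' @param phase_deg Rotation of the three protons about the axis, degrees.
#' @return List with `protons` (list of 3) and `methyl` (a
#'   [methyl_group()]), ready to assemble into a [spin_system()].
#' @export
make_methyl <- function(center, axis, r_CH = 1.09, tunnel_kHz = 0,
                        first_id = 1L, electron_position = c(0, 0, 0),
                        phase_deg = 0) {
  center <- as.numeric(center)
  axis <- as.numeric(axis)
  an <- sqrt(sum(axis^2))
  if (!is.finite(an) || an < 1e-12) stop("degenerate methyl axis")
  if (r_CH < 0.9 || r_CH > 1.3) stop("r_CH outside [0.9, 1.3] angstrom")
  n <- axis / an
  pb <- .perp_basis(n)
  ang <- acos(-1 / 3)          # tetrahedral H-C-axis angle, 109.47 deg
  protons <- vector("list", 3)
  for (i in 1:3) {
    ph <- (phase_deg + 120 * (i - 1)) * pi / 180
    dir <- cos(ang) * n + sin(ang) * (cos(ph) * pb$e1 + sin(ph) * pb$e2)
    pos <- center + r_CH * dir
    protons[[i]] <- proton(first_id + i - 1L, pos,
                           point_dipole_tensor(pos - electron_position))
  }
  list(protons = protons,
       methyl = methyl_group(first_id + 0:2, tunnel_kHz))
}

#' Trityl-like ring of methyl groups
#'
#' Places an even number of methyl groups symmetrically on a ring around
#' the electron at the origin, with radially outward axes and tunnel
#' splittings alternating between an inner and an outer value (emulating
#' the two methyl classes of a Finland-trityl core, where geminal pairs
#' sit above and below the aryl plane); alternating groups are displaced
#' by `+-z_split` out of the ring plane, which also keeps neighbouring
#' fragments from clashing. Hyperfine tensors are point-dipole. Optional
#' angular jitter (reproducible from `seed`) desymmetrizes the ring.
#'
#' @param n_methyls Even number of methyl groups (12 gives 36 protons).
#' @param ring_radius In-plane distance of the methyl carbons from the
#'   electron, angstrom.
#' @param tunnel_inner_kHz,tunnel_outer_kHz Alternating tunnel splittings.
#' @param seed Integer seed for the jitter (mandatory if `jitter_deg` > 0).
#' @param jitter_deg Standard deviation of the angular jitter, degrees.
#' @param z_split Out-of-plane displacement of alternating groups, A.
#' @param offset_sigma Offset width passed to [spin_system()], MHz.
#' @return A [spin_system()].
#' @export
#' @examples
#' sys <- make_trityl_like(12, 4.4, 4.8, 54.5, seed = 1)
#' length(sys$protons)  # 36
make_trityl_like <- function(n_methyls = 12L, ring_radius = 4.4,
                             tunnel_inner_kHz = 4.8,
                             tunnel_outer_kHz = 54.5, seed = 1L,
                             jitter_deg = 0, z_split = 1.8,
                             offset_sigma = 12 / (2 * sqrt(2 * log(2)))) {
  n_methyls <- as.integer(n_methyls)
  if (n_methyls < 2L || n_methyls %% 2L != 0L)
    stop("n_methyls must be an even integer >= 2")
  jit <- rep(0, n_methyls)
  if (jitter_deg > 0) {
    if (is.null(seed)) stop("seed is mandatory when jitter_deg > 0")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    jit <- stats::rnorm(n_methyls, 0, jitter_deg)
  }
  protons <- list()
  methyls <- list()
  for (i in seq_len(n_methyls)) {
    th <- 2 * pi * (i - 1) / n_methyls + jit[i] * pi / 180
    zc <- if (i %% 2L == 1L) z_split else -z_split
    center <- c(ring_radius * cos(th), ring_radius * sin(th), zc)
    tun <- if (i %% 2L == 1L) tunnel_inner_kHz else tunnel_outer_kHz
    frag <- make_methyl(center, axis = center, tunnel_kHz = tun,
                        first_id = 3L * (i - 1L) + 1L,
                        electron_position = c(0, 0, 0))
    protons <- c(protons, frag$protons)
    methyls <- c(methyls, list(frag$methyl))
  }
  # guard against overlapping fragments
  pos <- t(vapply(protons, function(p) p$position, numeric(3)))
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  if (min(dm) < 0.6) stop("overlapping methyl fragments; increase ring_radius")
  spin_system(protons, methyls, offset_sigma = offset_sigma)
}

#' Random proton bath
#'
#' Protons placed uniformly in a spherical shell around the electron,
#' with point-dipole hyperfine tensors; reproducible from `seed`.
#'
#' @param n Number of protons.
#' @param r_min,r_max Shell radii, angstrom (r_min >= 2).
#' @param seed Integer seed (mandatory).
#' @param min_dist Minimum proton-proton distance, angstrom.
#' @param offset_sigma Offset width passed to [spin_system()], MHz.
#' @return A [spin_system()] without methyl groups.
#' @export
make_random_bath <- function(n, r_min = 3, r_max = 8, seed,
                             min_dist = 1.5,
                             offset_sigma = 12 / (2 * sqrt(2 * log(2)))) {
  if (missing(seed)) stop("seed is mandatory for random baths")
  if (r_min < 2) stop("r_min must be >= 2 angstrom (point-dipole validity)")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 10000L * n) stop("could not place protons; relax constraints")
    u <- stats::runif(1)
    r <- (r_min^3 + u * (r_max^3 - r_min^3))^(1 / 3)
    v <- stats::rnorm(3)
    p <- r * v / sqrt(sum(v^2))
    if (placed > 0) {
      d <- sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                           matrix(p, placed, 3, byrow = TRUE))^2))
      if (min(d) < min_dist) next
    }
    placed <- placed + 1L
    pos[placed, ] <- p
  }
  protons <- lapply(seq_len(n), function(i)
    proton(i, pos[i, ], point_dipole_tensor(pos[i, ])))
  spin_system(protons, offset_sigma = offset_sigma)
}

# save/restore the global RNG state so generators do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
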