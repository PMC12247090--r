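# Domain model: protons with hyperfine tensors, methyl groups, and the
# conversion of geometry plus tensors into orientation-dependent couplings.

#' Hyperfine tensor
#'
#' A 3x3 hyperfine interaction tensor in MHz, given in the molecular frame.
#' Only the symmetric part enters orientation projections; an antisymmetric
#' component, if present, is discarded with a warning.
#'
#' @param matrix Numeric 3x3 matrix, MHz.
#' @return Object of class `hyperfine_tensor` (the symmetrized matrix).
#' @export
#' @examples
#' hyperfine_tensor(diag(c(2, 2, 5)))
hyperfine_tensor <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)) || any(!is.finite(m)))
    stop("hyperfine tensor must be a finite numeric 3x3 matrix")
  asym <- (m - t(m)) / 2
  if (max(abs(asym)) > 1e-10 * max(1, max(abs(m)))) {
    warning("antisymmetric hyperfine component discarded")
    m <- (m + t(m)) / 2
  } else {
    m <- (m + t(m)) / 2
  }
  structure(m, class = "hyperfine_tensor")
}

#' Proton bath spin
#'
#' @param id Integer identifier, unique within a spin system.
#' @param position Numeric length-3 position in angstrom (molecular frame).
#' @param tensor A [hyperfine_tensor()], or a 3x3 matrix coerced to one.
#' @return Object of class `proton`.
#' @export
proton <- function(id, position, tensor) {
  id <- as.integer(id)
  position <- as.numeric(position)
  if (length(id) != 1L || is.na(id)) stop("proton id must be a single integer")
  if (length(position) != 3L || any(!is.finite(position)))
    stop("proton position must be a finite 3-vector (angstrom)")
  if (!inherits(tensor, "hyperfine_tensor")) tensor <- hyperfine_tensor(tensor)
  structure(list(id = id, position = position, tensor = tensor),
            class = "proton")
}

#' Methyl group
#'
#' Three protons sharing a rotor, carrying a tunnel splitting that is
#' treated as a pairwise exchange coupling between them.
#'
#' @param proton_ids Integer vector of exactly 3 distinct proton ids.
#' @param tunnel_kHz Tunnel splitting, ordinary frequency in kHz, >= 0.
#' @return Object of class `methyl_group`.
#' @export
methyl_group <- function(proton_ids, tunnel_kHz) {
  proton_ids <- as.integer(proton_ids)
  if (length(proton_ids) != 3L || anyDuplicated(proton_ids))
    stop("a methyl group needs exactly 3 distinct proton ids")
  tunnel_kHz <- as.numeric(tunnel_kHz)
  if (length(tunnel_kHz) != 1L || !is.finite(tunnel_kHz) || tunnel_kHz < 0)
    stop("tunnel_kHz must be a single non-negative number")
  structure(list(proton_ids = proton_ids, tunnel_kHz = tunnel_kHz),
            class = "methyl_group")
}

#' Spin system: central electron spin plus proton bath
#'
#' @param protons List of [proton()] objects (N >= 1).
#' @param methyls List of [methyl_group()] objects; no proton may belong to
#'   two methyl groups.
#' @param electron_position Electron position, angstrom; origin by default.
#' @param offset_sigma Standard deviation of the Gaussian electron
#'   resonance-offset distribution, MHz. Default corresponds to a FWHM of
#'   12 MHz, typical of a trityl radical at Q band.
#' @return Object of class `spin_system`.
#' @export
spin_system <- function(protons, methyls = list(),
                        electron_position = c(0, 0, 0),
                        offset_sigma = 12 / (2 * sqrt(2 * log(2)))) {
  if (inherits(protons, "proton")) protons <- list(protons)
  if (inherits(methyls, "methyl_group")) methyls <- list(methyls)
  if (length(protons) < 1L) stop("a spin system needs at least one proton")
  ids <- vapply(protons, function(p) p$id, integer(1))
  if (anyDuplicated(ids)) stop("proton ids must be unique")
  all_methyl_ids <- unlist(lapply(methyls, function(m) m$proton_ids))
  if (anyDuplicated(all_methyl_ids))
    stop("a proton cannot belong to two methyl groups")
  if (!all(all_methyl_ids %in% ids))
    stop("methyl group references unknown proton ids")
  electron_position <- as.numeric(electron_position)
  if (length(electron_position) != 3L || any(!is.finite(electron_position)))
    stop("electron_position must be a finite 3-vector")
  if (!is.finite(offset_sigma) || offset_sigma < 0)
    stop("offset_sigma must be a non-negative number (MHz)")
  structure(list(protons = protons, methyls = methyls,
                 electron_position = electron_position,
                 offset_sigma = offset_sigma, ids = ids),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf("<spin_system> %d proton(s), %d methyl group(s)\n",
              length(x$protons), length(x$methyls)))
  if (length(x$methyls)) {
    tun <- vapply(x$methyls, function(m) m$tunnel_kHz, numeric(1))
    cat("  tunnel splittings [kHz]:", paste(signif(tun, 4), collapse = ", "),
        "\n")
  }
  cat(sprintf("  offset sigma: %.3g MHz\n", x$offset_sigma))
  invisible(x)
}

#' Field orientation
#'
#' Direction of the static magnetic field in the molecular frame, on the
#' upper hemisphere (inversion symmetry of the Hamiltonian).
#'
#' @param theta Polar angle, degrees, in `[0, 90]`.
#' @param phi Azimuthal angle, degrees, in `[0, 360)`.
#' @param weight Non-negative quadrature weight (default 1).
#' @return Object of class `orientation`.
#' @export
orientation <- function(theta, phi = 0, weight = 1) {
  if (!is.finite(theta) || theta < 0 || theta > 90)
    stop("theta must be in [0, 90] degrees")
  phi <- phi %% 360
  if (!is.finite(weight) || weight < 0) stop("weight must be non-negative")
  structure(list(theta = theta, phi = phi, weight = weight),
            class = "orientation")
}

# unit field direction in the molecular frame
.field_dir <- function(orientation) {
  th <- orientation$theta * pi / 180
  ph <- orientation$phi * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

# lab-frame basis triad (rows e_x, e_y, e_z = field direction), the rotation
# R with ZYZ Euler angles (phi, theta, 0) acting on molecular-frame vectors
.lab_triad <- function(orientation) {
  th <- orientation$theta * pi / 180
  ph <- orientation$phi * pi / 180
  rbind(c(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th)),
        c(-sin(ph), cos(ph), 0),
        c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th)))
}

#' Secular homonuclear dipolar coupling between two protons
#'
#' Point-dipole coupling `d_HH * (1 - 3 cos^2 theta) / r^3` with theta the
#' angle between the inter-proton vector and the field direction and
#' `d_HH = mu0 gammaH^2 hbar / (4 pi)` (about 120.1 kHz A^3 as an ordinary
#' frequency).
#'
#' @param r_vec Inter-proton vector, angstrom; must be longer than 0.5 A.
#' @param field_dir Field direction (any non-zero 3-vector; normalized).
#' @return Coupling in kHz (ordinary frequency, can be negative).
#' @export
#' @examples
#' dipolar_coupling(c(1.78, 0, 0), c(0, 0, 1))  # ~ +21.3 kHz
dipolar_coupling <- function(r_vec, field_dir) {
  r_vec <- as.numeric(r_vec)
  r <- sqrt(sum(r_vec^2))
  if (!is.finite(r) || r <= 0.5)
    stop("inter-proton distance below 0.5 angstrom: coincident protons?")
  n <- as.numeric(field_dir)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("field_dir must be a non-zero vector")
  cth <- sum(r_vec * n) / (r * nn)
  .const$d_HH_kHz_A3 * (1 - 3 * cth^2) / r^3
}

#' Project a hyperfine tensor onto a field orientation
#'
#' Returns the secular coupling `A` and the pseudo-secular components
#' `B_x`, `B_y` in the lab frame whose z axis is the field direction given
#' by `orientation`: `A = z' T z`, `B_x = x' T z`, `B_y = y' T z` with
#' (x, y, z) the lab triad.
#'
#' @param tensor A [hyperfine_tensor()] (or 3x3 matrix).
#' @param orientation An [orientation()].
#' @return Named numeric vector `c(A =, Bx =, By =)`, MHz.
#' @export
project_hyperfine <- function(tensor, orientation) {
  if (!inherits(tensor, "hyperfine_tensor")) tensor <- hyperfine_tensor(tensor)
  R <- .lab_triad(orientation)
  Tz <- unclass(tensor) %*% R[3, ]
  c(A = sum(R[3, ] * Tz), Bx = sum(R[1, ] * Tz), By = sum(R[2, ] * Tz))
}

#' Orientation-dependent coupling set for a spin system
#'
#' Assembles, for one field orientation, the secular and pseudo-secular
#' hyperfine couplings of every proton and the pair coupling matrices:
#' the bare dipolar couplings `wdd`, and the tunnel-substituted `wzz`
#' (`wdd - 2 wt/3`) and flip-flop `wnn` (`wdd + 4 wt/3`) couplings, where
#' the tunnel terms apply only to pairs within the same methyl group.
#'
#' @param system A [spin_system()].
#' @param orientation An [orientation()].
#' @return Object of class `coupling_set` with elements `A`, `Bx`, `By`
#'   (MHz, per proton), `wdd`, `wzz`, `wnn` (kHz, symmetric N x N matrices),
#'   `ids`, and `orientation`.
#' @export
couplings_for_orientation <- function(system, orientation) {
  stopifnot(inherits(system, "spin_system"))
  n <- length(system$protons)
  proj <- vapply(system$protons,
                 function(p) project_hyperfine(p$tensor, orientation),
                 numeric(3))
  fd <- .field_dir(orientation)
  wdd <- matrix(0, n, n)
  if (n > 1) {
    for (k in seq_len(n - 1)) for (l in (k + 1):n) {
      rv <- system$protons[[l]]$position - system$protons[[k]]$position
      wdd[k, l] <- wdd[l, k] <- dipolar_coupling(rv, fd)
    }
  }
  # tunnel substitution per methyl membership
  tun <- matrix(0, n, n)
  for (m in system$methyls) {
    ii <- match(m$proton_ids, system$ids)
    for (a in 1:2) for (b in (a + 1):3)
      tun[ii[a], ii[b]] <- tun[ii[b], ii[a]] <- m$tunnel_kHz
  }
  cc <- combine_couplings(wdd, tun, tun > 0 | .same_methyl_mask(system))
  structure(list(A = proj["A", ], Bx = proj["Bx", ], By = proj["By", ],
                 wdd = wdd, wzz = cc$wzz, wnn = cc$wnn,
                 ids = system$ids, orientation = orientation),
            class = "coupling_set")
}

# logical N x N mask of pairs belonging to the same methyl group
.same_methyl_mask <- function(system) {
  n <- length(system$protons)
  m <- matrix(FALSE, n, n)
  for (g in system$methyls) {
    ii <- match(g$proton_ids, system$ids)
    m[ii, ii] <- TRUE
  }
  diag(m) <- FALSE
  m
}
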