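test_that("dipolar coupling reproduces the point-dipole formula", {
  # independent evaluation of mu0 gammaH^2 hbar / (4 pi r^3) / (2 pi)
  # with CODATA values, at r = 1.78 A perpendicular to the field
  d_ref <- 1e-7 * 2.6752218744e8^2 * 1.054571817e-34 / 1e-30 / (2 * pi) / 1e3
  expect_equal(dipolar_coupling(c(1.78, 0, 0), c(0, 0, 1)),
               d_ref / 1.78^3, tolerance = 1e-10)
  expect_equal(dipolar_coupling(c(1.78, 0, 0), c(0, 0, 1)), 21.3,
               tolerance = 1e-3)
  # magic angle null
  th <- acos(sqrt(1 / 3))
  expect_equal(dipolar_coupling(3 * c(sin(th), 0, cos(th)), c(0, 0, 1)), 0,
               tolerance = 1e-12)
  # r^-3 law
  r1 <- dipolar_coupling(c(2, 0, 1), c(0, 0, 1))
  r2 <- dipolar_coupling(2 * c(2, 0, 1), c(0, 0, 1))
  expect_equal(r1 / r2, 8, tolerance = 1e-12)
  expect_error(dipolar_coupling(c(0.1, 0, 0), c(0, 0, 1)), "coincident")
})

test_that("dipolar coupling averages to zero over the sphere", {
  # Gauss-Legendre quadrature in cos(theta): integral of (1 - 3 x^2)
  gl <- pracma::gaussLegendre(40, -1, 1)
  vals <- vapply(gl$x, function(x) {
    th <- acos(x)
    dipolar_coupling(2.5 * c(sin(th), 0, cos(th)), c(0, 0, 1))
  }, numeric(1))
  avg <- sum(gl$w * vals) / 2
  scale <- max(abs(vals))
  expect_lt(abs(avg) / scale, 1e-3)
})

test_that("hyperfine projection handles isotropic, axial and generic tensors", {
  iso <- hyperfine_tensor(diag(rep(1.7, 3)))
  for (ori in list(orientation(0, 0), orientation(35, 120),
                   orientation(90, 271))) {
    p <- project_hyperfine(iso, ori)
    expect_equal(unname(p), c(1.7, 0, 0), tolerance = 1e-12)
  }
  # axial tensor, field along symmetry axis (z): A_parallel, no B
  ax <- hyperfine_tensor(diag(c(-1, -1, 2)) * 0.9 + diag(rep(0.3, 3)))
  p <- project_hyperfine(ax, orientation(0, 0))
  expect_equal(unname(p), c(0.3 + 2 * 0.9, 0, 0), tolerance = 1e-12)
  # generic angle: A = aiso + T (3 cos^2 th - 1), |B| = 3 T sin th cos th
  Tdip <- 0.9; aiso <- 0.3
  for (th in c(20, 54.7356, 75)) {
    p <- project_hyperfine(ax, orientation(th, 33))
    cth <- cos(th * pi / 180); sth <- sin(th * pi / 180)
    expect_equal(unname(p["A"]), aiso + Tdip * (3 * cth^2 - 1),
                 tolerance = 1e-10)
    expect_equal(sqrt(p["Bx"]^2 + p["By"]^2), 3 * Tdip * abs(sth * cth),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("projection agrees with explicit rotation-matrix evaluation", {
  set.seed(7)
  M <- matrix(rnorm(9), 3, 3)
  tens <- hyperfine_tensor((M + t(M)) / 2)
  for (i in 1:5) {
    th <- runif(1, 0, 90); ph <- runif(1, 0, 360)
    # independent construction: orthonormal triad from the field direction
    n <- c(sin(th * pi / 180) * cos(ph * pi / 180),
           sin(th * pi / 180) * sin(ph * pi / 180), cos(th * pi / 180))
    e1 <- c(cos(th * pi / 180) * cos(ph * pi / 180),
            cos(th * pi / 180) * sin(ph * pi / 180), -sin(th * pi / 180))
    e2 <- c(-sin(ph * pi / 180), cos(ph * pi / 180), 0)
    p <- project_hyperfine(tens, orientation(th, ph))
    A <- unclass(tens)
    expect_equal(unname(p), c(n %*% A %*% n, e1 %*% A %*% n, e2 %*% A %*% n),
                 tolerance = 1e-10)
    # bounded by the largest eigenvalue magnitude
    expect_lte(abs(p["A"]), max(abs(eigen(A)$values)) + 1e-12)
  }
})

test_that("antisymmetric tensor components are discarded with a warning", {
  M <- diag(c(1, 2, 3))
  M[1, 2] <- 0.5  # asymmetric
  expect_warning(tens <- hyperfine_tensor(M), "antisymmetric")
  expect_equal(unclass(tens), (M + t(M)) / 2)
})

test_that("coupling assembly is deterministic and permutation-equivariant", {
  sys <- make_secular_system(4, seed = 11, with_methyl = TRUE)
  ori <- orientation(63, 200)
  cpl <- couplings_for_orientation(sys, ori)
  expect_identical(cpl$wzz, t(cpl$wzz))
  expect_identical(cpl$wnn, t(cpl$wnn))
  expect_equal(cpl$A, couplings_for_orientation(sys, ori)$A)
  # relabel protons 1..4 -> 4..1 (methyl follows its protons)
  perm <- 4:1
  prot2 <- lapply(seq_along(perm), function(i) {
    p <- sys$protons[[perm[i]]]
    proton(i, p$position, p$tensor)
  })
  m2 <- methyl_group(match(sys$methyls[[1]]$proton_ids, perm),
                     sys$methyls[[1]]$tunnel_kHz)
  sys2 <- spin_system(prot2, list(m2))
  cpl2 <- couplings_for_orientation(sys2, ori)
  expect_equal(cpl2$A, cpl$A[perm], ignore_attr = TRUE)
  expect_equal(cpl2$wnn, cpl$wnn[perm, perm], ignore_attr = TRUE)
  expect_equal(cpl2$wzz, cpl$wzz[perm, perm], ignore_attr = TRUE)
})

test_that("single-proton and tunnel-free systems give bare pair couplings", {
  p1 <- proton(1L, c(0, 0, 4), point_dipole_tensor(c(0, 0, 4)))
  sys1 <- spin_system(list(p1))
  cpl1 <- couplings_for_orientation(sys1, orientation(45, 0))
  expect_equal(dim(cpl1$wnn), c(1L, 1L))
  expect_equal(cpl1$wnn[1, 1], 0)
  # methyl with zero tunnel splitting: flip-flop equals bare dipolar
  sys0 <- methyl_system(tunnel_kHz = 0)
  cpl0 <- couplings_for_orientation(sys0, orientation(30, 60))
  expect_equal(cpl0$wnn, cpl0$wdd)
  expect_equal(cpl0$wzz, cpl0$wdd)
})

test_that("two-proton couplings match hand-evaluated formulas", {
  # protons on the z axis above the electron; field along z
  p <- list(proton(1L, c(0, 0, 4), hyperfine_tensor(diag(rep(2, 3)))),
            proton(2L, c(0, 0, 6), hyperfine_tensor(diag(rep(1, 3)))))
  sys <- spin_system(p)
  cpl <- couplings_for_orientation(sys, orientation(0, 0))
  # inter-proton vector along field: (1 - 3 cos^2) = -2, r = 2 A
  d_HH <- spindec_constants()$d_HH_kHz_A3
  expect_equal(cpl$wdd[1, 2], d_HH * (-2) / 8, tolerance = 1e-12)
  expect_equal(unname(cpl$A), c(2, 1))
  expect_equal(unname(cpl$Bx), c(0, 0))
})
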