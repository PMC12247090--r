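test_that("a single secular-coupled proton gives no Hahn echo decay", {
  p <- proton(1L, c(0, 0, 4), hyperfine_tensor(diag(rep(2, 3))))
  sys <- spin_system(list(p))
  cpl <- couplings_for_orientation(sys, orientation(0, 0))
  sp <- sequence_spec("bare", seq(0, 30, 1))
  tr <- hahn_echo_trace(cpl, sp, include_pseudosecular = FALSE)
  expect_equal(tr$values, rep(1, 31), tolerance = 1e-9)
})

test_that("two-proton Hahn echo matches the analytical pair factor", {
  sys <- make_secular_system(2, seed = 21)
  ori <- orientation(52, 10)
  cpl <- couplings_for_orientation(sys, ori)
  tms <- seq(0, 40, 0.5)
  sp <- sequence_spec("bare", tms)
  tr <- hahn_echo_trace(cpl, sp, include_pseudosecular = FALSE)
  ref <- eq_pair_oracle(cpl$A[1], cpl$A[2], cpl$wnn[1, 2], tms)
  expect_lt(max(abs(tr$values - ref)), 1e-6)
  expect_equal(tr$values[1], 1, tolerance = 1e-9)
})

test_that("Hahn echo is independent of the resonance offset", {
  sys <- methyl_system()
  cpl <- couplings_for_orientation(sys, orientation(33, 200))
  tms <- seq(0, 20, 2)
  ref <- hahn_echo_trace(cpl, sequence_spec("bare", tms, OmegaS = 0))
  for (off in c(5, -7)) {
    tr <- hahn_echo_trace(cpl, sequence_spec("bare", tms, OmegaS = off))
    expect_equal(tr$values, ref$values, tolerance = 1e-9)
  }
})

test_that("dressed echo of the empty bath is flat under ideal PM pulses", {
  sp <- sequence_spec("dressed", seq(0.2, 30, 2), w1 = 100, OmegaS = 0)
  tr <- dressed_echo_trace(NULL, sp, integer(0))
  expect_equal(tr$values, rep(1, length(sp$times)), tolerance = 1e-9)
})

test_that("locked magnetization of a secular bath equals the slow fraction", {
  sys <- make_secular_system(3, seed = 9, a_range = c(-6, 6))
  cpl <- couplings_for_orientation(sys, orientation(48, 31))
  OmegaS <- 3; w1 <- 100
  H <- build_cluster_hamiltonian(cpl, OmegaS = OmegaS, w1 = w1,
                                 include_pseudosecular = FALSE)
  d <- 2^H$nspins
  Sx <- spin_operator("x", 1, H$nspins)
  rt <- Conj(t(H$V)) %*% (-Sx) %*% H$V
  # time average: drop eigenbasis coherences between distinct eigenvalues,
  # then sum the magnitudes of the conserved components
  keep <- outer(H$lambda, H$lambda, function(a, b) abs(a - b) < 1e-7)
  f_num <- 2 * sum(svd(rt * keep)$d) / d
  f_ana <- slow_fraction(cpl$A, OmegaS = OmegaS, w1 = w1)
  expect_equal(f_num, f_ana, tolerance = 1e-9)
  # the dressed echo amplitude itself sits close to f_slow in this regime
  sp <- sequence_spec("dressed", c(0.2, 5), w1 = w1, OmegaS = OmegaS)
  raw <- dressed_echo_trace(cpl, sp, include_pseudosecular = FALSE,
                            normalize = FALSE)
  expect_equal(abs(raw$values[1]), f_ana, tolerance = 1e-3)
})

test_that("traces are real and dressed equals empty when hyperfine is zeroed", {
  sys <- methyl_system()
  cpl <- couplings_for_orientation(sys, orientation(61, 120))
  tms <- seq(0.2, 20, 1)
  spd <- sequence_spec("dressed", tms, OmegaS = 2)
  cpl0 <- cpl
  cpl0$A[] <- 0; cpl0$Bx[] <- 0; cpl0$By[] <- 0
  trd <- dressed_echo_trace(cpl0, spd)
  we <- w_empty(spd, offset_samples = 2)
  expect_equal(trd$values, we$values, tolerance = 1e-9)
})

test_that("empty-bath reference behaves as specified", {
  spb <- sequence_spec("bare", seq(0, 10, 1))
  expect_equal(w_empty(spb)$values, rep(1, 11))
  spd <- sequence_spec("dressed", seq(0.2, 30, 2), w1 = 100)
  expect_equal(w_empty(spd, offset_sigma = 0)$values,
               rep(1, length(spd$times)), tolerance = 1e-9)
  we <- w_empty(spd, offset_sigma = 4, n_nodes = 15)
  expect_true(all(we$values >= 0.98))
  expect_true(all(we$values <= 1.01))
})

test_that("dressed methyl cluster decays more slowly than the bare one", {
  sys <- methyl_system(dist = 4.2)
  ori <- orientation(55, 20)
  cpl <- couplings_for_orientation(sys, ori)
  tb <- seq(0, 30, 0.5)
  trb <- hahn_echo_trace(cpl, sequence_spec("bare", tb))
  trd <- dressed_echo_trace(cpl, sequence_spec("dressed", seq(0.2, 30, 0.5),
                                               w1 = 100))
  expect_gt(min(trd$values), min(trb$values))
})

test_that("explicit phase-modulation pulses approach the ideal limit", {
  frag <- make_methyl(c(0, 0, 4.5), c(0, 0, 1), tunnel_kHz = 54.5)
  sys <- spin_system(frag$protons[1])
  cpl <- couplings_for_orientation(sys, orientation(40, 10))
  tms <- seq(0.2, 8, 0.6)
  tri <- dressed_echo_trace(cpl, sequence_spec("dressed", tms,
                                               pm_model = "ideal"))
  tre <- dressed_echo_trace(cpl, sequence_spec("dressed", tms,
                                               pm_model = "explicit",
                                               pm_amplitude = 0.3))
  expect_lt(max(abs(tri$values - tre$values)), 0.02)
  # finite pulses lose a little echo amplitude but still refocus: the raw
  # empty-bath echo is close to the full locked value
  tr0 <- dressed_echo_trace(NULL,
                            sequence_spec("dressed", c(0.2, 5),
                                          pm_model = "explicit"),
                            integer(0), normalize = FALSE)
  expect_gt(abs(tr0$values[1]), 0.95)
})

test_that("sequence specs are validated", {
  expect_error(sequence_spec("bare", c(2, 1)), "increasing")
  expect_error(sequence_spec("dressed", c(0, 1), w1 = 0), "w1")
  expect_warning(
    dressed_echo_trace(
      couplings_for_orientation(methyl_system(2.5), orientation(0, 0)),
      sequence_spec("dressed", c(0.2, 1), w1 = 10)),
    "marginal")
})
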