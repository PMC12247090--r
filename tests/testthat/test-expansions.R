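test_that("pair factor starts at 1 and its depth peaks at matching", {
  tms <- seq(0, 25, 0.5)
  W <- pair_eseem(2.1, 1.4, 80, tms)
  expect_equal(W[1], 1, tolerance = 1e-12)
  # lambda = 1/4 exactly when |Ak - Al| equals the flip-flop coupling
  expect_equal(pair_modulation_depth(1.06, 1.0, 60), 0.25, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:30) {
    lam <- pair_modulation_depth(runif(1, -3, 3), runif(1, -3, 3),
                                 runif(1, 0, 200))
    expect_lte(lam, 0.25 + 1e-12)
    expect_gte(lam, 0)
  }
})

test_that("APPA equals the product of simulated pair factors", {
  sys <- make_secular_system(3, seed = 31, with_methyl = TRUE)
  ori <- orientation(40, 110)
  cpl <- couplings_for_orientation(sys, ori)
  tms <- seq(0, 30, 1)
  ap <- appa_trace(cpl, tms)
  ref <- rep(1, length(tms))
  for (k in 1:2) for (l in (k + 1):3)
    ref <- ref * eq_pair_oracle(cpl$A[k], cpl$A[l], cpl$wnn[k, l], tms)
  expect_equal(ap$values, ref, tolerance = 1e-12)
  expect_equal(ap$values[1], 1)
})

test_that("APPA is identical to CCE-2 for secular systems", {
  tms <- seq(0, 30, 1.5)
  sp <- sequence_spec("bare", tms)
  for (cfg in list(list(n = 2, seed = 51), list(n = 3, seed = 52),
                   list(n = 4, seed = 53, methyl = TRUE))) {
    sys <- make_secular_system(cfg$n, seed = cfg$seed,
                               with_methyl = isTRUE(cfg$methyl))
    ori <- orientation(47, 213)
    res <- cce_trace(sys, 2, sp, ori)
    ap <- appa_trace(couplings_for_orientation(sys, ori), tms)
    expect_lt(max(abs(res$trace$values - ap$values)), 1e-6)
  }
})

test_that("CCE at full order reproduces the direct simulation", {
  sys <- methyl_system()
  ori <- orientation(55, 20)
  tms <- seq(0, 25, 1)
  spb <- sequence_spec("bare", tms)
  direct_b <- hahn_echo_trace(couplings_for_orientation(sys, ori), spb)
  res_b <- cce_trace(sys, 3, spb, ori)
  expect_lt(max(abs(res_b$trace$values - direct_b$values)), 1e-6)
  tmd <- seq(0.2, 25, 1)
  spd <- sequence_spec("dressed", tmd, w1 = 100)
  direct_d <- dressed_echo_trace(couplings_for_orientation(sys, ori), spd)
  res_d <- cce_trace(sys, 3, spd, ori)
  expect_lt(max(abs(res_d$trace$values - direct_d$values)), 1e-6)
})

test_that("bare CCE-1 of a secular high-field bath is flat", {
  sys <- make_secular_system(3, seed = 33)
  sp <- sequence_spec("bare", seq(0, 20, 2))
  res <- cce_trace(sys, 1, sp, orientation(30, 30))
  expect_equal(res$trace$values, rep(1, length(sp$times)), tolerance = 1e-9)
})

test_that("partitions are validated and methyl partitioning works", {
  sys <- make_trityl_like(4, 5.5, 4.8, 54.5, seed = 1)
  part <- methyl_partition(sys)
  expect_length(part, 4)
  expect_true(all(lengths(part) == 3))
  expect_error(cluster_partition(list(1:3, 4:5)), "same size")
  expect_error(cluster_partition(list(1:3, 3:5)), "disjoint")
  expect_error(cluster_partition(list(1:3, 37:39), sys), "unknown")
})

test_that("supercluster counts follow the binomial coefficient", {
  tms <- c(0, 1)
  sp <- sequence_spec("bare", tms)
  # 12 clusters of size 3 (36 protons), u = 3 -> 220 superclusters;
  # count before running the (expensive) simulations via choose()
  expect_equal(choose(12, 3), 220)
  expect_equal(choose(12, 2), 66)
  # and the engine records it on a feasible system: 4 clusters, u = 2 -> 6
  sys <- make_trityl_like(4, 5.5, 4.8, 54.5, seed = 1)
  res <- pcce_trace(sys, methyl_partition(sys), 2, sp, orientation(20, 40))
  expect_equal(res$supercluster_count, choose(4, 2))
  expect_equal(res$n_signals, 1L + 4L + 6L)
})

test_that("pCCE at full coverage reproduces the direct simulation", {
  sys <- two_pair_system()
  part <- list(c(1L, 2L), c(3L, 4L))
  ori <- orientation(66, 140)
  for (spec in list(sequence_spec("bare", seq(0, 25, 1)),
                    sequence_spec("dressed", seq(0.2, 25, 1), w1 = 100))) {
    res <- pcce_trace(sys, part, 2, spec, ori)
    cpl <- couplings_for_orientation(sys, ori)
    direct <- if (spec$mode == "bare") hahn_echo_trace(cpl, spec)
              else dressed_echo_trace(cpl, spec)
    expect_lt(max(abs(res$trace$values - direct$values)), 1e-6)
  }
})

test_that("cluster factorization equals pCCE(u=1) and is exact for
           non-interacting clusters", {
  sys <- two_pair_system()
  part <- list(c(1L, 2L), c(3L, 4L))
  ori <- orientation(50, 10)
  sp <- sequence_spec("bare", seq(0, 25, 1))
  cf <- cf_trace(sys, part, sp, ori)
  p1 <- pcce_trace(sys, part, 1, sp, ori)
  expect_equal(cf$trace$values, p1$trace$values, tolerance = 1e-12)
  # widely separated clusters: inter-cluster couplings negligible
  sysf <- two_pair_system(far = TRUE)
  cff <- cf_trace(sysf, part, sp, ori)
  direct <- hahn_echo_trace(couplings_for_orientation(sysf, ori), sp)
  expect_lt(max(abs(cff$trace$values - direct$values)), 1e-6)
})

test_that("engine traces start at 1 and report instability honestly", {
  sys <- methyl_system()
  ori <- orientation(45, 45)
  spb <- sequence_spec("bare", seq(0, 10, 1))
  for (res in list(cce_trace(sys, 2, spb, ori),
                   cf_trace(sys, methyl_partition(sys), spb, ori))) {
    expect_equal(res$trace$values[1], 1, tolerance = 1e-9)
    expect_false(res$unstable)
  }
  # a pathological floor flags divisions without patching the trace
  res <- cce_trace(sys, 2, spb, ori, floor = 10)
  expect_true(res$unstable)
})

test_that("CCE refinement converges monotonically on a 4-proton system", {
  frag <- make_methyl(c(0, 0, 4.2), c(0, 0, 1), tunnel_kHz = 54.5)
  by <- proton(4L, c(2.6, 0.5, 3.4), point_dipole_tensor(c(2.6, 0.5, 3.4)))
  sys <- spin_system(c(frag$protons, list(by)), list(frag$methyl))
  ori <- orientation(55, 20)
  tms <- seq(0, 30, 0.5)
  sp <- sequence_spec("bare", tms)
  exact <- hahn_echo_trace(couplings_for_orientation(sys, ori), sp)
  te <- min(decay_time(exact), max(tms))
  mask <- tms <= te
  errs <- vapply(1:4, function(o) {
    L <- cce_trace(sys, o, sp, ori)
    max(abs(L$trace$values[mask] - exact$values[mask]))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 1e-10)
})

test_that("instability rejection uses the negative / 1.1 thresholds", {
  tr_ok <- spindec:::.new_cluster_trace(0:5, c(1, .9, .8, .5, .2, 0.01),
                                        1, "bare")
  expect_false(reject_unstable(tr_ok))
  tr_hi <- spindec:::.new_cluster_trace(0:5, c(1, 1.2, .8, .5, .2, .1),
                                        1, "bare")
  expect_true(reject_unstable(tr_hi))
  expect_false(reject_unstable(tr_hi, window = 0.5))
  tr_neg <- spindec:::.new_cluster_trace(0:5, c(1, .9, .8, .5, -0.01, .1),
                                         1, "bare")
  expect_true(reject_unstable(tr_neg))
  expect_false(reject_unstable(tr_neg, window = 3))
  tr_edge <- spindec:::.new_cluster_trace(0:2, c(1, 1.09, 0), 1, "bare")
  expect_false(reject_unstable(tr_edge))
})
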