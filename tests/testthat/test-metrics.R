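# Flow-split ratio and tidal-volume metrics.

test_that("identical lungs split the flow exactly in half", {
  fr <- flow_ratio_series(ref_sim())
  expect_true(any(fr$valid))
  expect_equal(max(abs(fr$ratio[fr$valid] - 0.5)), 0, tolerance = 1e-9)
  tv <- tidal_volumes(ref_sim())
  expect_equal(tv$vt_share_r, rep(0.5, 3), tolerance = 1e-6)
})

test_that("right and left flow ratios are exactly complementary on valid samples", {
  sim <- simulate_bipap(lung_r = lung_parameters(C = 8),
                        lung_l = lung_parameters(C = 12),
                        control = quick_ctl())
  fr <- flow_ratio_series(sim)
  traj <- sim$trajectory
  v <- fr$valid
  ratio_l <- traj$q_l[v] / traj$q_s[v]
  expect_equal(fr$ratio[v] + ratio_l, rep(1, sum(v)), tolerance = 1e-12)
})

test_that("tidal volume approaches C * (IPAP - EPAP) in the quasi-static limit", {
  # long inspiration (10 s) and expiration: both phases fully equilibrate,
  # so the excursion is the compliance times the 18 cmH2O pressure swing
  sim <- simulate_bipap(ventilator_settings(Ti = 10, BPM = 3, Tr = 0.3),
                        control = sim_control(n_warmup = 1, n_record = 1))
  tv <- tidal_volumes(sim)
  expect_equal(tv$VT_r_mL, 10 * 18, tolerance = 0.02 * 180)
  expect_equal(tv$VT_l_mL, 10 * 18, tolerance = 0.02 * 180)
})

test_that("masked samples are rare and coincide with vanishing lung flows", {
  sim <- ref_sim()
  fr <- flow_ratio_series(sim)
  # zero-flow tails after each lung equilibrates (flow ~ sqrt(dp) dies in
  # finite time) leave a small masked fraction near q_s = 0
  expect_lt(mean(!fr$valid), 0.10)
  traj <- sim$trajectory
  expect_true(all(abs(traj$q_r[!fr$valid]) <= 1e-7))
  expect_true(all(abs(traj$q_l[!fr$valid]) <= 1e-7))
  # raising the floor masks more, never fewer, samples
  fr2 <- flow_ratio_series(sim, eps = 1e-5)
  expect_true(all(fr$valid | !fr2$valid))
})

test_that("flows are inspiratory-positive and expiratory-negative almost everywhere", {
  sim <- simulate_bipap(lung_r = lung_parameters(C = 8),
                        lung_l = lung_parameters(C = 10),
                        control = quick_ctl())
  traj <- sim$trajectory
  insp <- traj$phase == "insp"
  # significance floor well below peak flow (~1e-3 kg/s) but above the
  # equilibrium chatter that follows finite-time extinction of sqrt(dp) flow
  floor_q <- 1e-6
  for (q in list(traj$q_r, traj$q_l)) {
    expect_gt(mean(q[insp] >= -floor_q), 0.95)
    expect_gt(mean(q[!insp] <= floor_q), 0.95)
  }
})

test_that("mirror-image lung pairs have complementary tidal-volume shares", {
  a <- simulate_bipap(lung_r = lung_parameters(C = 8),
                      lung_l = lung_parameters(C = 14),
                      control = quick_ctl())
  b <- simulate_bipap(lung_r = lung_parameters(C = 14),
                      lung_l = lung_parameters(C = 8),
                      control = quick_ctl())
  expect_equal(tidal_volumes(a)$vt_share_r + tidal_volumes(b)$vt_share_r, 1,
               tolerance = 1e-12)
})

test_that("sweep summaries order scenarios and refuse mixed parameters", {
  ctl <- quick_ctl()
  sims <- lapply(c(12, 8, 10), function(C)
    simulate_bipap(lung_r = lung_parameters(C = C), lung_l = lung_parameters(),
                   control = ctl))
  tab <- sweep_summary(sims, "C_r", c(12, 8, 10))
  expect_identical(tab$value, c(8, 10, 12))
  expect_true(all(diff(tab$vt_share_r) > 0))
  expect_lt(tab$vt_share_r[1], 0.5)
  expect_equal(tab$vt_share_r[2], 0.5, tolerance = 1e-6)
  expect_gt(tab$vt_share_r[3], 0.5)
  expect_error(sweep_summary(sims, c("C_r", "d_r", "C_r"), c(8, 10, 12)),
               "mix")
  expect_error(sweep_summary(sims, "C_r", c(1, 2)), "equal length")
})
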