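# Coupled integration: equilibrium, symmetry, conservation, segmentation.

test_that("derivatives vanish when both lungs sit at the setpoint", {
  sc <- reference_scenario()
  g <- sc$gas
  # plateau phase: setpoint = IPAP
  st <- init_lung_state(sc$lung_r, g, sc$settings$IPAP)
  d <- system_derivatives(0.5, st, st, sc$settings, sc$lung_r, sc$lung_l, g)
  expect_identical(d$q_r, 0)
  expect_identical(d$q_l, 0)
  expect_identical(d$q_s, 0)
  expect_identical(unname(d$rates_r), c(0, 0, 0))
  expect_identical(unname(d$rates_l), c(0, 0, 0))
})

test_that("identical lungs produce identical per-lung derivatives and q_s = q_r + q_l", {
  sc <- reference_scenario()
  st <- init_lung_state(sc$lung_r, sc$gas, 7)
  for (t in c(0.05, 0.2, 0.6, 1.4, 2.9)) {
    d <- system_derivatives(t, st, st, sc$settings, sc$lung_r, sc$lung_l, sc$gas)
    expect_identical(d$rates_r, d$rates_l)
    expect_identical(d$q_s, d$q_r + d$q_l)
  }
})

test_that("total flow is the exact sum of lung flows at every trajectory sample", {
  traj <- ref_sim()$trajectory
  expect_identical(traj$q_s, traj$q_r + traj$q_l)
})

test_that("swapping the two lungs relabels the trajectory exactly", {
  A <- lung_parameters(C = 8)
  B <- lung_parameters(C = 14, d = 2.4)
  s1 <- simulate_bipap(lung_r = A, lung_l = B, control = quick_ctl())
  s2 <- simulate_bipap(lung_r = B, lung_l = A, control = quick_ctl())
  expect_identical(s1$trajectory$p_r_pa, s2$trajectory$p_l_pa)
  expect_identical(s1$trajectory$V_r, s2$trajectory$V_l)
  expect_identical(s1$trajectory$m_r, s2$trajectory$m_l)
  expect_identical(s1$trajectory$q_r, s2$trajectory$q_l)
  expect_identical(s1$trajectory$q_s, s2$trajectory$q_s)
})

test_that("the gas-law constraint is maintained along the trajectory", {
  res <- residuals(ref_sim())
  expect_lt(max(abs(res)), 1e-6)
})

test_that("lung mass tracks the time-integral of its inflow", {
  traj <- ref_sim()$trajectory
  i <- which(traj$cycle == 1)
  dt <- diff(traj$t[i][1:2])
  for (side in c("r", "l")) {
    q <- traj[[paste0("q_", side)]][i]
    m <- traj[[paste0("m_", side)]][i]
    qint <- sum((q[-1] + q[-length(q)]) / 2) * dt
    # trapezoid reconstruction on the 1 ms grid; the expiratory step at Ti
    # limits its accuracy to about the grid resolution
    expect_equal(m[length(m)] - m[1], qint,
                 tolerance = 0.01 * (max(m) - min(m)))
  }
})

test_that("a constant-pressure source drives flows and tidal volumes to zero", {
  s0 <- simulate_bipap(ventilator_settings(IPAP = 4, EPAP = 4),
                       control = quick_ctl())
  expect_lt(max(abs(s0$trajectory$q_s)), 1e-10)
  tv <- tidal_volumes(s0)
  expect_identical(tv$VT_r_mL, 0)
  expect_true(tv$degenerate)
})

test_that("cycle segmentation covers the trajectory with half-open phase ranges", {
  sim <- ref_sim()  # 3 recorded cycles at BPM 20, 1 ms grid
  cyc <- segment_cycles(sim)
  expect_length(cyc, 3)
  expect_true(all(vapply(cyc, function(cc) length(cc$idx), 1L) == 3000L))
  all_idx <- unlist(lapply(cyc, `[[`, "idx"))
  expect_identical(sort(all_idx), seq_len(nrow(sim$trajectory)))
  expect_identical(anyDuplicated(all_idx), 0L)
  for (cc in cyc) {
    expect_identical(sort(c(cc$insp, cc$exp)), cc$idx)
    # inspiration sub-range spans Ti seconds
    expect_equal(length(cc$insp) * sim$control$output_dt,
                 sim$settings$Ti, tolerance = 2e-3)
  }
})

test_that("the reference scenario is flagged steady after warm-up", {
  sim <- ref_sim()
  expect_true(sim$steady)
  expect_identical(nrow(sim$warmup_vt), 5L)
})

test_that("breakpoints off the output grid are still integrated cleanly", {
  # Tr and Ti deliberately not multiples of the 1 ms grid
  s <- ventilator_settings(Ti = 1.0005, Tr = 0.2503)
  sim <- simulate_bipap(s, control = quick_ctl())
  expect_lt(max(abs(residuals(sim))), 1e-6)
  expect_identical(sim$trajectory$q_s,
                   sim$trajectory$q_r + sim$trajectory$q_l)
})

test_that("simulation control validates its arguments", {
  expect_error(sim_control(n_record = 0), "n_record")
  expect_error(sim_control(rel_tol = 0), "positive")
  expect_error(sim_control(max_step = -1), "max_step")
})
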