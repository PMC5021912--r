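# Compressible orifice flow law, critical pressure ratio, unit conversions.

test_that("critical pressure ratio matches the closed form and its limits", {
  # air: (2/2.4)^3.5
  expect_equal(critical_pressure_ratio(1.4), (2 / 2.4)^3.5)
  expect_equal(critical_pressure_ratio(1.4), 0.5283, tolerance = 1e-4)
  # exact rational case
  expect_equal(critical_pressure_ratio(2), 4 / 9)
  # limit k -> 1+ is exp(-1/2) (frozen from evaluating the closed form at
  # k = 1 + 1e-9 independently)
  expect_equal(critical_pressure_ratio(1 + 1e-9), exp(-0.5), tolerance = 1e-6)
  expect_error(critical_pressure_ratio(1), "> 1")
  expect_error(critical_pressure_ratio(0.9), "> 1")
})

test_that("cmH2O gauge <-> absolute Pa conversions are exact inverses", {
  expect_identical(cmh2o_to_pa(0), 101325)
  expect_equal(cmh2o_to_pa(22), 101325 + 22 * 98.0665)
  for (x in c(-5, 0, 4, 22, 40))
    expect_equal(pa_to_cmh2o(cmh2o_to_pa(x)), x)
  expect_error(cmh2o_to_pa(-1100), "positive")
})

test_that("orifice flow vanishes at zero pressure difference and is antisymmetric", {
  g <- gas_properties()
  Ae <- throttle_geometry(3.2)$Ae
  expect_identical(orifice_mass_flow(101325, 101325, Ae, g), 0)
  expect_identical(orifice_mass_flow(2e5, 2e5, Ae, g), 0)
  set.seed(7)
  a <- runif(100, 2e4, 3e5)
  b <- runif(100, 2e4, 3e5)
  expect_identical(orifice_mass_flow(a, b, Ae, g),
                   -orifice_mass_flow(b, a, Ae, g))
})

test_that("orifice flow is proportional to effective area and monotone in p_down", {
  g <- gas_properties()
  Ae <- throttle_geometry(2.4)$Ae
  pu <- cmh2o_to_pa(22)
  pd <- cmh2o_to_pa(4)
  expect_identical(orifice_mass_flow(pu, pd, 2 * Ae, g),
                   2 * orifice_mass_flow(pu, pd, Ae, g))
  # non-increasing in p_down on the subsonic range (b*pu, pu]
  pds <- seq(g$b * pu * 1.001, pu, length.out = 200)
  q <- orifice_mass_flow(pu, pds, Ae, g)
  expect_true(all(diff(q) <= 0))
})

test_that("subsonic and choked branches join continuously and the plateau is flat", {
  g <- gas_properties()
  Ae <- throttle_geometry(3.2)$Ae
  pu <- 2e5
  eps <- 1e-9
  q_lo <- orifice_mass_flow(pu, pu * (g$b - eps), Ae, g)
  q_hi <- orifice_mass_flow(pu, pu * (g$b + eps), Ae, g)
  expect_equal(q_lo, q_hi, tolerance = 1e-6)
  # exactly at the critical ratio both expressions coincide
  expect_equal(orifice_mass_flow(pu, pu * g$b, Ae, g), q_lo, tolerance = 1e-9)
  # choked plateau: independent of downstream pressure
  pds <- seq(0.1 * pu, g$b * pu, length.out = 50)
  q <- orifice_mass_flow(pu, pds, Ae, g)
  expect_lt(diff(range(q)) / abs(mean(q)), 1e-12)
})

test_that("reference subsonic flow matches the independently evaluated formula", {
  # frozen one-line evaluation of the subsonic expression at
  # IPAP 22 -> EPAP 4 cmH2O, d = 3.2 mm, Cd = 1, air at theta = 293 K
  g <- gas_properties(theta = 293)
  Ae <- throttle_geometry(3.2)$Ae
  q <- orifice_mass_flow(cmh2o_to_pa(22), cmh2o_to_pa(4), Ae, g)
  expect_equal(q, 5.251904980523946e-4, tolerance = 1e-12)
  expect_gt(q, 0)
})

test_that("orifice flow rejects invalid inputs", {
  g <- gas_properties()
  expect_error(orifice_mass_flow(-1, 101325, 1e-6, g), "positive")
  expect_error(orifice_mass_flow(101325, 101325, -1e-6, g), "non-negative")
  expect_error(throttle_geometry(0), "positive")
  expect_error(throttle_geometry(3.2, Cd = 1.5), "\\(0, 1\\]")
})
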