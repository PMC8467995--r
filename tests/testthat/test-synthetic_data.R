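test_that("generated isotherms round-trip their spec targets", {
  sp <- isotherm_spec(
    a0 = 58, lift_off = 85, cs_max = 140, p_peak = 41,
    kink = 28, kink_floor = 22, collapse = 46, collapse_floor = 3,
    c_le = 60, p_max = 52
  )
  iso <- gen_isotherm(sp)
  expect_lt(abs(extract_a0(iso) / 58 - 1), 0.005)
  expect_lt(abs(max(iso$area) / 85 - 1), 0.02)
  prof <- compression_modulus(preprocess_isotherm(iso))
  expect_lt(abs(attr(prof, "cs_max") / 140 - 1), 0.02)
  tr <- detect_transitions(prof)
  expect_equal(tr$kink_pressures, 28, tolerance = 1)
  expect_equal(tr$collapse_pressures, 46, tolerance = 0.5)
})

test_that("isotherm generation is a deterministic function of the seed", {
  sp1 <- isotherm_spec(a0 = 58, cs_max = 140, p_peak = 41, noise_sd = 0.1, seed = 5)
  a <- gen_isotherm(sp1)
  b <- gen_isotherm(sp1)
  expect_identical(a$pressure, b$pressure)
  sp2 <- isotherm_spec(a0 = 58, cs_max = 140, p_peak = 41, noise_sd = 0.1, seed = 6)
  expect_false(identical(gen_isotherm(sp2)$pressure, a$pressure))
})

test_that("infeasible isotherm specs are rejected", {
  expect_error(
    isotherm_spec(a0 = 58, cs_max = 140, p_peak = 41, kink = 45, collapse = 40),
    class = "raftfilm_spec_error"
  )
  expect_error(
    isotherm_spec(a0 = 58, lift_off = 50, cs_max = 140, p_peak = 41),
    class = "raftfilm_spec_error"
  )
  expect_error(
    isotherm_spec(a0 = 58, cs_max = 140, p_peak = 41, post_collapse_a0 = 40),
    class = "raftfilm_spec_error"
  )
  expect_error(
    isotherm_spec(a0 = 58, cs_max = 140, p_peak = 41, kink = 30, kink_floor = 5),
    class = "raftfilm_spec_error"
  )
})

test_that("generated ACV curves round-trip minimum, pzfc and current mode", {
  sp <- acv_spec(c_min = 3.1, e_min = -0.21, pzfc = 0.305)
  cv <- gen_acv(sp)
  est <- min_capacitance(cv)
  expect_lt(abs(est$c_min - 3.1), 0.05)
  expect_lt(abs(est$e_at_min - (-0.21)), 0.02)
  pz <- find_pzfc(charge_density(cv))
  expect_lt(abs(as.numeric(pz) - 0.305), 0.002)

  # current-mode output re-inverted equals capacitance-mode output
  cvc <- gen_acv(acv_spec(c_min = 3.1, e_min = -0.21, pzfc = 0.305, mode = "current"))
  expect_equal(capacitance_from_ac(cvc)$capacitance, cv$capacitance,
    tolerance = 1e-9)

  expect_error(acv_spec(pzfc = 2), class = "raftfilm_spec_error")
})

test_that("generated spectra equal the circuit exactly and reproduce bitwise", {
  p <- fixture_circuit("1:2:1")
  sp <- gen_spectrum(spectrum_spec(p))
  z <- circuit_impedance(p, 2 * pi * sp$frequency)
  expect_identical(sp$z_real, Re(z))
  expect_identical(sp$z_imag, Im(z))
  n1 <- gen_spectrum(spectrum_spec(p, noise_relative = 0.01, seed = 4))
  n2 <- gen_spectrum(spectrum_spec(p, noise_relative = 0.01, seed = 4))
  expect_identical(n1$z_real, n2$z_real)
  # high-frequency limit approaches the solution resistance
  sp_hi <- gen_spectrum(spectrum_spec(p, f_min = 1e3, f_max = 2e5))
  expect_equal(sp_hi$z_real[which.max(sp_hi$frequency)], p$r_sol, tolerance = 0.01)
  expect_error(spectrum_spec(p, points_per_decade = 3), class = "raftfilm_spec_error")
})

test_that("the fixture registry reproduces the published descriptor set", {
  fx <- raft_fixtures()
  iso <- fx$isotherms

  expect_equal(extract_a0(iso$SM), 50.7, tolerance = 0.5)
  expect_equal(extract_a0(iso[["2:1:1"]]), 62.0, tolerance = 0.5)
  expect_equal(extract_a0(iso[["1:2:1"]]), 48.1, tolerance = 0.5)
  expect_equal(extract_a0(iso[["1:1:2"]]), 52.7, tolerance = 0.5)

  prof211 <- compression_modulus(preprocess_isotherm(iso[["2:1:1"]]))
  expect_equal(attr(prof211, "cs_max"), 98, tolerance = 2)
  expect_equal(classify_phase(attr(prof211, "cs_max")), "LE")
  prof111 <- compression_modulus(preprocess_isotherm(iso[["1:1:1"]]))
  expect_equal(attr(prof111, "cs_max"), 125, tolerance = 3)
  expect_equal(classify_phase(attr(prof111, "cs_max")), "LC")

  tr111 <- detect_transitions(prof111)
  expect_equal(tr111$kink_pressures, 30, tolerance = 1)
  expect_equal(tr111$collapse_pressures, 47.8, tolerance = 0.5)
  tr121 <- detect_transitions(compression_modulus(preprocess_isotherm(iso[["1:2:1"]])))
  expect_length(tr121$collapse_pressures, 0)
  expect_true(any(abs(tr121$kink_pressures - 50) < 1))

  # percent condensation at 30 mN/m: 11.9 / 3.9 / 3.6, negative for 1:1:1
  expect_equal(percent_condensation(fx$mixtures[["2:1:1"]], 30), 11.9, tolerance = 0.3)
  expect_equal(percent_condensation(fx$mixtures[["1:2:1"]], 30), 3.9, tolerance = 0.3)
  expect_equal(percent_condensation(fx$mixtures[["1:1:2"]], 30), 3.6, tolerance = 0.3)
  expect_lt(percent_condensation(fx$mixtures[["1:1:1"]], 30), 0)

  # post-collapse limiting areas
  expect_equal(extract_a0(iso[["1:1:2"]], segment = c(46.5, 55)), 31.0, tolerance = 0.5)
  expect_equal(extract_a0(iso[["1:1:1"]], segment = c(49.3, 55)), 50.5, tolerance = 0.5)
})

test_that("fixture stability traces plateau at 28 and 26 mN/m (or not at all)", {
  fx <- raft_fixtures()
  out112 <- stability_metrics(fx$stability[["1:1:2"]])
  expect_equal(attr(out112, "plateau_pressure"), 28, tolerance = 0.5)
  expect_lt(attr(out112, "time_to_plateau"), 2400)
  out121 <- stability_metrics(fx$stability[["1:2:1"]])
  expect_equal(attr(out121, "plateau_pressure"), 26, tolerance = 0.5)
  out211 <- stability_metrics(fx$stability[["2:1:1"]])
  expect_true(is.na(attr(out211, "plateau_pressure")))
  expect_lt(attr(out211, "drift_rate"), -0.5)
})

test_that("fixture ACV curves sit in the reported capacitance and pzfc ranges", {
  fx <- raft_fixtures()
  pz_expect <- c("2:1:1" = 0.300, "1:2:1" = 0.290, "1:1:2" = 0.270, "1:1:1" = 0.330)
  for (nm in names(fx$acv)) {
    est <- coverage(min_capacitance(fx$acv[[nm]]))
    expect_gte(est$c_min, 2.6)
    expect_lte(est$c_min, 3.5)
    expect_gte(est$theta, 0.92)
    expect_lte(est$theta, 0.95)
    pz <- as.numeric(find_pzfc(charge_density(fx$acv[[nm]])))
    expect_equal(pz, pz_expect[[nm]], tolerance = 0.01)
  }
  # the SM-rich film has its capacitance minimum at more negative potential
  e112 <- min_capacitance(fx$acv[["1:1:2"]])$e_at_min
  e111 <- min_capacitance(fx$acv[["1:1:1"]])$e_at_min
  expect_lt(e112, e111 - 0.02)
})

test_that("the fixture registry is deterministic and cached", {
  f1 <- raft_fixtures(seed = 0)
  f2 <- raft_fixtures(seed = 0)
  expect_identical(f1$isotherms[["1:1:1"]]$pressure, f2$isotherms[["1:1:1"]]$pressure)
  n1 <- raft_fixtures(seed = 0, noise = TRUE)
  expect_false(identical(
    n1$isotherms[["1:1:1"]]$pressure,
    f1$isotherms[["1:1:1"]]$pressure
  ))
})
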