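test_that("CPE impedance has the closed-form modulus and constant phase", {
  omega <- 2 * pi * c(0.1, 1, 10, 100)
  # alpha = 1 is an ideal capacitor: phase -90 degrees
  z <- cpe_impedance(5, 1, omega)
  expect_equal(Arg(z) * 180 / pi, rep(-90, 4), tolerance = 1e-9)
  expect_equal(Mod(z), 1 / (5e-6 * omega), tolerance = 1e-12)
  # alpha -> 0 approaches a resistor of 1/q
  z0 <- cpe_impedance(5, 1e-3, omega)
  expect_lt(max(abs(Arg(z0) * 180 / pi)), 0.1)
  expect_equal(Mod(z0), rep(1 / 5e-6, 4), tolerance = 0.01)
  # q = 5, alpha = 0.8, f = 1 Hz
  z1 <- cpe_impedance(5, 0.8, 2 * pi)
  expect_equal(Mod(z1), 1 / (5e-6 * (2 * pi)^0.8), tolerance = 1e-12)
  expect_equal(Mod(z1), 4.6e4, tolerance = 0.01)
  expect_equal(Arg(z1) * 180 / pi, -72, tolerance = 1e-9)
  expect_error(cpe_impedance(-1, 0.8, 1), "q must")
  expect_error(cpe_impedance(5, 1.2, 1), "alpha")
  expect_error(cpe_impedance(5, 0.8, -1), "positive")
})

test_that("the circuit collapses to its limiting forms", {
  p <- fixture_circuit("2:1:1")
  # CPEs short at high frequency: Z -> R_sol
  z_hi <- circuit_impedance(p, 1e6)
  expect_equal(Re(z_hi), p$r_sol, tolerance = 0.01)
  # blocking membrane without spacer: exactly R_sol + Z_Qm
  p2 <- circuit_params(p$r_sol, Inf, p$q_m, p$alpha_m)
  omega <- 2 * pi * 10^seq(-1, 3, by = 0.25)
  expect_equal(
    circuit_impedance(p2, omega),
    p$r_sol + cpe_impedance(p$q_m, p$alpha_m, omega)
  )
})

test_that("circuit impedance matches an independent complex-arithmetic evaluation", {
  p <- fixture_circuit("2:1:1")
  f <- 1
  w <- 2 * pi * f
  # independent oracle in polar arithmetic, assembled term by term
  polar <- function(mod, ph) complex(modulus = mod, argument = ph)
  z_qm <- polar(1 / (p$q_m * 1e-6 * w^p$alpha_m), -p$alpha_m * pi / 2)
  z_qsp <- polar(1 / (p$q_sp * 1e-6 * w^p$alpha_sp), -p$alpha_sp * pi / 2)
  branch <- p$r_m * 1e3 + z_qsp
  oracle <- p$r_sol + (z_qm * branch) / (z_qm + branch)
  got <- circuit_impedance(p, w)
  expect_lt(Mod(got - oracle) / Mod(oracle), 1e-12)
})

test_that("Bode conversion reproduces textbook values", {
  sp <- suppressWarnings(impedance_spectrum(c(1, 10), c(3, 50), c(-4, 0)))
  b <- to_bode(sp)
  expect_equal(10^b$log10_modulus[1], 5)
  expect_equal(b$phase_deg[1], -atan2(4, 3) * 180 / pi)
  expect_equal(b$phase_deg[1], -53.13, tolerance = 1e-3)
  expect_equal(b$phase_deg[2], 0)
  # pure CPE alpha = 0.94: constant phase -84.6 degrees
  omega <- 2 * pi * 10^seq(-1, 3, by = 0.5)
  z <- cpe_impedance(3, 0.94, omega)
  spc <- suppressWarnings(impedance_spectrum(omega / (2 * pi), Re(z), Im(z)))
  expect_equal(to_bode(spc)$phase_deg, rep(-0.94 * 90, length(omega)),
    tolerance = 1e-9)
})

test_that("simulated circuit phase stays capacitive for any positive parameters", {
  omega <- 2 * pi * 10^seq(-1, 3, by = 0.2)
  set.seed(7)
  for (i in 1:25) {
    p <- circuit_params(
      r_sol = runif(1, 1, 500), r_m = 10^runif(1, 0, 4),
      q_m = 10^runif(1, -1, 1.5), alpha_m = runif(1, 0.5, 1),
      q_sp = 10^runif(1, -1, 1.5), alpha_sp = runif(1, 0.5, 1)
    )
    ph <- Arg(circuit_impedance(p, omega)) * 180 / pi
    expect_true(all(ph > -90 & ph <= 1e-9))
  }
})

test_that("the CNLS fit is a fixed point at the truth", {
  p <- fixture_circuit("1:1:2")
  sp <- gen_spectrum(spectrum_spec(p))
  fit <- cnls_fit(sp, p)
  expect_true(fit$converged)
  expect_lt(fit$residual_norm, 1e-10)
  expect_equal(fit$params$r_m, p$r_m, tolerance = 1e-9)
})

test_that("the fit is invariant to frequency ordering", {
  p <- fixture_circuit("1:2:1")
  sp <- gen_spectrum(spectrum_spec(p, noise_relative = 0.01, seed = 3))
  init <- circuit_params(p$r_sol * 2, p$r_m * 2, p$q_m * 2, p$alpha_m,
    p$q_sp * 2, p$alpha_sp)
  f1 <- cnls_fit(sp, init)
  rev_sp <- impedance_spectrum(rev(sp$frequency), rev(sp$z_real), rev(sp$z_imag))
  f2 <- cnls_fit(rev_sp, init)
  expect_equal(f2$params$r_m, f1$params$r_m, tolerance = 1e-6)
  expect_equal(f2$params$q_sp, f1$params$q_sp, tolerance = 1e-6)
})

test_that("the fit is invariant to area normalisation", {
  # Z in ohm (not ohm cm^2) with Q rescaled by the area: same physics
  area <- 0.64 # cm^2
  p <- fixture_circuit("2:1:1")
  sp <- gen_spectrum(spectrum_spec(p))
  sp_ohm <- impedance_spectrum(sp$frequency, sp$z_real / area, sp$z_imag / area)
  init_cm <- circuit_params(p$r_sol * 2, p$r_m * 2, p$q_m * 2, p$alpha_m,
    p$q_sp * 2, p$alpha_sp)
  init_ohm <- circuit_params(p$r_sol * 2 / area, p$r_m * 2 / area,
    p$q_m * 2 * area, p$alpha_m, p$q_sp * 2 * area, p$alpha_sp)
  f_cm <- cnls_fit(sp, init_cm)
  f_ohm <- cnls_fit(sp_ohm, init_ohm)
  expect_equal(f_ohm$params$r_m * area, f_cm$params$r_m, tolerance = 1e-6)
  expect_equal(f_ohm$params$q_m / area, f_cm$params$q_m, tolerance = 1e-6)
  expect_equal(f_ohm$params$alpha_m, f_cm$params$alpha_m, tolerance = 1e-8)
})

test_that("dropping sub-hertz frequencies inflates the spacer uncertainty", {
  p <- fixture_circuit("1:1:1")
  sp <- gen_spectrum(spectrum_spec(p, noise_relative = 0.01, seed = 11))
  f_full <- cnls_fit(sp, p)
  keep <- sp$frequency >= 1
  sp_cut <- impedance_spectrum(sp$frequency[keep], sp$z_real[keep], sp$z_imag[keep])
  f_cut <- cnls_fit(sp_cut, p)
  expect_gt(f_cut$stderr[["q_sp"]] / f_full$stderr[["q_sp"]], 2)
})

test_that("goodness diagnostics are zero for the truth and positive for offsets", {
  p <- fixture_circuit("1:1:1")
  sp <- gen_spectrum(spectrum_spec(p))
  g0 <- goodness(sp, p)
  expect_equal(g0$chisq_per_point, 0, tolerance = 1e-20)
  expect_equal(g0$max_phase_residual_deg, 0, tolerance = 1e-9)
  p_off <- circuit_params(p$r_sol + 10, p$r_m, p$q_m, p$alpha_m, p$q_sp, p$alpha_sp)
  g1 <- goodness(sp, p_off)
  expect_gt(g1$chisq_per_point, 0)
  # the offset hurts most where |Z| is smallest: high frequency
  hi <- sp$frequency >= 100
  chis_hi <- goodness(impedance_spectrum(sp$frequency[hi], sp$z_real[hi], sp$z_imag[hi]), p_off)
  lo <- sp$frequency <= 1
  chis_lo <- goodness(impedance_spectrum(sp$frequency[lo], sp$z_real[lo], sp$z_imag[lo]), p_off)
  expect_gt(chis_hi$chisq_per_point, chis_lo$chisq_per_point)
  expect_error(impedance_spectrum(numeric(0), numeric(0), numeric(0)))
})
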