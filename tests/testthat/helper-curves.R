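# Analytic curves used as independent oracles.

# Linear condensed branch: pi = slope * (a0 - A), clipped at 0.
linear_isotherm <- function(a0 = 50, slope = 1, a_max = 60, n = 60) {
  a <- seq(a_max, a0 * 0.4, length.out = n)
  isotherm(area = a, pressure = pmax(slope * (a0 - a), 0))
}

# Ideal two-dimensional gas: pi * A = kT. kT at 21 degC in mN/m * A^2:
# 1.380649e-23 J/K * 294.15 K / 1e-23 (J per mN/m*A^2) = 406.12.
KT_21C <- 1.380649 * 294.15 / 10 # mN/m * A^2 per molecule

gas_isotherm <- function(a_min = 20, a_max = 100, n = 600) {
  a <- seq(a_max, a_min, length.out = n)
  isotherm(area = a, pressure = KT_21C / a)
}

# Flat-capacitance ACV curve.
flat_acv <- function(c_const = 2, e = seq(-0.5, 0.5, by = 0.01)) {
  acv_curve(potential = e, capacitance = rep(c_const, length(e)))
}

fixture_circuit <- function(composition = "2:1:1") {
  raft_fixtures()$circuit[[composition]]
}
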