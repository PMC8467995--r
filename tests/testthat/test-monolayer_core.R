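test_that("preprocess is an identity on clean uniform input and averages duplicates", {
  a <- seq(100, 50.5, by = -0.5)
  p <- pmax(60 - a, 0)
  iso <- isotherm(a, p)
  out <- preprocess_isotherm(iso, grid_step = 0.5)
  expect_equal(out$area, a)
  expect_equal(out$pressure, p, tolerance = 1e-12)

  # duplicate area readings are averaged
  a2 <- c(seq(100, 92, by = -1), 90, 90)
  p2 <- c(seq(0, 8, by = 1), 10, 12)
  out2 <- preprocess_isotherm(isotherm(a2, p2), grid_step = NULL)
  expect_equal(sum(out2$area == 90), 1)
  expect_equal(out2$pressure[out2$area == 90], 11)

  # shuffled rows give the same result as sorted rows (sort oracle)
  set.seed(42)
  ord <- sample(length(a))
  shuf <- preprocess_isotherm(isotherm(a[ord], p[ord]), grid_step = 0.5)
  expect_equal(shuf$area, out$area)
  expect_equal(shuf$pressure, out$pressure)
})

test_that("preprocess rejects degenerate input and clips sensor negatives", {
  expect_error(isotherm(c(50, 40, 30), c(0, 1, 2)), "at least 10")
  expect_error(
    isotherm(seq(100, 91), c(seq(0, 7), NA, 3)),
    "non-finite"
  )
  iso <- isotherm(seq(100, 91), c(-0.3, -0.1, seq(1, 8)))
  out <- preprocess_isotherm(iso, grid_step = NULL)
  expect_true(all(out$pressure >= 0))
})

test_that("compression modulus matches the ideal-gas closed form", {
  # for pi*A = kT, Cs^-1 = -A dpi/dA = kT/A = pi exactly
  prof <- compression_modulus(preprocess_isotherm(gas_isotherm(), grid_step = 0.1))
  interior <- prof$pressure > quantile(prof$pressure, 0.05) &
    prof$pressure < quantile(prof$pressure, 0.95)
  expect_lt(max(abs(prof$cs_inverse[interior] / prof$pressure[interior] - 1)), 0.01)
})

test_that("compression modulus is zero on a constant-pressure plateau", {
  a <- seq(80, 40.5, by = -0.5)
  p <- ifelse(a > 60, 60 - a + 20, 20) # rising then flat at 20
  prof <- compression_modulus(preprocess_isotherm(isotherm(a, pmax(p, 0)), grid_step = 0.5))
  plateau <- prof$area < 55
  expect_lt(max(abs(prof$cs_inverse[plateau & prof$area > 42])), 1e-8)
})

test_that("compression modulus is invariant under area rescaling", {
  iso <- gas_isotherm()
  prof1 <- compression_modulus(preprocess_isotherm(iso, grid_step = 0.1))
  iso2 <- isotherm(iso$area * 3.7, iso$pressure)
  prof2 <- compression_modulus(preprocess_isotherm(iso2, grid_step = 0.37))
  cs2_at <- approx(prof2$pressure, prof2$cs_inverse, xout = prof1$pressure)$y
  ok <- is.finite(cs2_at)
  expect_lt(max(abs(cs2_at[ok] - prof1$cs_inverse[ok])), 0.02 * max(prof1$cs_inverse))
})

test_that("numerical Cs^-1 agrees with symbolic derivatives on analytic isotherms", {
  # exponential: pi = a exp(-A/b) -> Cs^-1 = (A/b) pi
  a0 <- 120
  b <- 25
  a <- seq(100, 20, length.out = 800)
  iso <- preprocess_isotherm(isotherm(a, a0 * exp(-a / b)), grid_step = 0.1)
  prof <- compression_modulus(iso)
  truth <- (prof$area / b) * prof$pressure
  interior <- seq_len(nrow(prof)) > 0.05 * nrow(prof) &
    seq_len(nrow(prof)) < 0.95 * nrow(prof)
  expect_lt(max(abs(prof$cs_inverse[interior] / truth[interior] - 1)), 0.01)

  # power law: pi = c A^-k -> Cs^-1 = k pi
  k <- 2.5
  iso2 <- preprocess_isotherm(isotherm(a, 3e4 * a^-k), grid_step = 0.1)
  prof2 <- compression_modulus(iso2)
  expect_lt(max(abs(prof2$cs_inverse[interior] / (k * prof2$pressure[interior]) - 1)), 0.01)
})

test_that("phase classification uses exhaustive lower-edge-inclusive bins", {
  expect_equal(classify_phase(162), "LC")
  expect_equal(classify_phase(125), "LC")
  expect_equal(classify_phase(300), "S")
  expect_equal(classify_phase(5), "G")
  # boundaries
  expect_equal(
    classify_phase(c(0, 12.5, 12.51, 50, 100, 250, 250.01)),
    c("G", "G", "G-LE", "LE", "LC", "LC", "S")
  )
  # total on a dense grid
  labs <- classify_phase(seq(0, 400, by = 0.25))
  expect_true(all(labs %in% c("G", "G-LE", "LE", "LC", "S")))
  expect_error(classify_phase(-1), "non-negative")
})

test_that("A0 extrapolation is exact on linear branches at any grid density", {
  for (n in c(20, 60, 300)) {
    iso <- linear_isotherm(a0 = 50, slope = 1.3, n = n)
    expect_equal(extract_a0(iso), 50, tolerance = 1e-3)
  }
  # analytic intercept to <= 0.1% regardless of slope/scale
  iso <- linear_isotherm(a0 = 83.5, slope = 0.4, a_max = 95, n = 45)
  expect_lt(abs(extract_a0(iso) / 83.5 - 1), 0.001)
})

test_that("A0 extraction fails cleanly without a rising branch", {
  a <- seq(100, 90.1, by = -0.1)
  iso <- isotherm(a, rep(0, length(a)))
  expect_error(extract_a0(iso), class = "raftfilm_extraction_error")
})

test_that("area_at_pressure inverts linear and quadratic isotherms", {
  iso <- linear_isotherm(a0 = 60, slope = 1, a_max = 70)
  expect_equal(area_at_pressure(iso, 30), 30, tolerance = 1e-6)
  # at a recorded node the recorded area is returned
  pre <- preprocess_isotherm(iso, grid_step = NULL)
  i <- which(pre$pressure > 5)[1]
  expect_equal(area_at_pressure(pre, pre$pressure[i]), pre$area[i])
  # dense quadratic: pi = ((a0 - A)/c)^2, inverse A = a0 - c sqrt(pi)
  a0 <- 80
  cc <- 8
  a <- seq(79.9, 30, length.out = 900)
  quad <- isotherm(a, ((a0 - a) / cc)^2)
  q <- 17.3
  expect_lt(abs(area_at_pressure(quad, q) / (a0 - cc * sqrt(q)) - 1), 0.001)
  expect_error(area_at_pressure(iso, 1e4), class = "raftfilm_out_of_range")
})

test_that("no transitions are reported on monotone convex isotherms", {
  prof <- compression_modulus(preprocess_isotherm(gas_isotherm(), grid_step = 0.1))
  tr <- detect_transitions(prof)
  expect_length(tr$collapse_pressures, 0)
  expect_length(tr$kink_pressures, 0)
})

test_that("isotherm_features assembles the descriptor set", {
  iso <- raft_fixtures()$isotherms[["1:1:1"]]
  ft <- isotherm_features(iso)
  expect_s3_class(ft, "isotherm_features")
  expect_equal(ft$phase, "LC")
  expect_equal(ft$A0_post_collapse, 50.5, tolerance = 0.3)
  expect_lt(ft$A0_post_collapse, ft$A0)
})
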