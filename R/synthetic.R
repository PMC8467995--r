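#' Specification for a synthetic isotherm
#'
#' The generator works in elasticity space: it lays down a smooth reciprocal
#' compression modulus profile Cs^-1(π) — a (generalised) Gaussian rise to
#' `cs_max` at `p_peak`, optionally multiplied by narrow Gaussian troughs at
#' the kink and collapse pressures — and integrates the defining relation
#' dA/dπ = -A / Cs^-1(π) to obtain the isotherm. The curve is then scaled so
#' that the steepest-segment extrapolation reproduces `a0` exactly, the
#' low-pressure compressibility `c0` is calibrated to the requested lift-off
#' area, and (when given) the collapse-trough width is calibrated so the
#' post-collapse branch extrapolates to `post_collapse_a0`. A collapse keeps
#' Cs^-1 below 10 mN/m at its minimum; a kink stays above it.
#'
#' @param a0 Target limiting area (Å²/molecule) for the steepest-segment
#'   extrapolation.
#' @param lift_off Target area at zero pressure (Å²/molecule); must exceed
#'   `a0`. `NULL` keeps the default low-pressure compressibility instead.
#' @param cs_max Target maximum reciprocal compression modulus (mN/m).
#' @param p_peak Pressure of the Cs^-1 maximum (mN/m).
#' @param kink Pressure of a structural-reorganization kink (mN/m) or `NULL`.
#' @param kink_floor Cs^-1 value at the kink minimum (mN/m, must be > 10).
#' @param collapse Pressure of a partial collapse (mN/m) or `NULL`.
#' @param collapse_floor Cs^-1 value at the collapse minimum (mN/m, < 10).
#' @param post_collapse_a0 Target limiting area of the post-collapse branch,
#'   or `NULL` to leave the collapse-trough width at `dip_width`.
#' @param c0 Gas-region Cs^-1 baseline in mN/m near zero pressure;
#'   recalibrated when `lift_off` is given.
#' @param c_le Expanded-region Cs^-1 level in mN/m reached above the
#'   lift-off knee (before the condensed rise to `cs_max`).
#' @param p_knee,w_knee Centre and width (mN/m) of the knee joining the gas
#'   baseline to the expanded level.
#' @param w_left,w_right Widths (mN/m) of the Cs^-1 rise below and fall above
#'   the peak.
#' @param shape_left Exponent of the generalised-Gaussian rise (2 = Gaussian;
#'   larger values flatten the profile below the peak).
#' @param shoulder,shoulder_floor,shoulder_width Optional mid-pressure
#'   compressibility shoulder: a broad shallow trough of the Cs^-1 profile at
#'   `shoulder` (mN/m) dropping to `shoulder_floor`. Mixed films whose
#'   condensed branch is much steeper than their packing at the transfer
#'   pressure show this structure between the bilayer-equivalent pressure
#'   and the compression-modulus maximum.
#' @param dip_width Width (mN/m) of kink/collapse troughs; `kink_width`
#'   overrides the kink trough width.
#' @param kink_width Width (mN/m) of the kink trough (default `dip_width`).
#' @param p_max Final pressure of the record (mN/m).
#' @param noise_sd Gaussian pressure noise (mN/m).
#' @param seed Integer seed for the noise.
#' @param n_out Number of output points (sampled uniformly in area).
#' @param label Composition label.
#' @return An object of class `isotherm_spec`.
#' @export
isotherm_spec <- function(a0, lift_off = NULL, cs_max, p_peak,
                          kink = NULL, kink_floor = 20,
                          collapse = NULL, collapse_floor = 3,
                          post_collapse_a0 = NULL,
                          c0 = 1.5, c_le = 40, p_knee = 2, w_knee = 0.8,
                          w_left = 12, w_right = 8, shape_left = 2,
                          shoulder = NULL, shoulder_floor = 25,
                          shoulder_width = 4,
                          dip_width = 1.2, kink_width = NULL, p_max = 55,
                          noise_sd = 0, seed = 0, n_out = 800, label = "") {
  if (a0 <= 0 || cs_max <= 0) {
    stop(errorCondition("a0 and cs_max must be positive",
      class = c("raftfilm_spec_error", "error")))
  }
  if (!is.null(lift_off) && lift_off <= a0) {
    stop(errorCondition("lift_off must exceed a0",
      class = c("raftfilm_spec_error", "error")))
  }
  if (!is.null(kink) && !is.null(collapse) && collapse <= kink) {
    stop(errorCondition("collapse pressure must lie above the kink",
      class = c("raftfilm_spec_error", "error")))
  }
  if (kink_floor <= 10) {
    stop(errorCondition("kink_floor must stay above the 10 mN/m collapse threshold",
      class = c("raftfilm_spec_error", "error")))
  }
  if (collapse_floor >= 10) {
    stop(errorCondition("collapse_floor must fall below the 10 mN/m threshold",
      class = c("raftfilm_spec_error", "error")))
  }
  if (!is.null(post_collapse_a0) && is.null(collapse)) {
    stop(errorCondition("post_collapse_a0 needs a collapse pressure",
      class = c("raftfilm_spec_error", "error")))
  }
  if (!is.null(post_collapse_a0) && post_collapse_a0 >= a0) {
    stop(errorCondition("post_collapse_a0 must be smaller than a0",
      class = c("raftfilm_spec_error", "error")))
  }
  structure(as.list(environment()), class = "isotherm_spec")
}

# Cs^-1(π) profile of a spec on a pressure grid: gas baseline joined by a
# knee to the expanded level, a generalised-Gaussian condensed rise to the
# peak, and multiplicative troughs for shoulder/kink/collapse features.
cs_profile_of <- function(spec, p) {
  base_of <- function(p) {
    w <- ifelse(p < spec$p_peak, spec$w_left, spec$w_right)
    pl <- ifelse(p < spec$p_peak, spec$shape_left, 2)
    spec$c0 +
      (spec$c_le - spec$c0) / (1 + exp(-(p - spec$p_knee) / spec$w_knee)) +
      (spec$cs_max - spec$c_le) * exp(-abs((p - spec$p_peak) / w)^pl)
  }
  cs <- base_of(p)
  trough <- function(cs, at, floor_val, width) {
    depth <- 1 - floor_val / base_of(at)
    if (depth <= 0) return(cs)
    cs * (1 - depth * exp(-((p - at) / width)^2))
  }
  if (!is.null(spec$shoulder)) {
    cs <- trough(cs, spec$shoulder, spec$shoulder_floor, spec$shoulder_width)
  }
  if (!is.null(spec$kink)) {
    cs <- trough(cs, spec$kink, spec$kink_floor, spec$kink_width %||% spec$dip_width)
  }
  if (!is.null(spec$collapse)) {
    cs <- trough(cs, spec$collapse, spec$collapse_floor, spec$collapse_width %||% spec$dip_width)
  }
  pmax(cs, 0.5)
}

# Noise-free curve for a spec (fine grid), scaled so extract_a0 == a0.
# Returns list(pressure, area, scale).
gen_isotherm_clean <- function(spec) {
  pg <- seq(0, spec$p_max, by = 0.02)
  cs <- cs_profile_of(spec, pg)
  a_unit <- exp(-pracma::cumtrapz(pg, 1 / cs)[, 1])
  # provisional natural scale, then exact calibration via the extractor
  s0 <- spec$lift_off %||% (spec$a0 * 1.6)
  iso0 <- isotherm(area = rev(s0 * a_unit), pressure = rev(pg), label = spec$label)
  a0_hat <- extract_a0(iso0)
  s <- s0 * spec$a0 / a0_hat
  list(pressure = pg, area = s * a_unit, scale = s)
}

#' Generate a synthetic isotherm
#'
#' See [isotherm_spec()] for the construction. Noise-free output reproduces
#' the spec's limiting area within 0.5% and its Cs^-1 maximum within 2% when
#' analysed with [extract_a0()] and [compression_modulus()]; the kink and
#' collapse pressures round-trip through [detect_transitions()].
#'
#' @param spec An [isotherm_spec()].
#' @return An [isotherm()] sampled uniformly in area (compression order).
#' @export
gen_isotherm <- function(spec) {
  stopifnot(inherits(spec, "isotherm_spec"))
  # calibrate c0 to the requested lift-off area (scale is re-anchored to a0
  # each time, so c0 only shifts the lift-off/a0 ratio)
  if (!is.null(spec$lift_off)) {
    f <- function(c0) {
      s2 <- spec
      s2$c0 <- c0
      s2$lift_off <- NULL
      gen_isotherm_clean(s2)$area[1] - spec$lift_off
    }
    c0 <- tryCatch(uniroot(f, c(0.3, spec$c_le), tol = 1e-4)$root, error = function(e) NULL)
    if (is.null(c0)) {
      warning("lift-off target not reachable; keeping default low-pressure compressibility")
    } else {
      spec$c0 <- c0
    }
    spec$lift_off <- NULL
  }
  # calibrate the collapse-trough floor to the post-collapse limiting area:
  # a lower floor lets the film shed more area across the plateau without
  # broadening the trough into the compression-modulus peak
  if (!is.null(spec$post_collapse_a0)) {
    target_ratio <- spec$post_collapse_a0 / spec$a0
    g <- function(fl, wc) {
      s2 <- spec
      s2$collapse_floor <- fl
      s2$collapse_width <- wc
      cl <- gen_isotherm_clean(s2)
      iso <- isotherm(rev(cl$area), rev(cl$pressure))
      a0_post <- extract_a0(iso, segment = c(spec$collapse + 1.5, spec$p_max))
      a0_post / spec$a0 - target_ratio
    }
    done <- FALSE
    for (wc in unique(c(spec$dip_width, 1.6, 2, 2.5, 0.9, 0.7, 0.55))) {
      fl <- tryCatch(
        uniroot(function(x) g(x, wc), c(0.55, 9.8), tol = 1e-4)$root,
        error = function(e) NULL
      )
      if (!is.null(fl)) {
        spec$collapse_floor <- fl
        spec$collapse_width <- wc
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop(errorCondition(
        "post_collapse_a0 target not reachable by deepening the collapse trough",
        class = c("raftfilm_spec_error", "error")
      ))
    }
  }
  cl <- gen_isotherm_clean(spec)
  # sample uniformly in area, as a barrier-driven trough does
  a_out <- seq(cl$area[1], cl$area[length(cl$area)], length.out = spec$n_out)
  p_out <- approx(cl$area, cl$pressure, xout = a_out, ties = mean)$y
  if (spec$noise_sd > 0) {
    p_out <- with_seed(spec$seed, p_out + rnorm(length(p_out), sd = spec$noise_sd))
    p_out <- pmax(p_out, 0)
  }
  iso <- isotherm(
    area = a_out, pressure = p_out,
    label = spec$label
  )
  attr(iso, "spec") <- spec
  iso
}

#' Specification for a synthetic stability trace
#'
#' Stable films relax exponentially from the transfer pressure to a plateau;
#' unstable films (e.g. oxidising unsaturated lipids) lose pressure at a
#' steady rate and never satisfy the plateau rule.
#'
#' @param p0 Initial surface pressure (mN/m), the compression set point.
#' @param plateau Plateau pressure (mN/m) or `NULL` for a non-plateauing
#'   decaying film.
#' @param tau Relaxation time constant in seconds (default 480 s, settling
#'   well within half an hour).
#' @param decay_rate Pressure loss rate in mN/m per hour for non-plateauing
#'   films.
#' @param duration Trace length in seconds (default 4 h).
#' @param dt Sampling interval in seconds.
#' @param noise_sd Gaussian pressure noise (mN/m).
#' @param seed Integer seed.
#' @param label Composition label.
#' @return An object of class `stability_spec`.
#' @export
stability_spec <- function(p0 = 30, plateau = NULL, tau = 480,
                           decay_rate = 1.25, duration = 14400, dt = 5,
                           noise_sd = 0, seed = 0, label = "") {
  structure(as.list(environment()), class = "stability_spec")
}

#' Generate a synthetic surface pressure-time trace
#'
#' @param spec A [stability_spec()].
#' @return A [stability_trace()].
#' @export
gen_stability <- function(spec) {
  stopifnot(inherits(spec, "stability_spec"))
  t <- seq(0, spec$duration, by = spec$dt)
  p <- if (!is.null(spec$plateau)) {
    spec$plateau + (spec$p0 - spec$plateau) * exp(-t / spec$tau)
  } else {
    spec$p0 - spec$decay_rate * t / 3600
  }
  if (spec$noise_sd > 0) {
    p <- with_seed(spec$seed, p + rnorm(length(p), sd = spec$noise_sd))
  }
  stability_trace(time = t, pressure = p, label = spec$label)
}

#' Specification for a synthetic AC-voltammetry curve
#'
#' The capacitance-potential shape mimics a supported bilayer on gold: high
#' capacitance at positive potentials (poorly organised film), a sharp drop
#' near 0 V, a flat minimum of `c_min` near `e_min`, and a rise towards the
#' bare-electrode level at negative potentials as the film lifts off. The
#' integration anchor charge is chosen so that the charge density crosses
#' zero exactly at `pzfc`.
#'
#' @param c_min Minimum capacitance (µF/cm²).
#' @param e_min Potential of the minimum (V).
#' @param pzfc Target potential of zero free charge (V); must lie inside the
#'   sweep.
#' @param c_pos Capacitance level of the positive-potential tail (µF/cm²).
#' @param c_neg Bare-electrode-like level at the negative limit (µF/cm²).
#' @param e_lo,e_hi Sweep limits (V).
#' @param step Potential step (V).
#' @param curvature Parabolic curvature around the minimum (µF/cm²/V²).
#' @param frequency,amplitude AC perturbation (Hz, V rms).
#' @param r_series Series resistance (Ω·cm²) used when synthesising current
#'   components.
#' @param mode `"capacitance"` emits the capacitance column; `"current"`
#'   emits series-RC in-phase/out-of-phase current densities.
#' @param noise_sd Relative Gaussian noise on the capacitance.
#' @param seed Integer seed.
#' @param label Composition label.
#' @return An object of class `acv_spec`.
#' @export
acv_spec <- function(c_min = 3, e_min = -0.2, pzfc = 0.3, c_pos = 15,
                     c_neg = 35, e_lo = -0.8, e_hi = 0.5, step = 0.002,
                     curvature = 25, frequency = 20, amplitude = 0.01,
                     r_series = 100, mode = c("capacitance", "current"),
                     noise_sd = 0, seed = 0, label = "") {
  mode <- match.arg(mode)
  if (pzfc <= e_lo || pzfc >= e_hi) {
    stop(errorCondition("pzfc target outside the sweep",
      class = c("raftfilm_spec_error", "error")))
  }
  if (c_min <= 0) {
    stop(errorCondition("c_min must be positive",
      class = c("raftfilm_spec_error", "error")))
  }
  structure(as.list(environment()), class = "acv_spec")
}

#' Generate a synthetic AC-voltammetry curve
#'
#' @param spec An [acv_spec()].
#' @return An [acv_curve()] carrying the anchor used in construction, so the
#'   [charge_density()]/[find_pzfc()] round trip recovers the spec's pzfc.
#' @export
gen_acv <- function(spec) {
  stopifnot(inherits(spec, "acv_spec"))
  e <- seq(spec$e_lo, spec$e_hi, by = spec$step)
  shape <- spec$c_min +
    (spec$c_pos - spec$c_min) / (1 + exp(-(e - 0.05) / 0.03)) +
    (spec$c_neg - spec$c_min) / (1 + exp((e - (-0.55)) / 0.045)) +
    spec$curvature * (e - spec$e_min)^2
  # re-anchor so the realised minimum inside the packed window equals c_min
  win <- e >= spec$e_min - 0.1 & e <= spec$e_min + 0.1
  cap <- shape - (min(shape[win]) - spec$c_min)
  cap <- pmax(cap, 0.05)
  if (spec$noise_sd > 0) {
    cap <- with_seed(spec$seed, cap * (1 + rnorm(length(cap), sd = spec$noise_sd)))
    cap <- pmax(cap, 0.05)
  }
  # anchor charge chosen so sigma crosses zero at the pzfc target
  sig0 <- pracma::cumtrapz(e, cap)[, 1]
  anchor_sigma <- -approx(e, sig0, xout = spec$pzfc)$y
  if (spec$mode == "capacitance") {
    acv_curve(
      potential = e, capacitance = cap,
      amplitude = spec$amplitude, frequency = spec$frequency,
      anchor_potential = spec$e_lo, anchor_sigma = anchor_sigma,
      label = spec$label
    )
  } else {
    omega <- 2 * base::pi * spec$frequency
    c_f <- cap * 1e-6
    denom <- 1 + (omega * spec$r_series * c_f)^2
    i_out <- spec$amplitude * omega * c_f / denom
    i_in <- spec$amplitude * omega^2 * spec$r_series * c_f^2 / denom
    acv_curve(
      potential = e, i_in = i_in, i_out = i_out,
      amplitude = spec$amplitude, frequency = spec$frequency,
      anchor_potential = spec$e_lo, anchor_sigma = anchor_sigma,
      label = spec$label
    )
  }
}

#' Specification for a synthetic impedance spectrum
#'
#' @param params A [circuit_params()].
#' @param f_min,f_max Frequency range in Hz.
#' @param points_per_decade Log-spaced grid density (>= 5).
#' @param noise_relative Multiplicative complex Gaussian noise fraction.
#' @param seed Integer seed.
#' @param topology Circuit topology, see [circuit_impedance()].
#' @param label Composition label.
#' @return An object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(params, f_min = 0.1, f_max = 1000,
                          points_per_decade = 10, noise_relative = 0,
                          seed = 0, topology = "default", label = "") {
  stopifnot(inherits(params, "circuit_params"))
  if (f_min >= f_max) {
    stop(errorCondition("f_min must be below f_max",
      class = c("raftfilm_spec_error", "error")))
  }
  if (points_per_decade < 5) {
    stop(errorCondition("need at least 5 points per decade",
      class = c("raftfilm_spec_error", "error")))
  }
  structure(as.list(environment()), class = "spectrum_spec")
}

#' Generate a synthetic impedance spectrum
#'
#' Evaluates the equivalent circuit on a log-spaced frequency grid and
#' optionally applies multiplicative complex Gaussian noise,
#' Z -> Z (1 + σ(ε₁ + jε₂)).
#'
#' @param spec A [spectrum_spec()].
#' @return An [impedance_spectrum()].
#' @export
gen_spectrum <- function(spec) {
  stopifnot(inherits(spec, "spectrum_spec"))
  freq <- 10^seq(log10(spec$f_min), log10(spec$f_max), by = 1 / spec$points_per_decade)
  z <- circuit_impedance(spec$params, 2 * base::pi * freq, topology = spec$topology)
  if (spec$noise_relative > 0) {
    z <- with_seed(spec$seed, {
      n <- length(z)
      z * (1 + spec$noise_relative * complex(real = rnorm(n), imaginary = rnorm(n)))
    })
  }
  impedance_spectrum(
    frequency = freq, z_real = Re(z), z_imag = Im(z),
    label = spec$label
  )
}
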