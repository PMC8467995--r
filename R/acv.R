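#' Construct an AC-voltammetry curve
#'
#' Potential-resolved AC response of an electrode-supported bilayer. Either
#' the in-phase/out-of-phase AC current densities (plus the perturbation
#' amplitude and frequency) or a precomputed differential capacitance must be
#' present. Currents and amplitude follow the rms convention of a
#' single-frequency lock-in measurement; peak-convention inputs can be
#' declared via `amplitude_convention` and are converted on construction.
#'
#' @param potential Potential in V vs Ag|AgCl, monotone sweep.
#' @param i_in,i_out In-phase and out-of-phase AC current densities in
#'   A/cm² (rms), or `NULL` when `capacitance` is given.
#' @param capacitance Differential capacitance in µF/cm², or `NULL`.
#' @param amplitude AC perturbation amplitude in V (rms).
#' @param frequency Perturbation frequency in Hz.
#' @param amplitude_convention `"rms"` (default) or `"peak"`; peak values are
#'   divided by sqrt(2).
#' @param anchor_potential,anchor_sigma Optional integration anchor for
#'   [charge_density()]: the potential (V) at which the free charge density
#'   is `anchor_sigma` (µC/cm²). Synthetic curves carry the anchor used in
#'   their construction.
#' @param label Free-text label.
#' @return An object of class `acv_curve`.
#' @export
acv_curve <- function(potential, i_in = NULL, i_out = NULL, capacitance = NULL,
                      amplitude = 0.01, frequency = 20,
                      amplitude_convention = c("rms", "peak"),
                      anchor_potential = NULL, anchor_sigma = 0, label = "") {
  check_numeric(potential, "potential")
  if (is.unsorted(potential) && is.unsorted(rev(potential))) {
    stop_invalid("potential must be a monotone sweep")
  }
  amplitude_convention <- match.arg(amplitude_convention)
  has_cur <- !is.null(i_in) && !is.null(i_out)
  if (!has_cur && is.null(capacitance)) {
    stop_invalid("either both current components or capacitance must be present")
  }
  if (frequency <= 0) stop_invalid("frequency must be positive")
  if (amplitude <= 0) stop_invalid("amplitude must be positive")
  scale <- if (amplitude_convention == "peak") 1 / sqrt(2) else 1
  out <- data.frame(potential = as.numeric(potential))
  if (has_cur) {
    check_numeric(i_in, "i_in")
    check_numeric(i_out, "i_out")
    if (length(i_in) != length(potential) || length(i_out) != length(potential)) {
      stop_invalid("current components must match the potential grid")
    }
    out$i_in <- i_in * scale
    out$i_out <- i_out * scale
  }
  if (!is.null(capacitance)) {
    check_numeric(capacitance, "capacitance", positive = TRUE)
    if (length(capacitance) != length(potential)) {
      stop_invalid("capacitance must match the potential grid")
    }
    out$capacitance <- as.numeric(capacitance)
  }
  structure(out,
    amplitude = amplitude * scale, frequency = frequency,
    anchor_potential = anchor_potential, anchor_sigma = anchor_sigma,
    label = label, class = c("acv_curve", "data.frame")
  )
}

#' @export
print.acv_curve <- function(x, ...) {
  cat(sprintf(
    "<acv_curve>%s %d points, E = [%.2f, %.2f] V, f = %g Hz, E_ac = %g V rms%s\n",
    if (nzchar(attr(x, "label"))) paste0(" ", attr(x, "label"), ":") else "",
    nrow(x), min(x$potential), max(x$potential),
    attr(x, "frequency"), attr(x, "amplitude"),
    if (!is.null(x$capacitance)) {
      sprintf(", C = [%.2f, %.2f] µF/cm²", min(x$capacitance), max(x$capacitance))
    } else " (currents only)"
  ))
  invisible(x)
}

#' Differential capacitance from the AC current components
#'
#' Inverts the series-RC response of the membrane-covered electrode. For a
#' series resistance R and capacitance C driven at angular frequency
#' ω = 2πf with rms amplitude E, the admittance gives in-phase and
#' out-of-phase current densities whose exact inversion is
#' \deqn{C = \frac{i_{in}^2 + i_{out}^2}{\omega E\, i_{out}},}
#' independent of R. The result is exact for any series-RC response, not a
#' small-R approximation.
#'
#' @param curve An [acv_curve()] carrying current components.
#' @return The curve with the `capacitance` column (µF/cm²) filled in.
#' @export
capacitance_from_ac <- function(curve) {
  stopifnot(inherits(curve, "acv_curve"))
  if (is.null(curve$i_in) || is.null(curve$i_out)) {
    stop_invalid("curve carries no current components")
  }
  if (any(curve$i_out <= 0)) {
    stop(errorCondition(
      "out-of-phase current non-positive: no capacitive response to invert",
      class = c("raftfilm_degenerate_response", "error")
    ))
  }
  omega <- 2 * base::pi * attr(curve, "frequency")
  e_ac <- attr(curve, "amplitude")
  c_f <- (curve$i_in^2 + curve$i_out^2) / (omega * e_ac * curve$i_out) # F/cm²
  curve$capacitance <- c_f * 1e6
  curve
}

#' Capacitance minimum within a potential window
#'
#' Locates the minimum of the differential capacitance inside the window
#' where the bilayer is most densely packed. A flat window (degenerate
#' minimum) returns its first grid point and is flagged.
#'
#' @param curve An [acv_curve()] with capacitance present (run
#'   [capacitance_from_ac()] first if needed).
#' @param window Potential window `c(lo, hi)` in V (default `c(-0.3, 0)`).
#' @param c_bare Capacitance of the film-free electrode in µF/cm² (used later
#'   by [coverage()]; default 35).
#' @param c_ideal Capacitance of an ideal defect-free bilayer in µF/cm²
#'   (default 0.8).
#' @return A list of class `coverage_estimate` with `c_min`, `e_at_min`,
#'   `c_bare`, `c_ideal`, `theta` (filled by [coverage()], `NA` here) and
#'   `degenerate` flag.
#' @export
min_capacitance <- function(curve, window = c(-0.3, 0), c_bare = 35,
                            c_ideal = 0.8) {
  stopifnot(inherits(curve, "acv_curve"))
  if (is.null(curve$capacitance)) stop_invalid("capacitance not present; run capacitance_from_ac()")
  lo <- min(window)
  hi <- max(window)
  sel <- which(curve$potential >= lo & curve$potential <= hi)
  if (length(sel) == 0) {
    stop_range(sprintf("window [%.2f, %.2f] V outside the sweep", lo, hi))
  }
  cw <- curve$capacitance[sel]
  ew <- curve$potential[sel]
  degenerate <- diff(range(cw)) < 1e-12
  i <- which.min(cw)
  e_min <- ew[i]
  c_min <- cw[i]
  if (!degenerate && i > 1 && i < length(sel)) {
    e_min <- parabola_vertex(ew[(i - 1):(i + 1)], cw[(i - 1):(i + 1)])
    c_min <- approx(ew, cw, xout = e_min)$y
  }
  structure(list(
    c_min = c_min, e_at_min = e_min, c_bare = c_bare, c_ideal = c_ideal,
    theta = NA_real_, degenerate = degenerate
  ), class = "coverage_estimate")
}

#' Free charge density by integration of the capacitance
#'
#' \eqn{\sigma(E) = \sigma_a + \int_{E_a}^{E} C\,dE'} by the trapezoid rule,
#' with C in µF/cm² and E in V, giving σ in µC/cm². The anchor fixes the
#' integration constant; the potential of zero free charge reported by
#' [find_pzfc()] therefore depends on the anchor choice.
#'
#' @param curve An [acv_curve()] with capacitance.
#' @param anchor_potential Potential (V) where σ is known. Defaults to the
#'   curve's stored anchor, else the most negative sweep potential.
#' @param anchor_sigma σ at the anchor in µC/cm² (default: stored anchor
#'   value, else 0).
#' @return An object of class `charge_profile`: data frame with `potential`
#'   and `sigma`, plus attribute `e_pzfc` (`NA` until [find_pzfc()] is run).
#' @export
charge_density <- function(curve, anchor_potential = NULL, anchor_sigma = NULL) {
  stopifnot(inherits(curve, "acv_curve"))
  if (is.null(curve$capacitance)) stop_invalid("capacitance not present; run capacitance_from_ac()")
  if (is.null(anchor_potential)) anchor_potential <- attr(curve, "anchor_potential")
  if (is.null(anchor_sigma)) anchor_sigma <- attr(curve, "anchor_sigma") %||% 0
  ord <- order(curve$potential)
  e <- curve$potential[ord]
  cc <- curve$capacitance[ord]
  if (is.null(anchor_potential)) anchor_potential <- e[1]
  if (anchor_potential < e[1] || anchor_potential > e[length(e)]) {
    stop_range(sprintf("anchor %.3f V outside the sweep [%.3f, %.3f] V",
      anchor_potential, e[1], e[length(e)]))
  }
  sig <- pracma::cumtrapz(e, cc)[, 1]
  at_anchor <- approx(e, sig, xout = anchor_potential)$y
  sig <- sig - at_anchor + anchor_sigma
  structure(data.frame(potential = e, sigma = sig),
    e_pzfc = NA_real_, anchor_potential = anchor_potential,
    anchor_sigma = anchor_sigma,
    class = c("charge_profile", "data.frame")
  )
}

#' Potential of zero free charge
#'
#' Finds the sign change of the charge density by linear interpolation
#' between the bracketing grid points. When several crossings exist, the one
#' at the most positive potential is returned (the crossing on the
#' desorption-free branch); all crossings are attached as an attribute.
#'
#' @param profile A [charge_density()] result.
#' @return The potential of zero free charge in V, with attribute
#'   `all_crossings`.
#' @export
find_pzfc <- function(profile) {
  stopifnot(inherits(profile, "charge_profile"))
  s <- profile$sigma
  e <- profile$potential
  cross <- numeric(0)
  exact <- which(s == 0)
  cross <- c(cross, e[exact])
  idx <- which(s[-length(s)] * s[-1] < 0)
  for (i in idx) {
    cross <- c(cross, e[i] + (0 - s[i]) * (e[i + 1] - e[i]) / (s[i + 1] - s[i]))
  }
  if (length(cross) == 0) {
    stop_notfound("charge density does not change sign on the sweep")
  }
  cross <- sort(unique(cross))
  structure(max(cross), all_crossings = cross)
}

#' Electrode coverage from the capacitance minimum
#'
#' Two-capacitor mixture model of a defective film: a fraction θ of the
#' electrode is covered by membrane of capacitance `c_ideal` and the rest is
#' bare with capacitance `c_bare`, so
#' \deqn{\theta = \frac{c_{bare} - c_{min}}{c_{bare} - c_{ideal}}.}
#' The simpler uncorrected ratio `1 - c_min/c_bare` is available via
#' `formula = "ratio"`.
#'
#' @param est A [min_capacitance()] result (or any list with `c_min`,
#'   `c_bare`, `c_ideal`).
#' @param formula `"ideal_corrected"` (default) or `"ratio"`.
#' @return The `coverage_estimate` with `theta` filled in (fraction 0-1).
#' @export
coverage <- function(est, formula = c("ideal_corrected", "ratio")) {
  formula <- match.arg(formula)
  c_min <- est$c_min
  c_bare <- est$c_bare
  c_ideal <- est$c_ideal
  if (!(c_bare > c_ideal)) stop_invalid("c_bare must exceed c_ideal")
  if (c_min < c_ideal - 1e-12 || c_min > c_bare + 1e-12) {
    stop_invalid("expected c_ideal <= c_min <= c_bare")
  }
  theta <- switch(formula,
    ideal_corrected = (c_bare - c_min) / (c_bare - c_ideal),
    ratio = 1 - c_min / c_bare
  )
  est$theta <- min(max(theta, 0), 1)
  est
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf(
    "<coverage_estimate> C_min = %.2f µF/cm² at %.3f V (bare %.1f, ideal %.1f)%s%s\n",
    x$c_min, x$e_at_min, x$c_bare, x$c_ideal,
    if (is.na(x$theta)) "" else sprintf(", θ = %.3f", x$theta),
    if (isTRUE(x$degenerate)) " [degenerate: flat window]" else ""
  ))
  invisible(x)
}
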