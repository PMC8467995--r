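#' Construct a surface pressure-area isotherm
#'
#' An `isotherm` holds one compression record of a Langmuir monolayer:
#' area per molecule (Å²/molecule) against surface pressure (mN/m) at fixed
#' temperature. Raw trough exports may arrive unordered, with duplicate area
#' readings and small negative pressure readings from the Wilhelmy sensor;
#' [preprocess_isotherm()] cleans these before any analysis.
#'
#' @param area Numeric vector, area per molecule in Å²/molecule. Strictly
#'   positive and finite.
#' @param pressure Numeric vector, surface pressure in mN/m, same length as
#'   `area`. Values below -0.5 mN/m are rejected; small negatives are
#'   tolerated here and clipped to zero by [preprocess_isotherm()].
#' @param temperature Subphase temperature in degrees Celsius (metadata).
#' @param label Free-text composition label, e.g. `"DOPC:Chol:SM 1:1:1"`.
#' @return An object of class `isotherm`: a data frame with columns `area`
#'   and `pressure` plus `temperature` and `label` attributes.
#' @examples
#' iso <- isotherm(area = seq(100, 40, by = -2), pressure = seq(0, 30))
#' head(iso)
#' @export
isotherm <- function(area, pressure, temperature = 21, label = "") {
  check_numeric(area, "area", positive = TRUE)
  check_numeric(pressure, "pressure")
  if (length(area) != length(pressure)) {
    stop_invalid("area and pressure must have the same length")
  }
  if (length(area) < 10) stop_invalid("an isotherm needs at least 10 points")
  if (any(pressure < -0.5)) {
    stop_invalid("pressure readings below -0.5 mN/m are not plausible sensor noise")
  }
  out <- data.frame(area = as.numeric(area), pressure = as.numeric(pressure))
  structure(out,
    temperature = temperature, label = label, preprocessed = FALSE,
    class = c("isotherm", "data.frame")
  )
}

#' @export
print.isotherm <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf(
    "<isotherm>%s %d points, A = [%.1f, %.1f] Å², π = [%.1f, %.1f] mN/m, T = %s°C%s\n",
    if (nzchar(lab)) paste0(" ", lab, ":") else "", nrow(x),
    min(x$area), max(x$area), min(x$pressure), max(x$pressure),
    format(attr(x, "temperature")),
    if (isTRUE(attr(x, "preprocessed"))) " (preprocessed)" else ""
  ))
  invisible(x)
}

#' Clean and regrid a raw isotherm
#'
#' Sorts the record into compression order (strictly decreasing area),
#' averages duplicate area readings, clips negative sensor pressures to zero
#' and (by default) resamples onto a uniform area grid by linear
#' interpolation. The uniform grid is what makes the smoothed derivative in
#' [compression_modulus()] well behaved.
#'
#' @param raw An [isotherm()].
#' @param grid_step Area grid step in Å²/molecule for resampling; `NULL` or
#'   `NA` skips resampling and keeps the (deduplicated, sorted) raw grid.
#' @return A preprocessed `isotherm`.
#' @export
preprocess_isotherm <- function(raw, grid_step = 0.1) {
  if (!inherits(raw, "isotherm")) {
    raw <- isotherm(raw$area, raw$pressure)
  }
  a <- raw$area
  p <- pmax(raw$pressure, 0)
  if (length(a) < 10) stop_invalid("an isotherm needs at least 10 points")
  # average duplicated area readings
  if (anyDuplicated(a)) {
    p <- as.numeric(tapply(p, a, mean))
    a <- sort(unique(raw$area))
  }
  ord <- order(a, decreasing = TRUE)
  a <- a[ord]
  p <- p[ord]
  if (!is.null(grid_step) && !is.na(grid_step)) {
    if (grid_step <= 0) stop_invalid("grid_step must be positive")
    grid <- seq(max(a), min(a), by = -abs(grid_step))
    if (length(grid) < 10) {
      stop_invalid("grid_step too coarse for the recorded area range")
    }
    p <- approx(a, p, xout = grid, ties = mean)$y
    a <- grid
  }
  structure(data.frame(area = a, pressure = p),
    temperature = attr(raw, "temperature"), label = attr(raw, "label"),
    preprocessed = TRUE, class = c("isotherm", "data.frame")
  )
}

#' Interpolate the area per molecule at a given surface pressure
#'
#' Linear interpolation of A at the requested pressure on the pre-collapse
#' (monotonically rising) branch of the isotherm. When the record contains a
#' collapse plateau, only the rising envelope up to each pressure's first
#' attainment is used, so the answer is unique.
#'
#' @param iso An [isotherm()].
#' @param pi Surface pressure in mN/m at which to interpolate.
#' @return Area per molecule in Å²/molecule.
#' @export
area_at_pressure <- function(iso, pi) {
  if (!inherits(iso, "isotherm")) stop_invalid("iso must be an isotherm")
  if (!isTRUE(attr(iso, "preprocessed"))) iso <- preprocess_isotherm(iso)
  a <- iso$area
  p <- iso$pressure
  # rising envelope along compression: keep the first attainment of each
  # pressure level (strictly increasing running maximum)
  keep <- p > cummax(c(-Inf, p[-length(p)]))
  a <- a[keep]
  p <- p[keep]
  if (length(pi) != 1 || !is.finite(pi)) stop_invalid("pi must be a single finite value")
  if (pi < min(p) || pi > max(p)) {
    stop_range(sprintf(
      "pressure %.3g mN/m outside the recorded rising branch [%.3g, %.3g]",
      pi, min(p), max(p)
    ))
  }
  approx(p, a, xout = pi, ties = mean)$y
}
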