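#' Reciprocal compression modulus along an isotherm
#'
#' Computes the reciprocal of the compression modulus,
#' \deqn{C_s^{-1} = -A \left(\frac{d\pi}{dA}\right)_T,}
#' the standard measure of the in-plane elasticity of a Langmuir monolayer.
#' The derivative is taken on the uniform area grid with a locally smoothed
#' (Savitzky-Golay, window 5, degree 2) differentiator: quadratic local fits
#' give an unbiased derivative for locally parabolic data while suppressing
#' trough noise. End points use the one-sided fits of the same filter.
#'
#' @param iso An [isotherm()]; preprocessed automatically if needed.
#' @param window Odd smoothing window length in grid points (default 5).
#' @return An object of class `compression_profile`: data frame with columns
#'   `pressure`, `area` and `cs_inverse` (all along the compression order),
#'   plus attributes `cs_max` and `pressure_at_cs_max`.
#' @seealso [classify_phase()] for the phase assignment from the maximum,
#'   [detect_transitions()] for kink/collapse detection on the profile.
#' @export
compression_modulus <- function(iso, window = 5) {
  if (!inherits(iso, "isotherm")) stop_invalid("iso must be an isotherm")
  if (!isTRUE(attr(iso, "preprocessed"))) iso <- preprocess_isotherm(iso)
  if (window %% 2 != 1 || window < 3) stop_invalid("window must be odd and >= 3")
  n <- nrow(iso)
  if (n < window) stop_invalid("isotherm shorter than the smoothing window")
  # work on increasing area so the grid step is positive
  a <- rev(iso$area)
  p <- rev(iso$pressure)
  h <- diff(a)
  uniform <- length(unique(round(h / mean(h), 6))) == 1
  if (uniform) {
    dpda <- signal::sgolayfilt(p, p = 2, n = window, m = 1, ts = mean(h))
  } else {
    # non-uniform grid: local quadratic fits around each point
    dpda <- vapply(seq_len(n), function(i) {
      j <- max(1, min(i - (window - 1) / 2, n - window + 1))
      idx <- j:(j + window - 1)
      x <- a[idx] - a[i]
      coef(lm(p[idx] ~ x + I(x^2)))[2]
    }, numeric(1))
  }
  cs <- -a * dpda
  cs <- rev(cs) # back to compression order (decreasing area)
  imax <- which.max(cs)
  structure(
    data.frame(pressure = iso$pressure, area = iso$area, cs_inverse = cs),
    cs_max = cs[imax], pressure_at_cs_max = iso$pressure[imax],
    label = attr(iso, "label"),
    class = c("compression_profile", "data.frame")
  )
}

#' @export
print.compression_profile <- function(x, ...) {
  cat(sprintf(
    "<compression_profile> %d points, Cs^-1 max = %.1f mN/m at π = %.1f mN/m (%s)\n",
    nrow(x), attr(x, "cs_max"), attr(x, "pressure_at_cs_max"),
    classify_phase(max(attr(x, "cs_max"), 0))
  ))
  invisible(x)
}

#' Monolayer phase from the maximum reciprocal compression modulus
#'
#' Standard bins: 0-12.5 mN/m gas (G), 50-100 liquid-expanded (LE), 100-250
#' liquid-condensed (LC), above 250 solid (S). The unnamed 12.5-50 mN/m
#' region is labelled `"G-LE"` (expanded transition regime). Boundaries are
#' lower-edge-inclusive as listed.
#'
#' @param cs_max Maximum reciprocal compression modulus in mN/m (vectorised).
#' @return Character vector of phase labels among `G`, `G-LE`, `LE`, `LC`, `S`.
#' @export
classify_phase <- function(cs_max) {
  check_numeric(cs_max, "cs_max")
  if (any(cs_max < 0)) stop_invalid("cs_max must be non-negative")
  cut(cs_max,
    breaks = c(-Inf, 12.5, 50, 100, 250, Inf),
    labels = c("G", "G-LE", "LE", "LC", "S"),
    right = FALSE, include.lowest = TRUE
  ) -> bin
  # match lower-edge-inclusive convention at 12.5 exactly: cut(right=FALSE)
  # puts 12.5 into G-LE; the G bin is [0, 12.5]
  out <- as.character(bin)
  out[cs_max == 12.5] <- "G"
  out[cs_max == 250] <- "LC"
  out
}

#' Limiting area by extrapolation of the steepest isotherm branch
#'
#' The limiting (zero-pressure) area per molecule A0 is obtained by fitting a
#' line to the steepest contiguous part of the isotherm and extrapolating to
#' zero surface pressure. The steepest part is selected automatically as the
#' contiguous run of points whose reciprocal compression modulus is at least
#' 80% of the segment-local maximum; a `segment` pressure window overrides
#' the automatic choice (e.g. to extrapolate the branch above a partial
#' collapse and obtain the post-collapse limiting area).
#'
#' @param iso An [isotherm()].
#' @param segment Optional pressure window `c(lo, hi)` in mN/m restricting
#'   the search for the steepest branch.
#' @param frac Fraction of the segment-local maximum of Cs^-1 a point must
#'   reach to join the fitted branch (default 0.8).
#' @return Limiting area in Å²/molecule.
#' @export
extract_a0 <- function(iso, segment = NULL, frac = 0.8) {
  if (!inherits(iso, "isotherm")) stop_invalid("iso must be an isotherm")
  if (!isTRUE(attr(iso, "preprocessed"))) iso <- preprocess_isotherm(iso)
  prof <- compression_modulus(iso)
  idx <- seq_len(nrow(prof))
  if (!is.null(segment)) {
    if (length(segment) != 2) stop_invalid("segment must be c(lo, hi) in mN/m")
    idx <- which(prof$pressure >= min(segment) & prof$pressure <= max(segment))
    if (length(idx) < 3) stop_range("segment window contains fewer than 3 points")
  }
  cs <- prof$cs_inverse[idx]
  imax <- idx[which.max(cs)]
  thr <- frac * max(cs)
  # contiguous run around the maximum with cs >= threshold
  lo <- imax
  while (lo - 1 >= min(idx) && prof$cs_inverse[lo - 1] >= thr) lo <- lo - 1
  hi <- imax
  while (hi + 1 <= max(idx) && prof$cs_inverse[hi + 1] >= thr) hi <- hi + 1
  run <- lo:hi
  if (length(run) < 3) run <- max(min(idx), imax - 1):min(max(idx), imax + 1)
  fit <- lm(pressure ~ area, data = prof[run, ])
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope >= 0) {
    stop(errorCondition(
      "no branch with pressure rising under compression found for extrapolation",
      class = c("raftfilm_extraction_error", "error")
    ))
  }
  a0 <- -coef(fit)[[1]] / slope
  unname(a0)
}

#' Detect collapses and kinks on a compression-modulus profile
#'
#' Structural transitions of the monolayer appear as local minima of the
#' reciprocal compression modulus along pressure. A minimum that drops below
#' `collapse_threshold` after the film has already built substantial rigidity
#' marks a (partial) collapse: the film yields at nearly constant pressure. A
#' minimum that stays above the threshold is a kink: a structural
#' reorganization without breakdown of the two-dimensional film. Minimum
#' pressures are refined by local parabolic interpolation.
#'
#' @param profile A [compression_modulus()] result.
#' @param collapse_threshold Cs^-1 level (mN/m) separating collapse from kink
#'   (default 10).
#' @param min_prominence Minimum preceding Cs^-1 maximum, as a fraction of
#'   the global maximum, for a minimum to count as a transition (filters the
#'   shallow wiggles of the low-pressure gas/expanded region).
#' @param min_depth Minimum trough depth in mN/m: the minimum must lie at
#'   least this far (or 4% of the global maximum, whichever is larger) below
#'   the surrounding maxima on both sides, so grid-level ripples on flat
#'   profile stretches are not reported.
#' @return A list with sorted numeric vectors `collapse_pressures` and
#'   `kink_pressures` (either may be empty).
#' @export
detect_transitions <- function(profile, collapse_threshold = 10,
                               min_prominence = 0.25, min_depth = 2) {
  if (!inherits(profile, "compression_profile")) {
    stop_invalid("profile must be a compression_profile")
  }
  cs <- profile$cs_inverse
  p <- profile$pressure
  ord <- order(p)
  cs <- cs[ord]
  p <- p[ord]
  n <- length(cs)
  collapse <- numeric(0)
  collapse_depth <- numeric(0)
  kink <- numeric(0)
  kink_depth <- numeric(0)
  if (n >= 3) {
    gmax <- max(cs)
    runmax_l <- cummax(cs)
    runmax_r <- rev(cummax(rev(cs)))
    depth_need <- max(min_depth, 0.04 * gmax)
    d <- diff(cs)
    # strict interior local minima (falling then rising)
    cand <- which(d[-length(d)] < 0 & d[-1] > 0) + 1
    for (i in cand) {
      if (runmax_l[i] < max(2 * collapse_threshold, min_prominence * gmax)) next
      dep <- min(runmax_l[i], runmax_r[i]) - cs[i]
      if (dep < depth_need) next
      pref <- parabola_vertex(p[(i - 1):(i + 1)], cs[(i - 1):(i + 1)])
      if (cs[i] < collapse_threshold) {
        collapse <- c(collapse, pref)
        collapse_depth <- c(collapse_depth, dep)
      } else {
        kink <- c(kink, pref)
        kink_depth <- c(kink_depth, dep)
      }
    }
  }
  # merge minima closer than 1.5 mN/m (one physical trough), keeping the
  # deepest of each cluster
  merge_close <- function(x, dep) {
    if (length(x) < 2) return(x)
    ordx <- order(x)
    x <- x[ordx]
    dep <- dep[ordx]
    cluster <- cumsum(c(1, diff(x) >= 1.5))
    as.numeric(vapply(split(seq_along(x), cluster), function(idx) {
      x[idx[which.max(dep[idx])]]
    }, numeric(1)))
  }
  list(
    collapse_pressures = sort(merge_close(collapse, collapse_depth)),
    kink_pressures = sort(merge_close(kink, kink_depth))
  )
}

#' Full descriptor set for one isotherm
#'
#' Convenience wrapper running preprocessing, the compression modulus, phase
#' assignment, limiting-area extrapolation, transition detection and the
#' area at a reference pressure.
#'
#' @param iso An [isotherm()].
#' @param grid_step Area grid step passed to [preprocess_isotherm()].
#' @param collapse_threshold Passed to [detect_transitions()].
#' @param a0_window Optional pressure window for [extract_a0()].
#' @param reference_pressure Pressure (mN/m) at which to report the area
#'   (default 30, the bilayer-equivalent packing pressure).
#' @return A list of class `isotherm_features` with elements `A0`,
#'   `A0_post_collapse` (NA when no collapse), `A_at_ref`, `cs_max`,
#'   `pressure_at_cs_max`, `phase`, `collapse_pressures`, `kink_pressures`.
#' @export
isotherm_features <- function(iso, grid_step = 0.1, collapse_threshold = 10,
                              a0_window = NULL, reference_pressure = 30) {
  pre <- preprocess_isotherm(iso, grid_step = grid_step)
  prof <- compression_modulus(pre)
  trans <- detect_transitions(prof, collapse_threshold = collapse_threshold)
  a0 <- extract_a0(pre, segment = a0_window)
  a0_post <- NA_real_
  if (length(trans$collapse_pressures) > 0) {
    pc <- trans$collapse_pressures[1]
    hi <- max(pre$pressure)
    if (hi > pc + 2) {
      a0_post <- tryCatch(
        extract_a0(pre, segment = c(pc + 1.5, hi)),
        error = function(e) NA_real_
      )
    }
  }
  a_ref <- tryCatch(area_at_pressure(pre, reference_pressure),
    error = function(e) NA_real_
  )
  structure(list(
    label = attr(iso, "label"),
    A0 = a0, A0_post_collapse = a0_post, A_at_ref = a_ref,
    reference_pressure = reference_pressure,
    cs_max = attr(prof, "cs_max"),
    pressure_at_cs_max = attr(prof, "pressure_at_cs_max"),
    phase = classify_phase(attr(prof, "cs_max")),
    collapse_pressures = trans$collapse_pressures,
    kink_pressures = trans$kink_pressures
  ), class = "isotherm_features")
}

#' @export
print.isotherm_features <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<isotherm_features>%s\n  A0 = %.1f Å²/molec (post-collapse: %s)\n",
      "  A(π=%g) = %s Å²/molec\n  Cs^-1 max = %.1f mN/m at %.1f mN/m -> %s\n",
      "  collapses: %s | kinks: %s\n"
    ),
    if (nzchar(x$label %||% "")) paste0(" ", x$label) else "",
    x$A0,
    if (is.na(x$A0_post_collapse)) "none" else sprintf("%.1f", x$A0_post_collapse),
    x$reference_pressure,
    if (is.na(x$A_at_ref)) "NA" else sprintf("%.1f", x$A_at_ref),
    x$cs_max, x$pressure_at_cs_max, x$phase,
    if (length(x$collapse_pressures)) paste(sprintf("%.1f", x$collapse_pressures), collapse = ", ") else "none",
    if (length(x$kink_pressures)) paste(sprintf("%.1f", x$kink_pressures), collapse = ", ") else "none"
  ))
  invisible(x)
}
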