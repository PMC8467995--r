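#' Construct a surface pressure-time stability trace
#'
#' Record of the surface pressure of a compressed monolayer held at constant
#' trough area, used to judge whether the film is stable enough to transfer.
#'
#' @param time Time in seconds, strictly increasing.
#' @param pressure Surface pressure in mN/m.
#' @param label Free-text composition label.
#' @return An object of class `stability_trace`.
#' @export
stability_trace <- function(time, pressure, label = "") {
  check_numeric(time, "time")
  check_numeric(pressure, "pressure")
  if (length(time) != length(pressure)) {
    stop_invalid("time and pressure must have the same length")
  }
  if (any(diff(time) <= 0)) stop_invalid("time must be strictly increasing")
  structure(data.frame(time = as.numeric(time), pressure = as.numeric(pressure)),
    label = label, plateau_pressure = NA_real_, drift_rate = NA_real_,
    time_to_plateau = NA_real_,
    class = c("stability_trace", "data.frame")
  )
}

#' Plateau and drift metrics of a stability trace
#'
#' A plateau is declared at the earliest time from which the magnitude of the
#' rolling slope of pressure against time stays below `plateau_tol` for the
#' remainder of the trace. The plateau pressure is the mean pressure over the
#' plateau region; the drift rate is the least-squares slope over the final
#' hour of the record. Films that keep losing pressure (e.g. by oxidation of
#' unsaturated chains) never satisfy the plateau rule and report no plateau.
#'
#' @param trace A [stability_trace()] of at least 30 minutes.
#' @param plateau_tol Rolling-slope tolerance in mN/m per hour (default 0.5).
#' @param slope_window Width of the rolling-slope window in seconds
#'   (default 1200 s = 20 min).
#' @return The trace with attributes `plateau_pressure`, `drift_rate`
#'   (mN/m per hour) and `time_to_plateau` (s) filled in; plateau attributes
#'   stay `NA` when no plateau exists.
#' @export
stability_metrics <- function(trace, plateau_tol = 0.5, slope_window = 1200) {
  if (!inherits(trace, "stability_trace")) {
    stop_invalid("trace must be a stability_trace")
  }
  t <- trace$time
  p <- trace$pressure
  span <- max(t) - min(t)
  if (span < 1800) stop_invalid("stability trace shorter than 30 minutes")
  slope_window <- min(slope_window, span / 2)

  # rolling slopes (mN/m per hour) over windows starting at thinned indices
  starts <- which(t <= max(t) - slope_window)
  if (length(starts) > 400) {
    starts <- starts[unique(round(seq(1, length(starts), length.out = 400)))]
  }
  slopes <- vapply(starts, function(i) {
    j <- which(t >= t[i] & t <= t[i] + slope_window)
    if (length(j) < 3) return(0)
    slope_of(t[j], p[j]) * 3600
  }, numeric(1))

  bad <- which(abs(slopes) >= plateau_tol)
  if (length(bad) == 0) {
    t_plateau <- t[1]
  } else if (max(bad) == length(starts)) {
    t_plateau <- NA_real_
  } else {
    # first window after the last violating one
    t_plateau <- t[starts[max(bad) + 1]]
  }

  plateau_pressure <- if (is.na(t_plateau)) NA_real_ else mean(p[t >= t_plateau])

  last_hour <- t >= max(t) - 3600
  drift <- slope_of(t[last_hour], p[last_hour]) * 3600

  attr(trace, "plateau_pressure") <- plateau_pressure
  attr(trace, "time_to_plateau") <- t_plateau
  attr(trace, "drift_rate") <- drift
  trace
}

slope_of <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' @export
print.stability_trace <- function(x, ...) {
  pl <- attr(x, "plateau_pressure")
  cat(sprintf(
    "<stability_trace>%s %d points over %.1f h%s\n",
    if (nzchar(attr(x, "label"))) paste0(" ", attr(x, "label"), ":") else "",
    nrow(x), (max(x$time) - min(x$time)) / 3600,
    if (is.na(pl)) {
      if (is.na(attr(x, "drift_rate"))) "" else {
        sprintf(", no plateau, drift %.2f mN/m/h", attr(x, "drift_rate"))
      }
    } else {
      sprintf(
        ", plateau %.1f mN/m after %.0f min, drift %.2f mN/m/h",
        pl, attr(x, "time_to_plateau") / 60, attr(x, "drift_rate")
      )
    }
  ))
  invisible(x)
}
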