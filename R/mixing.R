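#' Avogadro constant (1/mol)
#' @keywords internal
AVOGADRO <- 6.02214076e23

# Joint unit factor for the excess Gibbs integral:
# A_exc [Å² -> m², 1e-20] times dπ [mN/m -> N/m, 1e-3] times N_A.
GIBBS_UNIT <- AVOGADRO * 1e-20 * 1e-3

#' Define a multi-component monolayer mixture
#'
#' Bundles the single-component isotherms, their mole fractions and the
#' measured mixture isotherm, the ingredients of the ideal-mixing analysis:
#' ideal area \eqn{A^{id} = \sum_i X_i A_i(\pi)}, excess area
#' \eqn{A^{Exc} = A_{mix} - A^{id}}, excess Gibbs energy
#' \eqn{\Delta G^{Exc} = N_A \int_0^{\pi} A^{Exc}\, d\pi} and percent
#' condensation \eqn{\%A = 100\,(A^{id} - A_{mix})/A^{id}}.
#'
#' @param components List of components, each a list with elements `label`
#'   (character), `isotherm` (an [isotherm()]) and `fraction` (mole
#'   fraction). At least two components; fractions must sum to 1.
#' @param mixture The measured mixture [isotherm()].
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, mixture) {
  if (!is.list(components) || length(components) < 2) {
    stop_invalid("need at least 2 components")
  }
  for (cmp in components) {
    if (!all(c("label", "isotherm", "fraction") %in% names(cmp))) {
      stop_invalid("each component needs label, isotherm and fraction")
    }
    if (!inherits(cmp$isotherm, "isotherm")) {
      stop_invalid("component '", cmp$label, "' is not an isotherm")
    }
    if (!is.numeric(cmp$fraction) || cmp$fraction <= 0) {
      stop_invalid("component '", cmp$label, "' needs a positive mole fraction")
    }
  }
  fr <- vapply(components, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) {
    stop_invalid("mole fractions must sum to 1 (got ", format(sum(fr)), ")")
  }
  if (!inherits(mixture, "isotherm")) stop_invalid("mixture must be an isotherm")
  structure(list(components = components, mixture = mixture),
    class = "mixture_spec"
  )
}

#' @export
print.mixture_spec <- function(x, ...) {
  labs <- vapply(x$components, `[[`, character(1), "label")
  fr <- vapply(x$components, `[[`, numeric(1), "fraction")
  cat(sprintf(
    "<mixture_spec> %s with fractions (%s)\n",
    paste(labs, collapse = ":"), paste(format(fr), collapse = ", ")
  ))
  invisible(x)
}

#' Ideal-mixing area per molecule at a surface pressure
#'
#' Mole-fraction-weighted sum of the component areas interpolated at the
#' requested pressure: the area an ideally mixing (or fully immiscible) film
#' would occupy.
#'
#' @param spec A [mixture_spec()].
#' @param pi Surface pressure in mN/m.
#' @return Ideal area per molecule in Å²/molecule.
#' @export
ideal_area <- function(spec, pi) {
  stopifnot(inherits(spec, "mixture_spec"))
  areas <- vapply(spec$components, function(cmp) {
    tryCatch(area_at_pressure(cmp$isotherm, pi), error = function(e) {
      stop_range(
        "component '", cmp$label, "' not interpolable at ",
        format(pi), " mN/m: ", conditionMessage(e)
      )
    })
  }, numeric(1))
  fr <- vapply(spec$components, `[[`, numeric(1), "fraction")
  sum(fr * areas)
}

#' Excess area of mixing at a surface pressure
#'
#' Measured mixture area minus the ideal-mixing area. Negative values signal
#' attractive interactions/condensation; positive values signal repulsive
#' interactions or domain separation.
#'
#' @inheritParams ideal_area
#' @return Excess area in Å²/molecule (signed).
#' @export
excess_area <- function(spec, pi) {
  stopifnot(inherits(spec, "mixture_spec"))
  a_mix <- tryCatch(area_at_pressure(spec$mixture, pi), error = function(e) {
    stop_range("mixture not interpolable at ", format(pi), " mN/m: ", conditionMessage(e))
  })
  a_mix - ideal_area(spec, pi)
}

#' Excess Gibbs energy of mixing up to a surface pressure
#'
#' Trapezoidal integration of the excess area over pressure from 0 to
#' `pi_max`, converted to J/mol:
#' \eqn{\Delta G^{Exc} = N_A \int_0^{\pi} A^{Exc} d\pi} with areas in Å²
#' (1 Å² = 1e-20 m²) and pressures in mN/m (1 mN/m = 1e-3 N/m). A constant
#' excess area of 1 Å² integrated to 30 mN/m therefore gives
#' 6.022e23 × 1e-20 × 30e-3 ≈ 180.7 J/mol.
#'
#' @inheritParams ideal_area
#' @param pi_max Upper integration limit in mN/m.
#' @param grid Pressure grid step in mN/m for the integrand (default 0.5).
#' @return Excess Gibbs energy in J/mol.
#' @export
excess_gibbs <- function(spec, pi_max, grid = 0.5) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (pi_max < 0) stop_invalid("pi_max must be non-negative")
  if (pi_max == 0) return(0)
  pgrid <- seq(0, pi_max, by = grid)
  if (pgrid[length(pgrid)] < pi_max) pgrid <- c(pgrid, pi_max)
  aexc <- vapply(pgrid, function(pp) excess_area(spec, pp), numeric(1))
  GIBBS_UNIT * pracma::trapz(pgrid, aexc)
}

#' Percent condensation of a mixed monolayer
#'
#' \eqn{\%A = 100 (A^{id} - A_{mix}) / A^{id}}: positive when the mixture is
#' more condensed (smaller) than ideal mixing predicts, negative when it is
#' expanded (e.g. by domain separation).
#'
#' @inheritParams ideal_area
#' @return Percent condensation (may be negative).
#' @export
percent_condensation <- function(spec, pi) {
  stopifnot(inherits(spec, "mixture_spec"))
  a_id <- ideal_area(spec, pi)
  a_mix <- tryCatch(area_at_pressure(spec$mixture, pi), error = function(e) {
    stop_range("mixture not interpolable at ", format(pi), " mN/m: ", conditionMessage(e))
  })
  100 * (a_id - a_mix) / a_id
}

#' Excess-quantity sweep over surface pressures
#'
#' Evaluates ideal area, excess area, cumulative excess Gibbs energy and
#' percent condensation at each requested pressure.
#'
#' @inheritParams excess_gibbs
#' @param pressures Numeric vector of surface pressures in mN/m.
#' @return A data frame of class `mixing_result` with columns `pressure`,
#'   `a_ideal`, `a_excess`, `g_excess` and `percent_condensation`.
#' @export
excess_sweep <- function(spec, pressures, grid = 0.5) {
  stopifnot(inherits(spec, "mixture_spec"))
  pressures <- sort(pressures)
  rows <- lapply(pressures, function(pp) {
    tryCatch(
      {
        a_id <- ideal_area(spec, pp)
        a_exc <- excess_area(spec, pp)
        data.frame(
          pressure = pp, a_ideal = a_id, a_excess = a_exc,
          g_excess = excess_gibbs(spec, pp, grid = grid),
          percent_condensation = 100 * (-a_exc) / a_id
        )
      },
      raftfilm_out_of_range = function(e) {
        stop_range("at π = ", format(pp), " mN/m: ", conditionMessage(e))
      }
    )
  })
  structure(do.call(rbind, rows), class = c("mixing_result", "data.frame"))
}
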