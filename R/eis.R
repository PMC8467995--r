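#' Constant-phase-element impedance
#'
#' \deqn{Z_{CPE}(\omega) = \frac{1}{Q (j\omega)^{\alpha}}} with Q in
#' µF cm^-2 s^(α-1) (the convention of impedance tables for supported
#' bilayers) and ω in rad/s, giving Z in Ω·cm². The modulus is
#' 1/(Q ω^α) and the phase is constant at -α·90°; α = 1 is an ideal
#' capacitor, α → 0 approaches a resistor of value 1/Q.
#'
#' @param q CPE magnitude in µF cm^-2 s^(α-1), > 0.
#' @param alpha CPE exponent in (0, 1].
#' @param omega Angular frequency in rad/s (vectorised), > 0.
#' @return Complex impedance in Ω·cm².
#' @export
cpe_impedance <- function(q, alpha, omega) {
  if (!is.numeric(q) || q <= 0) stop_invalid("q must be > 0")
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop_invalid("alpha must be in (0, 1]")
  }
  check_numeric(omega, "omega", positive = TRUE)
  1 / ((q * 1e-6) * (1i * omega)^alpha)
}

#' Equivalent-circuit parameters for a supported bilayer
#'
#' The five elements of the solution/membrane/spacer network: solution
#' resistance in series with the membrane CPE, which is in parallel with the
#' series combination of the membrane resistance and the submembrane
#' (water-spacer) CPE.
#'
#' @param r_sol Solution resistance in Ω·cm².
#' @param r_m Membrane resistance in kΩ·cm² (may be `Inf` for a blocking
#'   membrane).
#' @param q_m Membrane CPE magnitude in µF cm^-2 s^(α-1).
#' @param alpha_m Membrane CPE exponent in (0, 1].
#' @param q_sp Spacer CPE magnitude in µF cm^-2 s^(α-1), or `NULL` when the
#'   spacer branch is absent.
#' @param alpha_sp Spacer CPE exponent in (0, 1].
#' @return An object of class `circuit_params`.
#' @export
circuit_params <- function(r_sol, r_m, q_m, alpha_m, q_sp = NULL, alpha_sp = NULL) {
  if (r_sol <= 0) stop_invalid("r_sol must be > 0")
  if (r_m <= 0) stop_invalid("r_m must be > 0")
  if (q_m <= 0) stop_invalid("q_m must be > 0")
  if (alpha_m <= 0 || alpha_m > 1) stop_invalid("alpha_m must be in (0, 1]")
  if (!is.null(q_sp)) {
    if (q_sp <= 0) stop_invalid("q_sp must be > 0")
    if (is.null(alpha_sp) || alpha_sp <= 0 || alpha_sp > 1) {
      stop_invalid("alpha_sp must be in (0, 1]")
    }
  }
  structure(list(
    r_sol = r_sol, r_m = r_m, q_m = q_m, alpha_m = alpha_m,
    q_sp = q_sp, alpha_sp = alpha_sp
  ), class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf(
    "<circuit_params> R_sol = %.3g Ω·cm², R_m = %.4g kΩ·cm², Q_m = %.3g µF·cm⁻²·s^(α−1) (α = %.2f)%s\n",
    x$r_sol, x$r_m, x$q_m, x$alpha_m,
    if (is.null(x$q_sp)) ", no spacer branch" else {
      sprintf(", Q_sp = %.3g µF·cm⁻²·s^(α−1) (α = %.2f)", x$q_sp, x$alpha_sp)
    }
  ))
  invisible(x)
}

#' Impedance of the supported-bilayer equivalent circuit
#'
#' Default topology (a hydrated water spacer under the membrane):
#' \deqn{Z(\omega) = R_{sol} + Z_{Q_m} \parallel (R_m + Z_{Q_{sp}}).}
#' The alternative nested topology
#' \eqn{R_{sol} + (Z_{Q_m} \parallel R_m) + Z_{Q_{sp}}} treats the spacer as
#' a series blocking element and is selectable via `topology = "alt"`.
#'
#' @param p A [circuit_params()].
#' @param omega Angular frequency in rad/s (vectorised).
#' @param topology `"default"` or `"alt"`.
#' @return Complex impedance in Ω·cm².
#' @export
circuit_impedance <- function(p, omega, topology = c("default", "alt")) {
  stopifnot(inherits(p, "circuit_params"))
  topology <- match.arg(topology)
  check_numeric(omega, "omega", positive = TRUE)
  z_qm <- cpe_impedance(p$q_m, p$alpha_m, omega)
  r_m <- p$r_m * 1e3 # kΩ·cm² -> Ω·cm²
  if (topology == "default") {
    branch <- if (is.null(p$q_sp)) {
      rep(r_m, length(omega))
    } else {
      r_m + cpe_impedance(p$q_sp, p$alpha_sp, omega)
    }
    if (all(is.infinite(branch))) return(p$r_sol + z_qm)
    p$r_sol + 1 / (1 / z_qm + 1 / branch)
  } else {
    zpar <- if (is.infinite(r_m)) z_qm else 1 / (1 / z_qm + 1 / r_m)
    zsp <- if (is.null(p$q_sp)) 0 else cpe_impedance(p$q_sp, p$alpha_sp, omega)
    p$r_sol + zpar + zsp
  }
}

#' Construct an impedance spectrum
#'
#' Frequency-resolved complex impedance of the membrane-covered electrode,
#' area-normalised (Ω·cm²). The imaginary part is signed: capacitive
#' responses have negative `z_imag`.
#'
#' @param frequency Frequency in Hz, strictly positive, ascending or
#'   descending.
#' @param z_real,z_imag Real and imaginary impedance in Ω·cm².
#' @param label Free-text label.
#' @return An object of class `impedance_spectrum`.
#' @export
impedance_spectrum <- function(frequency, z_real, z_imag, label = "") {
  if (length(frequency) < 2) stop_invalid("a spectrum needs at least 2 frequencies")
  check_numeric(frequency, "frequency", positive = TRUE)
  check_numeric(z_real, "z_real")
  check_numeric(z_imag, "z_imag")
  if (length(z_real) != length(frequency) || length(z_imag) != length(frequency)) {
    stop_invalid("z_real and z_imag must match the frequency grid")
  }
  phase <- atan2(z_imag, z_real) * 180 / base::pi
  if (any(abs(phase) >= 90)) {
    stop_invalid("phase angle outside (-90°, 90°): not a passive one-port response")
  }
  lf <- log10(frequency)
  if (diff(range(lf)) > 0) {
    ppd <- (length(frequency) - 1) / diff(range(lf))
    if (ppd < 5) {
      warning("fewer than 5 frequencies per decade; fits may be poorly conditioned")
    }
  }
  structure(
    data.frame(frequency = as.numeric(frequency), z_real = z_real, z_imag = z_imag),
    label = label, class = c("impedance_spectrum", "data.frame")
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  cat(sprintf(
    "<impedance_spectrum>%s %d points, f = [%g, %g] Hz, |Z| = [%.3g, %.3g] Ω·cm²\n",
    if (nzchar(attr(x, "label"))) paste0(" ", attr(x, "label"), ":") else "",
    nrow(x), min(x$frequency), max(x$frequency),
    min(Mod(complex(real = x$z_real, imaginary = x$z_imag))),
    max(Mod(complex(real = x$z_real, imaginary = x$z_imag)))
  ))
  invisible(x)
}

#' Bode representation of an impedance spectrum
#'
#' @param spec An [impedance_spectrum()].
#' @return Data frame with `frequency`, `log10_modulus` (log10 of |Z| in
#'   Ω·cm²) and `phase_deg` (negative for capacitive responses).
#' @export
to_bode <- function(spec) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  z <- complex(real = spec$z_real, imaginary = spec$z_imag)
  if (any(Mod(z) == 0)) stop_invalid("zero impedance modulus")
  data.frame(
    frequency = spec$frequency,
    log10_modulus = log10(Mod(z)),
    phase_deg = atan2(spec$z_imag, spec$z_real) * 180 / base::pi
  )
}

# Pack/unpack the free parameters for the optimizer: magnitudes on log scale,
# exponents raw (box-constrained).
pack_params <- function(p) {
  v <- c(log(p$r_sol), log(p$r_m), log(p$q_m), p$alpha_m)
  if (!is.null(p$q_sp)) v <- c(v, log(p$q_sp), p$alpha_sp)
  names(v) <- c("log_r_sol", "log_r_m", "log_q_m", "alpha_m",
    if (!is.null(p$q_sp)) c("log_q_sp", "alpha_sp"))
  v
}

unpack_params <- function(v) {
  has_sp <- length(v) == 6
  v <- pmin(pmax(v, -600), 600) # keep exp() finite during line searches
  circuit_params(
    r_sol = exp(v[[1]]), r_m = exp(v[[2]]), q_m = exp(v[[3]]),
    alpha_m = min(max(v[[4]], 1e-3), 1),
    q_sp = if (has_sp) exp(v[[5]]) else NULL,
    alpha_sp = if (has_sp) min(max(v[[6]], 1e-3), 1) else NULL
  )
}

# Model impedance and its analytic Jacobian with respect to the packed
# parameters (complex dZ/dθ per frequency). The analytic Jacobian matters:
# the spacer CPE contributes well under 1% of |Z| on realistic spectra, and
# finite-difference derivatives lose that signal in truncation noise.
circuit_model_grad <- function(v, omega, topology = "default") {
  p <- unpack_params(v)
  has_sp <- !is.null(p$q_sp)
  s_pow <- function(alpha) (1i * omega)^alpha
  lns <- log(omega) + 1i * base::pi / 2
  r_m <- p$r_m * 1e3
  ym <- (p$q_m * 1e-6) * s_pow(p$alpha_m)
  if (topology == "default") {
    if (has_sp) {
      zqsp <- 1 / ((p$q_sp * 1e-6) * s_pow(p$alpha_sp))
      b <- r_m + zqsp
    } else {
      zqsp <- NULL
      b <- rep(r_m, length(omega))
    }
    yb <- 1 / b
    d <- ym + yb
    pz <- 1 / d
    z <- p$r_sol + pz
    dfac <- -pz^2
    jac <- cbind(
      rep(p$r_sol + 0i, length(omega)),
      dfac * (-(1 / b)^2 * r_m),
      dfac * ym,
      dfac * ym * lns,
      if (has_sp) dfac * (1 / b)^2 * zqsp,
      if (has_sp) dfac * (1 / b)^2 * zqsp * lns
    )
  } else {
    grm <- 1 / r_m
    d <- ym + grm
    pz <- 1 / d
    zqsp <- if (has_sp) 1 / ((p$q_sp * 1e-6) * s_pow(p$alpha_sp)) else 0
    z <- p$r_sol + pz + zqsp
    dfac <- -pz^2
    jac <- cbind(
      rep(p$r_sol + 0i, length(omega)),
      dfac * (-grm),
      dfac * ym,
      dfac * ym * lns,
      if (has_sp) -zqsp,
      if (has_sp) -zqsp * lns
    )
  }
  list(z = z, jac = jac)
}

# One bounded Levenberg-Marquardt run on a frequency subset with the
# analytic Jacobian; `free` indexes the packed parameters being varied.
lm_run <- function(v0, free, z_obs, omega, w, topology, max_iter) {
  lower <- rep(-Inf, length(v0))
  upper <- rep(Inf, length(v0))
  ia <- grep("^alpha", names(v0))
  lower[ia] <- 1e-3
  upper[ia] <- 1
  vfull <- v0
  fit <- minpack.lm::nls.lm(
    par = v0[free], lower = lower[free], upper = upper[free],
    fn = function(vf) {
      vfull[free] <- vf
      mg <- circuit_model_grad(vfull, omega, topology)
      c(w * (Re(mg$z) - Re(z_obs)), w * (Im(mg$z) - Im(z_obs)))
    },
    jac = function(vf) {
      vfull[free] <- vf
      mg <- circuit_model_grad(vfull, omega, topology)
      j <- mg$jac[, free, drop = FALSE]
      rbind(w * Re(j), w * Im(j))
    },
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0
    )
  )
  vfull[free] <- fit$par
  list(par = vfull, fit = fit)
}

resid_weights <- function(z_obs, weighting) {
  switch(weighting,
    modulus = {
      w <- 1 / Mod(z_obs)
      cbind(w, w)
    },
    unit = cbind(rep(1, length(z_obs)), rep(1, length(z_obs))),
    proportional = cbind(
      1 / pmax(abs(Re(z_obs)), 1e-12),
      1 / pmax(abs(Im(z_obs)), 1e-12)
    )
  )
}

#' Complex nonlinear least-squares fit of the equivalent circuit
#'
#' Fits the supported-bilayer circuit to a measured spectrum by minimising
#' the weighted sum of squared real and imaginary residuals,
#' \eqn{\sum_i w_i (\Delta Z_{re,i}^2 + \Delta Z_{im,i}^2)}, with modulus
#' weighting \eqn{w_i = 1/|Z_i|^2} by default (each point contributes its
#' relative error, appropriate for spectra spanning decades of impedance).
#' Magnitudes are optimised on the log scale (positivity by construction)
#' and CPE exponents are box-constrained to (0, 1], using bounded
#' Levenberg-Marquardt least squares. Standard errors come from the local
#' curvature (Gauss-Newton J'J) at the optimum, transformed back to the
#' natural scale.
#'
#' @param spec An [impedance_spectrum()].
#' @param init A [circuit_params()] starting point.
#' @param weighting `"modulus"` (default), `"unit"` or `"proportional"`.
#' @param topology Circuit topology, see [circuit_impedance()].
#' @param max_iter Maximum optimizer iterations per stage (default 200).
#' @param staged If `TRUE` (default) and the circuit has a spacer branch,
#'   precede the joint fit with two conditioning stages: solution resistance
#'   and membrane CPE on the high-frequency points, then membrane resistance
#'   and spacer CPE on the low-frequency points. This is the standard guard
#'   against the "vanishing spacer" local minimum of the joint problem; the
#'   plain joint fit from `init` is also run and the better optimum kept.
#' @param f_split Frequency (Hz) separating the two conditioning stages.
#' @return An object of class `fit_result`: list with `params`
#'   (circuit_params), `stderr` (named, natural scale; `NA` when the
#'   curvature is singular), `residual_norm` (weighted), `residuals`
#'   (per-frequency complex), `converged`, `iterations`, `weighting`,
#'   `topology`.
#' @export
cnls_fit <- function(spec, init, weighting = c("modulus", "unit", "proportional"),
                     topology = c("default", "alt"), max_iter = 200,
                     staged = TRUE, f_split = 10) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  stopifnot(inherits(init, "circuit_params"))
  weighting <- match.arg(weighting)
  topology <- match.arg(topology)
  z_obs <- complex(real = spec$z_real, imaginary = spec$z_imag)
  omega <- 2 * base::pi * spec$frequency
  v0 <- pack_params(init)
  npar <- length(v0)
  if (2 * length(z_obs) < 2 * npar) {
    stop_invalid("need at least as many complex points as free parameters")
  }
  w2 <- resid_weights(z_obs, weighting)
  # the analytic-Jacobian machinery uses one weight per point; fold the
  # proportional variant's two weights into their geometric mean
  w <- sqrt(w2[, 1] * w2[, 2])

  resid_norm2 <- function(v) {
    mg <- circuit_model_grad(v, omega, topology)
    sum((w * (Re(mg$z) - Re(z_obs)))^2 + (w * (Im(mg$z) - Im(z_obs)))^2)
  }

  # plain joint fit from the supplied start
  joint <- lm_run(v0, seq_len(npar), z_obs, omega, w, topology, max_iter)
  best <- joint
  niter <- joint$fit$niter

  hi <- spec$frequency >= f_split
  if (staged && npar == 6 && sum(hi) >= 4 && sum(!hi) >= 4) {
    s1 <- lm_run(v0, c(1, 3, 4), z_obs[hi], omega[hi], w[hi], topology, max_iter)
    s2 <- lm_run(s1$par, c(2, 5, 6), z_obs[!hi], omega[!hi], w[!hi], topology, max_iter)
    s3 <- lm_run(s2$par, seq_len(npar), z_obs, omega, w, topology, max_iter)
    niter <- niter + s1$fit$niter + s2$fit$niter + s3$fit$niter
    if (resid_norm2(s3$par) < resid_norm2(joint$par)) best <- s3
  }

  fit <- best$fit
  converged <- fit$info %in% 1:4
  v <- best$par
  params <- unpack_params(v)
  rnorm2 <- resid_norm2(v)
  # natural-scale standard errors via the delta method on the log
  # parameters, from the Gauss-Newton curvature J'J at the optimum
  se <- rep(NA_real_, npar)
  dof <- 2 * length(z_obs) - npar
  if (dof > 0) {
    mg <- circuit_model_grad(v, omega, topology)
    jn <- rbind(w * Re(mg$jac), w * Im(mg$jac))
    s2 <- rnorm2 / dof
    cov <- tryCatch(solve(crossprod(jn)) * s2, error = function(e) NULL)
    if (!is.null(cov) && all(is.finite(diag(cov))) && all(diag(cov) >= 0)) {
      se <- sqrt(diag(cov))
      mag <- grep("^log_", names(v0))
      nat <- exp(v[mag])
      se[mag] <- se[mag] * nat # d(exp(x)) = exp(x) dx
    }
  }
  names(se) <- sub("^log_", "", names(v0))
  if (!converged) {
    warning("CNLS fit did not converge (info = ", fit$info, "); returning best-so-far")
  }
  z_fit <- circuit_impedance(params, omega, topology = topology)
  structure(list(
    params = params, stderr = se, residual_norm = sqrt(rnorm2),
    residuals = z_fit - z_obs, converged = converged,
    iterations = niter, weighting = weighting, topology = topology
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
    sprintf("after %d iterations (%s weighting, %s topology)\n",
      x$iterations, x$weighting, x$topology))
  p <- x$params
  vals <- c(r_sol = p$r_sol, r_m = p$r_m, q_m = p$q_m, alpha_m = p$alpha_m)
  if (!is.null(p$q_sp)) vals <- c(vals, q_sp = p$q_sp, alpha_sp = p$alpha_sp)
  for (nm in names(vals)) {
    cat(sprintf("  %-8s %.5g ± %s\n", nm, vals[[nm]],
      if (is.na(x$stderr[[nm]])) "NA" else sprintf("%.3g", x$stderr[[nm]])))
  }
  cat(sprintf("  weighted residual norm %.4g\n", x$residual_norm))
  invisible(x)
}

#' Goodness-of-fit diagnostics for a circuit model
#'
#' @param spec An [impedance_spectrum()].
#' @param p A [circuit_params()].
#' @param weighting Residual weighting, see [cnls_fit()].
#' @param topology Circuit topology.
#' @return List with `chisq_per_point` (mean weighted squared residual) and
#'   `max_phase_residual_deg`.
#' @export
goodness <- function(spec, p, weighting = c("modulus", "unit", "proportional"),
                     topology = c("default", "alt")) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  stopifnot(inherits(p, "circuit_params"))
  weighting <- match.arg(weighting)
  topology <- match.arg(topology)
  if (nrow(spec) == 0) stop_invalid("empty spectrum")
  z_obs <- complex(real = spec$z_real, imaginary = spec$z_imag)
  omega <- 2 * base::pi * spec$frequency
  z_fit <- circuit_impedance(p, omega, topology = topology)
  w <- resid_weights(z_obs, weighting)
  chisq <- mean((w[, 1] * (Re(z_fit) - Re(z_obs)))^2 +
    (w[, 2] * (Im(z_fit) - Im(z_obs)))^2)
  ph_obs <- atan2(Im(z_obs), Re(z_obs)) * 180 / base::pi
  ph_fit <- atan2(Im(z_fit), Re(z_fit)) * 180 / base::pi
  list(
    chisq_per_point = chisq,
    max_phase_residual_deg = max(abs(ph_fit - ph_obs))
  )
}
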