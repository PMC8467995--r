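# CSV dialects ---------------------------------------------------------------

read_header_meta <- function(path) {
  lines <- readLines(path, n = 20, warn = FALSE)
  meta <- list()
  for (ln in grep("^#", lines, value = TRUE)) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.+)$", ln))[[1]]
    if (length(m) == 3) {
      v <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(v)) m[3] else v
    }
  }
  meta
}

#' Read an isotherm CSV
#'
#' Columns `area_A2,pressure_mN_m`, one header row; an optional
#' `# temperature_C: 21` comment line is honoured.
#'
#' @param path File path.
#' @param label Label for the isotherm (defaults to the file name).
#' @return An [isotherm()].
#' @export
read_isotherm_csv <- function(path, label = basename(path)) {
  meta <- read_header_meta(path)
  d <- read.csv(path, comment.char = "#")
  need <- c("area_A2", "pressure_mN_m")
  if (!all(need %in% names(d))) {
    stop_invalid("isotherm CSV needs columns ", paste(need, collapse = ","))
  }
  isotherm(d$area_A2, d$pressure_mN_m,
    temperature = meta$temperature_C %||% 21, label = label
  )
}

#' Write an isotherm CSV
#' @param iso An [isotherm()].
#' @param path File path.
#' @export
write_isotherm_csv <- function(iso, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_C: %s", format(attr(iso, "temperature"))), con)
  writeLines("area_A2,pressure_mN_m", con)
  writeLines(sprintf("%.6g,%.6g", iso$area, iso$pressure), con)
  invisible(path)
}

#' Read a stability-trace CSV (columns `time_s,pressure_mN_m`)
#' @inheritParams read_isotherm_csv
#' @return A [stability_trace()].
#' @export
read_stability_csv <- function(path, label = basename(path)) {
  d <- read.csv(path, comment.char = "#")
  need <- c("time_s", "pressure_mN_m")
  if (!all(need %in% names(d))) {
    stop_invalid("stability CSV needs columns ", paste(need, collapse = ","))
  }
  stability_trace(d$time_s, d$pressure_mN_m, label = label)
}

#' Write a stability-trace CSV
#' @param trace A [stability_trace()].
#' @param path File path.
#' @export
write_stability_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,pressure_mN_m", con)
  writeLines(sprintf("%.6g,%.6g", trace$time, trace$pressure), con)
  invisible(path)
}

#' Read an AC-voltammetry CSV
#'
#' Either `potential_V,i_in_A_cm2,i_out_A_cm2` with comment lines
#' `# frequency_Hz: 20` and `# amplitude_V_rms: 0.01`, or
#' `potential_V,capacitance_uF_cm2`.
#'
#' @inheritParams read_isotherm_csv
#' @return An [acv_curve()].
#' @export
read_acv_csv <- function(path, label = basename(path)) {
  meta <- read_header_meta(path)
  d <- read.csv(path, comment.char = "#")
  freq <- meta$frequency_Hz %||% 20
  amp <- meta$amplitude_V_rms %||% 0.01
  anchor_e <- meta$anchor_potential_V
  anchor_s <- meta$anchor_sigma_uC_cm2 %||% 0
  if (all(c("potential_V", "i_in_A_cm2", "i_out_A_cm2") %in% names(d))) {
    acv_curve(d$potential_V,
      i_in = d$i_in_A_cm2, i_out = d$i_out_A_cm2,
      amplitude = amp, frequency = freq, label = label,
      anchor_potential = anchor_e, anchor_sigma = anchor_s
    )
  } else if (all(c("potential_V", "capacitance_uF_cm2") %in% names(d))) {
    acv_curve(d$potential_V,
      capacitance = d$capacitance_uF_cm2,
      amplitude = amp, frequency = freq, label = label,
      anchor_potential = anchor_e, anchor_sigma = anchor_s
    )
  } else {
    stop_invalid(
      "ACV CSV needs potential_V plus either i_in_A_cm2,i_out_A_cm2 or capacitance_uF_cm2"
    )
  }
}

#' Write an AC-voltammetry CSV
#' @param curve An [acv_curve()].
#' @param path File path.
#' @export
write_acv_csv <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frequency_Hz: %g", attr(curve, "frequency")), con)
  writeLines(sprintf("# amplitude_V_rms: %g", attr(curve, "amplitude")), con)
  if (!is.null(attr(curve, "anchor_potential"))) {
    writeLines(sprintf("# anchor_potential_V: %.8g", attr(curve, "anchor_potential")), con)
    writeLines(sprintf("# anchor_sigma_uC_cm2: %.8g", attr(curve, "anchor_sigma") %||% 0), con)
  }
  if (!is.null(curve$i_in)) {
    writeLines("potential_V,i_in_A_cm2,i_out_A_cm2", con)
    writeLines(sprintf("%.8g,%.8g,%.8g", curve$potential, curve$i_in, curve$i_out), con)
  } else {
    writeLines("potential_V,capacitance_uF_cm2", con)
    writeLines(sprintf("%.8g,%.8g", curve$potential, curve$capacitance), con)
  }
  invisible(path)
}

#' Read an impedance-spectrum CSV
#'
#' Columns `frequency_Hz,z_real_ohm_cm2,z_imag_ohm_cm2`; `z_imag` is signed
#' (capacitive negative).
#'
#' @inheritParams read_isotherm_csv
#' @return An [impedance_spectrum()].
#' @export
read_eis_csv <- function(path, label = basename(path)) {
  d <- read.csv(path, comment.char = "#")
  need <- c("frequency_Hz", "z_real_ohm_cm2", "z_imag_ohm_cm2")
  if (!all(need %in% names(d))) {
    stop_invalid("EIS CSV needs columns ", paste(need, collapse = ","))
  }
  impedance_spectrum(d$frequency_Hz, d$z_real_ohm_cm2, d$z_imag_ohm_cm2,
    label = label
  )
}

#' Write an impedance-spectrum CSV
#' @param spec An [impedance_spectrum()].
#' @param path File path.
#' @export
write_eis_csv <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("frequency_Hz,z_real_ohm_cm2,z_imag_ohm_cm2", con)
  writeLines(sprintf("%.8g,%.8g,%.8g", spec$frequency, spec$z_real, spec$z_imag), con)
  invisible(path)
}

# Input validation ------------------------------------------------------------

csv_schema <- list(
  isotherm = c("area_A2", "pressure_mN_m"),
  stability = c("time_s", "pressure_mN_m"),
  acv = c("potential_V"),
  eis = c("frequency_Hz", "z_real_ohm_cm2", "z_imag_ohm_cm2")
)

#' Validate input CSV files against the module dialects
#'
#' Per-file schema check with line-numbered diagnostics; never throws —
#' problems are the output.
#'
#' @param paths Character vector of file paths.
#' @param dialects Character vector (recycled) naming the expected dialect of
#'   each file: `"isotherm"`, `"stability"`, `"acv"` or `"eis"`.
#' @return A data frame with columns `file`, `line`, `severity`, `message`;
#'   zero rows means all files passed.
#' @export
validate_inputs <- function(paths, dialects) {
  dialects <- rep_len(dialects, length(paths))
  out <- list()
  note <- function(file, line, severity, message) {
    out[[length(out) + 1]] <<- data.frame(
      file = file, line = line, severity = severity, message = message
    )
  }
  for (i in seq_along(paths)) {
    path <- paths[i]
    kind <- dialects[i]
    if (!kind %in% names(csv_schema)) {
      note(path, NA, "error", paste0("unknown dialect '", kind, "'"))
      next
    }
    if (!file.exists(path)) {
      note(path, NA, "error", "file does not exist")
      next
    }
    lines <- readLines(path, warn = FALSE)
    body <- which(!grepl("^#", lines) & nzchar(lines))
    if (length(body) < 2) {
      note(path, NA, "error", "no data rows")
      next
    }
    header <- strsplit(lines[body[1]], ",")[[1]]
    missing <- setdiff(csv_schema[[kind]], trimws(header))
    if (kind == "acv" && length(missing) == 0) {
      if (!all(c("i_in_A_cm2", "i_out_A_cm2") %in% header) &&
        !("capacitance_uF_cm2" %in% header)) {
        missing <- "i_in_A_cm2,i_out_A_cm2 or capacitance_uF_cm2"
      }
    }
    for (col in missing) {
      note(path, body[1], "error", paste0("missing column '", col, "'"))
    }
    if (length(missing) == 0) {
      ncol_expect <- length(header)
      for (j in body[-1]) {
        cells <- strsplit(lines[j], ",")[[1]]
        if (length(cells) != ncol_expect) {
          note(path, j, "error", sprintf(
            "expected %d fields, found %d", ncol_expect, length(cells)
          ))
        } else if (anyNA(suppressWarnings(as.numeric(cells)))) {
          bad <- which(is.na(suppressWarnings(as.numeric(cells))))[1]
          note(path, j, "error", sprintf(
            "non-numeric value '%s' in column '%s'", cells[bad], header[bad]
          ))
        }
      }
    }
  }
  if (length(out) == 0) {
    data.frame(
      file = character(), line = integer(), severity = character(),
      message = character()
    )
  } else {
    do.call(rbind, out)
  }
}

# Pipeline --------------------------------------------------------------------

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages (isotherm descriptors, mixing
#' thermodynamics, film stability, AC-voltammetry, impedance fitting) in
#' dependency order. Failures in one stage are recorded in the report
#' without aborting independent stages; the run is deterministic given the
#' configuration and seed.
#'
#' @param config A list (or path to a YAML file) with any of:
#' \describe{
#'   \item{isotherms}{named list/vector of isotherm CSV paths (or
#'     `isotherm` objects).}
#'   \item{mixing}{list with `mixture` (name of an entry in `isotherms`),
#'     `components` (named numeric vector of mole fractions, names being
#'     `isotherms` entries) and optional `pressures`.}
#'   \item{stability}{named list of stability CSV paths (or traces).}
#'   \item{acv}{named list of ACV CSV paths (or curves).}
#'   \item{eis}{named list of EIS CSV paths (or spectra); optional `eis_init`
#'     list of [circuit_params()] per name (defaults to a generic start).}
#'   \item{params}{analysis parameters: `grid_step`, `collapse_threshold`,
#'     `a0_window`, `plateau_tol`, `acv_window`, `c_bare`, `c_ideal`,
#'     `anchor_potential`, `anchor_sigma`, `weighting`, `topology`,
#'     `pressures`.}
#'   \item{seed}{integer seed echoed in the provenance block.}
#' }
#' @return A list of class `raft_report` with one entry per executed stage
#'   (each a list of per-dataset results or an `error` string), a `status`
#'   field (`"ok"`, `"partial"`, `"failed"`) and a `provenance` block
#'   (package version, seed, config echo).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  p <- modifyList(list(
    grid_step = 0.1, collapse_threshold = 10, a0_window = NULL,
    plateau_tol = 0.5, acv_window = c(-0.3, 0), c_bare = 35, c_ideal = 0.8,
    anchor_potential = NULL, anchor_sigma = NULL,
    weighting = "modulus", topology = "default",
    pressures = c(5, 10, 15, 20, 25, 30, 35, 40, 45)
  ), config$params %||% list())

  report <- list()
  failed <- 0L
  ran <- 0L
  run_stage <- function(x, fn) {
    lapply(x, function(item) {
      ran <<- ran + 1L
      tryCatch(
        {
          if (inherits(item, "raft_read_error")) stop_invalid(item$error)
          fn(item)
        },
        error = function(e) {
          failed <<- failed + 1L
          list(error = conditionMessage(e))
        }
      )
    })
  }
  # per-file reads must not abort the run: failures become per-item entries
  safe_read <- function(x, cls, reader) {
    if (inherits(x, cls)) return(x)
    tryCatch(reader(x), error = function(e) {
      structure(list(error = conditionMessage(e)), class = "raft_read_error")
    })
  }

  isotherms <- lapply(config$isotherms %||% list(), safe_read,
    cls = "isotherm", reader = read_isotherm_csv)

  if (length(isotherms)) {
    report$isotherms <- run_stage(isotherms, function(iso) {
      if (!inherits(iso, "isotherm")) stop_invalid("not a readable isotherm")
      unclass(isotherm_features(iso,
        grid_step = p$grid_step,
        collapse_threshold = p$collapse_threshold, a0_window = p$a0_window
      ))
    })
  }

  if (!is.null(config$mixing)) {
    ran <- ran + 1L
    report$mixing <- tryCatch({
      mx <- config$mixing
      comps <- lapply(names(mx$components), function(nm) {
        list(
          label = nm, isotherm = isotherms[[nm]],
          fraction = unname(mx$components[[nm]])
        )
      })
      spec <- mixture_spec(comps, isotherms[[mx$mixture]])
      as.list(excess_sweep(spec, mx$pressures %||% p$pressures))
    }, error = function(e) {
      failed <<- failed + 1L
      list(error = conditionMessage(e))
    })
  }

  if (!is.null(config$stability)) {
    traces <- lapply(config$stability, safe_read,
      cls = "stability_trace", reader = read_stability_csv)
    report$stability <- run_stage(traces, function(tr) {
      tr <- stability_metrics(tr, plateau_tol = p$plateau_tol)
      list(
        plateau_pressure_mN_m = attr(tr, "plateau_pressure"),
        time_to_plateau_s = attr(tr, "time_to_plateau"),
        drift_rate_mN_m_per_h = attr(tr, "drift_rate")
      )
    })
  }

  if (!is.null(config$acv)) {
    curves <- lapply(config$acv, safe_read,
      cls = "acv_curve", reader = read_acv_csv)
    report$acv <- run_stage(curves, function(cv) {
      if (is.null(cv$capacitance)) cv <- capacitance_from_ac(cv)
      est <- coverage(min_capacitance(cv,
        window = p$acv_window,
        c_bare = p$c_bare, c_ideal = p$c_ideal
      ))
      prof <- charge_density(cv,
        anchor_potential = p$anchor_potential,
        anchor_sigma = p$anchor_sigma
      )
      pz <- tryCatch(as.numeric(find_pzfc(prof)), error = function(e) NA_real_)
      list(
        c_min_uF_cm2 = est$c_min, e_at_min_V = est$e_at_min,
        coverage = est$theta, e_pzfc_V = pz
      )
    })
  }

  if (!is.null(config$eis)) {
    spectra <- lapply(config$eis, safe_read,
      cls = "impedance_spectrum", reader = read_eis_csv)
    report$eis <- run_stage(seq_along(spectra), function(i) {
      sp <- spectra[[i]]
      if (inherits(sp, "raft_read_error")) stop_invalid(sp$error)
      init <- (config$eis_init %||% list())[[names(spectra)[i] %||% ""]] %||%
        circuit_params(
          r_sol = 50, r_m = 1000, q_m = 5, alpha_m = 0.9,
          q_sp = 5, alpha_sp = 0.8
        )
      fit <- cnls_fit(sp, init, weighting = p$weighting, topology = p$topology)
      c(unclass(fit$params)[!vapply(unclass(fit$params), is.null, logical(1))],
        list(
          stderr = as.list(fit$stderr), residual_norm = fit$residual_norm,
          converged = fit$converged
        )
      )
    })
    names(report$eis) <- names(spectra)
  }

  status <- if (failed == 0L) "ok" else if (failed < ran) "partial" else "failed"
  structure(c(report, list(
    status = status,
    provenance = list(
      package = "raftfilm",
      version = as.character(packageVersion("raftfilm")),
      seed = config$seed %||% NA,
      units = list(
        area = "A2_per_molecule", pressure = "mN_per_m", time = "s",
        capacitance = "uF_cm-2", charge = "uC_cm-2", potential = "V_vs_AgAgCl",
        impedance = "ohm_cm2", r_m = "kohm_cm2", q = "uF_cm-2_s^(alpha-1)",
        g_excess = "J_per_mol"
      ),
      config = config[setdiff(names(config), c("isotherms", "stability", "acv", "eis"))]
    )
  )), class = "raft_report")
}

#' Write a pipeline report as JSON
#' @param report A [run_pipeline()] result.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null", force = TRUE
  )
  invisible(path)
}
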