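#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef lm median rnorm sd setNames uniroot
#' @importFrom utils modifyList read.csv write.csv packageVersion
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("raftfilm_invalid_input", "error")))
}

stop_range <- function(...) {
  stop(errorCondition(paste0(...), class = c("raftfilm_out_of_range", "error")))
}

stop_notfound <- function(...) {
  stop(errorCondition(paste0(...), class = c("raftfilm_not_found", "error")))
}

check_numeric <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x)) stop_invalid(name, " must be numeric")
  if (finite && any(!is.finite(x))) stop_invalid(name, " contains non-finite values")
  if (positive && any(x <= 0)) stop_invalid(name, " must be strictly positive")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parabolic refinement of an extremum: given three x (not necessarily
# equispaced) and y with the extremum at the middle point, return the vertex x.
parabola_vertex <- function(x, y) {
  d <- cbind(1, x, x^2)
  cf <- tryCatch(solve(d, y), error = function(e) NULL)
  if (is.null(cf) || !is.finite(cf[3]) || cf[3] == 0) return(x[2])
  v <- unname(-cf[2] / (2 * cf[3]))
  if (v < min(x) || v > max(x)) x[2] else v
}
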