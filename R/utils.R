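# Internal helpers: classed conditions and small numeric utilities.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "msnephys_error")))
}

format_error    <- function(msg) abort(msg, "msnephys_format_error")
integrity_error <- function(msg) abort(msg, "msnephys_integrity_error")
parameter_error <- function(msg) abort(msg, "msnephys_parameter_error")
analysis_error  <- function(msg) abort(msg, "msnephys_analysis_error")
capability_error <- function(msg) abort(msg, "msnephys_capability_error")

#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero, the
#' convention used for reporting response-type percentages (e.g. 10 of 57
#' cells is 17.54% and is reported as 18%). Base `round()` rounds half to
#' even and would report 17 or 18 depending on floating-point representation.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Seed handling for generators: set the RNG deterministically for the call
# and restore the caller's RNG state on exit.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    parameter_error("`seed` must be a single integer")
  }
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
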