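#' @keywords internal
#' @useDynLib mskSurrogate, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Seed handling: functions that consume randomness take an explicit seed,
# set it locally, and restore the caller's RNG state afterwards, so that
# results do not depend on call order.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# round half away from zero (round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

msg_stage <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ", ...)
}
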