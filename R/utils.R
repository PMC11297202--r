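# Internal condition helpers: every user-facing error carries a subclass so
# callers (and the pipeline) can branch on failure mode.

texmod_error <- function(subclass, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(subclass, "texmod_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

stopifnot_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    texmod_error("texmod_invalid_argument",
                 sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}

#' Geometric mean
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @keywords internal
geometric_mean <- function(x) {
  if (length(x) == 0L || any(x <= 0)) {
    texmod_error("texmod_invalid_argument",
                 "geometric mean requires a non-empty vector of positive values")
  }
  exp(mean(log(x)))
}
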