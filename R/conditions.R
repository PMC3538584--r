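# Typed conditions used throughout the package.
#
# Saturation: the observed (or exact) transition statistics fall outside the
# domain of a distance formula's logarithms, so the distance is undefined.
# Library-level operations signal a classed error; simulation drivers catch it
# (or work with vectorised NaN variants) and apply a documented cap policy.

stop_saturation <- function(message, which = NA_character_) {
  stop(structure(
    class = c("devadd_saturation_error", "devadd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), which = which)
  ))
}

stop_invalid <- function(message) {
  stop(structure(
    class = c("devadd_invalid_input", "devadd_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Test whether a condition is a saturation error
#'
#' @param x An object, typically caught by [tryCatch()].
#' @return `TRUE` if `x` is a saturation error signalled by this package.
#' @export
is_saturation_error <- function(x) inherits(x, "devadd_saturation_error")
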