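#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (the convention of most published rating tables), unlike [round()],
#' which rounds ties to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # the tiny offset guards against values like 2.4999999999999996 that are
  # exactly representable ties in decimal but not in binary
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Internal: stop with a classed condition so callers/tests can match on class.
gc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gcross_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Names of the seven variance components of the two-facet crossed model,
# in canonical order.
COMPONENT_NAMES <- c("p", "t", "r", "pt", "pr", "tr", "e")

MEASURES <- c("behavioural", "technical")
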