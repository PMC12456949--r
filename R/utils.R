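# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named child seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' child streams (traits, truth, trials, choices, bootstrap, ...), so any
#' component can be regenerated independently of the others. The derived
#' seed is always a valid 32-bit integer.
#'
#' @param master Integer master seed.
#' @param name Character stream label.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "traits")
child_seed <- function(master, name) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(name))
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v) * 97) %% 2147483647
  s <- ((abs(as.numeric(master)) %% 2147483647) * 48271 + h) %% 2147483647
  as.integer(s)
}

# Money lives on a 0.2-yuan grid; keep an exact integer-unit representation
# (1 unit = 0.2 yuan) to avoid floating-point equality hazards.
yuan_to_units <- function(x) as.integer(round(x * 5))
units_to_yuan <- function(u) u / 5

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_arg <- function(...) stop(..., call. = FALSE)
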