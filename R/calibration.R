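# Pain calibration: map device intensity to subjective pain ratings.
#
# Ratings on the 0-10 scale are modelled with a two-parameter logistic
# scaled to the rating ceiling,
#   rating(x) = ceiling / (1 + exp(-(x - midpoint) / width)),
# the simplest monotone sigmoid consistent with a bounded rating scale.

#' Fit the rating-intensity calibration curve
#'
#' Least-squares fit of the scaled logistic above, by bounded multi-start
#' optimization. Degenerate data (e.g. ratings that decrease with intensity,
#' which push the width against its bound) are returned with
#' `converged = FALSE` rather than silently falling back.
#'
#' @param intensity Stimulus intensities (device units); at least 4 distinct
#'   values.
#' @param rating Pain ratings in `[0, ceiling]`.
#' @param ceiling Rating-scale ceiling (default 10).
#' @return A list of class `ha_calibration`: `midpoint`, `width`,
#'   `ceiling`, `sse`, `converged`.
#' @export
fit_rating_curve <- function(intensity, rating, ceiling = 10) {
  if (length(intensity) != length(rating)) stop_arg("length mismatch")
  if (length(unique(intensity)) < 4) stop_arg("need >= 4 distinct intensities")
  if (any(!is.finite(rating)) || any(rating < 0 | rating > ceiling)) {
    stop_arg("ratings must lie in [0, ", ceiling, "]")
  }
  rng <- range(intensity)
  span <- max(diff(rng), 1e-6)
  sse <- function(p) {
    sum((rating - ceiling / (1 + exp(-(intensity - p[1]) / p[2])))^2)
  }
  lower <- c(rng[1] - 2 * span, span * 1e-4)
  upper <- c(rng[2] + 2 * span, span * 10)
  starts <- list(
    c(stats::median(intensity), span / 4),
    c(mean(rng), span / 10),
    c(mean(rng), span)
  )
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      stats::optim(s, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop_arg("calibration fit failed")
  at_bound <- best$par[2] <= lower[2] * 1.01 || best$par[2] >= upper[2] * 0.99
  structure(
    list(midpoint = best$par[1], width = best$par[2], ceiling = ceiling,
         sse = best$value,
         converged = best$convergence == 0 && !at_bound),
    class = "ha_calibration"
  )
}

#' Invert the calibration curve at a target rating
#'
#' Returns the intensity whose predicted rating equals `level`:
#' `midpoint + width * log(level / (ceiling - level))`. At half-ceiling this
#' is the midpoint itself.
#'
#' @param curve An `ha_calibration` object.
#' @param level Target rating strictly inside `(0, ceiling)`; experiments
#'   typically use level 7 on the 0-10 scale.
#' @return Intensity in device units.
#' @export
intensity_for_rating <- function(curve, level) {
  stopifnot(inherits(curve, "ha_calibration"))
  if (level <= 0 || level >= curve$ceiling) {
    stop_arg("`level` must lie strictly inside (0, ", curve$ceiling, ")")
  }
  curve$midpoint + curve$width * log(level / (curve$ceiling - level))
}
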