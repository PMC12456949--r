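# Effect size and post-hoc power for multiple regression.

#' Cohen's f-squared from a coefficient of determination
#'
#' `f2 = R2 / (1 - R2)`.
#'
#' @param r_squared R-squared in `[0, 1)`.
#' @return Cohen's f-squared.
#' @export
cohen_f2 <- function(r_squared) {
  if (any(r_squared < 0 | r_squared >= 1)) stop_arg("R-squared must lie in [0, 1)")
  r_squared / (1 - r_squared)
}

#' Post-hoc power of the multiple-regression F test
#'
#' Noncentral-F power for testing all `n_predictors` slopes at once:
#' `df1 = n_predictors`, `df2 = N - n_predictors - 1`, noncentrality
#' `lambda = f2 * N`, power `P(F'(df1, df2, lambda) > F_crit)`. (With these
#' df the alternative convention `lambda = f2 * (df1 + df2 + 1)` coincides,
#' since `df1 + df2 + 1 = N`.) At `f2 = 0` the power equals `alpha` exactly.
#'
#' @param f2 Cohen's f-squared (>= 0).
#' @param n_predictors Number of regressors tested.
#' @param N Sample size (must exceed `n_predictors + 1`).
#' @param alpha Significance level.
#' @return Object of class `ha_power`: `f2`, `n_predictors`, `N`, `alpha`,
#'   `lambda`, `df1`, `df2`, `power`.
#' @export
#' @examples
#' regression_posthoc_power(0.491, 7, 46)$power  # ~0.910
regression_posthoc_power <- function(f2, n_predictors, N, alpha = 0.05) {
  if (f2 < 0) stop_arg("f2 must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop_arg("alpha must lie in (0, 1)")
  df1 <- n_predictors
  df2 <- N - n_predictors - 1
  if (df1 < 1 || df2 < 1) stop_arg("invalid degrees of freedom")
  lambda <- f2 * N
  fcrit <- stats::qf(1 - alpha, df1, df2)
  structure(
    list(f2 = f2, n_predictors = n_predictors, N = N, alpha = alpha,
         lambda = lambda, df1 = df1, df2 = df2,
         power = stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)),
    class = "ha_power"
  )
}
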