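# Moderated mediation: IH -> harm framing -> relative harm sensitivity,
# with decision context moderating the IH -> framing path.
#
# Model M :  M ~ 1 + IH + DC + IH:DC + IB + EC
# Model Y :  Y ~ 1 + IH + M + DC + IH:DC + M:DC + IB + EC   (moderation screen)
# Model Y':  Y ~ 1 + IH + M + DC + IB + EC                  (reported model)
# with DC coded 1 = gain, 0 = loss, so a_loss is the IH coefficient of model
# M and a_gain adds the IH:DC interaction; b is the M coefficient of model
# Y' and c' its IH coefficient. Indirect effects are ab per context and the
# moderation index is delta_ab = ab_gain - ab_loss. Inference is by cluster
# bootstrap: subjects are the resampling unit and keep their paired context
# rows, preserving the repeated-measures dependence.

.med_context <- function(ctx) {
  if (is.character(ctx) || is.factor(ctx)) ctx <- as.integer(as.character(ctx) == "gain")
  stopifnot(all(ctx %in% c(0, 1)))
  as.numeric(ctx)
}

.med_check <- function(data) {
  need <- c("subject_id", "context", "IH", "IB", "EC", "M", "Y")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_arg("mediation data lacks columns: ",
                             paste(miss, collapse = ", "))
  data$context <- .med_context(data$context)
  data
}

.ols <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_arg("rank-deficient design; collinear columns: ",
             paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  dfr <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / dfr
  se <- sqrt(sigma2 * diag(chol2inv(chol(crossprod(X)))))
  tval <- beta / se
  list(coef = beta, se = se, t = tval, p = 2 * stats::pt(-abs(tval), dfr),
       rss = sum(res^2), df_residual = dfr)
}

.mm_M <- function(d) {
  cbind(Intercept = 1, IH = d$IH, DC = d$context, `IH:DC` = d$IH * d$context,
        IB = d$IB, EC = d$EC)
}

.mm_Y <- function(d, reduced) {
  X <- cbind(Intercept = 1, IH = d$IH, M = d$M, DC = d$context,
             IB = d$IB, EC = d$EC)
  if (!reduced) {
    X <- cbind(X, `IH:DC` = d$IH * d$context, `M:DC` = d$M * d$context)
  }
  X
}

#' Fit the mediator model M
#'
#' @param data Mediation table: two rows per subject (gain, loss) with
#'   columns `subject_id`, `context` (1 = gain / 0 = loss, or
#'   "gain"/"loss"), `IH`, `IB`, `EC`, `M` (framing report), `Y`.
#' @return List with the OLS summary (`coef`, `se`, `t`, `p`) and the
#'   context-specific IH -> M paths `a_gain`, `a_loss`.
#' @export
fit_model_M <- function(data) {
  d <- .med_check(data)
  fit <- .ols(.mm_M(d), d$M)
  fit$a_loss <- unname(fit$coef["IH"])
  fit$a_gain <- unname(fit$coef["IH"] + fit$coef["IH:DC"])
  fit
}

#' Fit the outcome model Y (full) or Y' (reduced)
#'
#' The full model carries the IH:DC and M:DC interactions used to screen
#' where moderation acts; the reduced model drops them and supplies the
#' reported paths `b` (M coefficient) and `c_prime` (IH coefficient).
#'
#' @inheritParams fit_model_M
#' @param reduced Fit the reduced model Y' (default) or the full model Y.
#' @return OLS summary list, plus `b` and `c_prime` when `reduced = TRUE`.
#' @export
fit_model_Y <- function(data, reduced = TRUE) {
  d <- .med_check(data)
  fit <- .ols(.mm_Y(d, reduced), d$Y)
  if (reduced) {
    fit$b <- unname(fit$coef["M"])
    fit$c_prime <- unname(fit$coef["IH"])
  }
  fit
}

#' Indirect-effect indices from fitted M and Y' models
#'
#' @param model_m Output of [fit_model_M()].
#' @param model_y Output of [fit_model_Y()] with `reduced = TRUE`.
#' @return Named vector: `ab_gain`, `ab_loss`, `delta_ab`, `b`, `c_prime`,
#'   `a_gain`, `a_loss`.
#' @export
mediation_indices <- function(model_m, model_y) {
  c(ab_gain = model_m$a_gain * model_y$b,
    ab_loss = model_m$a_loss * model_y$b,
    delta_ab = (model_m$a_gain - model_m$a_loss) * model_y$b,
    b = model_y$b, c_prime = model_y$c_prime,
    a_gain = model_m$a_gain, a_loss = model_m$a_loss)
}

.med_indices_fast <- function(XM, XYr, M, Y, rows) {
  cm <- qr.coef(qr(XM[rows, , drop = FALSE]), M[rows])
  cy <- qr.coef(qr(XYr[rows, , drop = FALSE]), Y[rows])
  a_loss <- cm["IH"]
  a_gain <- cm["IH"] + cm["IH:DC"]
  b <- cy["M"]
  unname(c(a_gain * b, a_loss * b, (a_gain - a_loss) * b, b, cy["IH"]))
}

#' Moderated mediation with subject-level cluster bootstrap
#'
#' Point estimates come from models M and Y' on the observed data; B
#' bootstrap resamples of whole subjects (both context rows travel
#' together) give percentile (default) or bias-corrected confidence
#' intervals and sign-proportion two-sided p-values
#' `2 * min(frac <= 0, frac >= 0)` for each index.
#'
#' @inheritParams fit_model_M
#' @param B Number of bootstrap resamples (>= 100; study-faithful 5000).
#' @param seed Integer seed; the draw sequence is deterministic given it.
#' @param conf Confidence level (default 0.95).
#' @param type `"percentile"` or `"bc"` (bias-corrected).
#' @return Object of class `ha_mediation`: `estimates`, `ci` (matrix),
#'   `p`, `B`, `n_subjects`, `seed`, `conf`, `type`, `model_M`,
#'   `model_Y_reduced`, `model_Y_full`, and the raw `draws`.
#' @export
bootstrap_mediation <- function(data, B = 5000, seed = NULL, conf = 0.95,
                                type = c("percentile", "bc")) {
  type <- match.arg(type)
  d <- .med_check(data)
  subjects <- unique(d$subject_id)
  if (length(subjects) < 10) stop_arg("need at least 10 subjects")
  if (B < 100) stop_arg("B must be >= 100 (percentiles are unstable below that)")
  if (!is.null(seed)) set.seed(seed)
  mM <- fit_model_M(d)
  mY <- fit_model_Y(d, reduced = TRUE)
  mYfull <- fit_model_Y(d, reduced = FALSE)
  est <- mediation_indices(mM, mY)
  XM <- .mm_M(d)
  XYr <- .mm_Y(d, reduced = TRUE)
  rowlist <- split(seq_len(nrow(d)), d$subject_id)
  idx_names <- c("ab_gain", "ab_loss", "delta_ab", "b", "c_prime")
  draws <- matrix(NA_real_, B, length(idx_names),
                  dimnames = list(NULL, idx_names))
  for (i in seq_len(B)) {
    pick <- sample(subjects, replace = TRUE)
    rows <- unlist(rowlist[as.character(pick)], use.names = FALSE)
    v <- tryCatch(.med_indices_fast(XM, XYr, d$M, d$Y, rows),
                  error = function(e) rep(NA_real_, length(idx_names)))
    draws[i, ] <- v
  }
  ci <- matrix(NA_real_, length(idx_names), 2,
               dimnames = list(idx_names, c("lower", "upper")))
  pv <- setNames(numeric(length(idx_names)), idx_names)
  alpha <- (1 - conf) / 2
  for (j in idx_names) {
    dj <- draws[, j]
    dj <- dj[is.finite(dj)]
    probs <- c(alpha, 1 - alpha)
    if (type == "bc") {
      z0 <- stats::qnorm(mean(dj < est[j]))
      probs <- stats::pnorm(2 * z0 + stats::qnorm(probs))
    }
    ci[j, ] <- stats::quantile(dj, probs, names = FALSE)
    pv[j] <- min(1, 2 * min(mean(dj <= 0), mean(dj >= 0)))
  }
  structure(
    list(estimates = est, ci = ci, p = pv, B = B,
         n_subjects = length(subjects), seed = seed, conf = conf,
         type = type, model_M = mM, model_Y_reduced = mY,
         model_Y_full = mYfull, draws = draws),
    class = "ha_mediation"
  )
}
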