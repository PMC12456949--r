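# The harm-aversion choice model.
#
# A trial's value difference is DeltaV = (1 - kappa) * delta_m - kappa * delta_s,
# the value of the MORE painful option (it gains the money advantage delta_m
# and costs delta_s extra shocks). Choices follow a softmax with consistency
# gamma. The probability of choosing the LESS painful option is therefore
#   P(less painful) = 1 / (1 + exp(-gamma * (kappa * delta_s - (1 - kappa) * delta_m)))
# i.e. P(more painful) = plogis(gamma * DeltaV). Under this orientation a
# larger kappa means more weight on sparing shocks, so kappa_other > kappa_self
# expresses hyperaltruism.

.CELL_LEVELS <- c("gain_self", "gain_other", "loss_self", "loss_other")

.cell_key <- function(context, recipient) paste(context, recipient, sep = "_")

#' Specify how model parameters are shared across conditions
#'
#' The harm-aversion weight kappa always varies by context x recipient cell;
#' the consistency gamma can be shared across all cells (the main model),
#' vary by decision context, or vary by cell.
#'
#' @param gamma One of `"single"`, `"per_context"`, `"per_condition"`.
#' @return An object of class `ha_model_spec`.
#' @export
model_spec <- function(gamma = c("single", "per_context", "per_condition")) {
  gamma <- match.arg(gamma)
  structure(list(gamma = gamma), class = "ha_model_spec")
}

#' Value difference between the more and less painful options
#'
#' @param kappa Harm-aversion weight in `[0, 1]`.
#' @param delta_m Money difference (positive magnitude, yuan).
#' @param delta_s Shock-count difference (positive magnitude).
#' @return `(1 - kappa) * delta_m - kappa * delta_s`.
#' @export
delta_value <- function(kappa, delta_m, delta_s) {
  if (any(kappa < 0 | kappa > 1)) stop_arg("kappa must lie in [0, 1]")
  (1 - kappa) * delta_m - kappa * delta_s
}

#' Probability of choosing the less painful option
#'
#' @inheritParams delta_value
#' @param gamma Choice consistency (>= 0); 0 gives 0.5 for every trial.
#' @return Choice probability; numerically stable for extreme arguments.
#' @export
p_less_painful <- function(kappa, gamma, delta_m, delta_s) {
  if (any(kappa < 0 | kappa > 1)) stop_arg("kappa must lie in [0, 1]")
  if (any(gamma < 0)) stop_arg("gamma must be >= 0")
  stats::plogis(gamma * (kappa * delta_s - (1 - kappa) * delta_m))
}

# Index a choice table into kappa / gamma parameter slots.
.prep_choices <- function(data, spec) {
  need <- c("context", "recipient", "delta_m", "delta_s", "choice")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_arg("choice data lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop_arg("empty choice data")
  if (!all(data$choice %in% c(0, 1))) stop_arg("choice must be 0/1")
  key <- .cell_key(data$context, data$recipient)
  cells <- .CELL_LEVELS[.CELL_LEVELS %in% unique(key)]
  if (length(cells) == 0L) stop_arg("no recognised context/recipient cells")
  kidx <- match(key, cells)
  ctxs <- unique(data$context)
  gidx <- switch(spec$gamma,
    single = rep(1L, nrow(data)),
    per_context = match(data$context, ctxs),
    per_condition = kidx
  )
  gnames <- switch(spec$gamma,
    single = "gamma",
    per_context = paste0("gamma_", ctxs),
    per_condition = paste0("gamma_", cells)
  )
  list(y = as.numeric(data$choice), ds = as.numeric(data$delta_s),
       dm = as.numeric(data$delta_m), kidx = kidx, gidx = gidx,
       cells = cells, n_k = length(cells), n_g = length(gnames),
       gnames = gnames)
}

.nll_fun <- function(pre) {
  force(pre)
  function(par) {
    k <- par[pre$kidx]
    g <- par[pre$n_k + pre$gidx]
    p <- stats::plogis(g * (k * pre$ds - (1 - k) * pre$dm))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(pre$y * log(p) + (1 - pre$y) * log(1 - p))
  }
}

.nll_grad <- function(pre) {
  force(pre)
  function(par) {
    k <- par[pre$kidx]
    g <- par[pre$n_k + pre$gidx]
    u <- k * pre$ds - (1 - k) * pre$dm
    p <- stats::plogis(g * u)
    r <- p - pre$y
    gk <- rowsum(r * g * (pre$ds + pre$dm), pre$kidx)
    gk_full <- numeric(pre$n_k)
    gk_full[as.integer(rownames(gk))] <- gk[, 1]
    gg <- rowsum(r * u, pre$gidx)
    gg_full <- numeric(pre$n_g)
    gg_full[as.integer(rownames(gg))] <- gg[, 1]
    c(gk_full, gg_full)
  }
}

#' Negative log-likelihood of the harm-aversion model
#'
#' Bernoulli likelihood of coded choices (1 = less painful option chosen)
#' under [p_less_painful()], with probabilities clipped to
#' `[1e-12, 1 - 1e-12]` before taking logs.
#'
#' @param par Parameter vector: the kappas for each cell present in the data
#'   (ordered gain_self, gain_other, loss_self, loss_other) followed by the
#'   gamma(s) of the spec.
#' @param data Choice table slice with columns `context`, `recipient`,
#'   `delta_m`, `delta_s`, `choice`.
#' @param spec A [model_spec()].
#' @return Scalar negative log-likelihood.
#' @export
neg_log_lik <- function(par, data, spec = model_spec()) {
  pre <- .prep_choices(data, spec)
  if (length(par) != pre$n_k + pre$n_g) {
    stop_arg("expected ", pre$n_k + pre$n_g, " parameters")
  }
  .nll_fun(pre)(par)
}

#' Fit the harm-aversion model to one subject's choices by multi-start MLE
#'
#' Bounded L-BFGS-B minimization of [neg_log_lik()] with kappa in `[0, 1]`
#' and gamma in `(0, gamma_max]`, restarted from `n_restarts` starting
#' points drawn uniformly within the bounds; the best solution is kept.
#' Estimates within `boundary_tol` of a bound are flagged (e.g. subjects who
#' always take the same option); such fits are returned, never dropped --
#' exclusion is the caller's policy.
#'
#' @param data One subject's (one session's) choice table.
#' @param spec A [model_spec()]; the default shares a single gamma.
#' @param n_restarts Number of random starts (study-faithful default 300;
#'   pipelines may use a smaller profile).
#' @param gamma_max Upper bound for gamma (value-difference units).
#' @param seed Optional seed for the restart draws.
#' @param boundary_tol Flag tolerance, as a fraction of each bound range.
#' @return A list of class `ha_fit`: `kappa` (named), `gamma` (named),
#'   `nll`, `n_trials`, `n_params`, `aic`, `bic`, `n_restarts`,
#'   `best_start_index`, `boundary` (named logical), `convergence`.
#' @export
fit_subject <- function(data, spec = model_spec(), n_restarts = 300,
                        gamma_max = 50, seed = NULL, boundary_tol = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  pre <- .prep_choices(data, spec)
  fn <- .nll_fun(pre)
  gr <- .nll_grad(pre)
  lower <- c(rep(0, pre$n_k), rep(1e-4, pre$n_g))
  upper <- c(rep(1, pre$n_k), rep(gamma_max, pre$n_g))
  best <- NULL
  best_i <- NA_integer_
  for (i in seq_len(max(1L, n_restarts))) {
    start <- stats::runif(length(lower), lower, upper)
    o <- tryCatch(
      stats::optim(start, fn, gr, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(o) && (is.null(best) || o$value < best$value)) {
      best <- o
      best_i <- i
    }
  }
  if (is.null(best)) stop_arg("all optimizer restarts failed")
  par <- best$par
  names(par) <- c(paste0("kappa_", pre$cells), pre$gnames)
  at_bound <- par <= lower + boundary_tol * (upper - lower) |
    par >= upper - boundary_tol * (upper - lower)
  kappa <- par[seq_len(pre$n_k)]
  names(kappa) <- pre$cells
  gamma <- par[pre$n_k + seq_len(pre$n_g)]
  names(gamma) <- pre$gnames
  n_par <- length(par)
  structure(
    list(kappa = kappa, gamma = gamma, spec = spec, nll = best$value,
         n_trials = length(pre$y), n_params = n_par,
         aic = 2 * best$value + 2 * n_par,
         bic = 2 * best$value + n_par * log(length(pre$y)),
         n_restarts = n_restarts, best_start_index = best_i,
         boundary = at_bound, convergence = best$convergence),
    class = "ha_fit"
  )
}

#' Hyperaltruism index per context
#'
#' The moral-preference contrast `kappa_other - kappa_self`, computed
#' separately for each context present in the fit.
#'
#' @param fit An `ha_fit` from [fit_subject()].
#' @return Named numeric vector (one element per context).
#' @export
hyperaltruism_index <- function(fit) {
  stopifnot(inherits(fit, "ha_fit"))
  k <- fit$kappa
  ctxs <- unique(sub("_(self|other)$", "", names(k)))
  out <- numeric(0)
  for (ctx in ctxs) {
    self <- paste0(ctx, "_self")
    other <- paste0(ctx, "_other")
    if (!(self %in% names(k)) || !(other %in% names(k))) {
      stop_arg("context '", ctx, "' is missing a recipient cell")
    }
    out[ctx] <- unname(k[other] - k[self])
  }
  out
}

#' Fit every subject (and session) in a choice table
#'
#' @param choices Long choice table with `subject_id` and optionally
#'   `treatment` columns in addition to the trial fields.
#' @param spec A [model_spec()].
#' @param n_restarts,gamma_max,seed Passed to [fit_subject()]; each fit uses
#'   a child seed derived from `seed` so results do not depend on fit order.
#' @return Data frame with one row per subject x treatment: the four kappas,
#'   gamma, `nll`, `aic`, `bic`, and `boundary_flags` (semicolon-joined
#'   parameter names at a bound, `""` if none).
#' @export
fit_subjects <- function(choices, spec = model_spec(), n_restarts = 300,
                         gamma_max = 50, seed = NULL) {
  stopifnot("subject_id" %in% names(choices))
  if (!"treatment" %in% names(choices)) choices$treatment <- "none"
  groups <- unique(choices[, c("subject_id", "treatment")])
  rows <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    sub <- choices[choices$subject_id == groups$subject_id[i] &
                     choices$treatment == groups$treatment[i], ]
    fseed <- if (is.null(seed)) NULL else {
      child_seed(seed, paste0("fit_", groups$subject_id[i], "_", groups$treatment[i]))
    }
    fit <- fit_subject(sub, spec = spec, n_restarts = n_restarts,
                       gamma_max = gamma_max, seed = fseed)
    k <- fit$kappa
    rows[[i]] <- data.frame(
      subject_id = groups$subject_id[i], treatment = groups$treatment[i],
      kappa_gain_self = unname(k["gain_self"]),
      kappa_gain_other = unname(k["gain_other"]),
      kappa_loss_self = unname(k["loss_self"]),
      kappa_loss_other = unname(k["loss_other"]),
      gamma = unname(fit$gamma[1]), nll = fit$nll, aic = fit$aic,
      bic = fit$bic,
      boundary_flags = paste(names(fit$boundary)[fit$boundary], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare model specifications by information criteria
#'
#' Fits each spec to every subject and ranks specs by total BIC (ties by
#' total AIC) across subjects. Within nested specs the richer model's
#' per-subject negative log-likelihood can never exceed the simpler one's.
#'
#' @param choices Long choice table with `subject_id`.
#' @param specs List of [model_spec()] objects (>= 1).
#' @param n_restarts,seed Passed to [fit_subject()].
#' @return List with `summary` (one row per spec, ranked) and `per_subject`
#'   (per subject x spec criteria).
#' @export
compare_specs <- function(choices, specs, n_restarts = 50, seed = NULL) {
  stopifnot(length(specs) >= 1)
  labels <- vapply(specs, function(s) s$gamma, "")
  subjects <- unique(choices$subject_id)
  per <- list()
  for (j in seq_along(specs)) {
    for (s in subjects) {
      fseed <- if (is.null(seed)) NULL else child_seed(seed, paste0("cmp_", j, "_", s))
      fit <- fit_subject(choices[choices$subject_id == s, ], spec = specs[[j]],
                         n_restarts = n_restarts, seed = fseed)
      per[[length(per) + 1L]] <- data.frame(
        spec = labels[j], subject_id = s, nll = fit$nll,
        n_params = fit$n_params, aic = fit$aic, bic = fit$bic,
        stringsAsFactors = FALSE
      )
    }
  }
  per <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(per, per$spec), function(d) {
    data.frame(spec = d$spec[1], total_nll = sum(d$nll),
               total_aic = sum(d$aic), total_bic = sum(d$bic),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$total_bic, agg$total_aic), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  list(summary = agg, per_subject = per)
}
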