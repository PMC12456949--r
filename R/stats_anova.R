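# Within-subject ANOVA (all factors two-level) and the Friedman test.
#
# With two-level factors every effect is a single-df contrast, so the usual
# repeated-measures decomposition reduces to per-subject contrast scores:
# for effect E with cell codes w in {-1, +1}, theta_i = mean_c(w_c * y_ic),
# SS_effect = n * C * mean(theta)^2 and the effect-by-subject error is
# SS_err = C * sum((theta_i - mean(theta))^2) on (1, n - 1) df. Sphericity
# corrections are vacuous at two levels, matching the (1, n-1) df reported
# for such designs.

#' Repeated-measures ANOVA for two-level within-subject factors
#'
#' @param data Long data frame: one value per subject per cell.
#' @param dv Name of the value column.
#' @param subject Name of the subject-id column.
#' @param factors Character vector of 2 or 3 within-subject factor columns,
#'   each with exactly two levels.
#' @return Object of class `ha_anova`: `table` with one row per effect
#'   (`F`, `df1`, `df2`, `p`, `partial_eta2`, sums of squares).
#' @export
rm_anova <- function(data, dv = "value", subject = "subject_id", factors) {
  stopifnot(length(factors) %in% 1:3, all(c(dv, subject, factors) %in% names(data)))
  for (f in factors) {
    if (length(unique(data[[f]])) != 2) stop_arg("factor '", f, "' must have 2 levels")
  }
  cellkey <- interaction(data[factors], drop = FALSE, lex.order = TRUE)
  full <- table(data[[subject]], cellkey)
  if (any(full == 0)) stop_arg("missing cells: design must be complete")
  agg <- stats::aggregate(data[[dv]],
                          by = c(list(subject = data[[subject]]),
                                 lapply(factors, function(f) data[[f]])),
                          FUN = mean)
  names(agg) <- c("subject", factors, "value")
  # wide subject x cell matrix, cells in lex order of factor levels
  codes <- lapply(factors, function(f) sort(unique(as.character(agg[[f]]))))
  cells <- expand.grid(rev(codes), stringsAsFactors = FALSE)
  cells <- cells[, rev(seq_along(factors)), drop = FALSE]
  names(cells) <- factors
  C <- nrow(cells)
  subjects <- sort(unique(agg$subject))
  n <- length(subjects)
  Y <- matrix(NA_real_, n, C)
  for (j in seq_len(C)) {
    sel <- rep(TRUE, nrow(agg))
    for (f in factors) sel <- sel & as.character(agg[[f]]) == cells[j, f]
    v <- agg$value[sel][match(subjects, agg$subject[sel])]
    Y[, j] <- v
  }
  effects <- unlist(lapply(seq_along(factors), function(k) {
    utils::combn(factors, k, simplify = FALSE)
  }), recursive = FALSE)
  rows <- lapply(effects, function(eff) {
    w <- rep(1, C)
    for (f in eff) {
      w <- w * ifelse(cells[[f]] == codes[[match(f, factors)]][2], 1, -1)
    }
    theta <- drop(Y %*% w) / C
    ss_eff <- n * C * mean(theta)^2
    ss_err <- C * sum((theta - mean(theta))^2)
    Fv <- ss_eff / (ss_err / (n - 1))
    data.frame(effect = paste(eff, collapse = ":"), F = Fv, df1 = 1,
               df2 = n - 1, p = stats::pf(Fv, 1, n - 1, lower.tail = FALSE),
               partial_eta2 = ss_eff / (ss_eff + ss_err),
               ss_effect = ss_eff, ss_error = ss_err,
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), n = n, factors = factors),
            class = "ha_anova")
}

#' Simple effects of a two-level factor within levels of a moderator
#'
#' Within each level of `within`, values are averaged over any remaining
#' factors per subject and the two levels of `factor` are compared by a
#' paired t test, reported as `F = t^2` on (1, n - 1) df with partial eta
#' squared `t^2 / (t^2 + n - 1)`.
#'
#' @inheritParams rm_anova
#' @param factor Factor whose effect is tested.
#' @param within Moderator factor defining the strata.
#' @return Data frame with one row per level of `within`.
#' @export
simple_effects <- function(data, dv = "value", subject = "subject_id",
                           factor, within) {
  stopifnot(all(c(dv, subject, factor, within) %in% names(data)))
  levs <- sort(unique(as.character(data[[within]])))
  flev <- sort(unique(as.character(data[[factor]])))
  if (length(flev) != 2) stop_arg("'factor' must have 2 levels")
  rows <- lapply(levs, function(lv) {
    d <- data[as.character(data[[within]]) == lv, ]
    m <- stats::aggregate(d[[dv]],
                          by = list(subject = d[[subject]],
                                    f = as.character(d[[factor]])),
                          FUN = mean)
    wide <- merge(m[m$f == flev[1], c("subject", "x")],
                  m[m$f == flev[2], c("subject", "x")], by = "subject")
    diff <- wide$x.y - wide$x.x
    n <- length(diff)
    tt <- stats::t.test(diff)
    tv <- unname(tt$statistic)
    data.frame(level = lv, mean_diff = mean(diff), F = tv^2, df1 = 1,
               df2 = n - 1, p = tt$p.value,
               partial_eta2 = tv^2 / (tv^2 + n - 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Friedman rank test with tie correction
#'
#' The rank-based within-subject test for k related conditions, with the
#' standard tie correction. The p-value comes from the chi-square
#' approximation on k - 1 df, or (for small tables) from exact enumeration
#' of all per-subject rank permutations. Optional pairwise follow-ups are
#' Bonferroni-scaled Wilcoxon signed-rank contrasts.
#'
#' @param x Matrix (subjects x conditions), complete rows.
#' @param exact Use the exact permutation distribution (enumerates
#'   `factorial(k)^n`; refuse above ~2e6).
#' @param pairwise Also return Bonferroni-adjusted pairwise contrasts.
#' @return List of class `ha_friedman`: `chi2`, `df`, `p`, `method`,
#'   `tie_correction`, optionally `contrasts`.
#' @export
friedman_test <- function(x, exact = FALSE, pairwise = FALSE) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop_arg("incomplete rows are not allowed")
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2 || n < 2) stop_arg("need >= 2 conditions and >= 2 subjects")
  R <- t(apply(x, 1, rank))
  stat_of <- function(R) {
    Rj <- colSums(R)
    12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  }
  ties <- sum(apply(x, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
  Ccorr <- 1 - ties / (n * k * (k^2 - 1))
  s0 <- stat_of(R)
  chi2 <- if (Ccorr > 0) s0 / Ccorr else 0
  if (exact) {
    perms <- .permutations(k)
    npmax <- nrow(perms)^n
    if (npmax > 2e6) stop_arg("exact enumeration too large (", npmax, " states)")
    counter <- rep(1L, n)
    hits <- 0L
    total <- 0L
    repeat {
      Rp <- do.call(rbind, lapply(seq_len(n), function(i) R[i, perms[counter[i], ]]))
      sp <- stat_of(Rp)
      statp <- if (Ccorr > 0) sp / Ccorr else 0
      if (statp >= chi2 - 1e-12) hits <- hits + 1L
      total <- total + 1L
      j <- 1L
      repeat {
        counter[j] <- counter[j] + 1L
        if (counter[j] <= nrow(perms)) break
        counter[j] <- 1L
        j <- j + 1L
        if (j > n) break
      }
      if (j > n) break
    }
    p <- hits / total
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(chi2, k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  out <- list(chi2 = chi2, df = k - 1, p = p, method = method,
              tie_correction = Ccorr, n = n, k = k)
  if (pairwise) {
    pairs <- utils::combn(k, 2)
    m <- ncol(pairs)
    contrasts <- lapply(seq_len(m), function(j) {
      i1 <- pairs[1, j]
      i2 <- pairs[2, j]
      wt <- suppressWarnings(stats::wilcox.test(x[, i1], x[, i2], paired = TRUE))
      data.frame(cond1 = i1, cond2 = i2, V = unname(wt$statistic),
                 p_raw = wt$p.value, p_bonferroni = min(1, wt$p.value * m),
                 stringsAsFactors = FALSE)
    })
    out$contrasts <- do.call(rbind, contrasts)
  }
  structure(out, class = "ha_friedman")
}

# all permutations of 1..k, rows
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), k - 1)))
  }
  out
}
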