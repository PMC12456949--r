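# Stimulus construction for the money-pain trade-off task.
#
# Each trial opposes a "more painful" option (more electric shocks, better
# money) to a "less painful" option (fewer shocks, worse money). A trial is
# built from a (delta_s, delta_m) difference pair drawn from an exhaustive
# pool, targeted at a desired trade-off ratio delta_m / (delta_s + delta_m).

#' Build the exhaustive pool of shock/money difference pairs
#'
#' The shock difference runs over 1..19 shocks and the money difference over
#' 0.2..19.8 yuan on a 0.2-yuan grid, giving 19 x 99 = 1881 distinct pairs.
#' Ordering is delta_s-major, then delta_m.
#'
#' @return A data frame of class `ha_pair_pool` with columns `delta_s`,
#'   `delta_m` (yuan), `dm_units` (integer 0.2-yuan units) and `ratio`
#'   (`delta_m / (delta_s + delta_m)`).
#' @export
#' @examples
#' pool <- build_pair_pool()
#' nrow(pool)  # 1881
build_pair_pool <- function() {
  g <- expand.grid(dm_units = 1:99, delta_s = 1:19)
  pool <- data.frame(
    delta_s = as.integer(g$delta_s),
    delta_m = units_to_yuan(g$dm_units),
    dm_units = as.integer(g$dm_units)
  )
  pool$ratio <- pool$delta_m / (pool$delta_s + pool$delta_m)
  class(pool) <- c("ha_pair_pool", "data.frame")
  pool
}

#' Evenly spaced grid of desired trade-off ratios
#'
#' @param n Number of ratios (>= 2).
#' @param lo,hi Grid endpoints, `0 <= lo < hi <= 1`.
#' @return Numeric vector of `n` evenly spaced values with endpoints exactly
#'   `lo` and `hi`.
#' @export
ratio_grid <- function(n, lo = 0.01, hi = 0.99) {
  if (length(n) != 1L || !is.finite(n) || n < 2) {
    stop_arg("`n` must be a single number >= 2")
  }
  if (!is.finite(lo) || !is.finite(hi) || lo < 0 || hi > 1 || lo >= hi) {
    stop_arg("need 0 <= lo < hi <= 1")
  }
  seq(lo, hi, length.out = n)
}

#' Select the pool pair closest to a desired ratio
#'
#' Minimizes `|delta_m/(delta_s + delta_m) - ratio|` over the pool. Exact
#' ties (e.g. ratio 0.5, where every pair with `delta_m == delta_s` is
#' equally close) are broken by a uniform draw from the tied set using the
#' current RNG stream, which spreads stimulus magnitudes across trials while
#' staying reproducible under a fixed seed.
#'
#' @param ratio Target ratio in (0, 1).
#' @param pool A pair pool from [build_pair_pool()] (or any subset of one).
#' @return A list with `delta_s`, `delta_m`, `dm_units`.
#' @export
select_pair <- function(ratio, pool) {
  if (is.null(nrow(pool)) || nrow(pool) == 0L) stop_arg("empty pair pool")
  d <- abs(pool$ratio - ratio)
  idx <- which(d <= min(d) + 1e-12)
  i <- if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
  list(delta_s = pool$delta_s[i], delta_m = pool$delta_m[i],
       dm_units = pool$dm_units[i])
}

#' Instantiate a concrete trial from a difference pair
#'
#' The less painful option's shock count is drawn uniformly from the feasible
#' integers and its money amount uniformly from the feasible 0.2-yuan grid;
#' the more painful option is computed additively
#' (`S_more = S_less + delta_s`, `M_more = M_less + delta_m`). Feasibility
#' uses the bounds `S_less + delta_s <= 20` and `M_less + delta_m <= 20`
#' (the non-strict bound is the minimal relaxation that keeps the extreme
#' pairs delta_s = 19 and delta_m = 19.8 realizable). Loss-context trials
#' are produced by [to_loss()].
#'
#' @param pair List with `delta_s` and `dm_units` (as from [select_pair()]).
#' @param context `"gain"` or `"loss"`.
#' @return One-row data frame with the trial fields.
#' @export
instantiate_options <- function(pair, context = c("gain", "loss")) {
  context <- match.arg(context)
  ds <- as.integer(pair$delta_s)
  dmu <- as.integer(pair$dm_units %||% yuan_to_units(pair$delta_m))
  stopifnot(ds >= 1L, ds <= 19L, dmu >= 1L, dmu <= 99L)
  s_feas <- seq_len(20L - ds)    # shocks_less with shocks_more <= 20
  m_feas <- seq_len(100L - dmu)  # money_less units with money_more <= 20 yuan
  s_less <- s_feas[sample.int(length(s_feas), 1L)]
  m_less_u <- m_feas[sample.int(length(m_feas), 1L)]
  trial <- data.frame(
    context = "gain",
    money_more = units_to_yuan(m_less_u + dmu),
    money_less = units_to_yuan(m_less_u),
    shocks_more = s_less + ds,
    shocks_less = s_less,
    delta_s = ds,
    delta_m = units_to_yuan(dmu),
    stringsAsFactors = FALSE
  )
  if (context == "loss") trial <- to_loss(trial) else trial
}

#' Transform gain-context trials into loss-context trials
#'
#' Money signs are flipped and the two options' money amounts swapped, so
#' the more painful option keeps the money advantage (the smaller loss);
#' shock counts and both difference magnitudes are unchanged. Applying the
#' flip-and-swap twice recovers the original money values.
#'
#' @param trial Data frame of gain-context trials.
#' @return The same rows in loss form.
#' @export
#' @examples
#' g <- data.frame(context = "gain", money_more = 15, money_less = 10,
#'                 shocks_more = 10, shocks_less = 5, delta_s = 5, delta_m = 5)
#' to_loss(g)[, c("money_more", "money_less")]  # -10, -15
to_loss <- function(trial) {
  if (any(trial$context != "gain")) stop_arg("to_loss() expects gain-context trials")
  out <- trial
  out$money_more <- -trial$money_less
  out$money_less <- -trial$money_more
  out$context <- "loss"
  out
}

#' Build a full within-subject trial set
#'
#' Generates `n_per_cell` trials for each of the four context x recipient
#' cells (gain/loss x self/other). Within each cell the desired ratios are
#' the even grid on `[ratio_lo, ratio_hi]`; each ratio is matched to the
#' closest pool pair and instantiated into concrete options. Gain and loss
#' trials form separate blocks whose order is randomized per call, trial
#' order is shuffled within blocks, and the screen side of the more painful
#' option is randomized per trial. Fully reproducible from `seed`.
#'
#' @param n_per_cell Trials per context x recipient cell (default 60, giving
#'   240 in total).
#' @param ratio_lo,ratio_hi Desired-ratio grid bounds (defaults 0.01, 0.99).
#' @param seed Optional integer seed.
#' @return Data frame of class `ha_trialset` with columns `trial_id`,
#'   `block`, `context`, `recipient`, `money_more`, `money_less`,
#'   `shocks_more`, `shocks_less`, `delta_m`, `delta_s`, `desired_ratio`,
#'   `side_more`; block order stored in `attr(, "block_order")`.
#' @export
build_trialset <- function(n_per_cell = 60, ratio_lo = 0.01, ratio_hi = 0.99,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- build_pair_pool()
  ratios <- ratio_grid(n_per_cell, ratio_lo, ratio_hi)
  block_order <- sample(c("gain", "loss"))
  blocks <- list()
  for (context in block_order) {
    cell_rows <- list()
    for (recipient in c("self", "other")) {
      for (r in ratios) {
        pr <- select_pair(r, pool)
        tr <- instantiate_options(pr, context = context)
        tr$recipient <- recipient
        tr$desired_ratio <- r
        cell_rows[[length(cell_rows) + 1L]] <- tr
      }
    }
    blk <- do.call(rbind, cell_rows)
    blk <- blk[sample.int(nrow(blk)), , drop = FALSE]
    blk$block <- match(context, block_order)
    blocks[[context]] <- blk
  }
  trials <- do.call(rbind, blocks[block_order])
  trials$side_more <- sample(c("left", "right"), nrow(trials), replace = TRUE)
  trials$trial_id <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  cols <- c("trial_id", "block", "context", "recipient", "money_more",
            "money_less", "shocks_more", "shocks_less", "delta_m", "delta_s",
            "desired_ratio", "side_more")
  trials <- trials[, cols]
  attr(trials, "block_order") <- block_order
  attr(trials, "seed") <- seed
  class(trials) <- c("ha_trialset", "data.frame")
  trials
}
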