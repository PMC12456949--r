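# Trial construction: pair pool, ratio grid, closest-pair selection,
# option instantiation, gain->loss transform, full trial sets, calibration.

test_that("pair pool is the exhaustive 19 x 99 grid", {
  pool <- build_pair_pool()
  expect_equal(nrow(pool), 1881)
  expect_equal(anyDuplicated(pool[, c("delta_s", "delta_m")]), 0)
  expect_true(all(pool$delta_s %in% 1:19))
  expect_true(all(pool$dm_units %in% 1:99))
  # corners present, delta_s-major ordering
  expect_equal(pool$delta_s[1], 1)
  expect_equal(pool$delta_m[1], 0.2)
  expect_equal(pool$delta_s[1881], 19)
  expect_equal(pool$delta_m[1881], 19.8)
  # forced arithmetic: ratio of the (19, 0.2) pair
  i <- which(pool$delta_s == 19 & pool$dm_units == 1)
  expect_equal(pool$ratio[i], 0.2 / 19.2)
})

test_that("ratio_grid spaces ratios evenly and validates its arguments", {
  g <- ratio_grid(60, 0.01, 0.99)
  expect_equal(g[1], 0.01)
  expect_equal(g[60], 0.99)
  expect_equal(unique(round(diff(g), 12)), round(0.98 / 59, 12))
  expect_equal(ratio_grid(3, 0, 1), c(0, 0.5, 1))
  expect_error(ratio_grid(1, 0.1, 0.9), "n")
  expect_error(ratio_grid(10, 0.9, 0.1), "lo < hi")
})

test_that("select_pair is an exact argmin with uniform tie-breaking", {
  pool <- build_pair_pool()
  # oracle equivalence over the full 60-ratio grid
  set.seed(11)
  for (r in ratio_grid(60, 0.01, 0.99)) {
    got <- select_pair(r, pool)
    orc <- oracle_closest(r, pool)
    expect_equal(abs(got$delta_m / (got$delta_s + got$delta_m) - r), orc$dist,
                 tolerance = 1e-12)
  }
  # extreme ratio pins the corner pair
  expect_equal(select_pair(0.01, pool)[c("delta_s", "delta_m")],
               list(delta_s = 19L, delta_m = 0.2))
  # ratio 0.5 ties across delta_m == delta_s pairs; draw varies but stays tied
  set.seed(2)
  picks <- replicate(40, {
    p <- select_pair(0.5, pool)
    expect_equal(p$delta_m, p$delta_s)
    p$delta_s
  })
  expect_gt(length(unique(picks)), 3)
  expect_error(select_pair(0.5, pool[0, ]), "empty")
})

test_that("instantiate_options respects the relaxed feasibility bounds", {
  set.seed(3)
  # the extreme pair admits a single feasible draw
  tr <- instantiate_options(list(delta_s = 19, dm_units = 99), "gain")
  expect_equal(tr$shocks_less, 1)
  expect_equal(tr$shocks_more, 20)
  expect_equal(tr$money_less, 0.2)
  expect_equal(tr$money_more, 20)
  # invariants over many random draws
  pool <- build_pair_pool()
  for (i in 1:200) {
    p <- pool[sample.int(1881, 1), ]
    tr <- instantiate_options(p, sample(c("gain", "loss"), 1))
    expect_gte(tr$shocks_less, 1)
    expect_lte(tr$shocks_more, 20)
    expect_lte(max(abs(tr$money_more), abs(tr$money_less)), 20)
    expect_equal(tr$shocks_more - tr$shocks_less, tr$delta_s)
    # additive money identity, exact on the 0.2-yuan integer grid
    expect_identical(round((tr$money_more - tr$money_less) * 5),
                     round(tr$delta_m * 5))
    if (tr$context == "gain") expect_gt(tr$money_less, 0)
    if (tr$context == "loss") expect_lte(tr$money_more, 0)
  }
})

test_that("to_loss flips and swaps money, preserves shocks and deltas", {
  g <- data.frame(context = "gain", money_more = 15, money_less = 10,
                  shocks_more = 10, shocks_less = 5, delta_s = 5, delta_m = 5)
  l <- to_loss(g)
  # the published worked example: [15, 10 shocks; 10, 5 shocks] ->
  # [-10, 10 shocks; -15, 5 shocks]
  expect_equal(l$money_more, -10)
  expect_equal(l$money_less, -15)
  expect_equal(l$shocks_more, 10)
  expect_equal(l$shocks_less, 5)
  expect_equal(l$delta_m, g$delta_m)
  expect_equal(l$delta_s, g$delta_s)
  # flip-and-swap is an involution on the money values
  l2 <- l
  l2$context <- "gain"
  back <- to_loss(l2)
  expect_equal(back$money_more, g$money_more)
  expect_equal(back$money_less, g$money_less)
  expect_error(to_loss(l), "gain-context")
})

test_that("build_trialset yields 60 trials per cell and is reproducible", {
  ts1 <- build_trialset(seed = 7)
  ts2 <- build_trialset(seed = 7)
  expect_identical(as.data.frame(ts1), as.data.frame(ts2))
  expect_equal(nrow(ts1), 240)
  tab <- table(ts1$context, ts1$recipient)
  expect_true(all(tab == 60))
  # per-cell desired ratios are the even grid
  for (ctx in c("gain", "loss")) {
    for (rec in c("self", "other")) {
      r <- sort(ts1$desired_ratio[ts1$context == ctx & ts1$recipient == rec])
      expect_equal(r, ratio_grid(60, 0.01, 0.99))
    }
  }
  # different seed, different set
  expect_false(identical(as.data.frame(build_trialset(seed = 8)),
                         as.data.frame(ts1)))
  # block structure: contexts do not interleave
  expect_equal(length(rle(ts1$context)$values), 2)
  # smaller designs honour n_per_cell
  expect_equal(nrow(build_trialset(n_per_cell = 5, seed = 1)), 20)
})

test_that("calibration curve recovers parameters and inverts in closed form", {
  x <- seq(1, 5, by = 0.25)
  r <- 10 / (1 + exp(-(x - 3) / 0.5))
  fit <- fit_rating_curve(x, r)
  expect_true(fit$converged)
  expect_equal(fit$midpoint, 3, tolerance = 1e-3)
  expect_equal(fit$width, 0.5, tolerance = 1e-3)
  expect_equal(intensity_for_rating(fit, 5), fit$midpoint, tolerance = 1e-9)
  expect_equal(intensity_for_rating(fit, 7),
               fit$midpoint + fit$width * log(7 / 3), tolerance = 1e-9)
  expect_error(intensity_for_rating(fit, 10), "strictly inside")
  expect_error(fit_rating_curve(c(1, 2, 3), c(1, 2, 3)), "4 distinct")
  expect_error(fit_rating_curve(x, r + 5), "\\[0, 10\\]")
  # decreasing ratings cannot be fit by an increasing sigmoid: flagged
  bad <- fit_rating_curve(x, rev(r))
  expect_false(bad$converged)
})
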