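# Harm-aversion model: value function, choice rule, likelihood, MLE.

test_that("delta_value implements the linear trade-off exactly", {
  expect_equal(delta_value(0, 5, 3), 5)
  expect_equal(delta_value(1, 5, 3), -3)
  expect_equal(delta_value(0.5, 2, 1), 0.5)
  expect_error(delta_value(1.2, 1, 1), "\\[0, 1\\]")
})

test_that("p_less_painful has the hyperaltruism-consistent orientation", {
  # indifference when kappa * ds == (1 - kappa) * dm
  expect_equal(p_less_painful(0.5, 3, 4, 4), 0.5)
  # gamma = 0 is random choice
  expect_equal(p_less_painful(0.9, 0, 1, 19), 0.5)
  # closed form
  expect_equal(p_less_painful(0.5, 1, 1, 3), 1 / (1 + exp(-1)), tolerance = 1e-12)
  # strictly increasing in kappa and delta_s, decreasing in delta_m
  ks <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(p_less_painful(ks, 2, 3, 5)) > 0))
  expect_true(all(diff(p_less_painful(0.4, 2, 3, 1:19)) > 0))
  expect_true(all(diff(p_less_painful(0.4, 2, seq(0.2, 19.8, 0.2), 5)) < 0))
  # numerically stable at extreme arguments
  expect_equal(p_less_painful(1, 50, 0.2, 19), 1)
  expect_equal(p_less_painful(0, 50, 19.8, 1), 0)
})

test_that("neg_log_lik matches closed forms and is additive", {
  d <- data.frame(context = "gain", recipient = "self",
                  delta_m = c(1, 2, 3), delta_s = c(3, 2, 1),
                  choice = c(1, 0, 1))
  # gamma = 0: every p is 0.5
  expect_equal(neg_log_lik(c(0.3, 1e-4), d, model_spec()), 3 * log(2),
               tolerance = 1e-3)
  # single-trial closed form
  d1 <- d[1, ]
  expect_equal(neg_log_lik(c(0.5, 1), d1, model_spec()),
               -log(1 / (1 + exp(-1))), tolerance = 1e-12)
  # additivity over trials
  total <- neg_log_lik(c(0.4, 2), d, model_spec())
  parts <- sum(vapply(1:3, function(i) neg_log_lik(c(0.4, 2), d[i, ], model_spec()),
                      0))
  expect_equal(total, parts, tolerance = 1e-12)
  expect_error(neg_log_lik(c(0.4, 2), d[0, ], model_spec()), "empty")
})

test_that("analytic gradient of the likelihood matches finite differences", {
  set.seed(4)
  ch <- sim_subject(c(gain_self = 0.3, gain_other = 0.6, loss_self = 0.4,
                      loss_other = 0.45), 2, n_per_cell = 15, seed = 4)
  pre <- harmaversion:::.prep_choices(ch, model_spec())
  fn <- harmaversion:::.nll_fun(pre)
  gr <- harmaversion:::.nll_grad(pre)
  par <- c(0.3, 0.55, 0.42, 0.5, 1.7)
  num <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    e <- numeric(length(par)); e[j] <- h
    (fn(par + e) - fn(par - e)) / (2 * h)
  }, 0)
  expect_equal(gr(par), num, tolerance = 1e-5)
})

test_that("MLE attains the grid-search oracle on a one-cell dataset", {
  set.seed(5)
  ts <- build_trialset(n_per_cell = 60, seed = 5)
  cell <- ts[ts$context == "gain" & ts$recipient == "self", ]
  ch <- simulate_choices(c(gain_self = 0.45), 1.5, cell)
  fit <- fit_subject(ch, n_restarts = 30, seed = 6)
  oracle <- oracle_grid_nll(ch)
  expect_lte(fit$nll, oracle + 1e-6)
})

test_that("fit_subject recovers generative parameters on a full session", {
  truth <- c(gain_self = 0.3, gain_other = 0.6, loss_self = 0.4,
             loss_other = 0.4)
  ch <- sim_subject(truth, 2, seed = 10)
  fit <- fit_subject(ch, n_restarts = 30, seed = 11)
  expect_lt(max(abs(fit$kappa[names(truth)] - truth)), 0.1)
  expect_equal(fit$aic, 2 * fit$nll + 2 * fit$n_params)
  expect_equal(fit$bic, 2 * fit$nll + fit$n_params * log(fit$n_trials))
  expect_false(any(fit$boundary))
})

test_that("degenerate responders are flagged at the bound, never dropped", {
  ts <- build_trialset(n_per_cell = 15, seed = 12)
  ch <- as.data.frame(ts)
  ch$choice <- 1  # always the less painful option
  fit <- fit_subject(ch, n_restarts = 20, seed = 13)
  expect_true(all(fit$kappa > 0.99))
  expect_true(any(fit$boundary))
})

test_that("hyperaltruism_index contrasts recipients per context", {
  fit <- structure(list(kappa = c(gain_self = 0.4, gain_other = 0.6,
                                  loss_self = 0.45, loss_other = 0.45)),
                   class = "ha_fit")
  idx <- hyperaltruism_index(fit)
  expect_equal(idx[["gain"]], 0.2)
  expect_equal(idx[["loss"]], 0)
  fit$kappa <- fit$kappa[-2]
  expect_error(hyperaltruism_index(fit), "missing a recipient")
})

test_that("richer gamma partitions never fit worse (nesting)", {
  set.seed(14)
  ch <- sim_subject(c(gain_self = 0.35, gain_other = 0.5, loss_self = 0.4,
                      loss_other = 0.4), 2, n_per_cell = 20, seed = 14)
  f1 <- fit_subject(ch, model_spec("single"), n_restarts = 25, seed = 15)
  f2 <- fit_subject(ch, model_spec("per_context"), n_restarts = 25, seed = 16)
  f4 <- fit_subject(ch, model_spec("per_condition"), n_restarts = 25, seed = 17)
  expect_lte(f2$nll, f1$nll + 1e-4)
  expect_lte(f4$nll, f2$nll + 1e-4)
  expect_equal(f1$n_params, 5)
  expect_equal(f2$n_params, 6)
  expect_equal(f4$n_params, 8)
})

test_that("compare_specs ranks by aggregate BIC and degenerates gracefully", {
  set.seed(18)
  ch <- do.call(rbind, lapply(1:3, function(s) {
    d <- sim_subject(c(gain_self = 0.35, gain_other = 0.5, loss_self = 0.4,
                       loss_other = 0.4), 2, n_per_cell = 15, seed = 18 + s)
    d$subject_id <- s
    d
  }))
  one <- compare_specs(ch, list(model_spec("single")), n_restarts = 10, seed = 19)
  expect_equal(nrow(one$summary), 1)
  expect_equal(one$summary$rank, 1)
  both <- compare_specs(ch, list(model_spec("single"), model_spec("per_context")),
                        n_restarts = 10, seed = 20)
  expect_setequal(both$summary$spec, c("single", "per_context"))
  expect_equal(both$summary$rank, 1:2)
})
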