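# Bayesian mediator, outcome, total-effect and attrition models, and the
# posterior summary conventions.

test_that("standardisation follows the n-1 convention and round-trips", {
  ref <- c(1, 3)
  st <- standardize_mediator(3, ref)
  expect_equal(st$values, (3 - 2) / sqrt(2), tolerance = 1e-12)
  x <- c(2.2, 5.5, 9.1, 4.4)
  st2 <- standardize_mediator(x)
  expect_equal(st2$values * st2$scale + st2$center, x, tolerance = 1e-12)
  expect_equal(mean(st2$values), 0, tolerance = 1e-12)
  expect_error(standardize_mediator(c(1, 2), c(5, 5)), "degenerate")
})

test_that("mediator model recovers the standardised arm effect", {
  cfg <- full_response(test_config(n = 2000))
  d <- simulate_trial(cfg, 301)
  fit <- fit_med_quick(d, "knowhow", 1, seed = 302)
  est <- median(fit$draws[, "arm"])
  expect_lt(abs(est - 0.55), 0.15)
  expect_lt(fit$diagnostics$max_rhat, 1.01)
  s <- summarize_draws(fit$draws[, "arm"], scale = "standardised_difference")
  expect_gt(s$prob_direction, 0.99)
  expect_true(s$ci_low <= s$estimate && s$estimate <= s$ci_high)
})

test_that("null arm effect yields prob_direction near one half", {
  cfg <- full_response(test_config(n = 1000))
  cfg$arm_effect[] <- 0
  pd <- vapply(1:5, function(s) {
    d <- simulate_trial(cfg, 310 + s)
    fit <- fit_med_quick(d, "confidence", 1, seed = 320 + s)
    summarize_draws(fit$draws[, "arm"])$prob_direction
  }, numeric(1))
  expect_gt(mean(pd), 0.3)
  expect_lt(mean(pd), 0.7)
})

test_that("the prior washes out at large n (agreement with least squares)", {
  cfg <- full_response(test_config(n = 20000))
  d <- simulate_trial(cfg, 331)
  fit <- fit_mediator_model(d, "knowhow", 1, n_chains = 2, n_keep = 400,
                            warmup = 200, seed = 332)
  yt <- standardize_mediator(d$knowhow_1)
  X <- fit$X
  ls <- lm.fit(X, yt$values)$coefficients
  post_sd <- sd(fit$draws[, "arm"])
  expect_lt(abs(median(fit$draws[, "arm"]) - ls["arm"]), 2 * post_sd)
})

test_that("insufficient rows raise an informative error", {
  cfg <- full_response(test_config(n = 10))
  d <- simulate_trial(cfg, 341)
  expect_error(fit_mediator_model(d, "knowhow", 3), "insufficient data")
})

test_that("outcome model recovers mediator coefficients and the null", {
  cfg <- full_response(single_mediator_config("knowhow", n = 12000, b = 0.8))
  d <- simulate_trial(cfg, 351)
  rows <- mediation_rows(d, "knowhow", 1, "prolonged", 3)
  fit <- fit_out_quick(d, "prolonged", 3, "knowhow", 1, rows = rows,
                       seed = 352)
  expect_lt(abs(median(fit$draws[, "med_knowhow"]) - 0.8), 0.12)
  expect_false(isTRUE(fit$diagnostics$separation_suspected))

  cfg0 <- full_response(test_config(n = 4000))
  for (o in names(cfg0$outcomes)) cfg0$outcomes[[o]]$b[] <- 0
  d0 <- simulate_trial(cfg0, 353)
  rows0 <- mediation_rows(d0, MEDIATORS_TEST, 1, "prolonged", 3)
  fit0 <- fit_out_quick(d0, "prolonged", 3, MEDIATORS_TEST, 1, rows = rows0,
                        seed = 354)
  pd0 <- numeric(0)
  for (m in MEDIATORS_TEST) {
    s <- summarize_draws(fit0$draws[, paste0("med_", m)])
    expect_lt(abs(s$estimate), 0.12)
    pd0 <- c(pd0, s$prob_direction)
  }
  # under the null prob_direction behaves like a p-value (roughly uniform
  # across datasets); only its average is pinned near one half
  expect_gt(mean(pd0), 0.2)
  expect_lt(mean(pd0), 0.8)
})

test_that("effect-coefficient priors are standard normal (prior recovery)", {
  cfg <- full_response(test_config(n = 60))
  d <- simulate_trial(cfg, 361)
  rows <- integer(0)
  # zero-row fits fall back to the prior
  des <- cfmediate:::build_design(d, seq_len(nrow(d)), "knowhow")
  X <- des$X[integer(0), , drop = FALSE]
  prior <- cfmediate:::prior_for_design(X)
  chains <- cfmediate:::gibbs_logistic(X, numeric(0), prior$mean, prior$sd,
                                       n_chains = 2, n_keep = 2000,
                                       warmup = 200, seed = 362)
  draws <- do.call(rbind, chains)
  expect_lt(abs(mean(draws[, "arm"])), 0.08)
  expect_lt(abs(sd(draws[, "arm"]) - 1), 0.08)
  expect_lt(abs(sd(draws[, "(Intercept)"]) - 10), 0.8)
})

test_that("total effect: subsample identity and the null", {
  cfg <- full_response(test_config(n = 3000))
  for (o in names(cfg$outcomes)) {
    cfg$outcomes[[o]]$theta_A <- 0
    cfg$outcomes[[o]]$b[] <- 0
  }
  d <- simulate_trial(cfg, 371)
  t_full <- fit_total_effect(d, "prolonged", 3, n_chains = 2, n_keep = 400,
                             warmup = 200, seed = 372)
  expect_gt(t_full$summary$ci_high, 1)
  expect_lt(t_full$summary$ci_low, 1)
  t_sub <- fit_total_effect(d, "prolonged", 3,
                            subsample_rule = function(x) rep(TRUE, nrow(x)),
                            n_chains = 2, n_keep = 400, warmup = 200,
                            seed = 372)
  expect_identical(t_sub$fit$draws, t_full$fit$draws)
  expect_error(fit_total_effect(d, "prolonged", 3,
                                subsample_rule = function(x) rep(FALSE, nrow(x))),
               "empty subsample")
})

test_that("attrition model finds the age and dependence-by-arm structure", {
  cfg <- test_config(n = 6000)
  d <- simulate_trial(cfg, 381)
  fit <- fit_attrition_model(d, 1, n_chains = 2, n_keep = 500, warmup = 250,
                             seed = 382)
  eff <- fit$arm_effects
  age_ctl <- eff[eff$covariate == "age_z" & eff$arm == "control", ]
  age_int <- eff[eff$covariate == "age_z" & eff$arm == "intervention", ]
  expect_gt(age_ctl$prob_direction, 0.9)
  expect_gt(age_int$prob_direction, 0.9)
  ftnd_int <- eff[eff$covariate == "ftnd_z" & eff$arm == "intervention", ]
  ftnd_ctl <- eff[eff$covariate == "ftnd_z" & eff$arm == "control", ]
  expect_lt(ftnd_int$prob_direction, 0.1)
  expect_lt(ftnd_int$estimate, 0)
  expect_gt(ftnd_ctl$prob_direction, 0.1)
  expect_gt(median(fit$fit$aux$tau), 0)
})

test_that("MCAR missingness leaves every attrition effect near the null", {
  cfg <- test_config(n = 3000)
  for (t in names(cfg$miss$med)) {
    cfg$miss$med[[t]]$age_slope <- 0
    cfg$miss$med[[t]]$ftnd_moderation <- FALSE
    cfg$miss$med[[t]]$int_rate <- 0.5
    cfg$miss$med[[t]]$ctl_rate <- 0.5
  }
  d <- simulate_trial(cfg, 391)
  fit <- fit_attrition_model(d, 1, n_chains = 2, n_keep = 500, warmup = 250,
                             seed = 392)
  pd <- fit$arm_effects$prob_direction
  expect_true(all(pd > 0.05 & pd < 0.95))
  expect_lt(mean(abs(fit$arm_effects$estimate)), 0.1)
})

test_that("degenerate responses are rejected", {
  cfg <- full_response(test_config(n = 200))
  d <- simulate_trial(cfg, 395)
  expect_error(fit_attrition_model(d, 1), "degenerate response")
  expect_error(fit_attrition_model(d, response_field = "nope"),
               "no such response field")
})

test_that("summaries are transform-equivariant and handle edge draws", {
  expect_equal(summarize_draws(c(-1, 0, 1))$estimate, 0)
  s <- summarize_draws(rep(0.7, 50), transform = "exp")
  expect_equal(s$estimate, exp(0.7), tolerance = 1e-12)
  expect_equal(s$ci_low, s$ci_high)
  # 2001 draws put the 2.5/50/97.5 percentiles exactly on order statistics,
  # where interpolation plays no role and equivariance is exact
  set.seed(99)
  x <- rnorm(2001, 0.3, 0.8)
  s_log <- summarize_draws(x)
  s_exp <- summarize_draws(x, transform = "exp")
  expect_equal(exp(s_log$estimate), s_exp$estimate, tolerance = 1e-10)
  expect_equal(exp(s_log$ci_low), s_exp$ci_low, tolerance = 1e-10)
  expect_equal(exp(s_log$ci_high), s_exp$ci_high, tolerance = 1e-10)
  expect_equal(s_log$prob_direction, s_exp$prob_direction)
  expect_error(summarize_draws(numeric(0)), "empty draws")
})

test_that("the diagnostics gate blocks suspect fits unless overridden", {
  fake <- structure(list(draws = matrix(rnorm(100), 50, 2),
                         diagnostics = list(max_rhat = 1.2, min_ess = 10,
                                            divergences = 0L),
                         spec = list(response = "toy")),
                    class = "posterior_draws")
  expect_error(check_diagnostics(fake), "Rhat")
  expect_warning(check_diagnostics(fake, override = TRUE), "Rhat")
  ok <- fake
  ok$diagnostics$max_rhat <- 1.002
  expect_silent(check_diagnostics(ok))
})
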