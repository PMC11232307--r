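# Counterfactual mediation: the integration kernel, the natural-effect
# engine, pairing identities and invariances.

toy_inputs <- function(n = 60, seed = 5) {
  set.seed(seed)
  X <- cbind(`(Intercept)` = 1, arm = rbinom(n, 1, 0.5), age_z = rnorm(n))
  out_draw <- c(`(Intercept)` = -1, arm = 0.6, age_z = -0.2,
                med_knowhow = 0.8)
  med_draws <- list(knowhow = list(
    coef = c(`(Intercept)` = 0.1, arm = 0.5, age_z = 0.15), sigma = 0.9))
  list(X = X, out = out_draw, med = med_draws)
}

test_that("integration collapses when the mediator carries no weight", {
  ti <- toy_inputs()
  out0 <- ti$out
  out0["med_knowhow"] <- 0
  p_a0 <- counterfactual_risk(out0, ti$med, 1, 0, ti$X)
  p_a1 <- counterfactual_risk(out0, ti$med, 1, 1, ti$X)
  Xd <- ti$X; Xd[, "arm"] <- 1
  plug <- mean(plogis(Xd %*% out0[colnames(Xd)]))
  expect_equal(p_a0, plug, tolerance = 1e-12)
  expect_equal(p_a1, plug, tolerance = 1e-12)
})

test_that("vanishing residual sd reduces to the plug-in of the mean", {
  ti <- toy_inputs()
  ti$med$knowhow$sigma <- 1e-12
  p <- counterfactual_risk(ti$out, ti$med, 0, 1, ti$X)
  Xm <- ti$X; Xm[, "arm"] <- 1
  mu <- Xm %*% ti$med$knowhow$coef
  X0 <- ti$X; X0[, "arm"] <- 0
  plug <- mean(plogis(X0 %*% ti$out[colnames(X0)] + 0.8 * mu))
  expect_equal(p, plug, tolerance = 1e-9)
})

test_that("Gauss-Hermite and Monte Carlo integration agree to 3 decimals", {
  ti <- toy_inputs()
  p_gh <- counterfactual_risk(ti$out, ti$med, 1, 0, ti$X,
                              method = "gauss_hermite", size = 64)
  p_mc <- counterfactual_risk(ti$out, ti$med, 1, 0, ti$X,
                              method = "monte_carlo", size = 1e6, seed = 2)
  expect_equal(p_gh, p_mc, tolerance = 5e-4)
  expect_error(counterfactual_risk(ti$out, ti$med, 1, 0, ti$X, size = 0),
               "size")
  bad <- ti$med; bad$knowhow$sigma <- NaN
  expect_error(counterfactual_risk(ti$out, bad, 1, 0, ti$X), "non-finite")
})

test_that("null mediation concentrates the NIE at one", {
  cfg <- full_response(test_config(n = 2500))
  for (o in names(cfg$outcomes)) cfg$outcomes[[o]]$b[] <- 0
  d <- simulate_trial(cfg, 401)
  rows <- mediation_rows(d, "knowhow", 1, "prolonged", 3)
  mf <- fit_med_quick(d, "knowhow", 1, rows = rows, seed = 402)
  of <- fit_out_quick(d, "prolonged", 3, "knowhow", 1, rows = rows,
                      seed = 403)
  ne <- natural_effects(list(knowhow = mf), of)
  log_nie <- ne$log_or_draws[, "nie"]
  expect_lt(abs(median(log_nie)), 3 * sd(log_nie))
  expect_lt(abs(log(ne$nde$estimate) - log(ne$te$estimate)), 0.05)
})

test_that("the complementary pairing multiplies exactly to the total effect", {
  cfg <- full_response(test_config(n = 1500))
  d <- simulate_trial(cfg, 411)
  rows <- mediation_rows(d, "confidence", 1, "prolonged", 3)
  mf <- fit_med_quick(d, "confidence", 1, rows = rows, seed = 412)
  of <- fit_out_quick(d, "prolonged", 3, "confidence", 1, rows = rows,
                      seed = 413)
  ne <- natural_effects(list(confidence = mf), of)
  expect_lt(ne$decomposition_max_abs_err, 1e-10)
  # headline pairing deviation from the multiplicative pairing is reported
  ne_c <- natural_effects(list(confidence = mf), of,
                          pairing = "total")
  expect_equal(ne_c$nde$estimate, ne$nde_comp$estimate, tolerance = 1e-12)
  expect_identical(ne$spec$pairing, "pure")
})

test_that("results are invariant to rescaling the raw mediator values", {
  cfg <- full_response(test_config(n = 1500))
  d <- simulate_trial(cfg, 421)
  run <- function(data) {
    rows <- mediation_rows(data, "knowhow", 1, "prolonged", 3)
    mf <- fit_med_quick(data, "knowhow", 1, rows = rows, seed = 422)
    of <- fit_out_quick(data, "prolonged", 3, "knowhow", 1, rows = rows,
                        seed = 423)
    natural_effects(list(knowhow = mf), of)
  }
  ne1 <- run(d)
  d10 <- d
  for (cc in grep("^knowhow_", names(d10), value = TRUE))
    d10[[cc]] <- d10[[cc]] * 10
  ne2 <- run(d10)
  expect_equal(ne1$nie$estimate, ne2$nie$estimate, tolerance = 1e-3)
  expect_equal(ne1$nde$estimate, ne2$nde$estimate, tolerance = 1e-3)
})

test_that("with one active mediator the joint model matches the single one", {
  cfg <- full_response(single_mediator_config("knowhow", n = 4000))
  d <- simulate_trial(cfg, 431)
  rows <- mediation_rows(d, MEDIATORS_TEST, 1, "prolonged", 3)
  mfits <- setNames(lapply(seq_along(MEDIATORS_TEST), function(j)
    fit_med_quick(d, MEDIATORS_TEST[j], 1, rows = rows, seed = 432 + j)),
    MEDIATORS_TEST)
  of_joint <- fit_out_quick(d, "prolonged", 3, MEDIATORS_TEST, 1,
                            rows = rows, seed = 436)
  joint <- joint_natural_effects(mfits, of_joint)
  of_single <- fit_out_quick(d, "prolonged", 3, "knowhow", 1, rows = rows,
                             seed = 437)
  single <- natural_effects(list(knowhow = mfits$knowhow), of_single)
  expect_lt(abs(log(joint$nie$estimate) - log(single$nie$estimate)), 0.07)
  expect_error(joint_natural_effects(mfits["knowhow"], of_joint),
               "three mediator")
})

test_that("misaligned fits are rejected", {
  cfg <- full_response(test_config(n = 800))
  d <- simulate_trial(cfg, 441)
  rows <- mediation_rows(d, "knowhow", 1, "prolonged", 3)
  mf <- fit_med_quick(d, "knowhow", 1, rows = rows[-1], seed = 442)
  of <- fit_out_quick(d, "prolonged", 3, "knowhow", 1, rows = rows,
                      seed = 443)
  expect_error(natural_effects(list(knowhow = mf), of), "not aligned")
  expect_error(natural_effects(list(mf), of), "named list")
})

test_that("mediation tables round-trip exactly and handle edge cases", {
  expect_identical(nrow(mediation_table(list())), 0L)
  cfg <- full_response(test_config(n = 800))
  d <- simulate_trial(cfg, 451)
  rows <- mediation_rows(d, "knowhow", 1, "prolonged", 3)
  mf <- fit_med_quick(d, "knowhow", 1, rows = rows, seed = 452)
  of <- fit_out_quick(d, "prolonged", 3, "knowhow", 1, rows = rows,
                      seed = 453)
  ne <- natural_effects(list(knowhow = mf), of)
  path <- tempfile(fileext = ".csv")
  tab <- mediation_table(list(knowhow_1_3 = ne), file = path)
  back <- parse_mediation_table(path)
  expect_equal(back$estimate, tab$estimate, tolerance = 0)
  expect_equal(back$ci_low, tab$ci_low, tolerance = 0)
  expect_identical(back$effect, tab$effect)
  unlink(path)
})
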