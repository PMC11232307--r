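# Synthetic trial generator: baseline distributions, block randomisation,
# mediator trajectories, outcomes, attrition, and the end-to-end contracts.

test_that("baseline sample reproduces the configured summary statistics", {
  cfg <- test_config(n = 100000)
  d <- generate_baseline(cfg, 42)
  expect_lt(abs(mean(d$age) - 45.4), 0.2)
  expect_lt(abs(sd(d$age) - 14), 0.2)
  expect_true(all(d$age >= 18))
  expect_lt(abs(mean(d$sex == "woman") - 0.81), 0.01)
  expect_lt(abs(mean(d$version == "surgery") - 0.062), 0.005)
  expect_true(all(d$ftnd >= 0 & d$ftnd <= 10))
  expect_true(all(d$cigs_per_week >= 1))
  for (m in MEDIATORS_TEST) {
    v <- d[[paste0(m, "_0")]]
    expect_true(all(v >= 1 & v <= 10))
  }
  # importance sits near its ceiling
  expect_gt(mean(d$importance_0), 9)
})

test_that("empty and repeated generation behave as contracted", {
  cfg <- test_config(n = 0)
  d0 <- generate_baseline(cfg, 1)
  expect_identical(nrow(d0), 0L)
  cfg <- test_config(n = 300)
  expect_identical(generate_baseline(cfg, 7), generate_baseline(cfg, 7))
  expect_identical(simulate_trial(cfg, 9), simulate_trial(cfg, 9))
})

test_that("invalid configurations are rejected", {
  cfg <- test_config(n = 100)
  cfg$age_sd <- -1
  expect_error(generate_baseline(cfg, 1), "age_sd")
  cfg <- test_config(n = 100)
  cfg$p_woman <- 1.4
  expect_error(generate_baseline(cfg, 1), "p_woman")
  cfg <- test_config(n = 100)
  cfg$block_sizes <- c(3)
  expect_error(cfmediate:::validate_generator_config(cfg), "block_sizes")
})

test_that("block randomisation balances arms within strata", {
  cfg <- test_config(n = 2)
  d <- generate_baseline(cfg, 3)
  d$version <- "general"
  r <- randomize(d, block_sizes = 2, seed = 5)
  expect_setequal(r$group, c("intervention", "control"))

  # imbalance bound over replicates and strata
  cfg <- test_config(n = 301)
  d <- generate_baseline(cfg, 11)
  for (s in 1:40) {
    r <- randomize(d, c(2, 4), seed = s)
    for (v in unique(r$version)) {
      g <- r$group[r$version == v]
      expect_lte(abs(sum(g == "intervention") - sum(g == "control")), 2)
    }
  }
})

test_that("allocation probability is 1/2 at every enrolment position", {
  cfg <- test_config(n = 300)
  d <- generate_baseline(cfg, 21)
  reps <- 5000
  counts <- matrix(0, reps, nrow(d))
  for (s in seq_len(reps))
    counts[s, ] <- randomize(d, c(2, 4), seed = 100000 + s)$group == "intervention"
  p_hat <- colMeans(counts)
  expect_lt(max(abs(p_hat - 0.5)), 0.035)
})

test_that("mediator trajectories follow the configured effect structure", {
  # null arm effects
  cfg <- test_config(n = 50000)
  cfg$arm_effect[] <- 0
  d <- simulate_trial(cfg, 31, missingness = FALSE)
  for (t in c(1, 3, 6)) {
    for (m in MEDIATORS_TEST) {
      v <- d[[paste0(m, "_", t)]]
      z <- (v - mean(v)) / sd(v)
      diff <- mean(z[d$group == "intervention"]) - mean(z[d$group == "control"])
      expect_lt(abs(diff), 0.05)
    }
  }
  # positive know-how effect raises the intervention mean
  cfg <- test_config(n = 50000)
  d <- simulate_trial(cfg, 32, missingness = FALSE)
  expect_gt(mean(d$knowhow_1[d$group == "intervention"]),
            mean(d$knowhow_1[d$group == "control"]))
  # default calibration: importance flat and high, know-how/confidence diverge
  for (t in c(1, 3, 6)) {
    imp_i <- mean(d[[paste0("importance_", t)]][d$group == "intervention"])
    imp_c <- mean(d[[paste0("importance_", t)]][d$group == "control"])
    expect_gt(imp_i, 8.5); expect_gt(imp_c, 8.5)
    if (t == 1) expect_lt(abs(imp_i - imp_c), 0.1)
    for (m in c("knowhow", "confidence")) {
      v <- d[[paste0(m, "_", t)]]
      expect_gt(mean(v[d$group == "intervention"]),
                mean(v[d$group == "control"]))
    }
  }
  # realised standardised effect matches the configured value
  cfg <- cfmediate:::ensure_cache(cfg)
  z <- (d$knowhow_1 - cfg$cache$std_center["knowhow", "1"]) /
    cfg$cache$std_scale["knowhow", "1"]
  diff <- mean(z[d$group == "intervention"]) - mean(z[d$group == "control"])
  expect_lt(abs(diff - 0.55), 0.03)
})

test_that("mediators require prior randomisation", {
  cfg <- test_config(n = 50)
  d <- generate_baseline(cfg, 1)
  expect_error(generate_mediators(d, cfg, 2), "randomised")
})

test_that("outcome generation respects nulls, monotonicity and the control rate", {
  cfg <- test_config(n = 100000)
  cfg$arm_effect[] <- 0
  for (o in names(cfg$outcomes)) {
    cfg$outcomes[[o]]$theta_A <- 0
    cfg$outcomes[[o]]$b[] <- 0
  }
  d <- simulate_trial(cfg, 41, missingness = FALSE)
  tab <- table(d$group, d$prolonged_3)
  or_emp <- (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
  expect_lt(abs(log(or_emp)), 0.08)

  # theta_0 monotonicity
  cfg2 <- test_config(n = 60000)
  cfg2$outcomes$prolonged_3$theta_0 <- cfg2$outcomes$prolonged_3$theta_0 + 0.7
  d1 <- simulate_trial(test_config(n = 60000), 43, missingness = FALSE)
  d2 <- simulate_trial(cfg2, 43, missingness = FALSE)
  r1 <- mean(d1$prolonged_3[d1$group == "control"])
  r2 <- mean(d2$prolonged_3[d2$group == "control"])
  expect_gt(r2, r1)

  # control-arm rate agrees with the oracle's marginal p(0, M(0))
  o <- oracle_true_effects(test_config(), "prolonged", 3, n_mc = 2e5, seed = 2)
  expect_lt(abs(r1 - o$p_marginal["p00"]), 0.01)
})

test_that("attrition masks follow the MAR response models", {
  # no-missingness limit: data unchanged
  cfg <- full_response(test_config(n = 2000))
  d_full <- simulate_trial(cfg, 51, missingness = FALSE)
  d_miss <- apply_missingness(d_full, cfg, 52)
  expect_true(all(d_miss$responded_med_1 == 1))
  expect_identical(d_miss$knowhow_1, d_full$knowhow_1)

  # default calibration reproduces the arm-specific 1-month rates
  cfg <- test_config(n = 1012)
  rates <- replicate(30, {
    d <- simulate_trial(cfg, sample.int(1e6, 1))
    c(all = mean(d$responded_med_1),
      int = mean(d$responded_med_1[d$group == "intervention"]),
      ctl = mean(d$responded_med_1[d$group == "control"]))
  })
  expect_lt(abs(mean(rates["all", ]) - 0.50), 0.03)
  expect_lt(mean(rates["int", ]), mean(rates["ctl", ]))

  # masked iff indicator 0; retained values unaltered
  d_pre <- simulate_trial(cfg, 61, missingness = FALSE)
  d_post <- apply_missingness(d_pre, cfg, 62)
  for (t in c(1, 3, 6)) {
    ind <- d_post[[paste0("responded_med_", t)]]
    for (m in MEDIATORS_TEST) {
      v <- d_post[[paste0(m, "_", t)]]
      expect_true(all(is.na(v[ind == 0])))
      expect_identical(v[ind == 1], d_pre[[paste0(m, "_", t)]][ind == 1])
    }
  }

  # refitting the attrition model recovers the dependence-by-arm interaction
  cfg_big <- test_config(n = 20000)
  d <- simulate_trial(cfg_big, 71)
  fit <- glm(responded_med_1 ~ age + group * ftnd, family = binomial(),
             data = transform(d, group = factor(group, c("control", "intervention"))))
  expect_lt(coef(fit)["groupintervention:ftnd"], 0)
  expect_gt(coef(fit)["age"], 0)
})
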