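# The MCMC engines: exact Polya-Gamma draws, the conjugate Gibbs samplers,
# and their diagnostics.

test_that("Polya-Gamma draws reproduce the known mean across tilt values", {
  set.seed(41)
  for (z in c(0, 0.8, 2.5, 6)) {
    x <- cfmediate:::.rpg(rep(z, 40000))
    m_true <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - m_true), 4 * se)
    expect_true(all(x > 0))
  }
})

test_that("logistic Gibbs posterior matches maximum likelihood at large n", {
  set.seed(7)
  n <- 3000
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), a = rbinom(n, 1, 0.5))
  y <- rbinom(n, 1, plogis(X %*% c(-1, 0.7, 0.5)))
  chains <- cfmediate:::gibbs_logistic(X, y, rep(0, 3), c(10, 1, 1),
                                       n_chains = 4, n_keep = 500,
                                       warmup = 250, seed = 2)
  draws <- do.call(rbind, chains)
  ml <- coef(glm(y ~ X - 1, family = binomial()))
  for (j in 1:3) {
    post_sd <- sd(draws[, j])
    expect_lt(abs(median(draws[, j]) - ml[j]), 2.5 * post_sd)
  }
  d <- cfmediate:::chain_diagnostics(chains)
  expect_lt(d$max_rhat, 1.01)
  expect_gt(d$min_ess, 400)
  expect_identical(d$divergences, 0L)
})

test_that("linear Gibbs recovers coefficients and the residual sd", {
  set.seed(8)
  n <- 2000
  X <- cbind(`(Intercept)` = 1, x = rnorm(n), a = rbinom(n, 1, 0.5))
  y <- as.vector(X %*% c(0.2, 0.6, 0.4)) + rnorm(n, sd = 0.9)
  fit <- cfmediate:::gibbs_linear(X, y, rep(0, 3), c(10, 1, 1),
                                  n_chains = 4, n_keep = 500, warmup = 250,
                                  seed = 3)
  draws <- do.call(rbind, fit$chains)
  truth <- c(0.2, 0.6, 0.4)
  for (j in 1:3)
    expect_lt(abs(median(draws[, j]) - truth[j]), 4 * sd(draws[, j]))
  expect_lt(abs(median(fit$sigma) - 0.9), 0.06)
  d <- cfmediate:::chain_diagnostics(fit$chains_full)
  expect_lt(d$max_rhat, 1.01)
})

test_that("with zero rows of data both samplers reproduce their priors", {
  X <- matrix(numeric(0), nrow = 0, ncol = 2,
              dimnames = list(NULL, c("(Intercept)", "x")))
  chains <- cfmediate:::gibbs_logistic(X, numeric(0), c(0, 0), c(10, 1),
                                       n_chains = 2, n_keep = 2000,
                                       warmup = 100, seed = 4)
  draws <- do.call(rbind, chains)
  expect_lt(abs(mean(draws[, "x"])), 0.08)
  expect_lt(abs(sd(draws[, "x"]) - 1), 0.08)
  fit <- cfmediate:::gibbs_linear(X, numeric(0), c(0, 0), c(10, 1),
                                  n_chains = 2, n_keep = 2000, warmup = 100,
                                  seed = 5)
  ld <- do.call(rbind, fit$chains)
  expect_lt(abs(mean(ld[, "x"])), 0.08)
  expect_lt(abs(sd(ld[, "x"]) - 1), 0.08)
})

test_that("posterior agrees with an independent JAGS fit on shared data", {
  set.seed(9)
  n <- 600
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x", "a")
  y <- rbinom(n, 1, plogis(X %*% c(-0.5, 0.8, 0.6)))
  chains <- cfmediate:::gibbs_logistic(X, y, rep(0, 3), c(10, 1, 1),
                                       n_chains = 2, n_keep = 1500,
                                       warmup = 300, seed = 10)
  ours <- apply(do.call(rbind, chains), 2, median)
  model <- "model {
    for (i in 1:n) { y[i] ~ dbern(ilogit(inprod(X[i,], beta[]))) }
    beta[1] ~ dnorm(0, 0.01)
    beta[2] ~ dnorm(0, 1)
    beta[3] ~ dnorm(0, 1)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(X = X, y = y, n = n),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Wichmann-Hill",
                                       .RNG.seed = 11))
  stats::update(jm, 500, progress.bar = "none")
  samp <- rjags::coda.samples(jm, "beta", 1500, progress.bar = "none")
  theirs <- apply(as.matrix(samp), 2, median)
  expect_lt(max(abs(ours - theirs)), 0.08)
})

test_that("hierarchical Cauchy-scale prior shrinks noise without crushing signal", {
  set.seed(12)
  n <- 2000
  age <- rnorm(n)
  X_small <- cbind(`(Intercept)` = 1, age = age)
  y <- rbinom(n, 1, plogis(0.3 + 0.8 * age))
  fit_small <- cfmediate:::gibbs_attrition(X_small, y, effect_cols = 2,
                                           n_chains = 2, n_keep = 500,
                                           warmup = 250, seed = 13)
  est_small <- median(do.call(rbind, fit_small$chains)[, "age"])
  noise <- matrix(rnorm(n * 20), n, 20,
                  dimnames = list(NULL, paste0("z", 1:20)))
  X_big <- cbind(X_small, noise)
  fit_big <- cfmediate:::gibbs_attrition(X_big, y, effect_cols = 2:22,
                                         n_chains = 2, n_keep = 500,
                                         warmup = 250, seed = 14)
  big <- do.call(rbind, fit_big$chains)
  est_big <- median(big[, "age"])
  expect_lt(abs(est_big - est_small) / abs(est_small), 0.25)
  # noise coefficients are shrunk towards zero
  expect_lt(max(abs(apply(big[, paste0("z", 1:20)], 2, median))), 0.15)
})
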