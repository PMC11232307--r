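# MCMC engines.
#
# Linear models with normal coefficient priors and a half-normal residual-sd
# prior use a blocked Gibbs sampler (conjugate multivariate-normal coefficient
# draw, 1-D slice update of log sigma). Logistic models with normal priors use
# the exact Polya-Gamma Gibbs sampler (compiled; see src/polyagamma.cpp).
# The attrition model puts Cauchy(0, tau) priors on all effect coefficients
# with a half-normal hyperprior on tau, expressed as a normal scale mixture
# (Cauchy = t_1), giving a fully conjugate Gibbs sweep apart from the 1-D tau
# update, again by slice sampling. Convergence diagnostics (split-chain
# potential scale reduction and effective sample size) come from coda; the
# samplers are Gibbs, so there are no divergent transitions to count.

# univariate slice sampler (stepping out + shrinkage), Neal (2003)
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  logy <- logf(x0) - rexp(1)
  L <- x0 - runif(1) * w
  R <- L + w
  j <- floor(runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# assemble cross-chain diagnostics from a list of (n_keep x p) matrices
chain_diagnostics <- function(chains) {
  ml <- coda::mcmc.list(lapply(chains, coda::mcmc))
  p <- ncol(chains[[1]])
  rhat <- rep(NA_real_, p)
  ok <- vapply(seq_len(p), function(j)
    sd(unlist(lapply(chains, function(ch) ch[, j]))) > 1e-12, logical(1))
  if (length(chains) > 1 && any(ok)) {
    sub <- coda::mcmc.list(lapply(chains, function(ch)
      coda::mcmc(ch[, ok, drop = FALSE])))
    gd <- try(coda::gelman.diag(sub, autoburnin = FALSE,
                                multivariate = FALSE)$psrf[, 1], silent = TRUE)
    if (!inherits(gd, "try-error")) rhat[ok] <- gd
  }
  rhat[!ok] <- 1
  ess <- as.numeric(coda::effectiveSize(ml))
  names(rhat) <- names(ess) <- colnames(chains[[1]])
  list(rhat = rhat, ess = ess,
       max_rhat = if (all(is.na(rhat))) NA_real_ else max(rhat, na.rm = TRUE),
       min_ess = min(ess), divergences = 0L)
}

new_posterior_draws <- function(chains, model, spec, rows, transforms,
                                sigma = NULL, aux = NULL) {
  draws <- do.call(rbind, chains)
  diag <- chain_diagnostics(chains)
  structure(list(draws = draws, sigma = sigma, aux = aux,
                 n_chains = length(chains),
                 n_draws = nrow(draws),
                 diagnostics = diag, model = model, spec = spec,
                 rows = rows, transforms = transforms),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("Bayesian %s model: %d draws (%d chains) x %d coefficients\n",
              x$model, x$n_draws, x$n_chains, ncol(x$draws)))
  cat(sprintf("  response: %s; rows used: %d\n",
              x$spec$response %||% "?", length(x$rows)))
  cat(sprintf("  max Rhat %.4f, min ESS %.0f, divergences %d%s\n",
              x$diagnostics$max_rhat, x$diagnostics$min_ess,
              x$diagnostics$divergences,
              if (isTRUE(x$diagnostics$separation_suspected))
                "; WARNING: possible separation" else ""))
  qs <- t(apply(x$draws, 2, quantile, c(0.5, 0.025, 0.975)))
  colnames(qs) <- c("median", "2.5%", "97.5%")
  print(round(qs, 3))
  invisible(x)
}

# Gibbs sampler for y = X beta + eps, eps ~ N(0, sigma^2);
# beta_j ~ N(prior_mean_j, prior_sd_j^2), sigma ~ half-N(0, sigma_prior_sd^2)
gibbs_linear <- function(X, y, prior_mean, prior_sd, sigma_prior_sd = 5,
                         n_chains = 4, n_keep = 1000, warmup = 500, seed = 1) {
  n <- nrow(X); p <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  prec <- 1 / prior_sd^2
  pb <- prec * prior_mean
  chains <- vector("list", n_chains)
  sig_chains <- vector("list", n_chains)
  set.seed(seed)
  for (ch in seq_len(n_chains)) {
    beta <- rnorm(p, 0, 0.5)
    sigma <- exp(rnorm(1, 0, 0.3))
    keep <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
    sig_keep <- numeric(n_keep)
    for (it in seq_len(warmup + n_keep)) {
      Vinv <- XtX / sigma^2 + diag(prec, p)
      U <- chol(Vinv)
      mu <- backsolve(U, forwardsolve(t(U), Xty / sigma^2 + pb))
      beta <- mu + backsolve(U, rnorm(p))
      ssr <- max(yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta)), 0)
      logf <- function(ls) {
        s2 <- exp(2 * ls)
        -n * ls - ssr / (2 * s2) - s2 / (2 * sigma_prior_sd^2) + ls
      }
      sigma <- exp(slice_sample1(log(sigma), logf, w = 0.5))
      if (it > warmup) {
        keep[it - warmup, ] <- beta
        sig_keep[it - warmup] <- sigma
      }
    }
    chains[[ch]] <- cbind(keep, sigma = sig_keep)
    sig_chains[[ch]] <- sig_keep
  }
  list(chains = lapply(chains, function(ch) ch[, seq_len(p), drop = FALSE]),
       chains_full = chains,
       sigma = unlist(sig_chains))
}

# Polya-Gamma Gibbs sampler for logistic regression with normal priors
gibbs_logistic <- function(X, y, prior_mean, prior_sd,
                           n_chains = 4, n_keep = 1000, warmup = 500,
                           seed = 1) {
  p <- ncol(X)
  prec <- 1 / prior_sd^2
  set.seed(seed)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    init <- rnorm(p, 0, 0.5)
    chains[[ch]] <- .gibbs_logistic_chain(X, y, prior_mean, prec,
                                          n_keep, warmup, init)
    colnames(chains[[ch]]) <- colnames(X)
  }
  chains
}

# Hierarchical logistic Gibbs for the attrition model:
# effect coefficients beta_j ~ Cauchy(0, tau) = N(0, tau^2 / gamma_j),
# gamma_j ~ Gamma(1/2, 1/2); tau ~ half-N(0, tau_prior_sd^2);
# intercept ~ N(0, 10^2).
gibbs_attrition <- function(X, y, effect_cols, tau_prior_sd = 1,
                            n_chains = 4, n_keep = 1000, warmup = 500,
                            seed = 1) {
  n <- nrow(X); p <- ncol(X)
  J <- length(effect_cols)
  kappa <- y - 0.5
  Xk <- crossprod(X, kappa)
  set.seed(seed)
  chains <- vector("list", n_chains)
  tau_chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    beta <- rnorm(p, 0, 0.3)
    gamma <- rep(1, J)
    tau <- abs(rnorm(1, 0, 0.5)) + 0.1
    keep <- matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X)))
    tau_keep <- numeric(n_keep)
    for (it in seq_len(warmup + n_keep)) {
      omega <- .rpg(as.vector(X %*% beta))
      prec <- rep(1 / 100, p)
      prec[effect_cols] <- gamma / tau^2
      M <- crossprod(X * omega, X)
      diag(M) <- diag(M) + prec
      U <- chol(M)
      mu <- backsolve(U, forwardsolve(t(U), Xk))
      beta <- mu + backsolve(U, rnorm(p))
      # partially collapsed update: tau is drawn with the mixing weights
      # integrated out (beta_j | tau ~ Cauchy(0, tau) marginally), then the
      # weights are refreshed — this decouples tau from gamma and mixes far
      # better than the uncollapsed sweep
      b2 <- beta[effect_cols]^2
      logf <- function(lt) {
        t2 <- exp(2 * lt)
        (J + 1) * lt - sum(log(t2 + b2)) - t2 / (2 * tau_prior_sd^2)
      }
      tau <- exp(slice_sample1(log(tau), logf, w = 0.5))
      gamma <- rgamma(J, shape = 1, rate = (1 + b2 / tau^2) / 2)
      if (it > warmup) {
        keep[it - warmup, ] <- beta
        tau_keep[it - warmup] <- tau
      }
    }
    chains[[ch]] <- keep
    tau_chains[[ch]] <- tau_keep
  }
  list(chains = chains, tau = tau_chains)
}
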