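#' @keywords internal
"_PACKAGE"

#' @useDynLib cfmediate, .registration = TRUE
#' @import Rcpp
#' @importFrom coda mcmc mcmc.list gelman.diag effectiveSize
#' @importFrom pracma gaussHermite
#' @importFrom stats coef glm median plogis pnorm predict qlogis quantile
#'   rbinom rexp rnorm runif sd setNames uniroot vcov dnorm qnorm rgamma
#'   binomial lm lm.fit
#' @importFrom utils read.csv write.csv
NULL

# Derive a reproducible sub-seed from a master seed and a stage offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483646L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Used for internal calibration simulations
# so they never perturb user-visible randomness.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# truncated-normal draw on [lo, Inf) via inverse-CDF
rtnorm_lower <- function(n, mean, sd, lo) {
  p_lo <- pnorm(lo, mean, sd)
  qnorm(runif(n, p_lo, 1), mean, sd)
}

# latent normal parameters whose lower-truncated (at `lo`) moments match
# the requested mean/sd; deterministic two-parameter Newton-type solve
latent_truncnorm_params <- function(target_mean, target_sd, lo) {
  obj <- function(par) {
    m <- par[1]; s <- exp(par[2])
    alpha <- (lo - m) / s
    lambda <- dnorm(alpha) / (1 - pnorm(alpha))
    mu_tr <- m + s * lambda
    var_tr <- s^2 * (1 + alpha * lambda - lambda^2)
    (mu_tr - target_mean)^2 + (sqrt(var_tr) - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

odds <- function(p) p / (1 - p)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
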