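# Synthetic two-arm trial generator.
#
# The generator emulates a smoking-cessation RCT: baseline covariates drawn
# to match the trial's published summary statistics, stratified permuted-block
# randomisation, three 1-10 mediator items (importance, know-how, confidence)
# measured at baseline and 1/3/6 months, binary abstinence outcomes (prolonged
# and 4-week point prevalence) at 3/6 months, and missing-at-random attrition
# driven by age and (at 1 month, intervention arm only) baseline nicotine
# dependence.
#
# Arm effects on mediators are specified on the standardised scale; the
# generator internally maps them to raw-scale coefficients so that the
# realised standardised arm difference (after clipping to the 1-10 range)
# equals the configured value. Those mappings, the standardisation constants
# and the attrition intercepts are solved once per configuration on a large
# deterministic internal sample and cached in the config object.

MEDIATORS <- c("importance", "knowhow", "confidence")
MED_INTERVALS <- c(1L, 3L, 6L)
OUT_INTERVALS <- c(3L, 6L)
OUTCOMES <- c("prolonged", "pp")

#' Default configuration of the synthetic trial generator
#'
#' Returns the full parameter set of the data-generating process. Baseline
#' distributions (sex, age, nicotine dependence, cigarettes per week,
#' surgery-version fraction, mediator baselines) and the standardised arm
#' effects on the mediators are set to the published trial summaries; the
#' mediator-to-outcome coefficients, direct effects and control-arm abstinence
#' rates are free parameters of the generator (the source trial does not
#' report arm-specific abstinence proportions) with defaults chosen to give
#' non-rare outcomes (~20-30% control-arm abstinence). Attrition follows the
#' reported arm-specific mediator response rates, with a positive age slope at
#' every interval and a negative dependence slope confined to the intervention
#' arm at 1 month.
#'
#' @param n number of participants.
#' @param seed_cache internal seed for the deterministic calibration sample.
#' @return an object of class `generator_config`.
#' @export
default_generator_config <- function(n = 1012, seed_cache = 20200918) {
  cfg <- list(
    n = n,
    p_woman = 0.81,
    age_mean = 45.4, age_sd = 14, age_min = 18,
    ftnd_mean = 5, ftnd_sd = 2.2,
    cigs_mean = 101, cigs_sd = 46.2, cigs_min = 1,
    p_surgery = 0.062,
    mediators = MEDIATORS,
    base_mean = c(importance = 9.4, knowhow = 5.5, confidence = 6.2),
    base_sd = c(importance = 1.3, knowhow = 2.6, confidence = 2.5),
    base_cor = 0,
    resid_cor = 0,
    round_mediators = FALSE,
    # standardised treatment effects on each mediator at 1/3/6 months
    arm_effect = matrix(c(-0.04, 0.13, 0.10,
                          0.55, 0.47, 0.47,
                          0.30, 0.23, 0.32),
                        nrow = 3, byrow = TRUE,
                        dimnames = list(MEDIATORS, c("1", "3", "6"))),
    exact_arm_effect = TRUE,
    # carry-over of the (centred) baseline item into each follow-up
    rho = c(importance = 0.5, knowhow = 0.5, confidence = 0.5),
    # raw mediator points per centred covariate unit (sex/surgery indicators,
    # age and FTND per standard deviation)
    med_cov = c(sex = 0.1, age = 0.05, surgery = 0.1, ftnd = -0.1),
    med_drift = matrix(0, nrow = 3, ncol = 3,
                       dimnames = list(MEDIATORS, c("1", "3", "6"))),
    outcomes = list(
      prolonged_3 = list(theta_0 = qlogis(0.25), theta_A = log(2.17),
                         b = c(importance = 0.35, knowhow = 0.80, confidence = 0.55),
                         b_base = c(importance = 0.1, knowhow = 0.1, confidence = 0.1),
                         cov = c(sex = 0.15, age = -0.1, surgery = 0.2, ftnd = -0.3)),
      pp_3 = list(theta_0 = qlogis(0.20), theta_A = log(2.09),
                  b = c(importance = 0.30, knowhow = 0.65, confidence = 0.35),
                  b_base = c(importance = 0.1, knowhow = 0.1, confidence = 0.1),
                  cov = c(sex = 0.15, age = -0.1, surgery = 0.2, ftnd = -0.3)),
      prolonged_6 = list(theta_0 = qlogis(0.25), theta_A = log(2.43),
                         b = c(importance = 0.30, knowhow = 0.70, confidence = 0.45),
                         b_base = c(importance = 0.1, knowhow = 0.1, confidence = 0.1),
                         cov = c(sex = 0.15, age = -0.1, surgery = 0.2, ftnd = -0.3)),
      pp_6 = list(theta_0 = qlogis(0.20), theta_A = log(1.24),
                  b = c(importance = 0.25, knowhow = 0.60, confidence = 0.35),
                  b_base = c(importance = 0.1, knowhow = 0.1, confidence = 0.1),
                  cov = c(sex = 0.15, age = -0.1, surgery = 0.2, ftnd = -0.3))
    ),
    miss = list(
      med = list(
        `1` = list(ctl_rate = 0.61, int_rate = 0.40, age_slope = 0.3,
                   ftnd_moderation = TRUE),
        `3` = list(ctl_rate = 0.47, int_rate = 0.41, age_slope = 0.3,
                   ftnd_moderation = FALSE),
        `6` = list(ctl_rate = 0.42, int_rate = 0.36, age_slope = 0.3,
                   ftnd_moderation = FALSE)),
      out = list(
        `3` = list(ctl_rate = 0.77, int_rate = 0.73, age_slope = 0.3,
                   ftnd_moderation = FALSE),
        `6` = list(ctl_rate = 0.72, int_rate = 0.68, age_slope = 0.3,
                   ftnd_moderation = FALSE))
    ),
    block_sizes = c(2L, 4L),
    seed_cache = seed_cache,
    n_cache = 200000L,
    cache = NULL
  )
  class(cfg) <- "generator_config"
  cfg
}

#' Remove attrition from a generator configuration
#'
#' Sets every response rate to 1 so `apply_missingness()` leaves the data
#' complete. Used for full-response simulation studies.
#' @param config a `generator_config`.
#' @return the modified configuration.
#' @export
full_response <- function(config) {
  for (blk in names(config$miss)) {
    for (t in names(config$miss[[blk]])) {
      config$miss[[blk]][[t]]$ctl_rate <- 1
      config$miss[[blk]][[t]]$int_rate <- 1
      config$miss[[blk]][[t]]$ftnd_moderation <- FALSE
    }
  }
  config$cache <- NULL
  config
}

validate_generator_config <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  bad <- character(0)
  if (config$n < 0) bad <- c(bad, "n must be >= 0")
  for (f in c("p_woman", "p_surgery")) {
    if (config[[f]] < 0 || config[[f]] > 1)
      bad <- c(bad, sprintf("%s must lie in [0, 1]", f))
  }
  for (f in c("age_sd", "ftnd_sd", "cigs_sd")) {
    if (config[[f]] <= 0) bad <- c(bad, sprintf("%s must be > 0", f))
  }
  if (any(config$base_sd <= 0)) bad <- c(bad, "base_sd must be > 0")
  if (length(config$block_sizes) == 0 || any(config$block_sizes %% 2 != 0))
    bad <- c(bad, "block_sizes must be non-empty and even")
  for (blk in names(config$miss)) {
    for (t in names(config$miss[[blk]])) {
      r <- config$miss[[blk]][[t]]
      if (r$ctl_rate < 0 || r$ctl_rate > 1 || r$int_rate < 0 || r$int_rate > 1)
        bad <- c(bad, sprintf("response rates for %s at %s must lie in [0, 1]", blk, t))
    }
  }
  if (length(bad) > 0)
    stop("invalid generator configuration: ", paste(bad, collapse = "; "),
         call. = FALSE)
  invisible(config)
}

# key over every field the calibration cache depends on
cache_key <- function(config) {
  paste(collapse = "|", c(
    "v1",
    sprintf("%.12g", c(config$p_woman, config$age_mean, config$age_sd,
                       config$age_min, config$ftnd_mean, config$ftnd_sd,
                       config$cigs_mean, config$cigs_sd, config$cigs_min,
                       config$p_surgery, config$base_mean, config$base_sd,
                       config$base_cor, config$resid_cor,
                       config$arm_effect, config$rho, config$med_cov,
                       config$med_drift, config$seed_cache, config$n_cache)),
    as.character(config$round_mediators),
    as.character(config$exact_arm_effect),
    unlist(lapply(config$miss, function(blk)
      lapply(blk, function(r) sprintf("%.12g%s", c(r$ctl_rate, r$int_rate,
                                                   r$age_slope),
                                      r$ftnd_moderation))))
  ))
}

# draw baseline covariates + baseline mediators (clipped); shared between the
# public generator and the internal calibration sample
draw_baseline_fields <- function(config, n, cache_params = NULL) {
  lat <- cache_params %||%
    latent_truncnorm_params(config$age_mean, config$age_sd, config$age_min)
  sex <- ifelse(runif(n) < config$p_woman, "woman", "other")
  age <- rtnorm_lower(n, lat["mean"], lat["sd"], config$age_min)
  version <- ifelse(runif(n) < config$p_surgery, "surgery", "general")
  ftnd <- clip(round(rnorm(n, config$ftnd_mean, config$ftnd_sd)), 0, 10)
  cigs <- rtnorm_lower(n, config$cigs_mean, config$cigs_sd, config$cigs_min)
  k <- length(config$mediators)
  R <- matrix(config$base_cor, k, k); diag(R) <- 1
  z <- matrix(rnorm(n * k), n, k) %*% chol(R)
  base <- sweep(sweep(z, 2, config$base_sd, `*`), 2, config$base_mean, `+`)
  base <- clip(base, 1, 10)
  if (config$round_mediators) base <- round(base)
  colnames(base) <- config$mediators
  list(sex = sex, age = age, version = version, ftnd = ftnd, cigs = cigs,
       base = base)
}

# centred covariate terms entering the mediator mean structure
med_cov_terms <- function(config, fields) {
  cc <- config$med_cov
  cc["sex"] * ((fields$sex == "woman") - config$p_woman) +
    cc["age"] * (fields$age - config$age_mean) / config$age_sd +
    cc["surgery"] * ((fields$version == "surgery") - config$p_surgery) +
    cc["ftnd"] * (fields$ftnd - config$ftnd_mean) / config$ftnd_sd
}

# mediator values at one interval for arm indicator a (0/1), given baseline
# fields, raw arm coefficients and a noise matrix (n x k, unit scale)
med_values <- function(config, fields, t_chr, a, a_raw, resid_sd, eps_unit) {
  k <- length(config$mediators)
  covt <- med_cov_terms(config, fields)
  out <- matrix(NA_real_, length(fields$age), k,
                dimnames = list(NULL, config$mediators))
  base_center <- colMeans(fields$base)
  for (j in seq_len(k)) {
    m <- config$mediators[j]
    mu <- config$base_mean[m] + config$med_drift[m, t_chr] +
      a_raw[m] * a +
      config$rho[m] * (fields$base[, m] - base_center[m]) +
      covt
    out[, j] <- mu + resid_sd[m] * eps_unit[, j]
  }
  out <- clip(out, 1, 10)
  if (config$round_mediators) out <- round(out)
  out
}

# correlated unit-scale residuals for the three mediators at one interval
draw_med_noise <- function(config, n) {
  k <- length(config$mediators)
  R <- matrix(config$resid_cor, k, k); diag(R) <- 1
  matrix(rnorm(n * k), n, k) %*% chol(R)
}

# Build (or reuse) the calibration cache: latent age parameters, raw-scale
# arm coefficients and residual sds per mediator x interval, standardisation
# constants, and attrition model intercepts/slopes solved to the configured
# response rates. Entirely deterministic given the config.
ensure_cache <- function(config) {
  validate_generator_config(config)
  key <- cache_key(config)
  if (!is.null(config$cache) && identical(config$cache$key, key))
    return(config)
  cache <- with_private_seed(config$seed_cache, {
    n <- config$n_cache
    lat_age <- latent_truncnorm_params(config$age_mean, config$age_sd,
                                       config$age_min)
    fields <- draw_baseline_fields(config, n, lat_age)
    meds <- config$mediators
    ts <- c("1", "3", "6")
    # residual sd chosen so the pooled marginal sd at each interval matches
    # the baseline sd (pre-clipping moment algebra)
    resid_sd <- a_raw <- std_center <- std_scale <-
      matrix(NA_real_, length(meds), length(ts), dimnames = list(meds, ts))
    noise <- lapply(ts, function(t) draw_med_noise(config, n))
    names(noise) <- ts
    for (t in ts) {
      for (m in meds) {
        a_std <- config$arm_effect[m, t]
        v <- config$base_sd[m]^2 * (1 - a_std^2 / 4) -
          config$rho[m]^2 * config$base_sd[m]^2
        if (v <= 0)
          stop("mediator residual variance non-positive for ", m,
               " at interval ", t, call. = FALSE)
        resid_sd[m, t] <- sqrt(v)
      }
      rs <- resid_sd[, t]
      # realised standardised arm effect as a function of the raw coefficient
      realized <- function(ar_vec) {
        m1 <- med_values(config, fields, t, 1, ar_vec, rs, noise[[t]])
        m0 <- med_values(config, fields, t, 0, ar_vec, rs, noise[[t]])
        mean_d <- colMeans(m1) - colMeans(m0)
        v_pool <- 0.5 * (apply(m1, 2, stats::var) + apply(m0, 2, stats::var)) +
          mean_d^2 / 4
        list(std = mean_d / sqrt(v_pool),
             center = 0.5 * (colMeans(m1) + colMeans(m0)),
             scale = sqrt(v_pool))
      }
      ar <- config$arm_effect[, t] * config$base_sd
      if (config$exact_arm_effect) {
        for (m in meds) {
          target <- config$arm_effect[m, t]
          if (abs(target) < 1e-12) { ar[m] <- 0; next }
          f <- function(x) {
            v <- ar; v[m] <- x
            realized(v)$std[m] - target
          }
          lo <- 0; hi <- 2 * target * config$base_sd[m]
          for (i in 1:20) {
            if (sign(f(lo)) != sign(f(hi))) break
            hi <- hi * 1.6
          }
          ar[m] <- uniroot(f, c(lo, hi), tol = 1e-6)$root
        }
      }
      fin <- realized(ar)
      a_raw[, t] <- ar
      std_center[, t] <- fin$center
      std_scale[, t] <- fin$scale
    }
    base_center <- colMeans(fields$base)
    base_scale <- apply(fields$base, 2, sd)
    # attrition intercepts solved to the configured marginal response rates
    agec <- (fields$age - config$age_mean) / config$age_sd
    miss_par <- list()
    for (blk in names(config$miss)) {
      miss_par[[blk]] <- list()
      for (t in names(config$miss[[blk]])) {
        r <- config$miss[[blk]][[t]]
        solve_alpha <- function(target, extra = 0) {
          if (target >= 1) return(Inf)
          if (target <= 0) return(-Inf)
          uniroot(function(al) mean(plogis(al + r$age_slope * agec + extra)) -
                    target, c(-20, 20), tol = 1e-8)$root
        }
        alpha_ctl <- solve_alpha(r$ctl_rate)
        if (isTRUE(r$ftnd_moderation)) {
          # common intercept; the arm difference in response runs entirely
          # through baseline dependence in the intervention arm
          if (!is.finite(alpha_ctl)) {
            delta <- 0; alpha_int <- alpha_ctl
          } else {
            delta <- uniroot(function(d)
              mean(plogis(alpha_ctl + r$age_slope * agec + d * fields$ftnd)) -
                r$int_rate, c(-3, 3), tol = 1e-8)$root
            alpha_int <- alpha_ctl
          }
        } else {
          delta <- 0
          alpha_int <- solve_alpha(r$int_rate)
        }
        miss_par[[blk]][[t]] <- list(alpha_ctl = alpha_ctl,
                                     alpha_int = alpha_int,
                                     age_slope = r$age_slope,
                                     ftnd_slope_int = delta)
      }
    }
    list(key = key, lat_age = lat_age, a_raw = a_raw, resid_sd = resid_sd,
         std_center = std_center, std_scale = std_scale,
         base_center = base_center, base_scale = base_scale,
         miss_par = miss_par)
  })
  config$cache <- cache
  config
}

#' Calibrate attrition intercepts to the configured response rates
#'
#' Solves the arm-specific intercepts (and, at 1 month, the intervention-arm
#' dependence slope) of every response model so that the marginal response
#' probabilities match the configured rates, and returns the configuration
#' with the solved parameters cached.
#' @param config a `generator_config`.
#' @return the configuration with a populated calibration cache.
#' @export
calibrate_missingness <- function(config) {
  ensure_cache(config)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic trial generator configuration\n")
  cat(sprintf("  n = %d; woman %.0f%%; age %.1f (%.1f); FTND %.1f (%.1f); surgery %.1f%%\n",
              x$n, 100 * x$p_woman, x$age_mean, x$age_sd, x$ftnd_mean,
              x$ftnd_sd, 100 * x$p_surgery))
  cat("  standardised arm effects on mediators (rows) at 1/3/6 months:\n")
  print(round(x$arm_effect, 3))
  cat(sprintf("  cache: %s\n", if (is.null(x$cache)) "not built" else "built"))
  invisible(x)
}

#' Generate pre-randomisation participant records
#'
#' Draws baseline covariates and baseline mediator scores from the configured
#' distributions: sex and surgery-version indicators, age from a normal
#' truncated at the eligibility minimum (latent parameters solved so the
#' truncated mean/sd match the configured values), nicotine dependence rounded
#' and clipped to 0-10, cigarettes per week truncated at 1, and the three
#' mediator items clipped to the 1-10 response range.
#'
#' @param config a `generator_config`.
#' @param seed integer seed.
#' @return a data.frame with one row per participant (no allocation yet).
#' @export
generate_baseline <- function(config, seed) {
  config <- ensure_cache(config)
  n <- config$n
  if (n == 0) {
    df <- data.frame(id = character(0), sex = character(0), age = numeric(0),
                     version = character(0), ftnd = integer(0),
                     cigs_per_week = numeric(0))
    for (m in config$mediators) df[[paste0(m, "_0")]] <- numeric(0)
    return(df)
  }
  set.seed(seed)
  fields <- draw_baseline_fields(config, n, config$cache$lat_age)
  df <- data.frame(id = sprintf("P%05d", seq_len(n)),
                   sex = fields$sex, age = fields$age,
                   version = fields$version, ftnd = as.integer(fields$ftnd),
                   cigs_per_week = fields$cigs,
                   stringsAsFactors = FALSE)
  for (m in config$mediators) df[[paste0(m, "_0")]] <- fields$base[, m]
  df
}

#' Stratified permuted-block randomisation
#'
#' Allocates participants 1:1 to intervention and control within each
#' intervention-version stratum, in blocks whose lengths are drawn uniformly
#' from `block_sizes`; each completed block contains exactly half intervention
#' and half control in uniformly random order. An incomplete final block is
#' left as-is, so within-stratum imbalance never exceeds `max(block_sizes)/2`.
#'
#' @param records data.frame with a `version` column.
#' @param block_sizes even block lengths to draw from.
#' @param seed integer seed.
#' @return `records` with a `group` column ("intervention"/"control").
#' @export
randomize <- function(records, block_sizes = c(2L, 4L), seed) {
  stopifnot(all(block_sizes %% 2 == 0), length(block_sizes) > 0)
  set.seed(seed)
  group <- character(nrow(records))
  for (stratum in unique(records$version)) {
    idx <- which(records$version == stratum)
    alloc <- character(0)
    while (length(alloc) < length(idx)) {
      bs <- if (length(block_sizes) == 1) block_sizes else
        sample(block_sizes, 1)
      block <- sample(rep(c("intervention", "control"), each = bs / 2))
      alloc <- c(alloc, block)
    }
    group[idx] <- alloc[seq_along(idx)]
  }
  records$group <- group
  records
}

#' Generate mediator trajectories
#'
#' Adds the three mediator scores at 1, 3 and 6 months. Each follow-up value
#' is the baseline item mean plus a configured time drift, the treatment
#' effect (specified on the standardised scale and mapped internally to the
#' raw scale), an autoregressive carry-over of the centred baseline item,
#' centred covariate terms and Gaussian noise, clipped to the 1-10 range.
#' With the default calibration, importance sits near its ceiling with an
#' essentially null treatment effect while know-how and confidence diverge
#' between arms after month 1.
#'
#' @param records randomised records (must carry `group`).
#' @param config a `generator_config`.
#' @param seed integer seed.
#' @return `records` with `<mediator>_<t>` columns added.
#' @export
generate_mediators <- function(records, config, seed) {
  if (is.null(records$group))
    stop("records must be randomised before mediators are generated",
         call. = FALSE)
  config <- ensure_cache(config)
  set.seed(seed)
  n <- nrow(records)
  fields <- list(sex = records$sex, age = records$age,
                 version = records$version, ftnd = records$ftnd,
                 base = as.matrix(records[paste0(config$mediators, "_0")]))
  colnames(fields$base) <- config$mediators
  a <- as.numeric(records$group == "intervention")
  for (t in c("1", "3", "6")) {
    eps <- draw_med_noise(config, n)
    covt <- med_cov_terms(config, fields)
    for (j in seq_along(config$mediators)) {
      m <- config$mediators[j]
      mu <- config$base_mean[m] + config$med_drift[m, t] +
        config$cache$a_raw[m, t] * a +
        config$rho[m] * (fields$base[, m] - config$cache$base_center[m]) +
        covt
      v <- mu + config$cache$resid_sd[m, t] * eps[, j]
      v <- clip(v, 1, 10)
      if (config$round_mediators) v <- round(v)
      records[[paste0(m, "_", t)]] <- v
    }
  }
  records
}

# standardised mediator values using the generator's own constants
true_standardized <- function(config, values, m, t_chr) {
  (values - config$cache$std_center[m, t_chr]) / config$cache$std_scale[m, t_chr]
}

# linear predictor of one outcome model given mediator values at the causally
# prior interval (columns named by mediator) and baseline fields
outcome_lp <- function(config, out_name, a, med_t, fields) {
  par <- config$outcomes[[out_name]]
  t_prior <- if (grepl("_3$", out_name)) "1" else "3"
  lp <- par$theta_0 + par$theta_A * a
  for (m in config$mediators) {
    lp <- lp + par$b[m] * true_standardized(config, med_t[, m], m, t_prior)
    zb <- (fields$base[, m] - config$cache$base_center[m]) /
      config$cache$base_scale[m]
    lp <- lp + par$b_base[m] * zb
  }
  lp + par$cov["sex"] * ((fields$sex == "woman") - config$p_woman) +
    par$cov["age"] * (fields$age - config$age_mean) / config$age_sd +
    par$cov["surgery"] * ((fields$version == "surgery") - config$p_surgery) +
    par$cov["ftnd"] * (fields$ftnd - config$ftnd_mean) / config$ftnd_sd
}

#' Generate binary abstinence outcomes
#'
#' Draws prolonged-abstinence and point-prevalence outcomes at 3 and 6 months
#' from logistic models whose linear predictor combines the direct treatment
#' effect, the standardised mediator values at the causally prior interval
#' (1 month for 3-month outcomes, 3 months for 6-month outcomes), baseline
#' mediator values and centred covariates. The two outcome definitions use
#' separate coefficient sets and independent Bernoulli noise.
#'
#' @param records records with mediators generated.
#' @param config a `generator_config`.
#' @param seed integer seed.
#' @return `records` with `prolonged_3`, `pp_3`, `prolonged_6`, `pp_6` added.
#' @export
generate_outcomes <- function(records, config, seed) {
  need <- paste0(config$mediators[1], "_", c(1, 3))
  if (!all(need %in% names(records)))
    stop("mediators must be generated before outcomes", call. = FALSE)
  config <- ensure_cache(config)
  set.seed(seed)
  fields <- list(sex = records$sex, age = records$age,
                 version = records$version, ftnd = records$ftnd,
                 base = as.matrix(records[paste0(config$mediators, "_0")]))
  colnames(fields$base) <- config$mediators
  a <- as.numeric(records$group == "intervention")
  for (out_name in names(config$outcomes)) {
    t_prior <- if (grepl("_3$", out_name)) "1" else "3"
    med_t <- as.matrix(records[paste0(config$mediators, "_", t_prior)])
    colnames(med_t) <- config$mediators
    lp <- outcome_lp(config, out_name, a, med_t, fields)
    records[[out_name]] <- rbinom(nrow(records), 1, plogis(lp))
  }
  records
}

#' Apply missing-at-random attrition
#'
#' Draws a response indicator for the mediator battery at each follow-up and
#' for the outcome assessments at 3 and 6 months from logistic models with a
#' positive age slope (older participants respond more) and, at the 1-month
#' mediator follow-up only, a negative baseline-dependence slope confined to
#' the intervention arm, which alone produces the arm gap in 1-month response
#' rates. Values whose indicator is 0 are masked to `NA`; retained values are
#' untouched. Missingness depends only on fully observed baseline fields, so
#' the mechanism is missing at random.
#'
#' @param records complete records.
#' @param config a `generator_config`.
#' @param seed integer seed.
#' @return `records` with `responded_med_*`/`responded_out_*` indicators and
#'   masked follow-up values.
#' @export
apply_missingness <- function(records, config, seed) {
  config <- ensure_cache(config)
  set.seed(seed)
  n <- nrow(records)
  a <- records$group == "intervention"
  agec <- (records$age - config$age_mean) / config$age_sd
  draw_resp <- function(par) {
    lp <- ifelse(a, par$alpha_int, par$alpha_ctl) + par$age_slope * agec +
      ifelse(a, par$ftnd_slope_int * records$ftnd, 0)
    p <- plogis(lp)
    p[is.infinite(lp) & lp > 0] <- 1
    p[is.infinite(lp) & lp < 0] <- 0
    rbinom(n, 1, p)
  }
  for (t in c("1", "3", "6")) {
    r <- draw_resp(config$cache$miss_par$med[[t]])
    records[[paste0("responded_med_", t)]] <- r
    for (m in config$mediators)
      records[[paste0(m, "_", t)]][r == 0] <- NA
  }
  for (t in c("3", "6")) {
    r <- draw_resp(config$cache$miss_par$out[[t]])
    records[[paste0("responded_out_", t)]] <- r
    for (o in OUTCOMES)
      records[[paste0(o, "_", t)]][r == 0] <- NA
  }
  records
}

#' Simulate a complete synthetic trial
#'
#' Runs the full generator chain: baseline, stratified block randomisation,
#' mediator trajectories, outcomes, attrition. Stage seeds are derived from
#' the master seed by fixed offsets, so identical seed and configuration give
#' byte-identical datasets.
#'
#' @param config a `generator_config`.
#' @param seed master integer seed.
#' @param missingness apply the attrition stage (default `TRUE`).
#' @return a data.frame of participant records; the finalized configuration is
#'   attached as attribute `"config"`.
#' @export
simulate_trial <- function(config = default_generator_config(), seed,
                           missingness = TRUE) {
  config <- ensure_cache(config)
  d <- generate_baseline(config, derive_seed(seed, 1))
  if (nrow(d) > 0) {
    d <- randomize(d, config$block_sizes, derive_seed(seed, 2))
    d <- generate_mediators(d, config, derive_seed(seed, 3))
    d <- generate_outcomes(d, config, derive_seed(seed, 4))
    if (missingness) d <- apply_missingness(d, config, derive_seed(seed, 5))
    else {
      for (t in c("1", "3", "6")) d[[paste0("responded_med_", t)]] <- 1L
      for (t in c("3", "6")) d[[paste0("responded_out_", t)]] <- 1L
    }
  }
  attr(d, "config") <- config
  d
}
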