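# Bayesian regression models in the trial's reporting format.
#
# All models share the adjustment set: sex, age, intervention version,
# baseline nicotine dependence, and the baseline value of each mediator in
# the model. Continuous covariates are standardised before entering, so the
# standard-normal priors on effect coefficients are on a meaningful scale.
# Intercepts get a wide normal prior (sd 10), linear-model residual sds a
# half-normal (sd 5) prior.

#' Standardise mediator values against a reference sample
#'
#' Centres and scales `values` by the mean and sample standard deviation
#' (denominator n-1) of `reference_values` — in the analysis, the available
#' observations at that interval pooled across arms. The transform is
#' returned so it can be reapplied to counterfactual predictions and
#' inverted.
#'
#' @param values numeric values to standardise.
#' @param reference_values reference sample defining the transform.
#' @return a list with `values`, `center`, `scale`.
#' @export
standardize_mediator <- function(values, reference_values = values) {
  center <- mean(reference_values)
  scale <- sd(reference_values)
  if (!is.finite(scale) || scale == 0)
    stop("degenerate scale: reference values have zero standard deviation",
         call. = FALSE)
  list(values = (values - center) / scale, center = center, scale = scale)
}

adjustment_fields <- function(mediators)
  c("group", "sex", "age", "version", "ftnd", paste0(mediators, "_0"))

#' Rows available for a mediation fit
#'
#' Complete-case rule: a row enters a mediation analysis only if arm, the
#' adjustment set, every mediator in the set at the prior interval, and the
#' outcome are all observed.
#'
#' @param data trial records.
#' @param mediator_set mediators in the model.
#' @param mediator_interval 1 or 3.
#' @param outcome "prolonged" or "pp" (or `NULL` to ignore outcomes).
#' @param outcome_interval 3 or 6.
#' @return integer row indices.
#' @export
mediation_rows <- function(data, mediator_set, mediator_interval,
                           outcome = NULL, outcome_interval = NULL) {
  need <- c(adjustment_fields(mediator_set),
            paste0(mediator_set, "_", mediator_interval))
  if (!is.null(outcome))
    need <- c(need, paste0(outcome, "_", outcome_interval))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  which(stats::complete.cases(data[need]))
}

# covariate design shared by every model: intercept, arm, adjustment set,
# standardised baselines of the requested mediators
build_design <- function(data, rows, baseline_mediators) {
  d <- data[rows, ]
  age_t <- standardize_mediator(d$age)
  ftnd_t <- standardize_mediator(as.numeric(d$ftnd))
  X <- cbind(`(Intercept)` = 1,
             arm = as.numeric(d$group == "intervention"),
             sex_woman = as.numeric(d$sex == "woman"),
             age_z = age_t$values,
             version_surgery = as.numeric(d$version == "surgery"),
             ftnd_z = ftnd_t$values)
  transforms <- list(age = age_t[c("center", "scale")],
                     ftnd = ftnd_t[c("center", "scale")])
  for (m in baseline_mediators) {
    bt <- standardize_mediator(d[[paste0(m, "_0")]])
    X <- cbind(X, bt$values)
    colnames(X)[ncol(X)] <- paste0("base_", m, "_z")
    transforms[[paste0("base_", m)]] <- bt[c("center", "scale")]
  }
  list(X = X, transforms = transforms)
}

prior_for_design <- function(X, intercept_sd = 10, slope_sd = 1) {
  p <- ncol(X)
  sds <- rep(slope_sd, p)
  sds[colnames(X) == "(Intercept)"] <- intercept_sd
  list(mean = rep(0, p), sd = sds)
}

#' Fit the Bayesian linear mediator model
#'
#' Linear regression of the standardised mediator at one follow-up interval on
#' the arm indicator plus the adjustment set (sex, age, version, baseline
#' dependence, standardised baseline value of the same mediator), with
#' standard-normal priors on all slope coefficients. Complete-case rows only;
#' by default rows with the mediator and the adjustment set observed.
#'
#' @param data trial records.
#' @param mediator one of "importance", "knowhow", "confidence".
#' @param interval follow-up interval (1, 3 or 6 months).
#' @param rows optional explicit row subset (e.g. a shared mediation sample).
#' @param n_chains,n_keep,warmup,seed sampler settings.
#' @param min_rows minimum usable rows before fitting.
#' @return a `posterior_draws` object; the arm coefficient is named `arm`.
#' @export
fit_mediator_model <- function(data, mediator, interval, rows = NULL,
                               n_chains = 4, n_keep = 1000, warmup = 500,
                               seed = 1, min_rows = 25) {
  resp <- paste0(mediator, "_", interval)
  if (is.null(rows)) rows <- mediation_rows(data, mediator, interval)
  if (length(rows) < min_rows)
    stop(sprintf("insufficient data: %d complete rows for %s at %s months",
                 length(rows), mediator, interval), call. = FALSE)
  des <- build_design(data, rows, mediator)
  yt <- standardize_mediator(data[[resp]][rows])
  prior <- prior_for_design(des$X)
  fit <- gibbs_linear(des$X, yt$values, prior$mean, prior$sd,
                      n_chains = n_chains, n_keep = n_keep, warmup = warmup,
                      seed = seed)
  des$transforms$response <- yt[c("center", "scale")]
  pd <- new_posterior_draws(fit$chains_full, model = "linear",
                            spec = list(response = resp, family = "linear",
                                        mediator = mediator,
                                        interval = interval,
                                        terms = colnames(des$X)),
                            rows = rows, transforms = des$transforms)
  pd$sigma <- pd$draws[, "sigma"]
  pd$X <- des$X
  pd
}

#' Fit the Bayesian logistic outcome model
#'
#' Logistic regression of an abstinence outcome on arm, the standardised
#' mediator value(s) at the causally prior interval (columns `med_<name>`),
#' and the adjustment set including the baseline value of each mediator in
#' the model. Standard-normal priors on effect coefficients. Possible
#' complete separation (detected on a maximum-likelihood sidecar fit) is
#' flagged in the diagnostics, never silently ignored.
#'
#' @param data trial records.
#' @param outcome "prolonged" or "pp".
#' @param outcome_interval 3 or 6.
#' @param mediator_set mediators entering the model.
#' @param mediator_interval 1 or 3 (must precede the outcome interval).
#' @param rows optional explicit row subset.
#' @param n_chains,n_keep,warmup,seed sampler settings.
#' @return a `posterior_draws` object.
#' @export
fit_outcome_model <- function(data, outcome, outcome_interval,
                              mediator_set, mediator_interval,
                              rows = NULL, n_chains = 4, n_keep = 1000,
                              warmup = 500, seed = 1) {
  stopifnot(mediator_interval < outcome_interval)
  resp <- paste0(outcome, "_", outcome_interval)
  if (is.null(rows))
    rows <- mediation_rows(data, mediator_set, mediator_interval,
                           outcome, outcome_interval)
  if (length(rows) < 25)
    stop(sprintf("insufficient data: %d complete rows for %s", length(rows),
                 resp), call. = FALSE)
  des <- build_design(data, rows, mediator_set)
  X <- des$X
  for (m in mediator_set) {
    mt <- standardize_mediator(data[[paste0(m, "_", mediator_interval)]][rows])
    X <- cbind(X, mt$values)
    colnames(X)[ncol(X)] <- paste0("med_", m)
    des$transforms[[paste0("med_", m)]] <- mt[c("center", "scale")]
  }
  y <- data[[resp]][rows]
  prior <- prior_for_design(X)
  chains <- gibbs_logistic(X, y, prior$mean, prior$sd, n_chains = n_chains,
                           n_keep = n_keep, warmup = warmup, seed = seed)
  pd <- new_posterior_draws(chains, model = "logistic",
                            spec = list(response = resp, family = "logistic",
                                        outcome = outcome,
                                        outcome_interval = outcome_interval,
                                        mediator_set = mediator_set,
                                        mediator_interval = mediator_interval,
                                        terms = colnames(X)),
                            rows = rows, transforms = des$transforms)
  ml <- suppressWarnings(glm.fit(X, y, family = binomial()))
  pd$diagnostics$separation_suspected <-
    !ml$converged || max(abs(coef(ml)), na.rm = TRUE) > 10
  pd$X <- X
  pd
}

#' Fit the adjusted total-effect model
#'
#' Logistic regression of an abstinence outcome on arm plus the adjustment
#' set (no mediators), optionally restricted to a subsample such as the
#' participants with mediation data available. The arm effect is summarised
#' on the odds-ratio scale twice: `summary` is the conditional (covariate-
#' held-fixed) odds ratio from the arm coefficient, and `marginal_summary`
#' the adjusted marginal odds ratio obtained per draw by averaging predicted
#' risks over the observed covariate rows under each arm (the two differ by
#' non-collapsibility of the odds ratio).
#'
#' @param data trial records.
#' @param outcome "prolonged" or "pp".
#' @param interval 3 or 6.
#' @param subsample_rule optional function `data -> logical` selecting rows.
#' @param baseline_mediators baselines to adjust for (default all three).
#' @param n_chains,n_keep,warmup,seed sampler settings.
#' @return a list of class `total_effect` with elements `summary` (an
#'   `effect_summary` on the odds-ratio scale) and `fit`.
#' @export
fit_total_effect <- function(data, outcome, interval, subsample_rule = NULL,
                             baseline_mediators = MEDIATORS,
                             n_chains = 4, n_keep = 1000, warmup = 500,
                             seed = 1) {
  resp <- paste0(outcome, "_", interval)
  need <- c(adjustment_fields(baseline_mediators), resp)
  keep <- stats::complete.cases(data[need])
  if (!is.null(subsample_rule)) keep <- keep & subsample_rule(data)
  rows <- which(keep)
  if (length(rows) == 0)
    stop("insufficient data: empty subsample for the total-effect model",
         call. = FALSE)
  des <- build_design(data, rows, baseline_mediators)
  y <- data[[resp]][rows]
  prior <- prior_for_design(des$X)
  chains <- gibbs_logistic(des$X, y, prior$mean, prior$sd,
                           n_chains = n_chains, n_keep = n_keep,
                           warmup = warmup, seed = seed)
  pd <- new_posterior_draws(chains, model = "logistic",
                            spec = list(response = resp, family = "logistic",
                                        terms = colnames(des$X),
                                        total_effect = TRUE),
                            rows = rows, transforms = des$transforms)
  # adjusted marginal OR by g-computation: per draw, average the predicted
  # risks over the observed covariate rows under each arm and take the odds
  # ratio; unlike the arm coefficient (a conditional OR), this estimand is
  # collapsible and matches the marginal odds ratios of the mediation module
  X1 <- des$X; X1[, "arm"] <- 1
  X0 <- des$X; X0[, "arm"] <- 0
  draws <- do.call(rbind, chains)
  log_or_marg <- vapply(seq_len(nrow(draws)), function(k) {
    b <- draws[k, ]
    p1 <- mean(plogis(X1 %*% b))
    p0 <- mean(plogis(X0 %*% b))
    log(odds(p1) / odds(p0))
  }, numeric(1))
  structure(list(summary = summarize_draws(pd$draws[, "arm"],
                                           transform = "exp"),
                 marginal_summary = summarize_draws(log_or_marg,
                                                    transform = "exp"),
                 fit = pd),
            class = "total_effect")
}

#' Fit the hierarchical attrition model
#'
#' Logistic regression of a response indicator on all baseline covariates,
#' arm, and arm-by-covariate interactions. Every effect coefficient gets a
#' Cauchy(0, tau) prior whose common scale tau has a half-normal(0, 1)
#' hyperprior, shrinking the deliberately large covariate set. Arm-specific
#' covariate effects (control: the main effect; intervention: main effect
#' plus interaction) are summarised per covariate.
#'
#' @param data trial records.
#' @param interval 1, 3 or 6 (selects `responded_med_<interval>` by default).
#' @param response_field response indicator column (overrides `interval`).
#' @param n_chains,n_keep,warmup,seed sampler settings.
#' @return a list of class `attrition_fit`: `fit` (a `posterior_draws` with
#'   hyperprior-scale draws in `aux$tau`) and `arm_effects` (a data.frame of
#'   per-covariate, per-arm summaries).
#' @export
fit_attrition_model <- function(data, interval = 1, response_field = NULL,
                                n_chains = 4, n_keep = 1000, warmup = 500,
                                seed = 1) {
  response_field <- response_field %||% paste0("responded_med_", interval)
  y <- data[[response_field]]
  if (is.null(y)) stop("no such response field: ", response_field,
                       call. = FALSE)
  if (length(unique(y)) < 2)
    stop("degenerate response: ", response_field,
         " is constant", call. = FALSE)
  covs <- c("sex_woman", "age_z", "version_surgery", "ftnd_z", "cigs_z",
            "base_importance_z", "base_knowhow_z", "base_confidence_z")
  rows <- which(stats::complete.cases(
    data[c("group", "sex", "age", "version", "ftnd", "cigs_per_week",
           paste0(MEDIATORS, "_0"))]))
  des <- build_design(data, rows, MEDIATORS)
  cigs_t <- standardize_mediator(data$cigs_per_week[rows])
  X <- cbind(des$X, cigs_z = cigs_t$values)
  des$transforms$cigs <- cigs_t[c("center", "scale")]
  X <- X[, c("(Intercept)", "arm", covs)]
  arm <- X[, "arm"]
  inter <- X[, covs, drop = FALSE] * arm
  colnames(inter) <- paste0("arm:", covs)
  X <- cbind(X, inter)
  effect_cols <- which(colnames(X) != "(Intercept)")
  res <- gibbs_attrition(X, y[rows], effect_cols, tau_prior_sd = 1,
                         n_chains = n_chains, n_keep = n_keep,
                         warmup = warmup, seed = seed)
  chains_full <- Map(function(b, t) cbind(b, tau = t), res$chains, res$tau)
  pd <- new_posterior_draws(chains_full, model = "attrition",
                            spec = list(response = response_field,
                                        family = "logistic",
                                        terms = colnames(X)),
                            rows = rows, transforms = des$transforms,
                            aux = list(tau = unlist(res$tau)))
  eff <- do.call(rbind, lapply(covs, function(cv) {
    ctl <- pd$draws[, cv]
    int <- pd$draws[, cv] + pd$draws[, paste0("arm:", cv)]
    rbind(
      data.frame(covariate = cv, arm = "control",
                 as.data.frame(unclass(summarize_draws(ctl))[
                   c("estimate", "ci_low", "ci_high", "prob_direction")])),
      data.frame(covariate = cv, arm = "intervention",
                 as.data.frame(unclass(summarize_draws(int))[
                   c("estimate", "ci_low", "ci_high", "prob_direction")])))
  }))
  rownames(eff) <- NULL
  structure(list(fit = pd, arm_effects = eff), class = "attrition_fit")
}

#' @export
print.attrition_fit <- function(x, ...) {
  cat(sprintf("Attrition model for %s (n = %d)\n", x$fit$spec$response,
              length(x$fit$rows)))
  cat(sprintf("  hyperprior scale tau: median %.3f\n",
              median(x$fit$aux$tau)))
  print(x$arm_effects, digits = 3)
  invisible(x)
}

#' @export
print.total_effect <- function(x, ...) {
  cat(sprintf("Total effect of intervention on %s (n = %d): ",
              x$fit$spec$response, length(x$fit$rows)))
  print(x$summary)
  invisible(x)
}

#' Summarise posterior draws
#'
#' Posterior median as the point estimate, 95% compatibility interval from
#' the 2.5% and 97.5% percentiles (linear interpolation), and the posterior
#' probability that the effect exceeds its null value (0 on the identity
#' scale, 1 after exponentiation). With `transform = "exp"` the percentiles
#' are taken of the exponentiated draws; the median is transform-equivariant
#' either way.
#'
#' @param draws numeric vector of posterior draws (identity scale).
#' @param transform "identity" or "exp".
#' @param scale reported scale label; defaults to "log_odds"/"odds_ratio"
#'   according to the transform.
#' @return an object of class `effect_summary`.
#' @export
summarize_draws <- function(draws, transform = c("identity", "exp"),
                            scale = NULL) {
  transform <- match.arg(transform)
  if (length(draws) == 0) stop("empty draws", call. = FALSE)
  prob_dir <- mean(draws > 0)
  x <- if (transform == "exp") exp(draws) else draws
  qs <- quantile(x, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  structure(list(estimate = qs[1], ci_low = qs[2], ci_high = qs[3],
                 prob_direction = prob_dir,
                 scale = scale %||%
                   if (transform == "exp") "odds_ratio" else "log_odds",
                 n_draws = length(draws)),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  null_lab <- if (x$scale == "odds_ratio") "OR > 1" else "Est. > 0"
  cat(sprintf("%.3f (%.3f; %.3f), Pr(%s) = %.1f%% [%s, %d draws]\n",
              x$estimate, x$ci_low, x$ci_high, null_lab,
              100 * x$prob_direction, x$scale, x$n_draws))
  invisible(x)
}

#' Gate a fit on its sampler diagnostics
#'
#' Fails (or warns, with `override = TRUE`) when the potential scale
#' reduction exceeds `max_rhat` or any divergent transition was recorded.
#'
#' @param fit a `posterior_draws` object.
#' @param max_rhat threshold on the potential scale reduction.
#' @param override downgrade failure to a warning.
#' @return invisibly, the fit.
#' @export
check_diagnostics <- function(fit, max_rhat = 1.01, override = FALSE) {
  d <- fit$diagnostics
  bad <- character(0)
  if (is.finite(d$max_rhat) && d$max_rhat > max_rhat)
    bad <- c(bad, sprintf("max Rhat %.3f > %.2f", d$max_rhat, max_rhat))
  if (d$divergences > 0)
    bad <- c(bad, sprintf("%d divergent transitions", d$divergences))
  if (length(bad) > 0) {
    msg <- paste0("sampler diagnostics flagged for ",
                  fit$spec$response %||% "model", ": ",
                  paste(bad, collapse = "; "))
    if (override) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  invisible(fit)
}
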