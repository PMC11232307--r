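# Counterfactual mediation formulas.
#
# For each posterior draw, the conditional law of the standardised mediator
# vector under arm a' (normal, mean from the mediator model, residual sd from
# its posterior) is integrated against the logistic outcome model evaluated
# at arm a, for every row of the observed covariate sample; the row-wise
# probabilities are averaged into the marginal counterfactual probability
# p(a, M(a')). With conditionally independent mediators the integrand depends
# on the mediators only through the scalar sum of their outcome coefficients
# times their values, which is itself normal, so Gauss-Hermite quadrature in
# one dimension is exact for any number of mediators; Monte Carlo integration
# with common random numbers across the four compositions is available as an
# independent route.
#
# Odds-ratio effects, per draw:
#   pure pairing:           OR_NDE = odds p(1,M(0)) / odds p(0,M(0))
#                           OR_NIE = odds p(0,M(1)) / odds p(0,M(0))
#   total pairing:          OR_NDE* = odds p(1,M(1)) / odds p(0,M(1))
#                           OR_NIE* = odds p(1,M(1)) / odds p(1,M(0))
#   total effect:           OR_TE  = odds p(1,M(1)) / odds p(0,M(0))
# OR_TE = OR_NDE* x OR_NIE = OR_NDE x OR_NIE* holds exactly per draw.

gh_rule <- function(size) {
  gh <- pracma::gaussHermite(size)
  list(x = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# marginal probability for one draw: c_i = row-wise fixed part, the mediator
# sum contributes mean mu_i and sd s
marginal_prob <- function(c_rows, s, rule) {
  .logistic_mix_mean(c_rows, s * rule$x, rule$w)
}

#' Marginal counterfactual probability for one posterior draw
#'
#' Integrates the conditional normal law of the standardised mediators under
#' arm `a_mediator` against the logistic outcome model evaluated at arm
#' `a_direct`, row by row over the observed covariate sample, and averages.
#'
#' @param outcome_draw named coefficient vector of the outcome model
#'   (mediator coefficients named `med_<mediator>`).
#' @param mediator_draws named list; per mediator a list with `coef` (named
#'   vector over the mediator-model design columns, including `arm`) and
#'   `sigma` (residual sd on the standardised scale).
#' @param a_direct,a_mediator arm indicators (0/1) for the direct path and
#'   the mediator law.
#' @param covariate_rows design matrix of the analysis sample containing every
#'   column named by the coefficient vectors except the `med_*` columns; its
#'   `arm` column is overridden.
#' @param method "gauss_hermite" (default) or "monte_carlo" (common random
#'   numbers shared through `seed`).
#' @param size nodes (Gauss-Hermite) or draws (Monte Carlo).
#' @param seed seed for the Monte Carlo route.
#' @return the marginal probability (scalar).
#' @export
counterfactual_risk <- function(outcome_draw, mediator_draws,
                                a_direct, a_mediator, covariate_rows,
                                method = c("gauss_hermite", "monte_carlo"),
                                size = 32, seed = 1) {
  method <- match.arg(method)
  if (size < 1) stop("integration size must be >= 1", call. = FALSE)
  X <- as.matrix(covariate_rows)
  meds <- names(mediator_draws)
  med_cols <- paste0("med_", meds)
  out_cov <- setdiff(names(outcome_draw), med_cols)
  if (!all(out_cov %in% colnames(X)))
    stop("covariate_rows lacks columns: ",
         paste(setdiff(out_cov, colnames(X)), collapse = ", "), call. = FALSE)
  Xa <- X
  Xa[, "arm"] <- a_direct
  c_rows <- as.vector(Xa[, out_cov, drop = FALSE] %*% outcome_draw[out_cov])
  b <- outcome_draw[med_cols]
  Xm <- X
  Xm[, "arm"] <- a_mediator
  sig2 <- 0
  for (j in seq_along(meds)) {
    md <- mediator_draws[[j]]
    if (any(!is.finite(md$coef)) || !is.finite(md$sigma))
      stop("non-finite mediator-law parameters", call. = FALSE)
    mu <- as.vector(Xm[, names(md$coef), drop = FALSE] %*% md$coef)
    c_rows <- c_rows + b[j] * mu
    sig2 <- sig2 + (b[j] * md$sigma)^2
  }
  s <- sqrt(sig2)
  if (method == "gauss_hermite") {
    marginal_prob(c_rows, s, gh_rule(size))
  } else {
    z <- with_private_seed(seed, rnorm(size))
    .logistic_mix_mean(c_rows, s * z, rep(1 / size, size))
  }
}

# extract the per-draw mediator laws and outcome coefficients shared by
# natural_effects(); validates alignment between fits
mediation_engine_inputs <- function(mediator_fits, outcome_fit) {
  meds <- names(mediator_fits)
  if (is.null(meds) || any(meds == ""))
    stop("mediator_fits must be a named list", call. = FALSE)
  set_out <- outcome_fit$spec$mediator_set
  if (!setequal(meds, set_out))
    stop("mediator sets of the fits disagree", call. = FALSE)
  rows <- outcome_fit$rows
  for (m in meds) {
    if (!identical(mediator_fits[[m]]$rows, rows))
      stop("row sets of the mediator and outcome fits are not aligned",
           call. = FALSE)
  }
  n_draws <- min(vapply(mediator_fits, function(f) f$n_draws, numeric(1)),
                 outcome_fit$n_draws)
  list(meds = meds, rows = rows, n_draws = n_draws)
}

#' Natural direct and indirect effect odds ratios
#'
#' Combines mediator-model and outcome-model posteriors through the
#' counterfactual mediation formula. Per posterior draw, the four marginal
#' compositions p(a_direct, M(a_mediator)) are computed by integrating the
#' conditional mediator law over the observed covariate rows of the shared
#' analysis sample, and the natural direct, natural indirect and total effect
#' odds ratios are formed. The headline summaries follow the requested
#' pairing; the complementary pairing (the one that multiplies exactly to the
#' total effect together with the headline NIE) is always reported alongside,
#' and the per-draw multiplicative-decomposition error is recorded.
#'
#' @param mediator_fits named list of `posterior_draws` from
#'   [fit_mediator_model()], fitted on the same rows as `outcome_fit`.
#' @param outcome_fit a `posterior_draws` from [fit_outcome_model()].
#' @param pairing "pure" (the pure natural effects: NDE at M(0), NIE in
#'   the control arm) or "total" (TNDE/TNIE).
#' @param method,size integration settings (see [counterfactual_risk()]).
#' @param seed seed for the Monte Carlo integration route.
#' @return an object of class `mediation_result` with `effect_summary`
#'   elements `nde`, `nie`, `te`, `nde_comp`, `nie_comp`.
#' @export
natural_effects <- function(mediator_fits, outcome_fit,
                            pairing = c("pure", "total"),
                            method = c("gauss_hermite", "monte_carlo"),
                            size = NULL, seed = 1) {
  pairing <- match.arg(pairing)
  method <- match.arg(method)
  inp <- mediation_engine_inputs(mediator_fits, outcome_fit)
  meds <- inp$meds
  size <- size %||% if (method == "gauss_hermite") 32 else 2000
  if (size < 1) stop("integration size must be >= 1", call. = FALSE)

  Xout <- outcome_fit$X
  med_cols <- paste0("med_", meds)
  out_cov <- setdiff(colnames(Xout), med_cols)
  arm_j <- which(out_cov == "arm")
  X0 <- Xout[, out_cov, drop = FALSE]
  X0[, "arm"] <- 0
  # mediator designs with arm zeroed; arm coefficient added separately
  Xm0 <- lapply(meds, function(m) {
    Xm <- mediator_fits[[m]]$X
    Xm[, "arm"] <- 0
    Xm
  })
  names(Xm0) <- meds

  rule <- if (method == "gauss_hermite") gh_rule(size) else {
    z <- with_private_seed(seed, rnorm(size))
    list(x = z, w = rep(1 / size, size))
  }

  nd <- inp$n_draws
  log_or <- matrix(NA_real_, nd, 5,
                   dimnames = list(NULL, c("nde", "nie", "te",
                                           "nde_comp", "nie_comp")))
  for (d in seq_len(nd)) {
    gam <- outcome_fit$draws[d, ]
    b <- gam[med_cols]
    lp0 <- as.vector(X0 %*% gam[out_cov])
    gam_arm <- gam["arm"]
    mu_shift0 <- 0; mu_shift1 <- 0; sig2 <- 0
    for (m in meds) {
      mf <- mediator_fits[[m]]
      beta <- mf$draws[d, mf$spec$terms]
      mu0 <- as.vector(Xm0[[m]] %*% beta)
      mu_shift0 <- mu_shift0 + b[paste0("med_", m)] * mu0
      mu_shift1 <- mu_shift1 + b[paste0("med_", m)] * (mu0 + beta["arm"])
      sig2 <- sig2 + (b[paste0("med_", m)] * mf$sigma[d])^2
    }
    s <- sqrt(sig2)
    p00 <- marginal_prob(lp0 + mu_shift0, s, rule)
    p01 <- marginal_prob(lp0 + mu_shift1, s, rule)
    p10 <- marginal_prob(lp0 + gam_arm + mu_shift0, s, rule)
    p11 <- marginal_prob(lp0 + gam_arm + mu_shift1, s, rule)
    log_or[d, ] <- c(log(odds(p10) / odds(p00)),
                     log(odds(p01) / odds(p00)),
                     log(odds(p11) / odds(p00)),
                     log(odds(p11) / odds(p01)),
                     log(odds(p11) / odds(p10)))
  }
  decomp_err <- max(abs(log_or[, "te"] -
                          log_or[, "nde_comp"] - log_or[, "nie"]))
  summaries <- lapply(as.data.frame(log_or), summarize_draws,
                      transform = "exp")
  headline <- if (pairing == "pure") {
    list(nde = summaries$nde, nie = summaries$nie)
  } else {
    list(nde = summaries$nde_comp, nie = summaries$nie_comp)
  }
  structure(list(nde = headline$nde, nie = headline$nie, te = summaries$te,
                 nde_comp = summaries$nde_comp, nie_comp = summaries$nie_comp,
                 nde_pure = summaries$nde, nie_pure = summaries$nie,
                 log_or_draws = log_or,
                 decomposition_max_abs_err = decomp_err,
                 spec = list(outcome = outcome_fit$spec$outcome,
                             outcome_interval = outcome_fit$spec$outcome_interval,
                             mediator_interval = outcome_fit$spec$mediator_interval,
                             mediator_set = meds, pairing = pairing,
                             method = method, size = size),
                 n_rows = length(inp$rows), n_draws = nd),
            class = "mediation_result")
}

#' Joint natural effects through all three mediators
#'
#' As [natural_effects()], but requires the outcome model to contain all
#' three mediators and shifts the whole mediator vector between its
#' control-arm and intervention-arm laws simultaneously (the mediators are
#' modelled as conditionally independent given the covariates).
#'
#' @inheritParams natural_effects
#' @export
joint_natural_effects <- function(mediator_fits, outcome_fit,
                                  pairing = c("pure", "total"),
                                  method = c("gauss_hermite", "monte_carlo"),
                                  size = NULL, seed = 1) {
  if (length(mediator_fits) != 3)
    stop("joint model requires the three mediator fits", call. = FALSE)
  natural_effects(mediator_fits, outcome_fit, pairing = pairing,
                  method = method, size = size, seed = seed)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation result: %s abstinence at %d months via %s at %d month(s)\n",
              x$spec$outcome %||% "?", x$spec$outcome_interval %||% NA,
              paste(x$spec$mediator_set, collapse = "+"),
              x$spec$mediator_interval %||% NA))
  cat(sprintf("  pairing: %s; integration: %s (%d); rows: %d; draws: %d\n",
              x$spec$pairing, x$spec$method, x$spec$size, x$n_rows, x$n_draws))
  for (nm in c("nie", "nde", "te")) {
    cat(sprintf("  %-25s", switch(nm, nie = "Natural indirect effect",
                                  nde = "Natural direct effect",
                                  te = "Total effect")))
    print(x[[nm]])
  }
  invisible(x)
}

#' Assemble the mediation results table
#'
#' Formats a set of `mediation_result` objects into the trial's reporting
#' layout: one block per mediator set, with "Natural indirect effect" and
#' "Natural direct effect" rows carrying the median odds ratio, the 95%
#' compatibility interval and Pr(OR > 1).
#'
#' @param results named list of `mediation_result` objects.
#' @param file optional path; the table is written as CSV with full-precision
#'   numbers so that [parse_mediation_table()] round-trips exactly.
#' @return a data.frame.
#' @export
mediation_table <- function(results, file = NULL) {
  rows <- list()
  for (nm in names(results)) {
    r <- results[[nm]]
    block <- if (length(r$spec$mediator_set) > 1) "full" else
      r$spec$mediator_set
    for (eff in c("nie", "nde")) {
      s <- r[[eff]]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = r$spec$outcome %||% NA_character_,
        outcome_interval = r$spec$outcome_interval %||% NA_integer_,
        mediator_interval = r$spec$mediator_interval %||% NA_integer_,
        block = block,
        effect = if (eff == "nie") "Natural indirect effect" else
          "Natural direct effect",
        estimate = s$estimate, ci_low = s$ci_low, ci_high = s$ci_high,
        pr_gt_1 = s$prob_direction,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) == 0) {
    data.frame(outcome = character(0), outcome_interval = integer(0),
               mediator_interval = integer(0), block = character(0),
               effect = character(0), estimate = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               pr_gt_1 = numeric(0), stringsAsFactors = FALSE)
  } else do.call(rbind, rows)
  if (!is.null(file)) {
    out <- tab
    for (cc in c("estimate", "ci_low", "ci_high", "pr_gt_1"))
      out[[cc]] <- sprintf("%.17g", out[[cc]])
    write.csv(out, file, row.names = FALSE, na = "")
  }
  tab
}

#' Read back a mediation table written by [mediation_table()]
#' @param path CSV path.
#' @return a data.frame with numeric summary columns.
#' @export
parse_mediation_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  for (cc in c("estimate", "ci_low", "ci_high", "pr_gt_1"))
    tab[[cc]] <- as.numeric(tab[[cc]])
  tab
}
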