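# Multiple imputation by chained equations, as the missing-data sensitivity
# analysis. Continuous mediators are imputed by predictive mean matching
# (type-1 parameter draw, donor pool of 5); binary outcomes by an approximate
# Bayesian logistic draw (coefficients sampled from the asymptotic posterior
# of a maximum-likelihood fit, then Bernoulli). Variables are visited in
# ascending order of missingness, cycling `n_iter` times; each variable's
# imputation model uses the baseline covariates, arm, and all other analysis
# variables (congenial with the mediation models, which condition on the
# outcome and mediators jointly).

impute_targets <- function(data) {
  cand <- c(paste0(rep(MEDIATORS, each = 3), "_", c(1, 3, 6)),
            paste0(rep(OUTCOMES, each = 2), "_", c(3, 6)))
  cand[cand %in% names(data) &
         vapply(cand, function(v) anyNA(data[[v]]), logical(1))]
}

imputation_predictors <- function(data, target) {
  base <- c("arm_num", "sex_num", "age", "version_num", "ftnd",
            "cigs_per_week", paste0(MEDIATORS, "_0"))
  others <- setdiff(c(paste0(rep(MEDIATORS, each = 3), "_", c(1, 3, 6)),
                      paste0(rep(OUTCOMES, each = 2), "_", c(3, 6))),
                    target)
  c(base, others[others %in% names(data)])
}

draw_mvn <- function(mean, cov) {
  L <- chol(cov + diag(1e-10, nrow(cov)))
  as.vector(mean + t(L) %*% rnorm(length(mean)))
}

# one predictive-mean-matching update of a continuous variable
pmm_impute <- function(y_obs, X_obs, X_mis, donors = 5) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- lm.fit(X_obs, y_obs)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(y_obs) - length(beta_hat), 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  XtXinv <- chol2inv(chol(crossprod(X_obs) + diag(1e-8, ncol(X_obs))))
  beta_star <- draw_mvn(beta_hat, sigma2 * XtXinv)
  yhat_obs <- as.vector(X_obs %*% beta_hat)
  yhat_mis <- as.vector(X_mis %*% beta_star)
  vapply(yhat_mis, function(v) {
    d <- abs(yhat_obs - v)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[sample(pool, 1)]
  }, numeric(1))
}

# one approximate-Bayesian logistic update of a binary variable
logreg_impute <- function(y_obs, X_obs, X_mis) {
  qrX <- qr(X_obs)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  X_obs <- X_obs[, keep, drop = FALSE]
  X_mis <- X_mis[, keep, drop = FALSE]
  fit <- tryCatch(
    suppressWarnings(glm.fit(X_obs, y_obs, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || any(!is.finite(coef(fit)))) {
    # degenerate model: fall back to the observed marginal rate
    p <- rep(mean(y_obs), nrow(X_mis))
    return(rbinom(nrow(X_mis), 1, p))
  }
  W <- fit$weights
  cov <- tryCatch(chol2inv(chol(crossprod(X_obs * sqrt(W)) +
                                  diag(1e-8, ncol(X_obs)))),
                  error = function(e) diag(1e-4, ncol(X_obs)))
  beta_star <- draw_mvn(coef(fit), cov)
  rbinom(nrow(X_mis), 1, plogis(as.vector(X_mis %*% beta_star)))
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed datasets. Missingness must be confined to the
#' follow-up mediator and outcome fields; baseline fields must be complete.
#' Continuous mediators are imputed by predictive mean matching (donor pool
#' of 5), so imputed values are always members of the observed value set;
#' binary outcomes by Bayesian logistic draws. Observed values are never
#' modified.
#'
#' @param data trial records.
#' @param m number of completed datasets.
#' @param n_iter chained-equation cycles per dataset.
#' @param seed integer seed; fixed seed gives an identical imputation set.
#' @param donors donor-pool size for predictive mean matching.
#' @return an object of class `imputation_set`: `datasets` (list of `m`
#'   completed data.frames), `methods`, `n_iter`, `seed`.
#' @export
impute_chained <- function(data, m = 20, n_iter = 20, seed = 1, donors = 5) {
  targets <- impute_targets(data)
  base_fields <- c("group", "sex", "age", "version", "ftnd", "cigs_per_week",
                   paste0(MEDIATORS, "_0"))
  if (anyNA(data[base_fields]))
    stop("baseline fields must be complete before imputation", call. = FALSE)
  all_missing <- targets[vapply(targets, function(v) all(is.na(data[[v]])),
                                logical(1))]
  if (length(all_missing) > 0)
    stop("variables with no observed values cannot be imputed: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  methods <- setNames(
    ifelse(grepl("^(prolonged|pp)_", targets), "logreg", "pmm"), targets)
  if (length(targets) == 0) {
    out <- structure(list(datasets = replicate(m, data, simplify = FALSE),
                          methods = methods, n_iter = n_iter, seed = seed),
                     class = "imputation_set")
    return(out)
  }
  # visit order: ascending missingness
  n_mis <- vapply(targets, function(v) sum(is.na(data[[v]])), numeric(1))
  targets <- targets[order(n_mis)]
  work0 <- data
  work0$arm_num <- as.numeric(data$group == "intervention")
  work0$sex_num <- as.numeric(data$sex == "woman")
  work0$version_num <- as.numeric(data$version == "surgery")
  set.seed(seed)
  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    work <- work0
    # initial fill: sample from observed values
    for (v in targets) {
      mis <- is.na(work[[v]])
      work[[v]][mis] <- sample(work[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (cycle in seq_len(n_iter)) {
      for (v in targets) {
        mis <- is.na(data[[v]])
        preds <- imputation_predictors(work, v)
        Xall <- cbind(1, as.matrix(work[preds]))
        y_obs <- data[[v]][!mis]
        imputed <- if (methods[v] == "pmm")
          pmm_impute(y_obs, Xall[!mis, , drop = FALSE],
                     Xall[mis, , drop = FALSE], donors)
        else
          logreg_impute(y_obs, Xall[!mis, , drop = FALSE],
                        Xall[mis, , drop = FALSE])
        work[[v]][mis] <- imputed
      }
    }
    work$arm_num <- work$sex_num <- work$version_num <- NULL
    datasets[[imp]] <- work
  }
  structure(list(datasets = datasets, methods = methods, n_iter = n_iter,
                 seed = seed),
            class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("Imputation set: m = %d completed datasets, %d cycles\n",
              length(x$datasets), x$n_iter))
  if (length(x$methods) > 0) {
    cat("  methods:\n")
    for (v in names(x$methods))
      cat(sprintf("    %-14s %s\n", v, x$methods[v]))
  } else cat("  no missing analysis fields; datasets are copies\n")
  invisible(x)
}

#' Pool posterior draws across imputed datasets
#'
#' Concatenates the coefficient draws of fits of the same model on each
#' completed dataset into one mixture posterior, reflecting within- plus
#' between-imputation uncertainty; summaries are then computed as usual.
#'
#' @param fits list of `posterior_draws` sharing coefficient names.
#' @return a pooled `posterior_draws` object.
#' @export
pool_posteriors <- function(fits) {
  stopifnot(length(fits) >= 1)
  nm <- colnames(fits[[1]]$draws)
  for (f in fits[-1]) {
    if (!identical(colnames(f$draws), nm))
      stop("fits have mismatched coefficient names", call. = FALSE)
  }
  draws <- do.call(rbind, lapply(fits, `[[`, "draws"))
  pooled <- fits[[1]]
  pooled$draws <- draws
  pooled$n_draws <- nrow(draws)
  pooled$n_chains <- sum(vapply(fits, `[[`, numeric(1), "n_chains"))
  pooled$sigma <- if (!is.null(fits[[1]]$sigma))
    unlist(lapply(fits, `[[`, "sigma")) else NULL
  pooled$diagnostics$max_rhat <-
    max(vapply(fits, function(f) f$diagnostics$max_rhat, numeric(1)))
  pooled$diagnostics$min_ess <-
    sum(vapply(fits, function(f) f$diagnostics$min_ess, numeric(1)))
  pooled$diagnostics$pooled_m <- length(fits)
  pooled
}
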