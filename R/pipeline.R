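# Orchestration: simulate -> fit -> mediate -> attrition -> (impute) ->
# report, as one seeded, reproducible run, plus the delimited-text data
# interface with schema validation.

TRIAL_COLUMNS <- function() {
  c("id", "sex", "age", "version", "ftnd", "cigs_per_week",
    paste0(MEDIATORS, "_0"), "group",
    paste0(rep(MEDIATORS, times = 3), "_", rep(c(1, 3, 6), each = 3)),
    "prolonged_3", "pp_3", "prolonged_6", "pp_6",
    paste0("responded_med_", c(1, 3, 6)),
    paste0("responded_out_", c(3, 6)))
}

#' Write trial records as delimited text
#'
#' Comma-separated, header row, UTF-8, missing values as empty fields.
#' @param data trial records.
#' @param path output file.
#' @export
write_trial_data <- function(data, path) {
  out <- data[intersect(TRIAL_COLUMNS(), names(data))]
  for (cc in names(out))
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]]))
      out[[cc]] <- sprintf("%.17g", out[[cc]])
  out[is.na(data[intersect(TRIAL_COLUMNS(), names(data))])] <- NA
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_trial_data <- function(data) {
  problems <- character(0)
  add <- function(rows, what) {
    if (length(rows) > 0)
      problems <<- c(problems,
                     sprintf("%s (rows %s)", what,
                             paste(utils::head(rows, 5), collapse = ", ")))
  }
  need <- c("id", "sex", "age", "version", "ftnd", "cigs_per_week",
            paste0(MEDIATORS, "_0"), "group")
  miss_col <- setdiff(need, names(data))
  if (length(miss_col) > 0)
    stop("missing required columns: ", paste(miss_col, collapse = ", "),
         call. = FALSE)
  add(which(!data$sex %in% c("woman", "other")), "invalid sex")
  add(which(!data$version %in% c("general", "surgery")), "invalid version")
  add(which(!data$group %in% c("intervention", "control")), "invalid group")
  add(which(data$age < 18), "age below eligibility minimum 18")
  add(which(data$cigs_per_week < 1), "cigarettes per week below 1")
  add(which(data$ftnd < 0 | data$ftnd > 10), "FTND outside [0, 10]")
  med_cols <- c(paste0(MEDIATORS, "_0"),
                intersect(paste0(rep(MEDIATORS, 3), "_", rep(c(1, 3, 6), each = 3)),
                          names(data)))
  for (cc in med_cols) {
    v <- data[[cc]]
    add(which(!is.na(v) & (v < 1 | v > 10)),
        sprintf("mediator %s outside [1, 10]", cc))
  }
  # a measure is missing iff its response indicator is 0
  for (t in c(1, 3, 6)) {
    ind <- data[[paste0("responded_med_", t)]]
    if (is.null(ind)) next
    for (m in MEDIATORS) {
      v <- data[[paste0(m, "_", t)]]
      if (is.null(v)) next
      add(which(ind == 1 & is.na(v)),
          sprintf("%s_%s missing despite response indicator 1", m, t))
      add(which(ind == 0 & !is.na(v)),
          sprintf("%s_%s present despite response indicator 0", m, t))
    }
  }
  for (t in c(3, 6)) {
    ind <- data[[paste0("responded_out_", t)]]
    if (is.null(ind)) next
    for (o in OUTCOMES) {
      v <- data[[paste0(o, "_", t)]]
      if (is.null(v)) next
      add(which(ind == 1 & is.na(v)),
          sprintf("%s_%s missing despite response indicator 1", o, t))
      add(which(ind == 0 & !is.na(v)),
          sprintf("%s_%s present despite response indicator 0", o, t))
    }
  }
  if (length(problems) > 0)
    stop("trial data failed validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  invisible(data)
}

#' Read and validate trial records
#'
#' Reads the delimited-text schema written by [write_trial_data()] and
#' enforces the data model: categorical levels, eligibility bounds, mediator
#' range 1-10, and the consistency rule that a measure is missing if and only
#' if its response indicator is 0. Violations are reported with row numbers.
#'
#' @param path CSV path.
#' @param validate run the schema checks (default `TRUE`).
#' @return a data.frame of participant records.
#' @export
read_trial_data <- function(path, validate = TRUE) {
  data <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  if (validate) validate_trial_data(data)
  data
}

mediation_analysis_plan <- function() {
  plan <- expand.grid(outcome = OUTCOMES, outcome_interval = OUT_INTERVALS,
                      block = c("full", MEDIATORS),
                      stringsAsFactors = FALSE)
  plan$mediator_interval <- ifelse(plan$outcome_interval == 3, 1L, 3L)
  plan
}

#' Run the full mediation analysis pipeline
#'
#' Executes, on supplied or freshly simulated data: the mediator-effect table
#' (adjusted standardised treatment effects at 1/3/6 months), the natural
#' direct/indirect effect tables for both abstinence outcomes (1-month
#' mediators for 3-month outcomes, 3-month mediators for 6-month outcomes;
#' full three-mediator block plus each single mediator), the hierarchical
#' attrition models, the total-effect comparison between the full sample and
#' the mediation-available subsample, and optionally a chained-equation
#' imputation sensitivity analysis of the total effect. Every stage seed is
#' derived from the master seed by a fixed offset. Any fit failing the
#' potential-scale-reduction gate aborts the run with the stage name unless
#' `override_diagnostics` is set.
#'
#' @param config generator configuration used when `data` is `NULL`.
#' @param data optional participant records (overrides `config`).
#' @param seed master seed.
#' @param n_chains,n_keep,warmup sampler settings for all fits.
#' @param gh_nodes Gauss-Hermite nodes for the mediation integration.
#' @param pairing headline pairing convention.
#' @param attrition_intervals mediator follow-ups to run attrition models on.
#' @param impute run the imputation sensitivity analysis.
#' @param m,n_iter imputation settings.
#' @param oracle_check,oracle_n_mc with simulated data, append a comparison of
#'   every estimated NIE against the generator's brute-force truth.
#' @param gate_rhat potential-scale-reduction threshold of the diagnostics
#'   gate. The production default is 1.01; short exploratory chains carry
#'   enough Monte Carlo noise in the Rhat estimate itself that a looser gate
#'   is appropriate for them.
#' @param override_diagnostics continue past flagged sampler diagnostics.
#' @return an object of class `run_report`.
#' @export
run_mediation_pipeline <- function(config = default_generator_config(),
                                   data = NULL, seed = 1,
                                   n_chains = 2, n_keep = 500, warmup = 250,
                                   gh_nodes = 16,
                                   pairing = "pure",
                                   attrition_intervals = 1,
                                   impute = FALSE, m = 5, n_iter = 10,
                                   oracle_check = FALSE, oracle_n_mc = 1e5,
                                   gate_rhat = 1.01,
                                   override_diagnostics = FALSE) {
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }
  simulated <- is.null(data)
  if (is.null(data)) {
    config <- ensure_cache(config)
    data <- simulate_trial(config, derive_seed(seed, 10))
    logf("simulate: n=%d seed=%d", nrow(data), derive_seed(seed, 10))
  } else {
    validate_trial_data(data)
    logf("data: supplied, n=%d rows", nrow(data))
  }
  gate <- function(fit, stage) {
    tryCatch(check_diagnostics(fit, max_rhat = gate_rhat,
                               override = override_diagnostics),
             error = function(e)
               stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
                    call. = FALSE))
    fit
  }

  # Mediator-effect table (available data), one cell per mediator x interval
  med_rows <- list()
  fit_id <- 0
  for (m_ in MEDIATORS) {
    for (t in MED_INTERVALS) {
      fit_id <- fit_id + 1
      f <- tryCatch(
        fit_mediator_model(data, m_, t, n_chains = n_chains, n_keep = n_keep,
                           warmup = warmup, seed = derive_seed(seed, 20 + fit_id)),
        error = function(e) e)
      if (inherits(f, "error")) {
        logf("mediator %s@%d: %s", m_, t, conditionMessage(f))
        next
      }
      gate(f, sprintf("mediator %s@%d", m_, t))
      s <- summarize_draws(f$draws[, "arm"], scale = "standardised_difference")
      med_rows[[length(med_rows) + 1]] <-
        data.frame(mediator = m_, interval = t, n = length(f$rows),
                   estimate = s$estimate, ci_low = s$ci_low,
                   ci_high = s$ci_high, pr_gt_0 = s$prob_direction)
      logf("mediator %s@%d: n=%d est=%.3f", m_, t, length(f$rows), s$estimate)
    }
  }
  mediator_table <- if (length(med_rows)) do.call(rbind, med_rows) else NULL

  # Mediation blocks
  plan <- mediation_analysis_plan()
  results <- list()
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    set <- if (pl$block == "full") MEDIATORS else pl$block
    key <- sprintf("%s_%d_%s", pl$outcome, pl$outcome_interval, pl$block)
    res <- tryCatch({
      rows <- mediation_rows(data, set, pl$mediator_interval, pl$outcome,
                             pl$outcome_interval)
      mfits <- setNames(lapply(seq_along(set), function(j)
        fit_mediator_model(data, set[j], pl$mediator_interval, rows = rows,
                           n_chains = n_chains, n_keep = n_keep,
                           warmup = warmup,
                           seed = derive_seed(seed, 100 + 10 * i + j))), set)
      ofit <- fit_outcome_model(data, pl$outcome, pl$outcome_interval, set,
                                pl$mediator_interval, rows = rows,
                                n_chains = n_chains, n_keep = n_keep,
                                warmup = warmup,
                                seed = derive_seed(seed, 100 + 10 * i))
      for (f in mfits) gate(f, key)
      gate(ofit, key)
      natural_effects(mfits, ofit, pairing = pairing, size = gh_nodes,
                      seed = derive_seed(seed, 300 + i))
    }, error = function(e) e)
    if (inherits(res, "error")) logf("mediation %s: %s", key,
                                     conditionMessage(res))
    else {
      results[[key]] <- res
      logf("mediation %s: n=%d NIE=%.3f NDE=%.3f", key, res$n_rows,
           res$nie$estimate, res$nde$estimate)
    }
  }
  mediation_tables <- lapply(setNames(nm = OUTCOMES), function(o)
    mediation_table(results[grepl(paste0("^", o, "_"), names(results))]))

  # Attrition models
  attrition <- list()
  for (t in attrition_intervals) {
    a <- tryCatch(
      fit_attrition_model(data, t, n_chains = n_chains, n_keep = n_keep,
                          warmup = warmup,
                          seed = derive_seed(seed, 400 + t)),
      error = function(e) e)
    if (inherits(a, "error")) logf("attrition@%d: %s", t, conditionMessage(a))
    else {
      gate(a$fit, sprintf("attrition@%d", t))
      attrition[[as.character(t)]] <- a
      logf("attrition@%d: fitted on %d rows", t, length(a$fit$rows))
    }
  }

  # Total effect: full sample vs mediation-available subsample
  total <- list()
  for (o in OUTCOMES) {
    for (ti in OUT_INTERVALS) {
      mi <- if (ti == 3) 1 else 3
      key <- sprintf("%s_%d", o, ti)
      sub_rule <- local({
        mi0 <- mi
        function(d) rowSums(is.na(d[paste0(MEDIATORS, "_", mi0)])) == 0
      })
      tf <- tryCatch(list(
        full = fit_total_effect(data, o, ti, n_chains = n_chains,
                                n_keep = n_keep, warmup = warmup,
                                seed = derive_seed(seed, 500 + ti)),
        subsample = fit_total_effect(data, o, ti, subsample_rule = sub_rule,
                                     n_chains = n_chains, n_keep = n_keep,
                                     warmup = warmup,
                                     seed = derive_seed(seed, 520 + ti))),
        error = function(e) e)
      if (inherits(tf, "error")) logf("total %s: %s", key, conditionMessage(tf))
      else {
        total[[key]] <- tf
        logf("total %s: full OR=%.3f, subsample OR=%.3f", key,
             tf$full$summary$estimate, tf$subsample$summary$estimate)
      }
    }
  }

  # Oracle-comparison appendix: only meaningful when the data came from the
  # generator, so the true NIE of every analysed block is computable
  oracle_comparison <- NULL
  if (oracle_check && simulated) {
    orc <- list()
    for (key in names(results)) {
      r <- results[[key]]
      o <- oracle_true_effects(config, r$spec$outcome,
                               r$spec$outcome_interval,
                               mediator_set = r$spec$mediator_set,
                               n_mc = oracle_n_mc,
                               seed = derive_seed(seed, 700))
      orc[[key]] <- data.frame(
        analysis = key, oracle_nie = unname(o$or_nie["value"]),
        est_nie = r$nie$estimate, ci_low = r$nie$ci_low,
        ci_high = r$nie$ci_high,
        covered = o$or_nie["value"] >= r$nie$ci_low &
          o$or_nie["value"] <= r$nie$ci_high)
    }
    oracle_comparison <- do.call(rbind, orc)
    rownames(oracle_comparison) <- NULL
    logf("oracle check: %d/%d NIE intervals cover the truth",
         sum(oracle_comparison$covered), nrow(oracle_comparison))
  }

  # Imputation sensitivity of the total effect
  imputation <- NULL
  if (impute) {
    imp <- impute_chained(data, m = m, n_iter = n_iter,
                          seed = derive_seed(seed, 600))
    fits <- lapply(seq_along(imp$datasets), function(k)
      fit_total_effect(imp$datasets[[k]], "prolonged", 6,
                       n_chains = n_chains, n_keep = n_keep, warmup = warmup,
                       seed = derive_seed(seed, 600 + k))$fit)
    pooled <- pool_posteriors(fits)
    imputation <- list(set = imp,
                       pooled_total = summarize_draws(pooled$draws[, "arm"],
                                                      transform = "exp"))
    logf("imputation: m=%d pooled prolonged_6 OR=%.3f", m,
         imputation$pooled_total$estimate)
  }

  report <- structure(list(
    mediator_table = mediator_table,
    mediation_results = results,
    mediation_tables = mediation_tables,
    attrition = attrition,
    total_effects = total,
    oracle_comparison = oracle_comparison,
    imputation = imputation,
    manifest = list(seed = seed, n = nrow(data),
                    n_chains = n_chains, n_keep = n_keep, warmup = warmup,
                    gh_nodes = gh_nodes, pairing = pairing,
                    package_version = as.character(utils::packageVersion("cfmediate")),
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    log = log_lines), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Mediation analysis run\n")
  cat(sprintf("  n = %d, seed = %d\n", x$manifest$n, x$manifest$seed))
  if (!is.null(x$mediator_table)) {
    cat("  mediator arm effects (standardised):\n")
    print(x$mediator_table, digits = 3)
  }
  for (o in names(x$mediation_tables)) {
    cat(sprintf("  mediation table (%s):\n", o))
    print(x$mediation_tables[[o]], digits = 3)
  }
  invisible(x)
}

#' Write a run report to a directory
#'
#' Emits the mediator-effect table, the per-outcome mediation tables, the
#' attrition summaries and the total-effect comparison as CSV files plus a
#' plain-text manifest and log.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$mediator_table))
    write.csv(report$mediator_table,
              file.path(dir, "mediator_effects.csv"), row.names = FALSE)
  for (o in names(report$mediation_tables)) {
    mediation_table(
      report$mediation_results[grepl(paste0("^", o, "_"),
                                     names(report$mediation_results))],
      file = file.path(dir, sprintf("mediation_%s.csv", o)))
  }
  if (length(report$attrition) > 0) {
    att <- do.call(rbind, lapply(names(report$attrition), function(t)
      cbind(interval = t, report$attrition[[t]]$arm_effects)))
    write.csv(att, file.path(dir, "attrition_effects.csv"), row.names = FALSE)
  }
  if (length(report$total_effects) > 0) {
    tot <- do.call(rbind, lapply(names(report$total_effects), function(k) {
      tf <- report$total_effects[[k]]
      data.frame(outcome = k,
                 sample = c("full", "mediation_available"),
                 estimate = c(tf$full$summary$estimate,
                              tf$subsample$summary$estimate),
                 ci_low = c(tf$full$summary$ci_low,
                            tf$subsample$summary$ci_low),
                 ci_high = c(tf$full$summary$ci_high,
                             tf$subsample$summary$ci_high))
    }))
    write.csv(tot, file.path(dir, "total_effects.csv"), row.names = FALSE)
  }
  writeLines(c(sprintf("%s: %s", names(report$manifest),
                       vapply(report$manifest, as.character, character(1))),
               "", "log:", report$log),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}
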