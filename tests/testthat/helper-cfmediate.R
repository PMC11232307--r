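# Shared fixtures. Test configurations use a reduced internal calibration
# sample (the defaults use 200k) and reduced sampler settings; the acceptance
# tests use the full study conditions.

test_config <- function(n = 1012, n_cache = 50000) {
  cfg <- default_generator_config(n = n)
  cfg$n_cache <- as.integer(n_cache)
  cfg
}

# a single-mediator configuration: only `mediator` carries an outcome path
single_mediator_config <- function(mediator = "knowhow", n = 2000,
                                   out = "prolonged_3", b = NULL) {
  cfg <- test_config(n = n)
  others <- setdiff(MEDIATORS_TEST, mediator)
  cfg$outcomes[[out]]$b[others] <- 0
  if (!is.null(b)) cfg$outcomes[[out]]$b[mediator] <- b
  cfg
}

MEDIATORS_TEST <- c("importance", "knowhow", "confidence")

quick_fit <- list(n_chains = 2, n_keep = 400, warmup = 200)

fit_med_quick <- function(data, mediator, interval, rows = NULL, seed = 1)
  fit_mediator_model(data, mediator, interval, rows = rows,
                     n_chains = quick_fit$n_chains, n_keep = quick_fit$n_keep,
                     warmup = quick_fit$warmup, seed = seed)

fit_out_quick <- function(data, outcome, oi, set, mi, rows = NULL, seed = 1)
  fit_outcome_model(data, outcome, oi, set, mi, rows = rows,
                    n_chains = quick_fit$n_chains, n_keep = quick_fit$n_keep,
                    warmup = quick_fit$warmup, seed = seed)
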