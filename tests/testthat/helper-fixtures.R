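# shared fixtures; heavy scenario runs are memoized across test files
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

toy_recording <- function(n_trials = 6, n_channels = 2, srate = 100,
                          window = c(-200, 500), seed = 1) {
  set.seed(seed)
  n_s <- n_epoch_samples(window, srate)
  epoched_recording(array(rnorm(n_trials * n_channels * n_s),
                          c(n_trials, n_channels, n_s)),
                    srate, window,
                    labels = rep(c("rare", "frequent"),
                                 length.out = n_trials),
                    participant_id = "TOY")
}

scaled_fc <- function() feature_config(freqs = seq(4, 14, by = 2))

scaled_cohort <- function(scenario, n_participants = 12, n_channels = 8,
                          seed = 42) {
  memo(paste0("cohort_", scenario, "_", n_participants), {
    simulate_cohort(make_scenario(scenario, n_participants = n_participants,
                                  n_channels = n_channels, seed = seed))
  })
}

# one full scaled procedure per scenario, participant-grouped splits
scaled_run <- function(scenario, n_iterations = 8) {
  memo(paste0("run_", scenario), {
    cohort <- scaled_cohort(scenario)
    plan <- sampling_plan(n_iterations = n_iterations, seed = 7)
    run <- run_procedure(cohort, plan, scaled_fc(), training_config(),
                         grouped = TRUE)
    aggregate_results(run$results)
  })
}

summary_of <- function(agg, model) {
  row <- agg$summary[agg$summary$model == model, ]
  list(mean = row$mean_accuracy, sem = row$sem)
}
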