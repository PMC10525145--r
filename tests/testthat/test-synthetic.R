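flat_topo <- function(n) rep(1, n)

quiet_cfg <- function(sources, n_rare = 6, n_frequent = 10, n_channels = 1,
                      seed = 3, rms = 1e-9) {
  sim_config(2, sources, n_rare = n_rare, n_frequent = n_frequent,
             srate = 150, n_channels = n_channels,
             background = list(alpha = 1, rms = rms), seed = seed)
}

test_that("a jitter-free transient reproduces its waveform exactly in every trial", {
  src <- source_spec("transient", amplitude = 4, topography = 1,
                     peak_latency = 350, width = 300)
  cfg <- quiet_cfg(list(list(rare = src, frequent = src)), rms = 0)
  rec <- simulate_participant(cfg, 1)
  t_ms <- rec_times(rec)
  expected <- 4 * exp(-4 * log(2) * (t_ms - 350)^2 / 300^2)
  for (i in c(1, 7, 16))
    expect_equal(rec$data[i, 1, ], expected, tolerance = 1e-12)
  # ERP equals the waveform (after baselining both)
  erp <- compute_erp(rec)
  expect_equal(erp$tensor[1, ],
               expected - mean(expected[t_ms >= -200 & t_ms <= 0]),
               tolerance = 1e-12)
})

test_that("cohorts are a pure function of the seed, with distinct participant streams", {
  cfg <- make_scenario("combined", n_participants = 3, n_channels = 2, seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1[[2]]$data, c2[[2]]$data)
  expect_false(identical(c1[[1]]$data, c1[[2]]$data))
  cfg2 <- make_scenario("combined", n_participants = 3, n_channels = 2, seed = 6)
  expect_false(identical(simulate_cohort(cfg2)[[1]]$data, c1[[1]]$data))
})

test_that("sources add linearly given shared RNG streams", {
  n_ch <- 2
  s1 <- source_spec("transient", amplitude = 3, topography = c(1, 0.5),
                    latency_jitter_sd = 10, amplitude_cv = 0.3)
  s2 <- source_spec("ongoing_oscillation", amplitude = 4,
                    topography = c(0.2, 1), center_freq = 8,
                    amplitude_cv = 0.2)
  zero1 <- s1; zero1$amplitude <- 0
  zero2 <- s2; zero2$amplitude <- 0
  pair <- function(a, b) list(list(rare = a, frequent = a),
                              list(rare = b, frequent = b))
  both <- simulate_participant(quiet_cfg(pair(s1, s2), n_channels = n_ch), 1)
  only1 <- simulate_participant(quiet_cfg(pair(s1, zero2), n_channels = n_ch), 1)
  only2 <- simulate_participant(quiet_cfg(pair(zero1, s2), n_channels = n_ch), 1)
  none <- simulate_participant(quiet_cfg(pair(zero1, zero2), n_channels = n_ch), 1)
  expect_equal(both$data - only1$data, only2$data - none$data,
               tolerance = 1e-10)
})

test_that("free-phase oscillations cancel in the average at the sqrt(n) rate", {
  src <- source_spec("ongoing_oscillation", amplitude = 1, topography = 1,
                     center_freq = 10, phase_mode = "free")
  avg_rms <- function(n_trials, seed) {
    cfg <- sim_config(1, list(list(rare = src, frequent = src)),
                      n_rare = n_trials, n_frequent = 1, srate = 150,
                      n_channels = 1, background = list(alpha = 1, rms = 0),
                      seed = seed)
    rec <- simulate_participant(cfg, 1)
    m <- colMeans(rec$data[rec$labels == "rare", 1, ])
    sqrt(mean(m^2))
  }
  r16 <- mean(sapply(1:12, function(s) avg_rms(16, s)))
  r64 <- mean(sapply(1:12, function(s) avg_rms(64, s)))
  # average amplitude decays ~ n^(-1/2): quadrupling trials halves the RMS
  expect_gt(r16 / r64, 1.5)
  expect_lt(r16 / r64, 2.7)
})

test_that("bimodal phase reset cancels the average but not single-trial amplitude", {
  src_r <- source_spec("ongoing_oscillation", amplitude = 2, topography = 1,
                       center_freq = 6, phase_mode = "reset_bimodal")
  src_f <- source_spec("ongoing_oscillation", amplitude = 2, topography = 1,
                       center_freq = 6, phase_mode = "free")
  cfg <- sim_config(1, list(list(rare = src_r, frequent = src_f)),
                    n_rare = 200, n_frequent = 200, srate = 150,
                    n_channels = 1, background = list(alpha = 1, rms = 0),
                    seed = 9)
  rec <- simulate_participant(cfg, 1)
  t_ms <- rec_times(rec)
  post <- t_ms > 500 & t_ms < 1800
  avg <- colMeans(rec$data[rec$labels == "rare", 1, ])
  expect_lt(sqrt(mean(avg[post]^2)), 0.15)  # ~2/sqrt(2*200) plus slack
  # every trial keeps full oscillation amplitude after the reset ramp
  trial_rms <- apply(rec$data[, 1, post], 1, function(x) sqrt(mean(x^2)))
  expect_true(all(abs(trial_rms - 2 / sqrt(2)) < 0.05))
  # and the per-trial envelope is identical across conditions
  expect_lt(max(abs(tapply(trial_rms, rec$labels, mean) -
                    2 / sqrt(2))), 0.01)
})

test_that("post-stimulus gain scales the oscillation envelope after the ramp", {
  src <- source_spec("ongoing_oscillation", amplitude = 2, topography = 1,
                     center_freq = 10, post_stimulus_gain = 0.5)
  cfg <- quiet_cfg(list(list(rare = src, frequent = src)), rms = 0)
  rec <- simulate_participant(cfg, 1)
  t_ms <- rec_times(rec)
  pre <- t_ms < -100
  post <- t_ms > 400
  rms_pre <- sqrt(mean(rec$data[1, 1, pre]^2))
  rms_post <- sqrt(mean(rec$data[1, 1, post]^2))
  expect_equal(rms_post / rms_pre, 0.5, tolerance = 0.02)
})

test_that("the 1/f background hits its RMS target", {
  cfg <- sim_config(1, list(), n_rare = 40, n_frequent = 40, srate = 150,
                    n_channels = 2, background = list(alpha = 1, rms = 8),
                    seed = 2)
  rec <- simulate_participant(cfg, 1)
  expect_equal(sqrt(mean(rec$data^2)), 8, tolerance = 0.05)
})

test_that("scenario construction validates names and plants the right effects", {
  expect_error(make_scenario("nope"), "valid names")
  # erp_only: rare-minus-frequent ERP near the configured amplitude delta
  cfg <- make_scenario("erp_only", n_participants = 1, n_channels = 8,
                       n_rare = 200, n_frequent = 200, seed = 13)
  rec <- simulate_participant(cfg, 1)
  erp_r <- compute_erp(rec, which(rec$labels == "rare"))$tensor
  erp_f <- compute_erp(rec, which(rec$labels == "frequent"))$tensor
  diff <- erp_r - erp_f
  t_ms <- rec_times(rec)
  peak_ch <- which.max(apply(abs(diff), 1, max))
  peak_val <- diff[peak_ch, which.min(abs(t_ms - 350))]
  # configured delta 4 uV at the transient's peak channel (gain ~0.96),
  # Monte-Carlo tolerance from 8 uV background over 200 trials/condition
  expect_gt(peak_val, 2.3)
  expect_lt(peak_val, 5.5)
  # null scenario: rare and frequent sources identical
  cfg0 <- make_scenario("null", n_participants = 1, n_channels = 4)
  for (pair in cfg0$sources) expect_identical(pair$rare, pair$frequent)
})
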