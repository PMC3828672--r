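test_that("spike-train generator honors rate, refractoriness and determinism", {
  expect_length(generate_spike_train(rep(0, 1000), 100, seed = 1), 0L)
  # homogeneous 20 Hz over 100 s: Poisson mean 2000, check within 3 sigma
  counts <- vapply(1:5, function(s) {
    length(generate_spike_train(rep(20, 1e5), 1000, refractory_s = 0, seed = s))
  }, numeric(1))
  expect_true(all(abs(counts - 2000) < 3 * sqrt(2000)))
  # refractory ceiling: 1000 Hz with 2 ms dead time cannot exceed 500 Hz
  st <- generate_spike_train(rep(1000, 1e4), 1000, refractory_s = 0.002,
                             seed = 2)
  expect_lte(length(st) / 10, 500)
  expect_gte(min(diff(st)), 0.002)
  expect_error(generate_spike_train(c(1, -1), 100), "negative rate")
  expect_identical(generate_spike_train(rep(10, 1e4), 1000, seed = 7),
                   generate_spike_train(rep(10, 1e4), 1000, seed = 7))
})

test_that("rendering superposes templates linearly at the right samples", {
  fs <- 24414
  tmpl <- spike_template(fs, 50e-6)
  y <- render_signal(1.0, tmpl, 2, fs)
  expect_equal(min(y), -50e-6)
  expect_equal(which.min(y),
               as.integer(round(1.0 * fs)) + 1L +
                 as.integer(round(attr(tmpl, "peak_offset_s") * fs)))
  expect_identical(render_signal(numeric(0), tmpl, 1, fs), numeric(fs))
  # two spikes 0.2 ms apart add pointwise
  y2 <- render_signal(c(0.5, 0.5002), tmpl, 1, fs)
  y2a <- render_signal(0.5, tmpl, 1, fs)
  y2b <- render_signal(0.5002, tmpl, 1, fs)
  expect_equal(y2, y2a + y2b)
  expect_error(render_signal(1.5, tmpl, 1, fs), "outside")
})

test_that("noise generator matches the requested sigma and burst structure", {
  x <- sin(seq_len(1e5) / 50)
  expect_identical(add_noise(x, "white", 0, seed = 3), x)
  y <- add_noise(x, "white", 5e-6, seed = 3)
  expect_equal(sd(y - x), 5e-6, tolerance = 0.02)
  # pink model keeps overall scale near sigma
  yp <- add_noise(x, "white+pink", 5e-6, seed = 4)
  expect_equal(sd(yp - x), 5e-6, tolerance = 0.15)
  # burst epochs are audibly louder than baseline
  yb <- add_noise(numeric(24414 * 20), "white+artifact_bursts", 1,
                  seed = 5, fs = 24414)
  ep <- attr(yb, "burst_epochs")
  expect_gt(nrow(ep), 0)
  in_burst <- rep(FALSE, length(yb))
  for (b in seq_len(nrow(ep)))
    in_burst[(floor(ep$t0[b] * 24414) + 1):ceiling(ep$t1[b] * 24414)] <- TRUE
  expect_gt(sd(yb[in_burst]), 2 * sd(yb[!in_burst]))
})

test_that("behavior generator produces the three-hit trial protocol", {
  cfg <- session_config(n_trials = 10, failure_fraction = 0, seed = 6)
  ev <- generate_behavior(cfg)
  expect_identical(sum(ev$event_type == "hit"), 30L)
  expect_identical(length(unique(ev$trial_id[ev$event_type == "hit"])), 10L)
  expect_true(all(ev$accepted_flag))
  # >= 9 s between the last hit of a trial and the first of the next
  last_hits <- tapply(ev$time_s[ev$event_type == "hit"],
                      ev$trial_id[ev$event_type == "hit"], max)
  first_hits <- tapply(ev$time_s[ev$event_type == "hit"],
                       ev$trial_id[ev$event_type == "hit"], min)
  expect_true(all(first_hits[-1] - last_hits[-10] >= 9))
  validate_events(ev)
  # infeasible duration is rejected
  cfg2 <- session_config(n_trials = 10, seed = 6)
  cfg2$duration_s <- 30
  expect_error(generate_behavior(cfg2), "does not fit")
  # failures are flagged with a reason
  cfg3 <- session_config(n_trials = 40, failure_fraction = 0.5, seed = 7)
  ev3 <- generate_behavior(cfg3)
  expect_gt(sum(!ev3$accepted_flag), 0)
  expect_true(all(ev3$failure_reason[!ev3$accepted_flag] %in%
                    c("non_preferred_limb", "premature_hit")))
})

test_that("sessions are reproducible and consistent with ground truth", {
  s <- cached_session()
  cfg <- session_config(n_trials = 6, n_channels = 2,
                        channel_categories = c("paw", "paw"),
                        baseline_rate_hz = 20, hit_modulation = 3,
                        spike_amp_v = 80e-6, noise_sigma = 10e-6,
                        noise_model = "white", seed = 42)
  s2 <- generate_session(cfg)
  expect_identical(s$session$signals, s2$session$signals)
  expect_identical(s$events, s2$events)
  expect_identical(s$truth$spike_times, s2$truth$spike_times)
  # every channel equally long; spike times sorted with >= 1 ms gaps
  expect_length(unique(lengths(s$session$signals)), 1L)
  for (st in s$truth$spike_times) {
    expect_true(!is.unsorted(st))
    expect_gte(min(diff(st)), 0.001)
  }
})

test_that("pre-hit rate elevation matches the configured modulation", {
  cfg <- session_config(n_trials = 25, n_channels = 1,
                        channel_categories = "paw",
                        baseline_rate_hz = 10, hit_modulation = 3,
                        premovement_onset_ms = -360,
                        noise_sigma = 0.1e-6, noise_model = "white",
                        failure_fraction = 0, short_pair_fraction = 0,
                        seed = 8)
  s <- generate_session(cfg)
  # first hits only: the pre-hit windows of later hits in a trial can
  # overlap the elevation of the preceding hit
  hits <- as.numeric(tapply(s$events$time_s[s$events$event_type == "hit"],
                            s$events$trial_id[s$events$event_type == "hit"],
                            min))
  st <- s$truth$spike_times[[1]]
  pre <- vapply(hits, function(h) sum(st >= h - 0.36 & st < h), numeric(1))
  base <- vapply(hits, function(h) sum(st >= h - 0.86 & st < h - 0.5),
                 numeric(1))
  # expectation: 30 Hz x 0.36 s = 10.8 and 10 Hz x 0.36 s = 3.6
  expect_equal(mean(pre), 10.8, tolerance = 0.15)
  expect_equal(mean(base), 3.6, tolerance = 0.25)
  # with the default -300 ms onset the pre-hit window mixes baseline:
  # 10 x 0.06 + 30 x 0.30 = 9.6 expected
  cfg2 <- session_config(n_trials = 25, n_channels = 1,
                         channel_categories = "paw",
                         baseline_rate_hz = 10, hit_modulation = 3,
                         noise_sigma = 0.1e-6, noise_model = "white",
                         failure_fraction = 0, short_pair_fraction = 0,
                         seed = 9)
  s2 <- generate_session(cfg2)
  hits2 <- as.numeric(tapply(s2$events$time_s[s2$events$event_type == "hit"],
                             s2$events$trial_id[s2$events$event_type == "hit"],
                             min))
  st2 <- s2$truth$spike_times[[1]]
  pre2 <- vapply(hits2, function(h) sum(st2 >= h - 0.36 & st2 < h),
                 numeric(1))
  expect_equal(mean(pre2), 9.6, tolerance = 0.15)
})

test_that("null configuration leaves hit and baseline counts indistinguishable", {
  cfg <- session_config(n_trials = 30, n_channels = 1,
                        channel_categories = "paw", baseline_rate_hz = 20,
                        hit_modulation = 1, nohit_background_gain = 1,
                        noise_sigma = 0.1e-6, noise_model = "white",
                        failure_fraction = 0, seed = 10)
  s <- generate_session(cfg)
  hits <- s$events$time_s[s$events$event_type == "hit"]
  st <- s$truth$spike_times[[1]]
  pre <- vapply(hits, function(h) sum(st >= h - 0.36 & st < h), numeric(1))
  base <- vapply(hits, function(h) sum(st >= h - 0.86 & st < h - 0.5),
                 numeric(1))
  expect_gt(t.test(pre, base)$p.value, 0.01)
})
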