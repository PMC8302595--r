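test_that("generators are deterministic under a fixed seed", {
  p <- ecog_params(seed = 11)
  a <- make_ecog(p); b <- make_ecog(p)
  expect_identical(a$ts$values, b$ts$values)
  expect_identical(a$truth$peak_times, b$truth$peak_times)

  ca <- calcium_params(n_cells = 5, seed = 12)
  x <- make_calcium(a$truth, ca, 60)
  y <- make_calcium(a$truth, ca, 60)
  expect_identical(x$traces$values, y$traces$values)

  s1 <- make_spiketrains(1, 5, seed = 13)
  s2 <- make_spiketrains(1, 5, seed = 13)
  expect_identical(s1, s2)
})

test_that("truth peaks lie inside the declared EA window", {
  for (s in 1:10) {
    e <- make_ecog(ecog_params(duration = 60, stim_onset = 10,
                               ea_delay = 3.4, ea_duration = 23, seed = s))
    expect_equal(e$truth$ea_onset, 13.4)
    expect_equal(e$truth$ea_offset, 36.4)
    expect_true(all(e$truth$peak_times >= e$truth$ea_onset))
    expect_true(all(e$truth$peak_times < e$truth$ea_offset))
  }
})

test_that("EA peak counts match the Poisson moment oracle", {
  ## rate 5 Hz over a 20 s EA: mean 100, SE of the mean sqrt(100/200)
  counts <- vapply(1:200, function(s)
    length(make_ecog(ecog_params(ea_duration = 20, peak_rate = 5,
                                 seed = s))$truth$peak_times), 0)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))
})

test_that("zero peak amplitude leaves the baseline statistics untouched", {
  e <- make_ecog(ecog_params(peak_amplitude = 0, baseline_sd = 1, seed = 4))
  expect_gt(length(e$truth$peak_times), 0)     # truth list still returned
  expect_equal(sd(e$ts$values), 1, tolerance = 1e-6)
  ## EA segment indistinguishable from baseline in amplitude
  ea <- segment(e$ts, e$truth$ea_onset, e$truth$ea_offset)
  expect_lt(max(abs(ea$values)) / sd(e$ts$values), 6)
})

test_that("a noiseless single event reproduces the transient kernel exactly", {
  truth <- structure(list(ea_onset = 9, ea_offset = 11, peak_times = 10,
                          stim_onset = 8), class = "synth_ground_truth")
  p <- calcium_params(n_cells = 1, coupled_fraction = 1, coupling_prob = 1,
                      jitter_sd = 0, baseline_event_rate = 0, noise_sd = 0,
                      event_amplitude = 2, seed = 1)
  ca <- make_calcium(truth, p, 30)
  tt <- (0:(30 * 20 - 1)) / 20
  expect_equal(ca$traces$values[1, ], 2 * oracle_kernel(tt - 10),
               tolerance = 1e-12)
  expect_identical(ca$truth$true_event_times[[1]], 10)
})

test_that("coupling retention matches the binomial moment oracle", {
  set.seed(20)
  truth <- structure(list(ea_onset = 10, ea_offset = 35,
                          peak_times = sort(runif(50, 10, 35)),
                          stim_onset = 8), class = "synth_ground_truth")
  p <- calcium_params(n_cells = 500, coupled_fraction = 1,
                      coupling_prob = 0.9, jitter_sd = 0.02,
                      baseline_event_rate = 0, noise_sd = 0, seed = 21)
  ca <- make_calcium(truth, p, 60)
  kept <- vapply(ca$truth$true_event_times, length, 0)
  se <- sqrt(50 * 0.9 * 0.1 / 500)
  expect_lt(abs(mean(kept) - 45), 3 * se)
  expect_true(all(ca$truth$coupled_flags))
})

test_that("uncoupled cells carry no coupled flags", {
  truth <- structure(list(ea_onset = 10, ea_offset = 20,
                          peak_times = c(11, 12), stim_onset = 8),
                     class = "synth_ground_truth")
  ca <- make_calcium(truth, calcium_params(n_cells = 4, coupled_fraction = 0,
                                           seed = 2), 30)
  expect_false(any(ca$truth$coupled_flags))
})

test_that("spike trains follow the pre/post Poisson rates", {
  trains <- make_spiketrains(1, 5, stim_onset = 12, n_trials = 1000,
                             trial_length = 24, seed = 31)
  pre <- vapply(trains, function(s) sum(s < 12), 0)
  post <- vapply(trains, function(s) sum(s >= 12), 0)
  expect_lt(abs(mean(pre) - 12), 3 * sqrt(12 / 1000))
  expect_lt(abs(mean(post) - 60), 3 * sqrt(60 / 1000))
  expect_error(make_spiketrains(-1, 5), "rates")
})

test_that("theta-band power of the EA segment exceeds the baseline's", {
  e <- make_ecog(ecog_params(seed = 7))            # 5 Hz peaks, amp 10 SD
  span <- window_layout(window_spec(), 400)$total_duration
  ea <- segment(e$ts, e$truth$ea_onset, e$truth$ea_onset + span + 0.01)
  base <- segment(e$ts, 0, span + 0.01)
  bp <- normalized_band_power(ea, base)
  expect_gt(bp$normalized_power[bp$name == "theta"], 1)
})
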