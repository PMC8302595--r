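test_that("window layouts reproduce the analysis epoch durations", {
  expect_equal(window_layout(window_spec(10, 512, 0.5), 400)$total_duration,
               7.04)
  expect_equal(window_layout(window_spec(1, 512, 0.5), 400)$total_duration,
               1.28)
  expect_equal(window_layout(window_spec(4, 256, 0.5), 256)$total_duration,
               2.5)
})

test_that("band power is zero for silence and concentrates a 6 Hz tone in theta", {
  n <- 512 + 9 * 256
  expect_true(all(band_power(time_series(rep(0, n), fs = 400))$absolute_power
                  == 0))

  tt <- (0:(n - 1)) / 400
  ts <- time_series(sin(2 * pi * 6 * tt), fs = 400)
  bands <- rbind(default_bands(), band_def("total", 0, 200))
  bp <- band_power(ts, bands)
  tot <- bp$absolute_power[bp$name == "total"]
  expect_gte(bp$absolute_power[bp$name == "theta"] / tot, 0.99)
  expect_lte(bp$absolute_power[bp$name == "alpha"] / tot, 0.005)
  expect_lte(bp$absolute_power[bp$name == "beta"] / tot, 0.005)
})

test_that("white-noise band powers are proportional to bandwidth", {
  n <- 512 + 9 * 256
  ratios <- vapply(1:200, function(s) {
    set.seed(s)
    bp <- band_power(time_series(rnorm(n), fs = 400))
    bp$absolute_power[1] / bp$absolute_power[3]       # theta : beta
  }, 0)
  expect_lt(abs(mean(ratios) - 4 / 17) / (4 / 17), 0.05)
})

test_that("periodogram bins partition the tapered mean square (Parseval)", {
  ## odd window length: no Nyquist bin, so [0, fs/2) holds every bin
  set.seed(5)
  spec <- window_spec(1, 511, 0)
  w <- 0.42 - 0.5 * cos(2 * pi * (0:510) / 510) +
    0.08 * cos(4 * pi * (0:510) / 510)
  for (i in 1:5) {
    x <- rnorm(511)
    bp <- band_power(time_series(x, fs = 400),
                     rbind(band_def("all", 0, 200)), spec)
    xm <- (x - mean(x)) * w
    expect_equal(bp$absolute_power, sum(xm^2) / sum(w^2), tolerance = 1e-6)
  }
})

test_that("band powers add over a partition and ignore constant offsets", {
  set.seed(6)
  n <- 512 + 9 * 256
  x <- rnorm(n)
  bands <- rbind(default_bands(), band_def("union", 4, 30))
  bp <- band_power(time_series(x, fs = 400), bands)
  expect_equal(sum(bp$absolute_power[1:3]), bp$absolute_power[4],
               tolerance = 1e-12)
  bp2 <- band_power(time_series(x + 7.3, fs = 400), bands)
  expect_equal(bp2$absolute_power, bp$absolute_power, tolerance = 1e-12)
})

test_that("normalized band power is a plain ratio with guarded baseline", {
  set.seed(7)
  n <- 512 + 9 * 256
  x <- rnorm(n)
  ts <- time_series(x, fs = 400)
  r <- normalized_band_power(ts, ts)
  expect_equal(r$normalized_power, rep(1, 3), tolerance = 1e-12)

  r2 <- normalized_band_power(time_series(2 * x, fs = 400), ts)
  expect_equal(r2$normalized_power, rep(4, 3), tolerance = 1e-12)

  expect_error(normalized_band_power(ts, time_series(rep(0, n), fs = 400)),
               "baseline")
  expect_error(band_power(ts, rbind(band_def("hf", 100, 300))), "Nyquist")
})

test_that("Morlet power is flat on a stationary tone and scales as amplitude^2", {
  expect_true(all(morlet_power(time_series(rep(0, 4000), fs = 400))$power
                  == 0))

  tt <- (0:(30 * 400 - 1)) / 400
  wp <- morlet_power(time_series(sin(2 * pi * 4 * tt), fs = 400))
  interior <- wp$power[!wp$edge & tt > 5 & tt < 25]
  expect_lt((max(interior) - min(interior)) / mean(interior), 0.01)

  wp3 <- morlet_power(time_series(3 * sin(2 * pi * 4 * tt), fs = 400))
  expect_equal(wp3$power, 9 * wp$power, tolerance = 1e-9)
})

test_that("Morlet power localizes a theta burst in noise", {
  set.seed(8)
  tt <- (0:(30 * 400 - 1)) / 400
  burst <- exp(-(tt - 15)^2 / 2) * sin(2 * pi * 4 * (tt - 15))
  x <- burst + rnorm(length(tt), 0, 0.03)           # SNR >> 10
  wp <- morlet_power(time_series(x, fs = 400))
  sm <- stats::filter(wp$power, rep(1 / 201, 201), sides = 2)
  expect_lt(abs(tt[which.max(sm)] - 15), 0.25)
})

test_that("mean power in an interval averages the selected samples", {
  wp <- structure(list(times = (0:99) / 10, power = rep(3, 100),
                       edge = rep(FALSE, 100), fc = 4, fb = 0.5, fs = 10),
                  class = "wavelet_power")
  expect_equal(mean_power_in_interval(wp, 2, 6), 3)

  wp$power <- c(rep(0, 50), rep(2, 50))             # 2 on exactly half
  expect_equal(mean_power_in_interval(wp, 0, 10), 1)
  expect_error(mean_power_in_interval(wp, 20, 30), "no power samples")
})
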