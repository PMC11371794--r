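make_raw <- function(data, rate = 1000, onsets = integer(0),
                     labels = integer(0)) {
  raw_recording(data, rate,
                event_table(onsets, labels, rep(0L, length(onsets))))
}

test_that("downsampling decimates samples and rescales onsets", {
  set.seed(2)
  raw <- make_raw(matrix(rnorm(2 * 4000), 2), 1000, c(100, 1001), c(0L, 1L))
  ds <- downsample(raw, 250)
  expect_equal(ds$sample_rate, 250)
  expect_equal(ncol(ds$data), 1000)
  expect_identical(ds$events$onset_sample, c(25L, 250L))
  expect_identical(downsample(raw, 1000), raw)
  expect_error(downsample(raw, 300), "non-integer")
})

test_that("downsampling preserves an in-band tone's frequency", {
  t <- seq(0, 4, by = 1 / 1000)[-1]
  raw <- make_raw(matrix(sin(2 * pi * 5 * t), 1), 1000)
  ds <- downsample(raw, 250)
  spec <- Mod(fft(ds$data[1, ]))[1:500]
  peak_hz <- (which.max(spec[-1])) * 250 / ncol(ds$data)
  expect_lt(abs(peak_hz - 5), 250 / ncol(ds$data) + 1e-9)
  # amplitude essentially untouched far below the anti-alias edge
  expect_equal(max(abs(ds$data)), 1, tolerance = 0.02)
})

test_that("segmentation windows are half-open slices of the raw data", {
  set.seed(3)
  raw <- make_raw(matrix(rnorm(3 * 1000), 3), 250, c(100, 400, 700),
                  c(0L, 1L, 0L))
  ep <- segment(raw, -200, 1000)
  expect_equal(dim(ep$data), c(3, 3, 300))
  expect_identical(ep$labels, c(0L, 1L, 0L))
  # epoch content equals the corresponding raw slice (0-based onset)
  expect_identical(ep$data[2, , ], raw$data[, (400 - 50) + 1:300])
  expect_equal(dim(segment(make_raw(matrix(0, 2, 100), 250))$data)[1], 0)
  expect_error(segment(raw, -500, 2000), "exceed data bounds")
})

test_that("band-pass attenuates stop-band, passes band, kills DC", {
  rate <- 250
  n <- 300
  tt <- (0:(n - 1)) / rate
  mk <- function(x) epoched_recording(
    array(rep(x, each = 2), c(1, 2, n)), 1L, rate, c(0, n / rate * 1000))
  hi <- bandpass(mk(sin(2 * pi * 50 * tt)), 2, 30)
  mid <- bandpass(mk(sin(2 * pi * 10 * tt)), 2, 30)
  dc <- bandpass(mk(rep(1, n)), 2, 30)
  # steady-state response measured on the central half of the epoch, away
  # from the edge transients of the 2 Hz high-pass
  centre <- (n %/% 4):(3 * n %/% 4)
  rms <- function(e) sqrt(mean(e$data[, , centre]^2))
  expect_lt(rms(hi) / sqrt(0.5), 0.05)
  expect_equal(rms(mid) / sqrt(0.5), 1, tolerance = 0.05)
  expect_lt(rms(dc), 0.02)
  expect_error(bandpass(mk(tt), 30, 2), "invalid band")
  expect_error(bandpass(mk(tt), 2, 200), "invalid band")
})

test_that("filtering is zero-phase: a symmetric pulse stays symmetric", {
  rate <- 250
  n <- 301
  pulse <- exp(-((0:(n - 1)) - 150)^2 / (2 * 15^2))
  ep <- epoched_recording(array(pulse, c(1, 1, n)), 1L, rate,
                          c(0, n / rate * 1000))
  out <- bandpass(ep, 2, 30)$data[1, 1, ]
  asym <- max(abs(out - rev(out))) / max(abs(out))
  expect_lt(asym, 1e-6)
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  set.seed(4)
  ep <- make_epochs(5, 4, 30)
  car <- rereference_car(ep)
  expect_lt(max(abs(apply(car$data, c(1, 3), mean))), 1e-10)
  expect_equal(rereference_car(car)$data, car$data, tolerance = 1e-12)
  # closed form for 2 channels
  two <- make_epochs(2, 2, 10, seed = 9)
  ref <- rereference_car(two)
  expect_all_equal(ref$data[, 1, ], (two$data[, 1, ] - two$data[, 2, ]) / 2)
  # constant offset on all channels vanishes
  const <- epoched_recording(array(7, c(2, 3, 10)), c(0L, 1L), 20,
                             c(0, 500))
  expect_all_equal(rereference_car(const)$data, 0)
  one <- make_epochs(2, 1, 10)
  expect_error(rereference_car(one), "2 channels")
})

test_that("cropping selects the contiguous sub-window", {
  set.seed(5)
  raw <- make_raw(matrix(rnorm(2 * 2000), 2), 250, c(300, 900), c(1L, 0L))
  ep <- segment(raw, -200, 1000)
  cr <- crop_window(ep, 0, 500)
  expect_equal(dim(cr$data)[3], 125)
  expect_equal(cr$window_ms, c(0, 500))
  expect_identical(cr$data[1, , ], ep$data[1, , 50 + 1:125])
  expect_identical(crop_window(ep, -200, 1000), ep)
  expect_error(crop_window(ep, -400, 500), "outside")
})

test_that("the composed chain matches its stages applied one by one", {
  set.seed(6)
  n <- 8000
  raw <- make_raw(matrix(rnorm(3 * n), 3), 1000, c(1000, 3000, 5000),
                  c(0L, 1L, 0L))
  chain <- preprocess_block(raw)
  manual <- rereference_car(bandpass(segment(downsample(raw, 250),
                                             -200, 1000), 2, 30))
  expect_equal(chain, manual, tolerance = 1e-12)
  expect_equal(dim(chain$data), c(3, 3, 300))
})
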