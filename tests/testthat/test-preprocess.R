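test_that("the notch removes a 50 Hz sinusoid almost completely", {
  srate <- 256
  t <- seq(0, 4, by = 1 / srate)
  x <- matrix(sin(2 * pi * 50 * t), nrow = 1)
  spec <- filter_spec(band_pass_hz = NULL, final_lowpass_hz = NULL)
  y <- apply_filters(x, spec, srate_hz = srate)
  interior <- 200:(length(t) - 200)          # avoid filter edge transients
  expect_lt(max(abs(y[1, interior])), 0.05)
})

test_that("the 30 Hz low-pass attenuates supra-35 Hz power by >= 20 dB", {
  srate <- 256
  set.seed(1)
  x <- matrix(rnorm(8192), nrow = 1)
  spec <- filter_spec(band_pass_hz = NULL, notch_hz = NULL)
  y <- apply_filters(x, spec, srate_hz = srate)
  band_power <- function(v) {
    n <- length(v)
    f <- (seq_len(n) - 1) * srate / n
    p <- abs(fft(v))^2
    sum(p[f >= 35 & f <= srate / 2])
  }
  ratio <- band_power(y[1, ]) / band_power(x[1, ])
  expect_lt(10 * log10(ratio), -20)
})

test_that("filtering is linear and shape-preserving", {
  x <- matrix(0, nrow = 3, ncol = 500)
  y <- apply_filters(x, filter_spec(), srate_hz = 256)
  expect_equal(dim(y), dim(x))
  expect_true(all(y == 0))
  ep <- tiny_epochs(fill = function(tr, ch, t) sin(2 * pi * 10 * t / 1000))
  out <- apply_filters(ep, filter_spec(band_pass_hz = NULL, notch_hz = NULL))
  expect_s3_class(out, "epoch_set")
  expect_equal(dim(out), dim(ep))
})

test_that("cutoffs at or above Nyquist are rejected", {
  x <- matrix(rnorm(100), nrow = 1)
  expect_error(apply_filters(x, filter_spec(), srate_hz = 100), "Nyquist")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  tt <- quick_task(81, n_per_cond = 2)
  sim <- simulate_eeg(tt, eeg_gen_config(channels = ch16(), srate_hz = 128),
                      seed = 5)
  ref <- average_reference(sim$epochs)
  expect_equal(ref$reference_state, "average")
  means <- apply(ref$data, c(1, 3), mean)
  expect_lt(max(abs(means)), 1e-10)
  expect_warning(ref2 <- average_reference(ref), "already")
  expect_equal(ref2$data, ref$data)
  # a single-channel montage is annihilated by definition
  one <- tiny_epochs(channels = "Cz", fill = function(tr, ch, t) 3.3)
  expect_true(all(average_reference(one)$data == 0))
})

test_that("filtering and average reference commute", {
  tt <- quick_task(91, n_per_cond = 2)
  sim <- simulate_eeg(tt, eeg_gen_config(channels = ch16()[1:6],
                                         srate_hz = 128), seed = 6)
  spec <- filter_spec(band_pass_hz = NULL, notch_hz = NULL,
                      final_lowpass_hz = 30)
  a <- average_reference(apply_filters(sim$epochs, spec))
  b <- suppressWarnings(apply_filters(average_reference(sim$epochs), spec))
  expect_equal(a$data, b$data, tolerance = 1e-8)
})

test_that("epoching extracts the right grid and baseline-corrects", {
  srate <- 256
  cont <- matrix(7.5, nrow = 2, ncol = 5000)   # constant channels
  ep <- epoch_and_baseline(cont, events = c(1000, 2000, 3000), srate,
                           channels = c("Pz", "Cz"))
  expect_equal(dim(ep), c(3, 2, 641))          # (2500/1000)*256 + 1 samples
  expect_true(all(abs(ep$data) < 1e-12))       # constant minus its baseline
  # events too close to the record edge are dropped, not fatal
  expect_message(
    ep2 <- epoch_and_baseline(cont, events = c(50, 2000, 4900), srate,
                              channels = c("Pz", "Cz")),
    "dropped")
  expect_equal(dim(ep2)[1], 1)
})

test_that("epoching preserves the extracted segment exactly", {
  srate <- 128
  set.seed(2)
  cont <- matrix(rnorm(2 * 2000), nrow = 2)
  ev <- 700
  ep <- epoch_and_baseline(cont, ev, srate, c("a", "b"), baseline_ms = NULL)
  offs <- seq(round(-500 / (1000 / srate)), round(2000 / (1000 / srate)))
  expect_equal(ep$data[1, , ], cont[, ev + offs])
})

test_that("amplitude rejection drops exactly the offending epochs", {
  ep <- tiny_epochs(n_trials = 5,
                    fill = function(tr, ch, t) if (tr == 3) 250 else 1)
  trials <- tibble::tibble(trial_index = 1:5)
  out <- reject_epochs(ep, trials, threshold_uv = 100)
  expect_equal(out$rejected, 3)
  expect_equal(dim(out$epochs)[1], 4)
  expect_equal(out$trials$trial_index, c(1, 2, 4, 5))
})
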