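make_rec <- function(x, srate = 250, events = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1, dimnames = list("Cz", NULL))
  new_recording(x, srate, events = events)
}

sine_rec <- function(freq, secs = 20, srate = 250, amp = 1) {
  t <- seq(0, secs, by = 1 / srate)
  make_rec(amp * sin(2 * pi * freq * t), srate)
}

mid_amp <- function(rec) {
  n <- ncol(rec$data)
  max(abs(rec$data[1, round(n * 0.3):round(n * 0.7)]))
}

test_that("band definitions are the seven canonical bands", {
  b <- band_specs()
  expect_equal(b$band, c("delta", "theta", "alpha", "beta1", "beta2",
                         "gamma1", "gamma2"))
  expect_equal(b$low_hz, c(1.5, 4, 8, 13, 20, 30, 52))
  expect_equal(b$high_hz, c(4, 8, 13, 20, 30, 48, 70))
  expect_error(band_specs("omega"), "unknown")
})

test_that("bandpass passes in-band and attenuates out-of-band tones", {
  # 6 Hz tone through theta: amplitude preserved within 5%
  out <- bandpass(sine_rec(6), "theta")
  expect_equal(mid_amp(out), 1, tolerance = 0.05)
  # 25 Hz tone through theta: attenuated by >= 20 dB
  out25 <- bandpass(sine_rec(25), "theta")
  expect_lt(20 * log10(mid_amp(out25)), -20)
  # DC input: residual below 1% of input level
  dc <- make_rec(rep(5, 5000))
  for (bd in c("delta", "gamma2")) {
    expect_lt(mean(abs(bandpass(dc, bd)$data)), 0.05)
  }
  # band above Nyquist errors
  expect_error(bandpass(make_rec(rnorm(1000), srate = 100), "gamma2"),
               "Nyquist")
  # output length preserved
  expect_equal(ncol(out$data), ncol(sine_rec(6)$data))
})

test_that("bandpass is approximately idempotent in the passband", {
  once <- bandpass(sine_rec(6), "theta")
  twice <- bandpass(once, "theta")
  expect_equal(mid_amp(twice) / mid_amp(once), 1, tolerance = 0.01)
})

test_that("50 Hz notch removes mains but spares neighbors", {
  out50 <- notch_50hz(sine_rec(50))
  # residual RMS <= 10% of input RMS
  n <- ncol(out50$data)
  mid <- round(n * 0.3):round(n * 0.7)
  expect_lt(sqrt(mean(out50$data[1, mid]^2)) / sqrt(0.5), 0.10)
  # 45/55 Hz attenuated by less than 3 dB; 10 Hz within 5%
  for (f in c(45, 55)) {
    expect_gt(20 * log10(mid_amp(notch_50hz(sine_rec(f)))), -3)
  }
  expect_equal(mid_amp(notch_50hz(sine_rec(10))), 1, tolerance = 0.05)
  # zero in, zero out
  z <- notch_50hz(make_rec(rep(0, 1000)))
  expect_equal(max(abs(z$data)), 0)
  expect_error(notch_50hz(make_rec(rnorm(500), srate = 100)), "100 Hz")
})

test_that("epoching cuts exact stimulus-locked windows", {
  ev <- tibble::tibble(onset_sample = c(1000L, 2000L))
  rec <- make_rec(seq_len(3000), events = ev)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(2, 1, 200))           # 0.8 s x 250 Hz
  expect_equal(as.numeric(ep$data[1, 1, ]), 1000:1199)
  expect_equal(as.numeric(ep$data[2, 1, ]), 2000:2199)
})

test_that("epoching drops and logs events too close to the end", {
  ev <- tibble::tibble(onset_sample = c(100L, 2951L))  # 50 samples from end
  rec <- make_rec(seq_len(3000), events = ev)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(nrow(ep$dropped), 1)
  expect_match(ep$dropped$reason, "exceeds")
  # conservation: retained + rejected + dropped = events
  expect_equal(nrow(ep$metadata) + nrow(ep$dropped), nrow(ev))
})

test_that("zero events yield an empty epoch set, empty recording errors", {
  rec <- make_rec(seq_len(1000))
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data)[1], 0)
  empty <- make_rec(matrix(numeric(0), 1, 0, dimnames = list("Cz", NULL)))
  expect_error(epoch_recording(empty), "empty")
})

test_that("amplitude rejection flags strictly above threshold only", {
  ev <- tibble::tibble(onset_sample = c(1L, 301L, 601L))
  x <- rep(0, 1000)
  x[50] <- 250          # trial 1: above
  x[350] <- 200         # trial 2: exactly at threshold
  x[650] <- -150        # trial 3: within bounds
  rec <- make_rec(x, events = ev)
  ep <- reject_artifacts(epoch_recording(rec))
  expect_equal(ep$metadata$retained, c(FALSE, TRUE, TRUE))
  expect_equal(ep$metadata$rejection_reason[1], "amplitude")
  # flags only; sample data untouched
  expect_equal(unname(ep$data[1, 1, 50]), 250)
  # order independence: re-running changes nothing
  ep2 <- reject_artifacts(ep)
  expect_identical(ep2$metadata, ep$metadata)
})

test_that("SNR follows A / (2 * sd_noise)", {
  set.seed(42)
  template <- 5 * sin(2 * pi * 5 * (0:199) / 250)     # peak-to-peak ~10
  n_tr <- 400
  data <- array(rep(template, each = n_tr), c(n_tr, 1, 200)) +
    array(rnorm(n_tr * 200, 0, 2.5), c(n_tr, 1, 200))
  ep <- structure(list(data = data, srate = 250, epoch_length = 0.8,
                       channels = "Cz",
                       metadata = tibble::tibble(
                         trial = 1:n_tr, onset_sample = 1L,
                         retained = TRUE, rejection_reason = NA_character_),
                       dropped = tibble::tibble()),
                  class = "eeg_epochs")
  snr <- compute_snr(ep)
  expect_equal(snr$snr, (max(template) - min(template)) / (2 * 2.5),
               tolerance = 0.1)
})

test_that("identical trials give infinite SNR with a degenerate flag", {
  data <- array(rep(sin(1:200), each = 4), c(4, 1, 200))
  ep <- structure(list(data = data, srate = 250, epoch_length = 0.8,
                       channels = "Cz",
                       metadata = tibble::tibble(
                         trial = 1:4, onset_sample = 1L,
                         retained = TRUE, rejection_reason = NA_character_),
                       dropped = tibble::tibble()),
                  class = "eeg_epochs")
  snr <- compute_snr(ep)
  expect_true(snr$degenerate)
  expect_equal(snr$snr, Inf)
  ep$metadata$retained[2:4] <- FALSE
  expect_error(compute_snr(ep), "2 retained")
})

test_that("pure-noise SNR decreases monotonically with trial count", {
  set.seed(7)
  snr_at <- function(n) {
    ep <- structure(list(data = array(rnorm(n * 200), c(n, 1, 200)),
                         srate = 250, epoch_length = 0.8, channels = "Cz",
                         metadata = tibble::tibble(
                           trial = seq_len(n), onset_sample = 1L,
                           retained = TRUE,
                           rejection_reason = NA_character_),
                         dropped = tibble::tibble()),
                    class = "eeg_epochs")
    compute_snr(ep)$snr
  }
  vals <- vapply(c(8, 64, 512), snr_at, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("trial selection requires correctness and adequate SNR", {
  ev <- tibble::tibble(onset_sample = c(1L, 301L, 601L))
  rec <- make_rec(sin(seq_len(1000)), events = ev)
  md <- tibble::tibble(correct = c(TRUE, FALSE, TRUE))
  ep <- epoch_recording(rec, metadata = md)
  sel <- select_trials(ep, snr_min = 0)
  expect_equal(sel$metadata$retained, c(TRUE, FALSE, TRUE))
  expect_equal(sel$metadata$rejection_reason[2], "incorrect")
  # snr_min = 0 leaves the SNR criterion vacuous even for noise
  expect_true(any(sel$metadata$retained))
  # an impossible SNR floor excludes everything
  sel2 <- select_trials(ep, snr_min = Inf)
  expect_false(any(sel2$metadata$retained))
})
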