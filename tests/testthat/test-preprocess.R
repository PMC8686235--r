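test_that("downsampling preserves DC and passband content and rejects bad ratios", {
  rec <- probe_recording(fs = 1000, dur = 6, freqs = 1, amps = 0, dc = 7.3)
  out <- downsample(rec)
  expect_equal(out$fs, 200)
  interior <- out$signal[1, 100:(ncol(out$signal) - 100)]
  expect_lt(max(abs(interior - 7.3)), 1e-6)

  rec10 <- probe_recording(fs = 1000, dur = 6, freqs = 10, amps = 1)
  out10 <- downsample(rec10)
  t200 <- (seq_len(ncol(out10$signal)) - 1) / 200
  ref <- sin(2 * pi * 10 * t200)
  interior <- 200:(ncol(out10$signal) - 200)
  expect_lt(max(abs(out10$signal[1, interior] - ref[interior])), 0.01)

  rec450 <- probe_recording(fs = 1000, dur = 6, freqs = 450, amps = 1)
  out450 <- downsample(rec450)
  rms_in <- sqrt(mean(rec450$signal[1, ]^2))
  rms_out <- sqrt(mean(out450$signal[1, interior]^2))
  expect_lt(rms_out, 0.01 * rms_in)

  expect_error(downsample(probe_recording(fs = 500, dur = 1), 200), "integer multiple")
})

test_that("downsampling remaps event indices onto the decimated grid", {
  rec <- probe_recording(fs = 1000, dur = 4, events_at = c(1, 1000, 2501))
  out <- downsample(rec)
  expect_equal(out$events$sample, c(1L, 201L, 501L))  # nearest decimated sample
})

test_that("common average reference zeroes the channel mean exactly and is idempotent", {
  rec <- eeg_recording(matrix(c(1, 3), 2, 10), 200, c("a", "b"))
  out <- rereference_car(rec)
  expect_equal(out$signal[, 1], c(-1, 1))
  withr::with_seed(2, {
    big <- eeg_recording(matrix(rnorm(63 * 1000), 63), 200, paste0("ch", 1:63))
  })
  ref <- rereference_car(big)
  expect_lt(max(abs(colMeans(ref$signal))), 1e-10)
  expect_equal(rereference_car(ref)$signal, ref$signal, tolerance = 1e-12)
  expect_error(rereference_car(eeg_recording(matrix(1, 1, 10), 200, "a")), "2 channels")
})

test_that("band-pass keeps passband amplitude, kills DC and stopband, at zero lag", {
  rec <- probe_recording(fs = 200, dur = 30, freqs = 10, amps = 1)
  out <- bandpass_filter(rec)
  interior <- 1000:(ncol(out$signal) - 1000)
  amp <- max(abs(out$signal[1, interior]))
  expect_gte(amp, 0.98); expect_lte(amp, 1.02)
  # zero phase: cross-correlation with the input peaks at lag 0
  cc <- stats::ccf(out$signal[1, interior], rec$signal[1, interior],
                   lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  dc <- bandpass_filter(probe_recording(fs = 200, dur = 30, freqs = 1, amps = 0, dc = 5))
  expect_lt(max(abs(dc$signal[1, interior])), 0.05)

  hi <- bandpass_filter(probe_recording(fs = 200, dur = 30, freqs = 80, amps = 1))
  expect_lt(max(abs(hi$signal[1, interior])), 0.05)

  expect_error(bandpass_filter(probe_recording(fs = 100, dur = 1)), "Nyquist")
})

test_that("epoching cuts exactly fs samples per 1-s trial and drops edge events", {
  ev <- seq(500, 5500, length.out = 30)
  rec <- probe_recording(fs = 200, dur = 30, events_at = ev)
  ep <- epoch_trials(rec)
  expect_equal(dim(ep$data), c(30, 4, 200))

  rec2 <- probe_recording(fs = 200, dur = 4, events_at = c(50, 400))
  ep2 <- epoch_trials(rec2)
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(attr(ep2, "dropped_events"), 1L)

  rec3 <- probe_recording(fs = 200, dur = 1, events_at = 5)
  expect_error(epoch_trials(rec3), "no usable events")
  expect_error(epoch_trials(probe_recording(fs = 200, dur = 1)), "no events")
})

test_that("the chain is channel-order invariant and logs every stage", {
  sim <- quick_sim()
  rec <- sim$recording
  perm <- withr::with_seed(4, sample.int(nrow(rec$signal)))
  rec_p <- eeg_recording(rec$signal[perm, ], rec$fs, rec$labels[perm], rec$events)
  chain <- function(r) bandpass_filter(rereference_car(downsample(r)))
  a <- chain(rec); b <- chain(rec_p)
  expect_equal(b$signal, a$signal[perm, ], tolerance = 1e-10)

  ep <- preprocess_recording(rec, subject = "S01", hand = "right")
  stages <- vapply(attr(ep, "log"), `[[`, character(1), "stage")
  expect_equal(stages, c("downsample", "car", "bandpass", "artifacts"))
})
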