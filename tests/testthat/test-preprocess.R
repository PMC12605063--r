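make_test_recording <- function(n_ch = 4, dur_s = 12, fs = 500, seed = 7,
                                events = integer(0)) {
  set.seed(seed)
  n <- dur_s * fs
  data <- matrix(stats::rnorm(n_ch * n, sd = 5), n_ch)
  ev <- if (length(events)) {
    data.frame(sample = as.integer(events),
               stimulus_id = sprintf("s%d", seq_along(events)),
               condition = rep("consonant", length(events)))
  } else {
    data.frame(sample = integer(), stimulus_id = character(),
               condition = character())
  }
  eeg_recording(data, fs, paste0("ch", seq_len(n_ch)), ev)
}

test_that("temporal_filter is zero-phase and respects Nyquist", {
  fs <- 500
  t <- seq(0, 12, by = 1 / fs)[-1]
  rec <- eeg_recording(rbind(sin(2 * pi * 50 * t), sin(2 * pi * 10 * t)),
                       fs, c("a", "b"))
  out <- temporal_filter(rec, "band_stop", c(45, 55))
  mid <- seq(1000, length(t) - 1000)
  expect_lt(sqrt(2 * mean(out$data[1, mid]^2)), 0.05)
  expect_gt(sqrt(2 * mean(out$data[2, mid]^2)), 0.95)
  expect_error(temporal_filter(rec, "band_pass", c(1, 300)), "Nyquist")
})

test_that("downsampling halves samples, keeps spectra, and rescales events", {
  rec <- make_test_recording(events = c(501, 2501, 5001)) # 1.0, 5.0, 10.0 s
  out <- downsample(rec, 250)
  expect_equal(out$sfreq, 250)
  expect_lte(abs(ncol(out$data) - ncol(rec$data) / 2), 1)
  # event at 1.000 s stays put within one new sample (4 ms)
  expect_true(all(abs((out$events$sample - 1) / 250 -
                        (rec$events$sample - 1) / 500) <= 0.004))
  # a 10 Hz tone still peaks at 10 Hz
  fs <- 500
  t <- seq(1 / fs, 20, by = 1 / fs)
  tone <- eeg_recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)),
                        fs, c("a", "b"))
  ds <- downsample(tone, 250)
  pw <- Mod(stats::fft(ds$data[1, ]))^2
  freqs <- (seq_along(pw) - 1) * 250 / length(pw)
  peak <- freqs[which.max(pw[freqs <= 125])]
  expect_lt(abs(peak - 10), 0.2)
  expect_error(downsample(rec, 600), "below")
  expect_error(downsample(rec, 170), "integer")
})

test_that("common average referencing zeroes the mean and keeps differences", {
  rec <- make_test_recording()
  out <- rereference_car(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  # idempotent
  expect_equal(rereference_car(out)$data, out$data, tolerance = 1e-12)
  # channel differences invariant
  expect_equal(out$data[1, ] - out$data[3, ], rec$data[1, ] - rec$data[3, ],
               tolerance = 1e-12)
})

test_that("bad channels are flagged by amplitude and spectral outliers", {
  rec <- make_test_recording(n_ch = 6)
  rec$data[3, 100] <- 150
  expect_equal(detect_bad_channels(rec, 100), "ch3")
  zeros <- eeg_recording(matrix(0, 3, 1000), 500, c("a", "b", "c"))
  expect_length(detect_bad_channels(zeros, 100), 0)
  expect_length(detect_bad_channels(rec, Inf), 0)
  # a channel with grossly inflated power trips the optional z rule
  rec2 <- make_test_recording(n_ch = 8)
  rec2$data[5, ] <- rec2$data[5, ] * 12
  expect_true("ch5" %in% detect_bad_channels(rec2, Inf, power_z = 3))
  dropped <- drop_channels(rec2, "ch5")
  expect_equal(nrow(dropped$data), 7)
})

test_that("epoching baselines every trial and drops edge events", {
  rec <- make_test_recording(dur_s = 20, events = c(2000, 5000, 8000))
  ep <- epoch_and_baseline(rec)
  expect_equal(dim(ep$data)[1], 3)
  expect_equal(range(ep$times_ms), c(-100, 800))
  bl <- ep$times_ms >= -100 & ep$times_ms <= 0
  for (tr in 1:3) {
    expect_lt(max(abs(rowMeans(ep$data[tr, , bl]))), 1e-9)
  }
  # constant-offset channel becomes identically zero
  rec$data[2, ] <- 3.3
  ep2 <- epoch_and_baseline(rec)
  expect_equal(max(abs(ep2$data[, 2, ])), 0)
  # event too close to the edge is dropped with a message
  rec_edge <- make_test_recording(dur_s = 20, events = c(20, 5000))
  expect_message(ep3 <- epoch_and_baseline(rec_edge), "dropping 1")
  expect_equal(dim(ep3$data)[1], 1)
})

test_that("FastICA unmixes independent sources up to sign and order", {
  set.seed(5)
  n <- 5000
  S <- rbind(sin(2 * pi * 3 * (1:n) / 500),
             sign(sin(2 * pi * 7 * (1:n) / 500)),
             stats::runif(n) - 0.5)
  A <- matrix(c(1, 0.5, 0.2, 0.3, 1, 0.4, 0.1, 0.2, 1), 3, 3)
  ic <- fastica(A %*% S, seed = 2)
  r <- abs(stats::cor(t(ic$S), t(S)))
  expect_true(all(apply(r, 2, max) > 0.95))
  # every source claimed by a distinct component
  expect_equal(sort(apply(r, 2, which.max)), 1:3)
  # reconstruction identity: A S + mean == input
  expect_equal(ic$A %*% ic$S + ic$means, A %*% S, tolerance = 1e-6)
})

test_that("ocular cleaning removes blinks and spares clean recordings", {
  m <- standard_montage()
  keep <- c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "Fz", "Cz", "C3", "C4",
            "Pz", "P3", "P4", "O1", "O2", "Oz")
  sched <- make_schedule(build_stimulus_set()[1:8], 2, seed = 2)
  truth <- default_ground_truth()
  truth$blinks$enabled <- TRUE
  rec64 <- simulate_recording(m, sched, truth, seed = 11, min_duration_s = 45)
  rec <- drop_channels(rec64, setdiff(m$name, keep))
  blinks <- chordaffect:::detect_blink_events(rec)
  expect_gt(length(blinks), 2)
  # some noise components legitimately fail to converge on this short
  # fixture; the result is flagged partial, which is fine here
  res <- suppressWarnings(fastica_remove_ocular(rec, seed = 3))
  expect_gt(nrow(res$report), 0)
  front <- which(rec$ch_names %in% c("Fp1", "Fp2"))
  blink_amp <- function(r) {
    v <- colMeans(r$data[front, , drop = FALSE])
    mean(vapply(blinks, function(e) {
      max(abs(v[max(1, e - 50):min(ncol(r$data), e + 50)]))
    }, numeric(1)))
  }
  expect_lt(blink_amp(res$recording), 0.3 * blink_amp(rec))
  # clean recording: no blinks detected, data pass through identically
  truth$blinks$enabled <- FALSE
  clean <- drop_channels(
    simulate_recording(m, sched, truth, seed = 11, min_duration_s = 45),
    setdiff(m$name, keep))
  res0 <- fastica_remove_ocular(clean, seed = 3)
  expect_equal(nrow(res0$report), 0)
  expect_identical(res0$recording$data, clean$data)
})

test_that("the full chain preserves the ERP template through filtering", {
  m <- standard_montage()
  sched <- make_schedule(chord_stimuli_only(), 1, seed = 3)
  truth <- quiet_truth()
  rec <- simulate_recording(m, sched, truth, seed = 1)
  pp <- suppressMessages(preprocess_recording(rec, seed = 1))
  expect_equal(pp$epochs$sfreq, 250)
  expect_length(pp$bad_channels, 0)
  ga <- grand_average(pp$epochs, "dissonant")
  # reference: the template pushed through the same linear stages
  tpl <- gen_erp_template("dissonant", m, truth, 500)
  ref_rec <- eeg_recording(tpl, 500, m$name,
                           events = data.frame(sample = 51L, stimulus_id = "t",
                                               condition = "dissonant"))
  ref <- temporal_filter(temporal_filter(downsample(ref_rec, 250),
                                         "band_stop", c(45, 55)),
                         "band_pass", c(1, 45))
  ref <- rereference_car(ref)
  ref_ep <- epoch_and_baseline(ref, window_ms = c(-88, 788),
                               baseline_ms = c(-88, 0))
  sel <- pp$epochs$times_ms >= -88 & pp$epochs$times_ms <= 788
  expect_gt(stats::cor(as.vector(ga[, sel]), as.vector(ref_ep$data[1, , ])),
            0.99)
  # against the raw template the correlation stays high but the 1 Hz
  # high-pass inevitably removes part of the slow P3 energy
  tpl250 <- gen_erp_template("dissonant", m, truth, 250)
  tpl250 <- sweep(tpl250, 2, colMeans(tpl250))
  expect_gt(stats::cor(as.vector(ga), as.vector(tpl250)), 0.95)
})
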