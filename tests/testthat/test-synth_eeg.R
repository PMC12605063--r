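test_that("the montage is a complete 64-channel unit-sphere layout", {
  m <- standard_montage()
  expect_equal(nrow(m), 64)
  expect_false(any(duplicated(m$name)))
  expect_equal(attr(m, "reference"), "FCz")
  radii <- sqrt(m$x^2 + m$y^2 + m$z^2)
  expect_equal(radii, rep(1, 64), tolerance = 1e-12)
  adj <- channel_adjacency(m)
  expect_true(isSymmetric(adj))
  expect_equal(stats::median(rowSums(adj)), 6, tolerance = 1)
})

test_that("fractional Gaussian noise is seeded, standardised, and H-faithful", {
  x <- gen_lrtc_series(2^14, 0.7, seed = 5)
  expect_identical(x, gen_lrtc_series(2^14, 0.7, seed = 5))
  expect_false(identical(x, gen_lrtc_series(2^14, 0.7, seed = 6)))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(stats::sd(x), 1, tolerance = 1e-12)
  expect_error(gen_lrtc_series(2^12, 1.2), "H must lie")
  # white-noise limit, averaged over seeds to tame estimator variance
  e5 <- mean(vapply(1:5, function(i) {
    dfa_exponent(gen_lrtc_series(2^17, 0.5, seed = i), 250)$exponent
  }, numeric(1)))
  expect_lt(abs(e5 - 0.5), 0.03)
  e7 <- mean(vapply(1:3, function(i) {
    dfa_exponent(gen_lrtc_series(2^17, 0.7, seed = i), 250)$exponent
  }, numeric(1)))
  expect_lt(abs(e7 - 0.7), 0.05)
})

test_that("LRTC envelopes survive the positivity transform", {
  e <- mean(vapply(1:5, function(i) {
    env <- chordaffect:::gen_lrtc_envelope(2^17, 0.7, sigma = 0.3, seed = i)
    expect_true(all(env > 0))
    dfa_exponent(env, 250)$exponent
  }, numeric(1)))
  expect_lt(abs(e - 0.7), 0.10)
})

test_that("band oscillations concentrate power and track their envelope", {
  fs <- 250
  n <- fs * 120
  env <- chordaffect:::gen_lrtc_envelope(n, 0.7, seed = 2)
  osc <- gen_band_oscillation(c(8, 12), env, fs, seed = 3)
  pw <- Mod(stats::fft(osc))^2
  freqs <- (seq_along(pw) - 1) * fs / n
  half <- freqs <= fs / 2
  in_band <- half & freqs >= 7 & freqs <= 13
  expect_gt(sum(pw[in_band]) / sum(pw[half]), 0.8)
  # zero envelope silences the output
  expect_equal(gen_band_oscillation(c(8, 12), numeric(1000), fs, seed = 1),
               numeric(1000))
  # recovered Hilbert envelope tracks an imposed slow modulator; the raw
  # sample-by-sample correlation is bounded near 0.5 by the carrier's own
  # Rayleigh-distributed modulus, so the comparison smooths the Hilbert
  # envelope at the 1 s modulation timescale
  tt <- seq_len(n) / fs
  slow <- 1 + 0.5 * sin(2 * pi * 0.05 * tt)
  osc_s <- gen_band_oscillation(c(8, 12), slow, fs, seed = 4)
  rec_env <- band_envelope(osc_s, c(8, 12), fs)
  sm <- as.numeric(stats::filter(rec_env, rep(1 / 501, 501), sides = 2))
  mid <- seq(1200, n - 1200)
  expect_gt(stats::cor(sm[mid], slow[mid]), 0.8)
  expect_error(gen_band_oscillation(c(100, 130), numeric(100), fs), "Nyquist")
})

test_that("ERP templates have the configured peaks and condition ordering", {
  m <- standard_montage()
  truth <- default_ground_truth()
  fs <- 250
  tpl_d <- gen_erp_template("dissonant", m, truth, fs)
  tpl_n <- gen_erp_template("neutral", m, truth, fs)
  times <- attr(tpl_d, "times_ms")
  late <- times >= 290 & times <= 310
  expect_gt(max(abs(tpl_d[, late])), max(abs(tpl_n[, late])))
  # peak latency at the configured component latency (+/- one sample)
  pz <- match("Pz", m$name)
  post <- times > 200
  peak_t <- times[post][which.max(tpl_d[pz, post])]
  expect_lte(abs(peak_t - 300), 1000 / fs)
  # zero-amplitude truth gives a zero kernel
  truth0 <- truth
  truth0$components$amp_uv <- 0
  expect_equal(max(abs(gen_erp_template("dissonant", m, truth0, fs))), 0)
  expect_error(gen_erp_template("unheard", m, truth, fs), "unknown condition")
})

test_that("simulated recordings carry events and reproduce templates", {
  m <- standard_montage()
  sched <- make_schedule(chord_stimuli_only(), 1, seed = 3)
  truth <- quiet_truth()
  rec <- simulate_recording(m, sched, truth, seed = 1)
  expect_equal(nrow(rec$events), nrow(sched))
  expect_equal(rec$events$sample, round(sched$onset_s * 500) + 1L)
  # noise-free: epoch average equals the template exactly
  ga <- grand_average(epoch_and_baseline(rec), "dissonant")
  tpl <- gen_erp_template("dissonant", m, truth, 500)
  expect_equal(unclass(ga), unclass(tpl), tolerance = 1e-12, ignore_attr = TRUE)
  # linearity in component amplitude
  truth3 <- truth
  truth3$components$amp_uv <- 3 * truth$components$amp_uv
  ga3 <- grand_average(epoch_and_baseline(
    simulate_recording(m, sched, truth3, seed = 1)), "dissonant")
  expect_equal(unclass(ga3), 3 * unclass(ga), tolerance = 1e-9, ignore_attr = TRUE)
  # determinism
  rec_b <- simulate_recording(m, sched, truth, seed = 1)
  expect_identical(rec$data, rec_b$data)
})

test_that("grand-average fidelity grows with trial count", {
  m <- standard_montage()
  truth <- default_ground_truth()
  tpl <- gen_erp_template("dissonant", m, truth, 500)
  stim <- chord_stimuli_only()
  cors <- vapply(c(1, 4, 10), function(reps) {
    sched <- make_schedule(stim[15:21], reps, seed = reps) # dissonant roots only
    rec <- simulate_recording(m, sched, truth, seed = 40 + reps)
    ga <- grand_average(epoch_and_baseline(rec), "dissonant")
    stats::cor(as.vector(ga), as.vector(tpl))
  }, numeric(1))
  expect_true(all(diff(cors) > 0))
})

test_that("behavioural tables respect congruency bookkeeping and RT targets", {
  stim <- build_stimulus_set()
  sched <- make_schedule(stim, 5, seed = 1)
  trials <- do.call(rbind, lapply(1:30, function(i) {
    simulate_behaviour(sched, subject = sprintf("S%02d", i), seed = i)
  }))
  expect_identical(trials$accuracy, trials$congruent)
  target <- c(consonant = "pleasant", dissonant = "unpleasant", neutral = "neutral")
  expect_identical(trials$congruent,
                   unname(trials$response == target[trials$stimulus_type]))
  # mean congruent dissonant RT within 5% of the 522 ms target
  sel <- trials$stimulus_type == "dissonant" & trials$congruent
  expect_lt(abs(mean(trials$rt_ms[sel]) - 522) / 522, 0.05)
  sel_c <- trials$stimulus_type == "consonant" & trials$congruent
  expect_lt(abs(mean(trials$rt_ms[sel_c]) - 464) / 464, 0.05)
  expect_true(all(trials$rt_ms > 0))
})

test_that("deterministic response probabilities yield all-congruent tables", {
  truth <- default_ground_truth()
  truth$behaviour$response_probs[] <- 0
  truth$behaviour$response_probs["consonant", "pleasant"] <- 1
  truth$behaviour$response_probs["dissonant", "unpleasant"] <- 1
  truth$behaviour$response_probs["neutral", "neutral"] <- 1
  sched <- make_schedule(build_stimulus_set(), 2, seed = 2)
  trials <- simulate_behaviour(sched, truth, seed = 9)
  expect_true(all(trials$congruent))
})

test_that("generated accuracies match the model-implied probabilities", {
  truth <- default_ground_truth()
  am <- truth$behaviour$accuracy_model
  am$sd_subj_intercept <- am$sd_subj_slope_dissonant <-
    am$sd_subj_slope_neutral <- am$sd_item <- 0
  truth$behaviour$accuracy_model <- am
  sched <- make_schedule(build_stimulus_set(), 5, seed = 4)
  trials <- do.call(rbind, lapply(1:20, function(i) {
    simulate_behaviour(sched, truth, neural = 0,
                       subject = sprintf("S%02d", i), seed = 100 + i)
  }))
  p_target <- c(consonant = 0.75, dissonant = 0.70, neutral = 0.60)
  for (ty in names(p_target)) {
    sel <- trials$stimulus_type == ty
    n <- sum(sel)
    phat <- mean(trials$congruent[sel])
    se <- sqrt(p_target[[ty]] * (1 - p_target[[ty]]) / n)
    expect_lt(abs(phat - p_target[[ty]]), 4 * se)
  }
})
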