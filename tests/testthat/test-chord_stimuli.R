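test_that("equal-temperament pitch math reproduces the octave endpoints", {
  # printed range endpoints, 1 dp
  expect_equal(round(pitch_frequency(48), 1), 130.8) # C3
  expect_equal(round(pitch_frequency(59), 1), 246.9) # B3
  expect_equal(round(pitch_frequency(60), 1), 261.6) # C4
  expect_equal(round(pitch_frequency(71), 1), 493.9) # B4
  expect_equal(pitch_frequency(69), 440)             # reference pitch
  # octave identity over the whole range
  idx <- 24:96
  expect_equal(pitch_frequency(idx + 12) / pitch_frequency(idx),
               rep(2, length(idx)))
  expect_error(pitch_frequency(60.5), "integer")
  expect_equal(pitch_name(c(48, 66, 71)), c("C3", "F#4", "B4"))
})

test_that("chord construction matches the printed spellings", {
  expect_equal(build_chord("C", "consonant_root")$pitches, c(48, 52, 55, 60))
  expect_equal(build_chord("C", "consonant_root")$label, "C–E–G–C")
  expect_equal(build_chord("C", "consonant_64")$label, "G–C–E–G")
  d64 <- build_chord("D", "consonant_64")
  expect_equal(d64$pitches, c(57, 62, 66, 69))
  expect_equal(d64$label, "A–D–F#–A")
  expect_equal(build_chord("C", "dissonant_t1")$pitches, c(48, 54, 59, 60))
  expect_equal(build_chord("C", "dissonant_t1")$label, "C–F#–B–C")
  expect_equal(build_chord("D", "dissonant_t2")$pitches, c(50, 51, 56, 62))
  expect_equal(build_chord("D", "dissonant_t2")$label, "D–D#–G#–D")
  expect_error(build_chord("H", "consonant_root"), "unknown root")
  expect_error(build_chord("C", "neutral_click"), "unknown chord category")
})

test_that("chords respect range and interval invariants for every root", {
  offsets <- list(consonant_root = c(0, 4, 7, 12), consonant_64 = c(-5, 0, 4, 7),
                  dissonant_t1 = c(0, 6, 11, 12), dissonant_t2 = c(0, 1, 6, 12))
  for (cat in names(offsets)) {
    for (root in c("C", "D", "E", "F", "G", "A", "B")) {
      ch <- build_chord(root, cat)
      expect_true(all(diff(ch$pitches) > 0))
      expect_true(all(ch$pitches >= 48 & ch$pitches <= 71))
      # offset pattern preserved up to the octave shift
      expect_equal(diff(ch$pitches), diff(offsets[[cat]]))
    }
    # root-position and six-four voicings share the pitch-class set
  }
  for (root in c("C", "D", "E", "F", "G", "A", "B")) {
    pc <- function(x) sort(unique(x %% 12))
    expect_equal(pc(build_chord(root, "consonant_root")$pitches),
                 pc(build_chord(root, "consonant_64")$pitches))
  }
})

test_that("the stimulus set has the full inventory with no duplicates", {
  stim <- build_stimulus_set()
  expect_length(stim, 42)
  cats <- vapply(stim, function(s) s$chord$category, character(1))
  expect_equal(unname(table(cats)[c("consonant_root", "consonant_64",
                                    "dissonant_t1", "dissonant_t2",
                                    "neutral_click")]),
               c(7L, 7L, 7L, 7L, 14L), ignore_attr = TRUE)
  ids <- vapply(stim, function(s) s$id, character(1))
  expect_false(any(duplicated(ids)))
  pitch_sets <- vapply(stim, function(s) paste(s$chord$category,
                                               paste(s$chord$pitches, collapse = ",")),
                       character(1))
  expect_false(any(duplicated(pitch_sets)))
  expect_length(build_stimulus_set(n_neutral = 5), 33)
  expect_error(build_stimulus_set(n_neutral = 0), "at least one")
})

test_that("rendered stimuli have exact duration and matched RMS", {
  stim <- build_stimulus_set()
  w1 <- synthesize_waveform(stim[[1]], 44100)
  expect_length(w1, 35280) # 800 ms at 44.1 kHz
  w2 <- synthesize_waveform(stim[[9]], 44100)
  rms <- function(x) sqrt(mean(x^2))
  expect_true(rms(w1) / rms(w2) > 0.99 && rms(w1) / rms(w2) < 1.01)
  expect_length(synthesize_waveform(stim[[1]], 8000), 6400)
  expect_error(synthesize_waveform(stim[[1]], 4000), "8000")
})

test_that("a click has its spectral peak at the nominal frequency", {
  spec <- stimulus_spec(chordaffect:::neutral_click_chord(69),
                        duration_ms = 60) # A4 = 440 Hz
  w <- synthesize_waveform(spec, 44100)
  pw <- Mod(stats::fft(c(w, numeric(2^15 - length(w)))))^2
  freqs <- (seq_along(pw) - 1) * 44100 / 2^15
  half <- freqs < 22050
  peak <- freqs[half][which.max(pw[half])]
  expect_lt(abs(peak - 440), 44100 / 2^15 + 1e-9) # within one FFT bin
})

test_that("schedules repeat every stimulus exactly and bound the ISI", {
  stim <- build_stimulus_set()
  sched <- make_schedule(stim, repetitions = 5, seed = 11)
  expect_equal(nrow(sched), 210)
  expect_true(all(table(sched$stimulus_id) == 5))
  # exhaustive ISI check over > 10,000 draws
  big <- make_schedule(stim, repetitions = 240, seed = 12)
  expect_gte(nrow(big), 10000)
  expect_true(all(big$isi_ms >= 200 & big$isi_ms <= 300))
  expect_true(all(diff(sched$onset_s) > 0))
  # determinism
  expect_identical(make_schedule(stim, 5, seed = 3), make_schedule(stim, 5, seed = 3))
  expect_false(identical(make_schedule(stim, 5, seed = 3)$stimulus_id,
                         make_schedule(stim, 5, seed = 4)$stimulus_id))
  expect_error(make_schedule(list(), 5, seed = 1), "empty")
  expect_error(make_schedule(stim, 0, seed = 1), "repetitions")
})

test_that("randomisation places every stimulus uniformly on average", {
  stim <- build_stimulus_set()
  n_rep <- 400
  pos_sum <- numeric(42)
  for (s in seq_len(n_rep)) {
    sched <- make_schedule(stim, repetitions = 1, seed = 10000 + s)
    pos_sum[match(sched$stimulus_id, sprintf("stim%03d", 1:42))] <-
      pos_sum[match(sched$stimulus_id, sprintf("stim%03d", 1:42))] + sched$trial
  }
  mean_pos <- pos_sum / n_rep
  # mean trial position is (43)/2 = 21.5; SE = sd(1:42)/sqrt(400) ~ 0.61
  expect_true(all(abs(mean_pos - 21.5) < 4 * stats::sd(1:42) / sqrt(n_rep)))
})

test_that("the stimulus manifest and WAV writer round out the interface", {
  stim <- build_stimulus_set(n_neutral = 2)
  man <- stimulus_manifest(stim)
  expect_equal(nrow(man), 30)
  expect_setequal(unique(man$condition), c("consonant", "dissonant", "neutral"))
  path <- tempfile(fileext = ".wav")
  write_wav(synthesize_waveform(stim[[1]], 8000), path, 8000)
  con <- file(path, "rb")
  on.exit(close(con))
  expect_identical(readChar(con, 4), "RIFF")
  invisible(readBin(con, integer(), 1, 4))
  expect_identical(readChar(con, 4), "WAVE")
})
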