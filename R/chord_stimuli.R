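# Stimulus inventory: equal-temperament pitch math, chord spellings,
# piano-like additive synthesis, and the randomised session schedule.

PITCH_CLASSES <- c("C", "C#", "D", "D#", "E", "F", "F#", "G", "G#", "A", "A#", "B")
DIATONIC_ROOTS <- c(C = 48L, D = 50L, E = 52L, F = 53L, G = 55L, A = 57L, B = 59L)
CHORD_OFFSETS <- list(
  consonant_root = c(0L, 4L, 7L, 12L),
  consonant_64   = c(-5L, 0L, 4L, 7L),
  dissonant_t1   = c(0L, 6L, 11L, 12L),
  dissonant_t2   = c(0L, 1L, 6L, 12L)
)
CHORD_CATEGORIES <- c(names(CHORD_OFFSETS), "neutral_click")
PITCH_RANGE <- c(48L, 71L) # C3..B4

#' Pitch frequency in 12-tone equal temperament
#'
#' Maps a semitone index (MIDI convention, C4 = 60, A4 = 69) to frequency,
#' with A4 tuned to 440 Hz.
#'
#' @param index Integer semitone index (vectorised).
#' @return Frequency in Hz.
#' @export
pitch_frequency <- function(index) {
  stop_if_not(all(index == round(index)), "semitone index must be integer")
  440 * 2^((index - 69) / 12)
}

#' Pitch name for a semitone index
#'
#' @param index Integer semitone index (vectorised).
#' @return Pitch-class plus octave label, e.g. `"C3"`, `"F#4"`.
#' @export
pitch_name <- function(index) {
  stop_if_not(all(index == round(index)), "semitone index must be integer")
  paste0(PITCH_CLASSES[index %% 12 + 1], index %/% 12 - 1)
}

pitch_class <- function(index) PITCH_CLASSES[index %% 12 + 1]

#' Build a chord from a diatonic root and category
#'
#' Consonant chords are major triads with a doubled root (root position,
#' offsets 0/4/7/12) or six-four voicings starting a fourth below the root
#' (offsets -5/0/4/7). Dissonant chords superimpose fixed clashing interval
#' patterns (tritones and minor seconds) on the same diatonic roots.
#' Voicings falling below C3 are raised an octave so that all pitches stay
#' within C3-B4.
#'
#' @param root_name One of `"C".."B"` (natural diatonic roots).
#' @param category One of `"consonant_root"`, `"consonant_64"`,
#'   `"dissonant_t1"`, `"dissonant_t2"`.
#' @return A `chord` object: list with `root`, `category`, `pitches`
#'   (ascending semitone indices) and `label`.
#' @export
build_chord <- function(root_name, category) {
  stop_if_not(root_name %in% names(DIATONIC_ROOTS), "unknown root '%s'", root_name)
  stop_if_not(category %in% names(CHORD_OFFSETS), "unknown chord category '%s'", category)
  root <- DIATONIC_ROOTS[[root_name]]
  pitches <- root + CHORD_OFFSETS[[category]]
  if (min(pitches) < PITCH_RANGE[1]) pitches <- pitches + 12L
  stop_if_not(max(pitches) <= PITCH_RANGE[2], "chord exceeds B4")
  structure(
    list(
      root = root,
      category = category,
      pitches = pitches,
      label = paste(pitch_class(pitches), collapse = "–")
    ),
    class = "chord"
  )
}

neutral_click_chord <- function(index) {
  stop_if_not(index >= PITCH_RANGE[1] && index <= PITCH_RANGE[2],
              "click pitch outside C3-B4")
  structure(
    list(root = as.integer(index), category = "neutral_click",
         pitches = as.integer(index), label = pitch_name(index)),
    class = "chord"
  )
}

#' @export
print.chord <- function(x, ...) {
  cat(sprintf("<chord> %s [%s] pitches: %s\n", x$label, x$category,
              paste(pitch_name(x$pitches), collapse = " ")))
  invisible(x)
}

#' Build the full stimulus inventory
#'
#' Seven chords per chord category (one per natural diatonic root) plus
#' `n_neutral` single-pitch metronome clicks. The default 14 clicks cover the
#' natural diatonic tones of both the small (C3-B3) and one-line (C4-B4)
#' octaves.
#'
#' @param n_neutral Number of neutral click stimuli (>= 1).
#' @param duration_ms Chord duration in ms (default 800).
#' @param click_duration_ms Click duration in ms.
#' @param rms_target Common RMS level for rendered waveforms.
#' @return Data-frame-like list of `stimulus_spec` objects with unique ids.
#' @export
build_stimulus_set <- function(n_neutral = 14, duration_ms = 800,
                               click_duration_ms = 60, rms_target = 0.1) {
  stop_if_not(n_neutral >= 1, "need at least one neutral stimulus")
  specs <- list()
  for (cat in names(CHORD_OFFSETS)) {
    for (root in names(DIATONIC_ROOTS)) {
      specs[[length(specs) + 1L]] <- stimulus_spec(
        build_chord(root, cat), duration_ms = duration_ms, rms_target = rms_target
      )
    }
  }
  diatonic_both <- c(DIATONIC_ROOTS, DIATONIC_ROOTS + 12L)
  click_pitches <- rep_len(sort(unname(diatonic_both)), n_neutral)
  for (p in click_pitches) {
    specs[[length(specs) + 1L]] <- stimulus_spec(
      neutral_click_chord(p), duration_ms = click_duration_ms, rms_target = rms_target
    )
  }
  for (i in seq_along(specs)) specs[[i]]$id <- sprintf("stim%03d", i)
  specs
}

#' Stimulus specification
#'
#' @param chord A `chord` object.
#' @param duration_ms Rendered duration in ms.
#' @param timbre List of synthesiser parameters: `n_harmonics`, `t60_s`
#'   (fundamental 60 dB decay time), `brightness` (per-harmonic amplitude
#'   rolloff exponent), `harmonic_damping` (extra decay per harmonic).
#' @param rms_target RMS level all stimuli are normalised to.
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(chord, duration_ms = 800,
                          timbre = list(n_harmonics = 8, t60_s = 1,
                                        brightness = 1, harmonic_damping = 0.3),
                          rms_target = 0.1) {
  stop_if_not(inherits(chord, "chord"), "chord must be a chord object")
  stop_if_not(duration_ms > 0, "duration must be positive")
  structure(
    list(id = NA_character_, chord = chord, duration_ms = duration_ms,
         timbre = timbre, rms_target = rms_target),
    class = "stimulus_spec"
  )
}

#' Render a stimulus to a mono waveform
#'
#' Chords are additive sums of damped harmonic piano-like tones, one per
#' pitch; clicks are the same synthesis with a fast decay. All stimuli are
#' normalised to the spec's common RMS target and shaped with short 5 ms
#' cosine onset/offset ramps.
#'
#' @param spec A `stimulus_spec`.
#' @param sample_rate Output rate in Hz (>= 8000).
#' @return Numeric vector of samples, `duration_ms` long exactly.
#' @export
synthesize_waveform <- function(spec, sample_rate = 44100) {
  stop_if_not(sample_rate >= 8000, "sample rate must be >= 8000 Hz")
  stop_if_not(length(spec$chord$pitches) >= 1, "empty chord")
  n <- round(spec$duration_ms / 1000 * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  tb <- spec$timbre
  is_click <- spec$chord$category == "neutral_click"
  t60 <- if (is_click) 0.06 else tb$t60_s
  tau <- t60 / (3 * log(10)) # 60 dB in t60 seconds
  y <- numeric(n)
  for (p in spec$chord$pitches) {
    f0 <- pitch_frequency(p)
    for (h in seq_len(tb$n_harmonics)) {
      fh <- h * f0
      if (fh >= sample_rate / 2) break
      amp <- h^(-tb$brightness)
      tau_h <- tau / (1 + tb$harmonic_damping * (h - 1))
      y <- y + amp * exp(-t / tau_h) * sin(2 * pi * fh * t)
    }
  }
  nramp <- min(round(0.005 * sample_rate), floor(n / 2))
  if (nramp > 1) {
    ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nramp)))
    y[seq_len(nramp)] <- y[seq_len(nramp)] * ramp
    y[seq(n - nramp + 1, n)] <- y[seq(n - nramp + 1, n)] * rev(ramp)
  }
  y * spec$rms_target / sqrt(mean(y^2))
}

#' Randomised session schedule
#'
#' Each stimulus is repeated `repetitions` times and the full trial list is
#' shuffled with the given seed. Inter-stimulus intervals are drawn uniformly
#' from 200-300 ms; onsets accumulate stimulus durations and ISIs after an
#' initial lead-in.
#'
#' @param stimuli List of `stimulus_spec` objects (ids assigned).
#' @param repetitions Presentations per stimulus (default 5).
#' @param seed RNG seed; identical seeds give identical schedules.
#' @param isi_range_ms ISI bounds in ms.
#' @param lead_in_s Silence before the first onset, in seconds.
#' @return A `schedule` data frame: trial, stimulus_id, category, condition,
#'   onset_s, isi_ms; repetitions and seed stored as attributes.
#' @export
make_schedule <- function(stimuli, repetitions = 5, seed = 1,
                          isi_range_ms = c(200, 300), lead_in_s = 2) {
  stop_if_not(length(stimuli) >= 1, "empty stimulus list")
  stop_if_not(repetitions >= 1, "repetitions must be >= 1")
  ids <- vapply(stimuli, function(s) s$id, character(1))
  stop_if_not(!anyNA(ids) && !any(duplicated(ids)), "stimuli must carry unique ids")
  cats <- vapply(stimuli, function(s) s$chord$category, character(1))
  durs <- vapply(stimuli, function(s) s$duration_ms, numeric(1))
  with_seed(seed, {
    order_idx <- sample(rep(seq_along(stimuli), times = repetitions))
    isi <- stats::runif(length(order_idx), isi_range_ms[1], isi_range_ms[2])
    onset <- lead_in_s + cumsum(c(0, (durs[order_idx][-length(order_idx)] + isi[-length(isi)]) / 1000))
    out <- data.frame(
      trial = seq_along(order_idx),
      stimulus_id = ids[order_idx],
      category = cats[order_idx],
      condition = condition_of_category(cats[order_idx]),
      onset_s = onset,
      isi_ms = isi,
      stringsAsFactors = FALSE
    )
    attr(out, "repetitions") <- repetitions
    attr(out, "seed") <- seed
    class(out) <- c("schedule", "data.frame")
    out
  })
}

#' Map a stimulus category to its analysis condition
#'
#' @param category Character vector of stimulus categories.
#' @return `"consonant"`, `"dissonant"` or `"neutral"`.
#' @export
condition_of_category <- function(category) {
  out <- character(length(category))
  out[category %in% c("consonant_root", "consonant_64")] <- "consonant"
  out[category %in% c("dissonant_t1", "dissonant_t2")] <- "dissonant"
  out[category == "neutral_click"] <- "neutral"
  stop_if_not(all(nzchar(out)), "unknown stimulus category")
  out
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' @param samples Numeric vector in [-1, 1].
#' @param path Output file.
#' @param sample_rate Rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")  # PCM
  writeBin(1L, con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Stimulus manifest table
#'
#' @param stimuli List of `stimulus_spec` objects.
#' @return Data frame: id, category, condition, label, pitches, duration_ms.
#' @export
stimulus_manifest <- function(stimuli) {
  data.frame(
    id = vapply(stimuli, function(s) s$id, character(1)),
    category = vapply(stimuli, function(s) s$chord$category, character(1)),
    condition = condition_of_category(vapply(stimuli, function(s) s$chord$category, character(1))),
    label = vapply(stimuli, function(s) s$chord$label, character(1)),
    pitches = vapply(stimuli, function(s) paste(s$chord$pitches, collapse = ","), character(1)),
    duration_ms = vapply(stimuli, function(s) s$duration_ms, numeric(1)),
    stringsAsFactors = FALSE
  )
}
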