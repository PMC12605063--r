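# Preprocessing chain: zero-phase Butterworth notch and band-pass filtering,
# anti-aliased downsampling, common average reference, amplitude-based bad
# channel detection, FastICA ocular cleaning, epoching with baseline
# correction. The canonical stage order (enforced by preprocess_recording)
# is downsample -> notch -> band-pass -> CAR -> bad channels -> ICA -> epoch.

#' Zero-phase temporal filter over all channels
#'
#' @param rec An `eeg_recording`.
#' @param kind `"band_stop"` or `"band_pass"`.
#' @param edges_hz Band edges in Hz (length 2, increasing).
#' @param order Butterworth order of the analog prototype (default 2 for
#'   band-stop, 4 for band-pass).
#' @return Filtered `eeg_recording`.
#' @export
temporal_filter <- function(rec, kind = c("band_pass", "band_stop"), edges_hz,
                            order = if (match.arg(kind) == "band_stop") 2 else 4) {
  kind <- match.arg(kind)
  nyq <- rec$sfreq / 2
  stop_if_not(all(edges_hz > 0) && all(edges_hz < nyq),
              "filter edges must lie in (0, Nyquist = %g Hz)", nyq)
  flt <- butter_design(order, edges_hz / nyq,
                       if (kind == "band_stop") "stop" else "pass")
  out <- rec
  for (ch in seq_len(nrow(rec$data))) {
    out$data[ch, ] <- filtfilt_zp(flt$b, flt$a, rec$data[ch, ])
  }
  out
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth at 80% of
#' the new Nyquist) before decimation. Event sample indices are rescaled and
#' rounded to the nearest sample (ties round down).
#'
#' @param rec An `eeg_recording`.
#' @param target_rate New sampling rate; must divide the current rate.
#' @return Downsampled `eeg_recording`.
#' @export
downsample <- function(rec, target_rate) {
  stop_if_not(target_rate < rec$sfreq, "target rate must be below current rate")
  factor <- rec$sfreq / target_rate
  stop_if_not(abs(factor - round(factor)) < 1e-9,
              "only integer decimation is supported (got ratio %g)", factor)
  factor <- round(factor)
  flt <- butter_design(8, 0.8 / factor, "low")
  keep <- seq(1, ncol(rec$data), by = factor)
  data <- matrix(0, nrow(rec$data), length(keep))
  for (ch in seq_len(nrow(rec$data))) {
    data[ch, ] <- filtfilt_zp(flt$b, flt$a, rec$data[ch, ])[keep]
  }
  events <- rec$events
  if (nrow(events)) {
    # nearest new sample to the old event time; .5 ties round down
    events$sample <- as.integer(ceiling((events$sample - 1) / factor - 0.5) + 1L)
  }
  eeg_recording(data, target_rate, rec$ch_names, events, rec$montage)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel.
#' Idempotent; channel differences are unchanged.
#'
#' @param rec An `eeg_recording`.
#' @return Re-referenced `eeg_recording`.
#' @export
rereference_car <- function(rec) {
  stop_if_not(nrow(rec$data) >= 2, "need at least 2 channels")
  out <- rec
  out$data <- sweep(rec$data, 2, colMeans(rec$data))
  out
}

#' Detect bad channels by amplitude
#'
#' Flags channels whose absolute amplitude exceeds `threshold_uv` at any
#' sample, plus (optionally) channels whose total band power is an outlier
#' (|z| > `power_z`) across channels.
#'
#' @param rec An `eeg_recording`.
#' @param threshold_uv Absolute amplitude threshold in uV (default 100).
#' @param power_z Optional z-score threshold on log total power; `NULL`
#'   disables the spectral rule.
#' @return Character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(rec, threshold_uv = 100, power_z = NULL) {
  stop_if_not(threshold_uv > 0, "threshold must be positive")
  peak <- apply(abs(rec$data), 1, max)
  bad <- peak > threshold_uv
  if (!is.null(power_z)) {
    lp <- log(rowMeans(rec$data^2) + .Machine$double.eps)
    z <- (lp - stats::median(lp)) / (stats::mad(lp) + .Machine$double.eps)
    bad <- bad | abs(z) > power_z
  }
  rec$ch_names[bad]
}

#' Drop channels from a recording
#'
#' @param rec An `eeg_recording`.
#' @param names Channel names to remove.
#' @return Recording without those channels (montage subset accordingly).
#' @export
drop_channels <- function(rec, names) {
  keep <- !(rec$ch_names %in% names)
  stop_if_not(sum(keep) >= 2, "cannot drop to fewer than 2 channels")
  montage <- rec$montage
  if (!is.null(montage)) {
    ref <- attr(montage, "reference")
    montage <- montage[montage$name %in% rec$ch_names[keep], , drop = FALSE]
    attr(montage, "reference") <- ref
    class(montage) <- c("montage", "data.frame")
  }
  eeg_recording(rec$data[keep, , drop = FALSE], rec$sfreq, rec$ch_names[keep],
                rec$events, montage)
}

#' Epoch a recording and baseline-correct
#'
#' Cuts stimulus-locked windows around every event and subtracts the mean of
#' the pre-stimulus baseline interval per trial and channel. Events whose
#' window falls outside the recording are dropped with a message.
#'
#' @param rec An `eeg_recording` with events.
#' @param window_ms Epoch window relative to onset (default -100..800 ms).
#' @param baseline_ms Baseline interval (default -100..0 ms); must lie
#'   within the pre-stimulus part of the window.
#' @return An `eeg_epochs` object: `data` array (trials x channels x time),
#'   `times_ms`, `conditions`, `stimulus_id`, `sfreq`, `ch_names`,
#'   `montage`, `baseline_ms`.
#' @export
epoch_and_baseline <- function(rec, window_ms = c(-100, 800),
                               baseline_ms = c(-100, 0)) {
  stop_if_not(nrow(rec$events) >= 1, "recording has no events")
  stop_if_not(baseline_ms[1] >= window_ms[1] && baseline_ms[2] <= 0,
              "baseline must lie in the pre-stimulus part of the window")
  i0 <- round(window_ms[1] / 1000 * rec$sfreq)
  i1 <- round(window_ms[2] / 1000 * rec$sfreq)
  times <- seq(i0, i1) / rec$sfreq * 1000
  ok <- rec$events$sample + i0 >= 1 & rec$events$sample + i1 <= ncol(rec$data)
  if (any(!ok)) {
    message(sprintf("dropping %d event(s) too close to the recording edge", sum(!ok)))
  }
  ev <- rec$events[ok, , drop = FALSE]
  stop_if_not(nrow(ev) >= 1, "no event has a full window inside the recording")
  n_t <- length(times)
  arr <- array(0, c(nrow(ev), nrow(rec$data), n_t))
  bl <- times >= baseline_ms[1] & times <= baseline_ms[2]
  for (tr in seq_len(nrow(ev))) {
    seg <- rec$data[, seq(ev$sample[tr] + i0, ev$sample[tr] + i1), drop = FALSE]
    arr[tr, , ] <- seg - rowMeans(seg[, bl, drop = FALSE])
  }
  structure(list(data = arr, times_ms = times, conditions = ev$condition,
                 stimulus_id = ev$stimulus_id, sfreq = rec$sfreq,
                 ch_names = rec$ch_names, montage = rec$montage,
                 baseline_ms = baseline_ms),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  invisible(x)
}

#' Run the full preprocessing chain
#'
#' Canonical order: downsample, 45-55 Hz notch, 1-45 Hz band-pass, common
#' average reference, bad-channel exclusion, FastICA ocular cleaning,
#' epoching with baseline correction.
#'
#' @param rec An `eeg_recording`.
#' @param target_rate Downsampled rate in Hz (default 250).
#' @param notch_hz Band-stop edges (default 45-55 Hz, order 2).
#' @param bandpass_hz Band-pass edges (default 1-45 Hz, order 4).
#' @param bad_threshold_uv Bad-channel amplitude threshold.
#' @param run_ica Run FastICA ocular cleaning (skipped automatically when no
#'   blink events are detected).
#' @param window_ms,baseline_ms Epoch and baseline windows.
#' @param seed Seed for the ICA initialisation.
#' @return List: `epochs` (an `eeg_epochs`), `recording` (the cleaned
#'   continuous `eeg_recording`), `bad_channels`, `ica_report`.
#' @export
preprocess_recording <- function(rec, target_rate = 250,
                                 notch_hz = c(45, 55), bandpass_hz = c(1, 45),
                                 bad_threshold_uv = 100, run_ica = TRUE,
                                 window_ms = c(-100, 800),
                                 baseline_ms = c(-100, 0), seed = 1) {
  if (target_rate < rec$sfreq) rec <- downsample(rec, target_rate)
  rec <- temporal_filter(rec, "band_stop", notch_hz)
  rec <- temporal_filter(rec, "band_pass", bandpass_hz)
  rec <- rereference_car(rec)
  bad <- detect_bad_channels(rec, bad_threshold_uv)
  if (length(bad)) rec <- drop_channels(rec, bad)
  ica_report <- NULL
  if (isTRUE(run_ica)) {
    cleaned <- fastica_remove_ocular(rec, seed = seed)
    rec <- cleaned$recording
    ica_report <- cleaned$report
  }
  list(epochs = epoch_and_baseline(rec, window_ms, baseline_ms),
       recording = rec, bad_channels = bad, ica_report = ica_report)
}
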