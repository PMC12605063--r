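# Band-limited amplitude and long-range temporal correlation estimation:
# zero-phase Butterworth band filtering, Hilbert envelopes, and detrended
# fluctuation analysis (DFA) over log-spaced windows.

#' Default frequency bands
#'
#' Alpha 8-12 Hz, beta 20-25 Hz, gamma 35-40 Hz.
#'
#' @return Data frame: name, low, high.
#' @export
default_bands <- function() {
  data.frame(name = c("alpha", "beta", "gamma"),
             low = c(8, 20, 35), high = c(12, 25, 40),
             stringsAsFactors = FALSE)
}

#' Band-limited amplitude envelope
#'
#' Zero-phase Butterworth band-pass followed by the magnitude of the
#' analytic (Hilbert) signal.
#'
#' @param x Single-channel numeric series.
#' @param band Length-2 band edges in Hz.
#' @param sample_rate Sampling rate in Hz.
#' @param order Butterworth order (default 4).
#' @return Non-negative envelope series, same length as `x`.
#' @export
band_envelope <- function(x, band, sample_rate, order = 4) {
  nyq <- sample_rate / 2
  stop_if_not(band[1] > 0 && band[1] < band[2] && band[2] < nyq,
              "band must satisfy 0 < low < high < Nyquist")
  flt <- butter_design(order, band / nyq, "pass")
  Mod(analytic_signal(filtfilt_zp(flt$b, flt$a, x)))
}

#' Mean envelope amplitude
#'
#' @param envelope Envelope series.
#' @return Arithmetic mean (uV when the input is in uV).
#' @export
mean_amplitude <- function(envelope) {
  stop_if_not(length(envelope) >= 1, "empty envelope")
  mean(envelope)
}

#' Detrended fluctuation analysis exponent
#'
#' Integrates the mean-centred series, splits it into 50%-overlapping
#' windows at `n_windows` log-spaced sizes within `window_range_s`, removes
#' a linear trend per window, and regresses log10 RMS fluctuation on log10
#' window size. The slope is the DFA exponent (0.5 for uncorrelated noise,
#' 1.5 for Brownian motion).
#'
#' @param x Series to analyse (e.g. a band envelope).
#' @param sample_rate Sampling rate in Hz.
#' @param window_range_s Smallest and largest window in seconds
#'   (default 5-50).
#' @param n_windows Number of log-spaced window sizes (default 10).
#' @param overlap Fractional window overlap (default 0.5).
#' @return List: `exponent`, `r_squared`, `window_s`, `fluctuation`.
#' @export
dfa_exponent <- function(x, sample_rate, window_range_s = c(5, 50),
                         n_windows = 10, overlap = 0.5) {
  sizes <- unique(round(10^seq(log10(window_range_s[1] * sample_rate),
                               log10(window_range_s[2] * sample_rate),
                               length.out = n_windows)))
  stop_if_not(length(x) >= 2 * max(sizes),
              "series too short for DFA: need >= %d samples (2 x largest window)",
              2 * max(sizes))
  y <- cumsum(x - mean(x))
  fluct <- vapply(sizes, function(L) {
    step <- max(1L, round(L * (1 - overlap)))
    starts <- seq(1L, length(y) - L + 1L, by = step)
    segs <- vapply(starts, function(s) y[seq(s, s + L - 1L)], numeric(L))
    t <- seq_len(L)
    X <- cbind(1, t)
    coef <- solve(crossprod(X), crossprod(X, segs))
    res <- segs - X %*% coef
    sqrt(mean(colMeans(res^2)))
  }, numeric(1))
  lx <- log10(sizes / sample_rate)
  ly <- log10(fluct)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(exponent = unname(fit$coefficients[2]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       window_s = sizes / sample_rate,
       fluctuation = fluct)
}

#' Envelope statistics per channel and band
#'
#' For each channel and band: the mean Hilbert-envelope amplitude and the
#' DFA exponent (with fit quality) of the envelope, computed on the
#' continuous recording.
#'
#' @param rec An `eeg_recording`.
#' @param bands Data frame with name/low/high (default [default_bands()]).
#' @param channels Channel names to analyse (default all).
#' @param window_range_s,n_windows DFA settings.
#' @return Data frame: channel, band, amplitude, dfa, r_squared.
#' @export
envelope_stats <- function(rec, bands = default_bands(),
                           channels = rec$ch_names,
                           window_range_s = c(5, 50), n_windows = 10) {
  stop_if_not(all(channels %in% rec$ch_names), "unknown channel requested")
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    for (ch in channels) {
      env <- band_envelope(rec$data[match(ch, rec$ch_names), ],
                           c(bands$low[b], bands$high[b]), rec$sfreq)
      dfa <- dfa_exponent(env, rec$sfreq, window_range_s, n_windows)
      rows[[length(rows) + 1L]] <- data.frame(
        channel = ch, band = bands$name[b],
        amplitude = mean_amplitude(env),
        dfa = dfa$exponent, r_squared = dfa$r_squared,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Reduce channel-level envelope statistics to subject scalars
#'
#' Across-channel mean per band and measure — the scalar predictors used by
#' the accuracy models.
#'
#' @param stats Output of [envelope_stats()].
#' @return Data frame: band, amplitude, dfa.
#' @export
subject_band_summary <- function(stats) {
  out <- do.call(rbind, lapply(split(stats, stats$band), function(s) {
    data.frame(band = s$band[1], amplitude = mean(s$amplitude),
               dfa = mean(s$dfa), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
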