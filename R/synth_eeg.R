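# Synthetic EEG + behaviour generator. Produces seeded recordings with the
# statistical structure the downstream analyses assume: condition-dependent
# ERP components, narrowband oscillations whose envelopes carry long-range
# temporal correlations, 1/f background noise, optional blink artifacts,
# and a behavioural trial table driven by a mixed-effects logistic accuracy
# model.

#' Fractional Gaussian noise via spectral synthesis
#'
#' Generates a zero-mean, unit-variance stationary series whose detrended
#' fluctuation analysis (DFA) exponent approximates the Hurst exponent `H`:
#' the power spectrum is shaped as f^(1-2H) with random phases.
#'
#' @param n_samples Series length (>= 2).
#' @param H Hurst exponent in (0, 1). 0.5 gives white noise.
#' @param seed RNG seed.
#' @return Numeric vector of length `n_samples`.
#' @export
gen_lrtc_series <- function(n_samples, H, seed = NULL) {
  stop_if_not(H > 0 && H < 1, "H must lie in (0, 1)")
  stop_if_not(n_samples >= 2, "need at least 2 samples")
  with_seed(seed, spectral_noise(n_samples, beta = 2 * H - 1))
}

# Noise with power spectral density proportional to f^(-beta); beta = 0 is
# white, beta = 1 is classic 1/f "pink" noise. Output standardised to zero
# mean, unit variance, per column. Synthesis runs at a 5-smooth padded FFT
# length and truncates, which leaves the spectrum shape intact.
spectral_noise <- function(n, beta, ncol = 1) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  k <- seq_len(floor(nfft / 2))
  mag <- (k / nfft)^(-beta / 2)
  nk <- length(k)
  re <- matrix(stats::rnorm(nk * ncol), nk, ncol) * mag
  im <- matrix(stats::rnorm(nk * ncol), nk, ncol) * mag
  if (nfft %% 2 == 0) im[nk, ] <- 0 # Nyquist bin is real
  spec <- matrix(complex(real = re, imaginary = im), nk, ncol)
  mirror <- Conj(spec[seq(nk - (1 - nfft %% 2), 1), , drop = FALSE])
  full <- rbind(matrix(0 + 0i, 1, ncol), spec, mirror)
  x <- Re(stats::mvfft(full, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  if (ncol == 1) drop(x) else x
}

#' Narrowband oscillation with an imposed amplitude envelope
#'
#' Band-limits white noise with a zero-phase Butterworth filter, scales the
#' carrier to unit variance, and multiplies by the supplied (non-negative)
#' envelope.
#'
#' @param band Numeric length-2: band edges in Hz.
#' @param envelope Non-negative series; its length fixes the output length.
#' @param sample_rate Sampling rate in Hz.
#' @param seed RNG seed.
#' @return Numeric vector, `length(envelope)` samples.
#' @export
gen_band_oscillation <- function(band, envelope, sample_rate, seed = NULL) {
  nyq <- sample_rate / 2
  stop_if_not(band[1] > 0 && band[1] < band[2] && band[2] < nyq,
              "band must satisfy 0 < low < high < Nyquist")
  stop_if_not(all(envelope >= 0), "envelope must be non-negative")
  n <- length(envelope)
  with_seed(seed, {
    flt <- butter_design(4, band / nyq, "pass")
    carrier <- filtfilt_zp(flt$b, flt$a, stats::rnorm(n))
    carrier <- carrier / stats::sd(carrier)
    carrier * envelope
  })
}

# Strictly positive LRTC envelope: exp(sigma * low-passed fGn). Amplitude
# envelopes of narrowband rhythms vary more slowly than the band's own
# bandwidth, so the fGn is low-passed (default 2 Hz at the given rate)
# before the positivity transform; this leaves detrended fluctuations at
# the multi-second DFA scales (and hence the exponent) untouched. The
# exponential is smooth and monotone, so the exponent survives it for
# moderate sigma (<= 0.5).
gen_lrtc_envelope <- function(n, H, sigma = 0.3, seed = NULL,
                              sample_rate = NULL, cutoff_hz = 2) {
  x <- gen_lrtc_series(n, H, seed)
  if (!is.null(sample_rate) && cutoff_hz < sample_rate / 2) {
    flt <- butter_design(4, cutoff_hz / (sample_rate / 2), "low")
    x <- filtfilt_zp(flt$b, flt$a, x)
    x <- (x - mean(x)) / stats::sd(x)
  }
  exp(sigma * x)
}

#' Default ground truth for the simulator
#'
#' The stated world of the generator: three ERP components at 100/200/300 ms
#' (N1 centred centrally, P2 central, P3 parietal) with dissonant chords
#' producing the strongest P2/P3, band oscillations (alpha 8-12, beta 20-25,
#' gamma 35-40 Hz) with long-range correlated envelopes, pink background
#' noise, and a behavioural model whose congruent-response probabilities and
#' reaction-time means follow the reported group means (e.g. 522 ms for
#' congruent dissonant trials).
#'
#' @param snr Multiplier applied to ERP component amplitudes (default 1).
#' @return A `ground_truth` list; see fields in the implementation.
#' @export
default_ground_truth <- function(snr = 1) {
  components <- expand.grid(
    name = c("N1", "P2", "P3"), condition = c("consonant", "dissonant", "neutral"),
    stringsAsFactors = FALSE
  )
  components$latency_ms <- c(100, 200, 300)[match(components$name, c("N1", "P2", "P3"))]
  components$width_ms <- c(12, 15, 20)[match(components$name, c("N1", "P2", "P3"))]
  components$centre <- c(N1 = "Cz", P2 = "Cz", P3 = "Pz")[components$name]
  components$spread_deg <- c(N1 = 40, P2 = 45, P3 = 50)[components$name]
  amp <- rbind( # uV, rows N1/P2/P3
    consonant = c(-3.0, 2.5, 2.5),
    dissonant = c(-3.5, 4.0, 5.0),
    neutral   = c(-2.5, 2.0, 3.0)
  )
  components$amp_uv <- snr * amp[cbind(match(components$condition, rownames(amp)),
                                       match(components$name, c("N1", "P2", "P3")))]
  truth <- list(
    epoch_ms = c(-100, 800),
    components = components,
    bands = data.frame(
      name = c("alpha", "beta", "gamma"),
      low = c(8, 20, 35), high = c(12, 25, 40),
      amp_uv = c(4, 2, 1), hurst = c(0.7, 0.7, 0.7),
      stringsAsFactors = FALSE
    ),
    envelope_sigma = 0.3,
    osc_n_sources = 8,
    noise = list(pink_uv = 10, exponent = 1),
    blinks = list(enabled = FALSE, rate_per_min = 12, amp_uv = 150, duration_ms = 300),
    behaviour = list(
      # P(response | stimulus type); rows = type, cols = response
      response_probs = matrix(
        c(0.75, 0.17, 0.08,
          0.12, 0.18, 0.70,
          0.20, 0.60, 0.20),
        nrow = 3, byrow = TRUE,
        dimnames = list(c("consonant", "dissonant", "neutral"),
                        c("pleasant", "neutral", "unpleasant"))
      ),
      rt_mean_ms = matrix(
        c(464, 1158,
          522, 1123,
          747, 688),
        nrow = 3, byrow = TRUE,
        dimnames = list(c("consonant", "dissonant", "neutral"),
                        c("congruent", "incongruent"))
      ),
      rt_sdlog = 0.35,
      accuracy_model = list(
        # slopes of the logistic accuracy model on a standardised neural
        # predictor; type intercepts are derived from response_probs unless
        # `beta` is supplied explicitly (named: intercept, dissonant,
        # neutral, pred, dissonant_pred, neutral_pred)
        beta = NULL,
        slope_pred = 0.2,
        slope_dissonant_pred = -0.6,
        slope_neutral_pred = -0.8,
        sd_subj_intercept = 0.5,
        sd_subj_slope_dissonant = 0.4,
        sd_subj_slope_neutral = 0.4,
        sd_item = 0.3
      )
    )
  )
  class(truth) <- c("ground_truth", "list")
  truth
}

accuracy_fixed_effects <- function(behaviour) {
  am <- behaviour$accuracy_model
  if (!is.null(am$beta)) return(am$beta)
  p <- behaviour$response_probs
  congruent <- c(consonant = p["consonant", "pleasant"],
                 dissonant = p["dissonant", "unpleasant"],
                 neutral = p["neutral", "neutral"])
  congruent <- pmin(pmax(congruent, 1e-12), 1 - 1e-12) # keep logits finite
  c(intercept = stats::qlogis(congruent[["consonant"]]),
    dissonant = stats::qlogis(congruent[["dissonant"]]) - stats::qlogis(congruent[["consonant"]]),
    neutral = stats::qlogis(congruent[["neutral"]]) - stats::qlogis(congruent[["consonant"]]),
    pred = am$slope_pred,
    dissonant_pred = am$slope_dissonant_pred,
    neutral_pred = am$slope_neutral_pred)
}

#' Condition ERP template
#'
#' Sum of Gaussian-in-time components, each spread over channels with a
#' Gaussian falloff in great-circle distance from its centre electrode.
#'
#' @param condition `"consonant"`, `"dissonant"` or `"neutral"`.
#' @param montage A `montage`.
#' @param truth A `ground_truth`.
#' @param sample_rate Sampling rate of the template time axis.
#' @return channels x time matrix (uV) with a `times_ms` attribute covering
#'   the truth's epoch window.
#' @export
gen_erp_template <- function(condition, montage, truth, sample_rate = 500) {
  comp <- truth$components[truth$components$condition == condition, , drop = FALSE]
  stop_if_not(nrow(comp) > 0, "unknown condition '%s'", condition)
  times <- seq(truth$epoch_ms[1], truth$epoch_ms[2], by = 1000 / sample_rate)
  d <- montage_distances(montage)
  out <- matrix(0, nrow(montage), length(times))
  for (i in seq_len(nrow(comp))) {
    stop_if_not(comp$centre[i] %in% montage$name,
                "component centre '%s' not in montage", comp$centre[i])
    bump <- exp(-(times - comp$latency_ms[i])^2 / (2 * comp$width_ms[i]^2))
    w <- exp(-d[, comp$centre[i]]^2 / (2 * comp$spread_deg[i]^2))
    out <- out + comp$amp_uv[i] * outer(w, bump)
  }
  rownames(out) <- montage$name
  attr(out, "times_ms") <- times
  out
}

blink_waveform <- function(duration_ms, sample_rate) {
  n <- round(duration_ms / 1000 * sample_rate)
  t <- seq(0, 1, length.out = n)
  sin(pi * t)^2 * (1 - 0.4 * sin(2 * pi * t)) # asymmetric biphasic-ish bump
}

#' Simulate a raw multichannel recording
#'
#' Composes 1/f background noise, band-limited oscillations with long-range
#' correlated envelopes (mixed into channels from a small set of spatial
#' sources), per-trial ERP kernels at scheduled onsets and, optionally,
#' frontal blink artifacts. Events are recorded at exact onset samples.
#'
#' @param montage A `montage`.
#' @param schedule A `schedule` from [make_schedule()].
#' @param truth A `ground_truth`.
#' @param sample_rate Sampling rate in Hz (default 500).
#' @param seed RNG seed; the recording is a pure function of its arguments.
#' @param min_duration_s Pad the recording to at least this length.
#' @return An `eeg_recording`: list with `data` (channels x samples, uV),
#'   `sfreq`, `ch_names`, `events` (data frame: sample, stimulus_id,
#'   condition) and the montage.
#' @export
simulate_recording <- function(montage, schedule, truth = default_ground_truth(),
                               sample_rate = 500, seed = 1, min_duration_s = 0) {
  stop_if_not(nrow(schedule) >= 1, "empty schedule")
  n_ch <- nrow(montage)
  tail_s <- truth$epoch_ms[2] / 1000 + 1
  n <- ceiling(max(max(schedule$onset_s) + tail_s, min_duration_s) * sample_rate)
  with_seed(seed, {
    # 1/f background, independent per channel
    data <- if (truth$noise$pink_uv > 0) {
      truth$noise$pink_uv * t(spectral_noise(n, truth$noise$exponent, ncol = n_ch))
    } else {
      matrix(0, n_ch, n)
    }
    # band oscillations: a few LRTC-enveloped sources per band, mixed into
    # channels with smooth Gaussian maps around random centre electrodes
    d <- montage_distances(montage)
    sources <- list()
    mix <- list()
    for (b in seq_len(nrow(truth$bands))) {
      band <- truth$bands[b, ]
      if (band$amp_uv <= 0) next
      for (s in seq_len(truth$osc_n_sources)) {
        env <- gen_lrtc_envelope(n, band$hurst, truth$envelope_sigma,
                                 sample_rate = sample_rate)
        sources[[length(sources) + 1L]] <-
          gen_band_oscillation(c(band$low, band$high), env, sample_rate)
        centre <- sample.int(n_ch, 1)
        mix[[length(mix) + 1L]] <- band$amp_uv / sqrt(truth$osc_n_sources) *
          exp(-d[, centre]^2 / (2 * 50^2))
      }
    }
    if (length(sources)) {
      data <- data + do.call(cbind, mix) %*%
        matrix(unlist(sources), nrow = length(sources), byrow = TRUE)
    }
    # stimulus-locked ERP kernels
    templates <- lapply(unique(schedule$condition), gen_erp_template,
                        montage = montage, truth = truth, sample_rate = sample_rate)
    names(templates) <- unique(schedule$condition)
    offset <- round(truth$epoch_ms[1] / 1000 * sample_rate)
    event_sample <- round(schedule$onset_s * sample_rate) + 1L
    for (i in seq_len(nrow(schedule))) {
      tpl <- templates[[schedule$condition[i]]]
      idx <- seq(event_sample[i] + offset, length.out = ncol(tpl))
      keep <- idx >= 1 & idx <= n
      data[, idx[keep]] <- data[, idx[keep]] + tpl[, keep]
    }
    # optional frontal blinks
    if (isTRUE(truth$blinks$enabled)) {
      wav <- truth$blinks$amp_uv * blink_waveform(truth$blinks$duration_ms, sample_rate)
      front <- (montage$y + 1) / 2
      map <- pmax(front, 0)^4
      map <- map / max(map)
      n_blinks <- stats::rpois(1, truth$blinks$rate_per_min * n / sample_rate / 60)
      if (n_blinks > 0) {
        starts <- sort(sample.int(n - length(wav), n_blinks))
        for (s0 in starts) {
          idx <- seq(s0, length.out = length(wav))
          data[, idx] <- data[, idx] + map %*% t(wav)
        }
      }
    }
    eeg_recording(data, sample_rate, montage$name,
                  events = data.frame(sample = event_sample,
                                      stimulus_id = schedule$stimulus_id,
                                      condition = schedule$condition,
                                      stringsAsFactors = FALSE),
                  montage = montage)
  })
}

#' Construct an EEG recording object
#'
#' @param data channels x samples numeric matrix, in uV.
#' @param sfreq Sampling rate in Hz.
#' @param ch_names Channel names (length = nrow(data)).
#' @param events Data frame with columns sample (1-based), stimulus_id,
#'   condition; may have zero rows.
#' @param montage Optional `montage`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, sfreq, ch_names,
                          events = data.frame(sample = integer(),
                                              stimulus_id = character(),
                                              condition = character()),
                          montage = NULL) {
  stop_if_not(is.matrix(data) && nrow(data) == length(ch_names),
              "data must be channels x samples with one name per row")
  stop_if_not(sfreq > 0, "sampling rate must be positive")
  stop_if_not(all(is.finite(data)), "data must be finite")
  if (nrow(events) > 1) {
    stop_if_not(!is.unsorted(events$sample, strictly = TRUE),
                "events must be strictly increasing in time")
  }
  rownames(data) <- ch_names
  structure(list(data = data, sfreq = sfreq, ch_names = ch_names,
                 events = events, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$sfreq, nrow(x$events)))
  invisible(x)
}

#' Simulate a behavioural trial table
#'
#' Trial accuracy follows a mixed-effects logistic model: type fixed effects
#' (derived from the truth's congruent-response probabilities), a
#' standardised neural predictor with type interactions, a subject random
#' intercept with uncorrelated per-type slopes, and item random intercepts.
#' Congruent trials receive the a-priori response; incongruent trials pick
#' one of the two remaining categories in proportion to the truth's response
#' table. Reaction times are log-normal with means per type x congruency.
#'
#' @param schedule A `schedule`.
#' @param truth A `ground_truth`.
#' @param neural Scalar standardised neural predictor for this subject.
#' @param subject Subject identifier.
#' @param seed RNG seed.
#' @param item_effects Optional named vector of item random intercepts
#'   (names = stimulus ids) shared across subjects; drawn if `NULL`.
#' @param subject_effects Optional named vector `c(intercept, dissonant,
#'   neutral)` of this subject's random effects; drawn if `NULL`.
#' @return A `trial_table` data frame: subject, item, stimulus_type,
#'   response, rt_ms, congruent, accuracy.
#' @export
simulate_behaviour <- function(schedule, truth = default_ground_truth(),
                               neural = 0, subject = "S01", seed = 1,
                               item_effects = NULL, subject_effects = NULL) {
  beh <- truth$behaviour
  stop_if_not(all(abs(rowSums(beh$response_probs) - 1) < 1e-8),
              "response probabilities must sum to 1 per stimulus type")
  am <- beh$accuracy_model
  fe <- accuracy_fixed_effects(beh)
  with_seed(seed, {
    items <- unique(schedule$stimulus_id)
    if (is.null(item_effects)) {
      item_effects <- stats::setNames(stats::rnorm(length(items), 0, am$sd_item), items)
    }
    if (is.null(subject_effects)) {
      subject_effects <- c(
        intercept = stats::rnorm(1, 0, am$sd_subj_intercept),
        dissonant = stats::rnorm(1, 0, am$sd_subj_slope_dissonant),
        neutral = stats::rnorm(1, 0, am$sd_subj_slope_neutral)
      )
    }
    type <- schedule$condition
    is_d <- as.numeric(type == "dissonant")
    is_n <- as.numeric(type == "neutral")
    lp <- fe[["intercept"]] + fe[["dissonant"]] * is_d + fe[["neutral"]] * is_n +
      neural * (fe[["pred"]] + fe[["dissonant_pred"]] * is_d + fe[["neutral_pred"]] * is_n) +
      subject_effects[["intercept"]] + subject_effects[["dissonant"]] * is_d +
      subject_effects[["neutral"]] * is_n +
      item_effects[schedule$stimulus_id]
    congruent <- stats::runif(length(lp)) < stats::plogis(lp)
    target <- c(consonant = "pleasant", dissonant = "unpleasant", neutral = "neutral")[type]
    response <- target
    for (i in which(!congruent)) {
      others <- setdiff(colnames(beh$response_probs), target[i])
      pr <- beh$response_probs[type[i], others]
      response[i] <- sample(others, 1, prob = pr / sum(pr))
    }
    congr_col <- ifelse(congruent, "congruent", "incongruent")
    m <- beh$rt_mean_ms[cbind(type, congr_col)]
    meanlog <- log(m) - beh$rt_sdlog^2 / 2
    rt <- stats::rlnorm(length(m), meanlog, beh$rt_sdlog)
    out <- data.frame(
      subject = subject,
      item = schedule$stimulus_id,
      stimulus_type = type,
      response = unname(response),
      rt_ms = rt,
      congruent = congruent,
      accuracy = congruent,
      stringsAsFactors = FALSE
    )
    class(out) <- c("trial_table", "data.frame")
    out
  })
}
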