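# Deflationary fixed-point FastICA (tanh contrast) and ocular component
# removal. Components are rejected only when BOTH their spatial pattern
# matches a frontal template and their time course tracks detected blink
# events; recordings without detectable blinks pass through untouched.

#' FastICA decomposition
#'
#' Whitens the data (PCA, dropping near-zero variance directions) and
#' extracts components one by one with the fixed-point tanh-contrast
#' iteration under deflationary orthogonalisation.
#'
#' @param x channels x samples matrix (row-centred internally).
#' @param n_components Number of components; default = rank after whitening.
#' @param max_iter Maximum fixed-point iterations per component.
#' @param tol Convergence tolerance on the weight update.
#' @param seed Seed for the random initial weights.
#' @return List: `S` (components x samples), `A` (mixing, channels x comps),
#'   `W` (unmixing, comps x channels), `means`, `converged` (per component).
#' @export
fastica <- function(x, n_components = NULL, max_iter = 200, tol = 1e-4,
                    seed = 1) {
  stop_if_not(is.matrix(x) && nrow(x) >= 2, "need a channels x samples matrix")
  n_ch <- nrow(x)
  means <- rowMeans(x)
  xc <- x - means
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-9
  rank <- sum(pos)
  k <- min(n_components %||% rank, rank)
  stop_if_not(k >= 1 && k <= n_ch, "invalid component count")
  D <- eg$values[seq_len(k)]
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  wh <- diag(1 / sqrt(D), k) %*% t(E)       # whitening: k x channels
  dewh <- E %*% diag(sqrt(D), k)            # de-whitening: channels x k
  z <- wh %*% xc
  n <- ncol(z)
  W <- matrix(0, k, k)
  converged <- logical(k)
  with_seed(seed, {
    for (comp in seq_len(k)) {
      w <- stats::rnorm(k)
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wz <- drop(crossprod(w, z))
        g <- tanh(wz)
        gp <- 1 - g^2
        w_new <- drop(z %*% g) / n - mean(gp) * w
        if (comp > 1) {
          proj <- W[seq_len(comp - 1), , drop = FALSE]
          w_new <- w_new - drop(crossprod(proj, proj %*% w_new))
        }
        w_new <- w_new / sqrt(sum(w_new^2))
        delta <- 1 - abs(sum(w_new * w))
        w <- w_new
        if (delta < tol) {
          converged[comp] <- TRUE
          break
        }
      }
      W[comp, ] <- w
    }
  })
  unmix <- W %*% wh          # comps x channels
  mixing <- dewh %*% t(W)    # channels x comps
  list(S = unmix %*% xc, A = mixing, W = unmix, means = means,
       converged = converged)
}

# Blink detection on frontal channels: band-limit to 1-10 Hz, average the
# most anterior channels, and mark well-separated threshold crossings. The
# robust z threshold is high because ocular deflections dwarf background
# EEG on frontal sites; ordinary noise must not trigger the ICA pass.
detect_blink_events <- function(rec, z_threshold = 8, min_gap_s = 0.25) {
  front_idx <- if (!is.null(rec$montage)) {
    order(rec$montage$y, decreasing = TRUE)[seq_len(min(4, nrow(rec$montage)))]
  } else {
    grep("^(Fp|AF)", rec$ch_names)
  }
  if (!length(front_idx)) front_idx <- seq_len(min(4, nrow(rec$data)))
  flt <- butter_design(3, c(1, 10) / (rec$sfreq / 2), "pass")
  f <- filtfilt_zp(flt$b, flt$a, colMeans(rec$data[front_idx, , drop = FALSE]))
  z <- (f - stats::median(f)) / (stats::mad(f) + .Machine$double.eps)
  above <- which(abs(z) > z_threshold)
  if (!length(above)) return(integer(0))
  gaps <- which(diff(above) > min_gap_s * rec$sfreq)
  starts <- c(above[1], above[gaps + 1])
  ends <- c(above[gaps], above[length(above)])
  peaks <- integer(length(starts))
  for (i in seq_along(starts)) {
    seg <- starts[i]:ends[i]
    peaks[i] <- seg[which.max(abs(z[seg]))]
  }
  peaks
}

#' Remove ocular components with FastICA
#'
#' Detects blink events on frontal channels; when present, runs FastICA and
#' zeroes components whose spatial pattern correlates with a frontal
#' template above `spatial_r` AND whose time course correlates with the
#' blink event regressor above `temporal_r`. Without detectable blinks the
#' recording is returned unchanged (there is nothing to regress out).
#'
#' @param rec An `eeg_recording` (>= 30 s of data recommended).
#' @param n_components Components to extract; default = rank.
#' @param spatial_r,temporal_r Rejection thresholds (defaults 0.7 / 0.5).
#' @param seed Seed for FastICA initialisation.
#' @return List: `recording` (cleaned), `report` (data frame of removed
#'   components with their correlations; zero rows when none removed).
#' @export
fastica_remove_ocular <- function(rec, n_components = NULL,
                                  spatial_r = 0.7, temporal_r = 0.5, seed = 1) {
  blinks <- detect_blink_events(rec)
  empty_report <- data.frame(component = integer(), spatial_r = numeric(),
                             temporal_r = numeric())
  if (!length(blinks)) {
    return(list(recording = rec,
                report = structure(empty_report, n_blinks = 0L,
                                   converged = TRUE)))
  }
  ica <- fastica(rec$data, n_components = n_components, seed = seed)
  if (!all(ica$converged)) {
    warning(sprintf("FastICA: %d component(s) did not converge; result is partial",
                    sum(!ica$converged)))
  }
  # frontal spatial template from montage geometry (anterior falloff)
  template <- if (!is.null(rec$montage)) {
    pmax(rec$montage$y, 0)^2
  } else {
    as.numeric(grepl("^(Fp|AF)", rec$ch_names))
  }
  # blink regressor: smoothed impulses at detected events
  n <- ncol(rec$data)
  reg <- numeric(n)
  halfw <- round(0.15 * rec$sfreq)
  kern <- exp(-seq(-halfw, halfw)^2 / (2 * (halfw / 2)^2))
  for (b in blinks) {
    idx <- seq(b - halfw, b + halfw)
    keep <- idx >= 1 & idx <= n
    reg[idx[keep]] <- pmax(reg[idx[keep]], kern[keep])
  }
  k <- ncol(ica$A)
  sp <- vapply(seq_len(k), function(j) {
    abs(stats::cor(abs(ica$A[, j]), template))
  }, numeric(1))
  tp <- vapply(seq_len(k), function(j) {
    abs(stats::cor(abs(ica$S[j, ]), reg))
  }, numeric(1))
  remove <- which(sp > spatial_r & tp > temporal_r)
  out <- rec
  if (length(remove)) {
    S <- ica$S
    S[remove, ] <- 0
    out$data <- ica$A %*% S + ica$means
    rownames(out$data) <- rec$ch_names
  }
  report <- data.frame(component = remove,
                       spatial_r = sp[remove], temporal_r = tp[remove])
  list(recording = out,
       report = structure(report, n_blinks = length(blinks),
                          converged = all(ica$converged)))
}
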