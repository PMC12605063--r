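# ERP statistics: grand averages, global field power (GFP), data-driven
# peak windows, and cluster-based permutation contrasts across electrodes
# using per-channel Wilcoxon signed-rank statistics.

#' Grand average over trials
#'
#' @param epochs An `eeg_epochs`.
#' @param condition Optional condition label; `NULL` averages all trials.
#' @return channels x time matrix with a `times_ms` attribute.
#' @export
grand_average <- function(epochs, condition = NULL) {
  sel <- if (is.null(condition)) rep(TRUE, dim(epochs$data)[1]) else
    epochs$conditions == condition
  stop_if_not(any(sel), "no trials for condition '%s'", condition %||% "<all>")
  avg <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  rownames(avg) <- epochs$ch_names
  attr(avg, "times_ms") <- epochs$times_ms
  avg
}

#' Global field power
#'
#' Per time point, the standard deviation across channels (spatial SD with
#' the instantaneous channel mean removed).
#'
#' @param avg channels x time matrix with a `times_ms` attribute (e.g. from
#'   [grand_average()]), or any matrix plus explicit `times_ms`.
#' @param times_ms Optional time axis override.
#' @return A `gfp_curve` data frame: time_ms, gfp.
#' @export
gfp_curve <- function(avg, times_ms = attr(avg, "times_ms")) {
  stop_if_not(nrow(avg) >= 2, "GFP needs at least 2 channels")
  stop_if_not(!is.null(times_ms) && length(times_ms) == ncol(avg),
              "need a time axis matching the data")
  centred <- sweep(avg, 2, colMeans(avg))
  gfp <- sqrt(colSums(centred^2) / (nrow(avg) - 1))
  structure(data.frame(time_ms = times_ms, gfp = gfp),
            class = c("gfp_curve", "data.frame"))
}

# Peak prominence on a discrete curve: height above the higher of the two
# bases (lowest point between the peak and the nearest higher point, per
# side; curve edge if none).
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    left <- y[seq_len(p - 1)]
    right <- y[seq(p + 1, length(y))]
    higher_l <- which(left > y[p])
    base_l <- if (length(higher_l)) min(y[seq(max(higher_l) + 1, p - 1)]) else min(left)
    higher_r <- which(right > y[p])
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)]) else min(right)
    y[p] - max(base_l, base_r)
  }, numeric(1))
}

#' Select analysis windows from GFP peaks
#'
#' Finds post-stimulus local maxima of the GFP curve, ranks them by
#' prominence (ties broken by earlier latency), and returns windows of
#' peak +/- `half_width_ms` around the `n_peaks` most prominent ones,
#' ordered by latency.
#'
#' @param curve A `gfp_curve`.
#' @param n_peaks Number of windows requested (default 3).
#' @param half_width_ms Half-width of each window in ms (default 10).
#' @return Data frame: peak_ms, start_ms, end_ms, prominence. Fewer rows
#'   than requested (with a warning) when the curve has fewer maxima.
#' @export
select_windows <- function(curve, n_peaks = 3, half_width_ms = 10) {
  stop_if_not(n_peaks >= 1, "n_peaks must be >= 1")
  post <- curve$time_ms > 0
  stop_if_not(any(post), "curve has no post-stimulus samples")
  y <- curve$gfp[post]
  t <- curve$time_ms[post]
  n <- length(y)
  is_peak <- which(y[seq(2, n - 1)] > y[seq(1, n - 2)] &
                     y[seq(2, n - 1)] >= y[seq(3, n)]) + 1L
  if (!length(is_peak)) {
    warning("no local maxima in the post-stimulus GFP curve")
    return(data.frame(peak_ms = numeric(), start_ms = numeric(),
                      end_ms = numeric(), prominence = numeric()))
  }
  prom <- peak_prominence(y, is_peak)
  ord <- order(-prom, t[is_peak]) # prominence desc, earlier latency wins ties
  take <- is_peak[ord][seq_len(min(n_peaks, length(is_peak)))]
  if (length(take) < n_peaks) {
    warning(sprintf("only %d local maxima available (%d requested)",
                    length(take), n_peaks))
  }
  take <- take[order(t[take])]
  data.frame(peak_ms = t[take],
             start_ms = t[take] - half_width_ms,
             end_ms = t[take] + half_width_ms,
             prominence = prom[match(take, is_peak)])
}

#' Per-subject window-mean channel maps
#'
#' For each subject's epochs, the mean over trials of a condition and over a
#' time window, per channel — the unit of observation for the cluster test.
#'
#' @param epochs_list List of `eeg_epochs`, one per subject.
#' @param condition Condition label.
#' @param window_ms Length-2 window in ms.
#' @return subjects x channels matrix.
#' @export
window_mean_maps <- function(epochs_list, condition, window_ms) {
  maps <- t(vapply(epochs_list, function(ep) {
    sel_t <- ep$times_ms >= window_ms[1] & ep$times_ms <= window_ms[2]
    sel_tr <- ep$conditions == condition
    stop_if_not(any(sel_tr), "a subject has no '%s' trials", condition)
    apply(ep$data[sel_tr, , sel_t, drop = FALSE], 2, mean)
  }, numeric(dim(epochs_list[[1]]$data)[2])))
  colnames(maps) <- epochs_list[[1]]$ch_names
  maps
}

# Wilcoxon signed-rank z statistics per column of a subjects x channels
# difference matrix (normal approximation, mid-ranks, zeros dropped).
signed_rank_z <- function(d) {
  apply(d, 2, function(x) {
    x <- x[x != 0]
    n <- length(x)
    if (n < 1) return(0)
    r <- rank(abs(x))
    w <- sum(r[x > 0])
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) return(0)
    (w - mu) / sqrt(sig2)
  })
}

# Connected components of suprathreshold channels with a common sign.
find_clusters <- function(z, threshold, adjacency) {
  supra <- which(abs(z) > threshold)
  clusters <- list()
  visited <- logical(length(z))
  for (s in supra) {
    if (visited[s]) next
    sgn <- sign(z[s])
    queue <- s
    members <- integer(0)
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      members <- c(members, v)
      nb <- which(adjacency[v, ] & !visited & abs(z) > threshold & sign(z) == sgn)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    clusters[[length(clusters) + 1L]] <- members
  }
  clusters
}

#' Cluster-based permutation contrast over electrodes
#'
#' Paired contrast of per-subject channel maps: per channel a Wilcoxon
#' signed-rank z on the condition differences; channels with |z| above the
#' cluster-forming threshold join spatial clusters (same sign, adjacency
#' graph); the cluster mass is the sum of |z|. The null distribution is the
#' maximum cluster mass over random within-subject condition swaps (sign
#' flips of the difference maps), giving family-wise error corrected
#' p-values.
#'
#' @param maps_a,maps_b subjects x channels matrices (paired by row).
#' @param adjacency Logical channel adjacency matrix.
#' @param n_perm Number of permutations (default 800).
#' @param cluster_alpha Two-sided per-channel cluster-forming level
#'   (default 0.05).
#' @param seed RNG seed for the permutation draws.
#' @return A `cluster_result` data frame (one row per cluster): channels
#'   (comma-joined names), n_channels, mass, p, sign; attributes carry the
#'   per-channel z values, threshold and permutation count. Zero rows when
#'   no channel is suprathreshold.
#' @export
cluster_permutation <- function(maps_a, maps_b, adjacency, n_perm = 800,
                                cluster_alpha = 0.05, seed = 1) {
  stop_if_not(all(dim(maps_a) == dim(maps_b)), "paired maps must match in shape")
  n_sub <- nrow(maps_a)
  stop_if_not(n_sub >= 6, "signed-rank permutation needs at least 6 subjects")
  n_ch <- ncol(maps_a)
  stop_if_not(all(dim(adjacency) == c(n_ch, n_ch)), "adjacency must be channels x channels")
  d <- maps_a - maps_b
  threshold <- stats::qnorm(1 - cluster_alpha / 2)
  z_obs <- signed_rank_z(d)
  clusters <- find_clusters(z_obs, threshold, adjacency)
  mass <- vapply(clusters, function(m) sum(abs(z_obs[m])), numeric(1))
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      flips <- sample(c(-1, 1), n_sub, replace = TRUE)
      z_p <- signed_rank_z(d * flips)
      cl <- find_clusters(z_p, threshold, adjacency)
      if (!length(cl)) 0 else max(vapply(cl, function(m) sum(abs(z_p[m])), numeric(1)))
    }, numeric(1))
  })
  p <- vapply(mass, function(m) (1 + sum(null_max >= m)) / (1 + n_perm), numeric(1))
  ch_names <- colnames(maps_a) %||% as.character(seq_len(n_ch))
  out <- data.frame(
    cluster = seq_along(clusters),
    channels = vapply(clusters, function(m) paste(ch_names[m], collapse = ","), character(1)),
    n_channels = lengths(clusters),
    mass = mass,
    sign = vapply(clusters, function(m) sign(z_obs[m[1]]), numeric(1)),
    p = p
  )
  out <- out[order(out$p, -out$mass), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, z = z_obs, threshold = threshold, n_perm = n_perm,
            class = c("cluster_result", "data.frame"))
}
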