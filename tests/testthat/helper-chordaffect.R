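# Shared fixtures and independent oracles, built in code at test time.

# ground truth with all noise sources silenced (ERP kernels only)
quiet_truth <- function() {
  truth <- default_ground_truth()
  truth$noise$pink_uv <- 0
  truth$bands$amp_uv <- rep(0, nrow(truth$bands))
  truth
}

# chord-only stimuli: 800 ms durations guarantee non-overlapping epochs
chord_stimuli_only <- function() {
  Filter(function(s) s$chord$category != "neutral_click", build_stimulus_set())
}

# Independent plain-logistic oracle: iteratively reweighted least squares,
# written from the textbook update (no glm/glmer machinery).
irls_logistic <- function(X, y, max_iter = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- unname(drop(beta_new))
      break
    }
    beta <- unname(drop(beta_new))
  }
  beta
}

# Enumeration oracle for Fisher's test on small r x c tables: recursively
# enumerate all tables with the observed margins, sum the probabilities of
# those at most as probable as the observed table.
fisher_enumerate <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  logp <- function(m) {
    sum(lfactorial(rowSums(m))) + sum(lfactorial(colSums(m))) -
      lfactorial(sum(m)) - sum(lfactorial(m))
  }
  target <- logp(tab)
  total <- 0
  recurse <- function(partial, row) {
    if (row == nrow(tab)) {
      last <- cs - colSums(partial)
      if (all(last >= 0)) {
        m <- rbind(partial, last)
        if (logp(m) <= target + 1e-9) total <<- total + exp(logp(m))
      }
      return(invisible())
    }
    fill_row <- function(cells, col, remaining) {
      if (col == ncol(tab)) {
        recurse(rbind(partial, c(cells, remaining)), row + 1)
        return(invisible())
      }
      avail <- cs[col] - if (nrow(partial)) sum(partial[, col]) else 0
      for (v in 0:min(remaining, avail)) fill_row(c(cells, v), col + 1, remaining - v)
    }
    fill_row(integer(0), 1, rs[row])
  }
  recurse(matrix(0L, 0, ncol(tab)), 1)
  total
}

# Map-level simulator for the cluster permutation experiments: per-subject
# window-mean channel maps = condition template window mean (after CAR, as
# in the pipeline) + iid noise. The noise SD (0.8 uV) was calibrated once
# against full-pipeline window maps at default SNR.
simulate_window_maps <- function(n_subjects, condition, window_ms, montage,
                                 truth = default_ground_truth(),
                                 noise_sd = 0.8, seed = 1) {
  tpl <- gen_erp_template(condition, montage, truth, 250)
  tpl <- sweep(tpl, 2, colMeans(tpl))
  sel <- attr(tpl, "times_ms") >= window_ms[1] & attr(tpl, "times_ms") <= window_ms[2]
  base <- rowMeans(tpl[, sel, drop = FALSE])
  set.seed(seed)
  maps <- matrix(rep(base, each = n_subjects), n_subjects) +
    matrix(stats::rnorm(n_subjects * length(base), 0, noise_sd), n_subjects)
  colnames(maps) <- montage$name
  maps
}
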