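# Behavioural statistics: stimulus x response association (Fisher's exact
# test, exact for 2x2 and Monte-Carlo for larger tables), Kruskal-Wallis
# comparison of reaction times across type x congruency groups, and
# Bonferroni-corrected pairwise Wilcoxon rank-sum post-hocs.

#' Contingency table of stimulus type by response category
#'
#' @param trials A `trial_table`.
#' @return 3x3 integer matrix (rows: consonant/dissonant/neutral, columns:
#'   pleasant/neutral/unpleasant).
#' @export
contingency_table <- function(trials) {
  tab <- table(factor(trials$stimulus_type, c("consonant", "dissonant", "neutral")),
               factor(trials$response, c("pleasant", "neutral", "unpleasant")))
  unclass(as.matrix(tab))
}

#' Fisher's exact test of independence
#'
#' For 2x2 tables the two-sided p is computed exactly by enumerating the
#' hypergeometric support (summing probabilities of tables at most as
#' probable as the observed one). For larger tables a Monte-Carlo p is
#' computed over tables sampled with fixed margins, with the add-one
#' correction (1 + #extreme) / (1 + n_sim).
#'
#' @param tab Matrix of non-negative integer counts.
#' @param n_sim Monte-Carlo sample count for tables larger than 2x2.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return List: `p`, `method` (`"exact"` or `"monte-carlo"`).
#' @export
fisher_exact <- function(tab, n_sim = 1e4, seed = 1) {
  tab <- as.matrix(tab)
  stop_if_not(sum(tab) > 0, "empty table")
  stop_if_not(all(tab >= 0) && all(tab == round(tab)), "counts must be non-negative integers")
  if (all(dim(tab) == c(2, 2))) {
    m <- sum(tab[1, ])
    n <- sum(tab[2, ])
    k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    p_obs <- stats::dhyper(tab[1, 1], m, n, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    return(list(p = min(p, 1), method = "exact"))
  }
  stop_if_not(n_sim >= 1e4, "use at least 10^4 simulations for r x c tables")
  log_p_obs <- table_log_prob(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  extreme <- with_seed(seed, {
    sims <- stats::r2dtable(n_sim, rs, cs)
    sum(vapply(sims, table_log_prob, numeric(1)) <= log_p_obs + 1e-7)
  })
  list(p = (1 + extreme) / (1 + n_sim), method = "monte-carlo")
}

# log probability of a table under the fixed-margins (multivariate
# hypergeometric) null
table_log_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

#' Build reaction-time groups by stimulus type and congruency
#'
#' @param trials A `trial_table`.
#' @return Named list of six RT vectors
#'   (`consonant.congruent`, ..., `neutral.incongruent`); empty groups are
#'   kept as zero-length vectors.
#' @export
rt_groups <- function(trials) {
  congr <- ifelse(trials$congruent, "congruent", "incongruent")
  groups <- split(trials$rt_ms,
                  interaction(factor(trials$stimulus_type,
                                     c("consonant", "dissonant", "neutral")),
                              factor(congr, c("congruent", "incongruent"))))
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with the usual tie correction; p from the
#' chi-square approximation with k - 1 degrees of freedom.
#'
#' @param groups Named list of numeric vectors, all non-empty.
#' @return List: `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(length(groups) >= 2, "need at least two groups")
  stop_if_not(all(lengths(groups) > 0), "all groups must be non-empty")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (correction > 0) h / correction else 0
  df <- length(groups) - 1
  list(statistic = h, df = df, p = stats::pchisq(h, df, lower.tail = FALSE))
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni correction
#'
#' Two-sided rank-sum tests (normal approximation with tie correction) for
#' every unordered pair of groups; adjusted p = min(1, m * p) with m the
#' number of pairs performed.
#'
#' @param groups Named list of numeric vectors.
#' @return Symmetric matrix of Bonferroni-adjusted p-values (NA diagonal).
#' @export
pairwise_wilcoxon_bonferroni <- function(groups) {
  stop_if_not(length(groups) >= 2, "need at least two groups")
  stop_if_not(all(lengths(groups) > 0), "all groups must be non-empty")
  k <- length(groups)
  m <- k * (k - 1) / 2
  out <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      p <- suppressWarnings(
        stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE, correct = TRUE)$p.value
      )
      out[i, j] <- out[j, i] <- min(1, m * p)
    }
  }
  out
}

#' Full behavioural analysis of a trial table
#'
#' @param trials A `trial_table`.
#' @param n_sim Monte-Carlo samples for the association test.
#' @param seed RNG seed.
#' @return List: `counts`, `association` (Fisher p), `kruskal`
#'   (H/df/p over the six RT groups present), `pairwise` (adjusted p
#'   matrix), `rt_means` (per group).
#' @export
behavioural_report <- function(trials, n_sim = 1e4, seed = 1) {
  counts <- contingency_table(trials)
  assoc <- fisher_exact(counts, n_sim = n_sim, seed = seed)
  groups <- Filter(length, rt_groups(trials))
  kw <- kruskal_wallis(groups)
  pw <- pairwise_wilcoxon_bonferroni(groups)
  list(counts = counts, association = assoc, kruskal = kw, pairwise = pw,
       rt_means = vapply(groups, mean, numeric(1)))
}
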