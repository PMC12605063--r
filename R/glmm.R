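# Mixed-effects logistic regression of trial accuracy on stimulus type, a
# standardised neural predictor, and their interaction, with a subject
# random intercept, uncorrelated per-type subject slopes, and item random
# intercepts. Estimation is maximum likelihood via the Laplace
# approximation (lme4 backend).

#' Specify an accuracy model
#'
#' @param predictor Name of the neural predictor column (default
#'   `"neural"`); `NULL` fits a type-only model.
#' @param interaction Include type x predictor interactions (default TRUE).
#' @param reference Reference stimulus type (default `"consonant"`).
#' @param standardise Standardise the predictor to mean 0, SD 1 before
#'   fitting (default TRUE).
#' @return A `glmm_spec` list.
#' @export
glmm_spec <- function(predictor = "neural", interaction = TRUE,
                      reference = "consonant", standardise = TRUE) {
  structure(list(predictor = predictor, interaction = interaction,
                 reference = reference, standardise = standardise),
            class = "glmm_spec")
}

glmm_frame <- function(trials, neural, spec) {
  df <- as.data.frame(trials)
  stop_if_not(length(unique(df$subject)) >= 2, "need at least 2 subjects")
  stop_if_not(length(unique(df$item)) >= 2, "need at least 2 items")
  acc <- as.numeric(df$accuracy)
  stop_if_not(length(unique(acc)) == 2,
              "outcome is degenerate (all %d)", unique(acc)[1])
  df$acc <- acc
  df$stimulus_type <- stats::relevel(factor(df$stimulus_type), spec$reference)
  lev <- levels(df$stimulus_type)
  for (l in lev[-1]) df[[paste0("type_", l)]] <- as.numeric(df$stimulus_type == l)
  scale_info <- NULL
  if (!is.null(spec$predictor)) {
    if (!is.null(neural)) {
      stop_if_not(all(df$subject %in% names(neural)),
                  "neural predictor missing for some subjects")
      df[[spec$predictor]] <- unname(neural[df$subject])
    }
    stop_if_not(spec$predictor %in% names(df),
                "predictor column '%s' not found", spec$predictor)
    x <- df[[spec$predictor]]
    if (isTRUE(spec$standardise)) {
      scale_info <- c(mean = mean(x), sd = stats::sd(x))
      x <- (x - scale_info[["mean"]]) / scale_info[["sd"]]
    }
    df$.pred <- x
  }
  list(df = df, levels = lev, scale = scale_info)
}

glmm_formula <- function(spec, levels) {
  others <- levels[-1]
  fixed <- "stimulus_type"
  if (!is.null(spec$predictor)) {
    fixed <- if (isTRUE(spec$interaction)) "stimulus_type * .pred" else
      paste("stimulus_type + .pred")
  }
  slopes <- paste(sprintf("(0 + type_%s | subject)", others), collapse = " + ")
  stats::as.formula(paste("acc ~", fixed, "+ (1 | subject) +", slopes, "+ (1 | item)"))
}

#' Fit the mixed-effects logistic accuracy model
#'
#' @param trials A `trial_table` (columns subject, item, stimulus_type,
#'   accuracy, and optionally the predictor column).
#' @param neural Named vector of per-subject predictor values (names =
#'   subject ids), or `NULL` when the predictor is already a trial column.
#' @param spec A [glmm_spec()].
#' @param nagq Integration points: 1 = Laplace (default), 0 = faster
#'   penalised-likelihood approximation for large simulation studies.
#' @param random Set `FALSE` to constrain all random-effect variances to
#'   zero, in which case the model reduces exactly to plain logistic
#'   regression (fitted by iteratively reweighted least squares).
#' @return A `glmm_fit`: coefficients table (estimate, se, z, p),
#'   `vcov_names`, `varcor`, `logLik`, `converged`, `n_obs`, the fitted
#'   lme4 model in `$model`, and the predictor scaling used.
#' @export
fit_mixed_logit <- function(trials, neural = NULL, spec = glmm_spec(),
                            nagq = 1, random = TRUE) {
  fr <- glmm_frame(trials, neural, spec)
  if (!isTRUE(random)) {
    fixed <- if (is.null(spec$predictor)) "stimulus_type" else if
      (isTRUE(spec$interaction)) "stimulus_type * .pred" else "stimulus_type + .pred"
    fit <- stats::glm(stats::as.formula(paste("acc ~", fixed)),
                      family = stats::binomial("logit"), data = fr$df,
                      control = stats::glm.control(epsilon = 1e-12))
    sm <- summary(fit)$coefficients
    coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                        z = sm[, 3], p = sm[, 4], row.names = NULL)
    return(structure(list(coefficients = coefs, varcor = NULL,
                          logLik = as.numeric(stats::logLik(fit)),
                          n_par = attr(stats::logLik(fit), "df"),
                          converged = fit$converged, n_obs = nrow(fr$df),
                          scale = fr$scale, spec = spec, model = fit),
                     class = "glmm_fit"))
  }
  form <- glmm_formula(spec, fr$levels)
  fit <- suppressMessages(lme4::glmer(
    form, data = fr$df, family = stats::binomial("logit"), nAGQ = nagq,
    control = lme4::glmerControl(calc.derivs = FALSE,
                                 check.conv.singular = "ignore")
  ))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(list(coefficients = coefs,
                 varcor = lme4::VarCorr(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 n_par = attr(stats::logLik(fit), "df"),
                 converged = conv,
                 n_obs = nrow(fr$df),
                 scale = fr$scale,
                 spec = spec,
                 model = fit),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> logLik = %.2f, %d obs%s\n", x$logLik, x$n_obs,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,reduced `glmm_fit` objects; `reduced` must be nested in
#'   `full` (fewer parameters, same data).
#' @return List: `chisq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stop_if_not(inherits(full, "glmm_fit") && inherits(reduced, "glmm_fit"),
              "both arguments must be glmm_fit objects")
  stop_if_not(full$n_obs == reduced$n_obs, "fits use different data")
  df <- full$n_par - reduced$n_par
  stop_if_not(df >= 0, "reduced model is not nested in full (more parameters)")
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df == 0) {
    if (chisq < 1e-8) 1 else 0
  } else {
    stats::pchisq(chisq, df, lower.tail = FALSE)
  }
  list(chisq = chisq, df = df, p = p)
}

#' Odds ratios with confidence intervals
#'
#' OR = exp(beta), Wald CI = exp(beta +/- z * SE). Extremely wide intervals
#' (upper/lower ratio above 10^3) are flagged, mirroring the caution owed to
#' imbalanced outcomes.
#'
#' @param fit A `glmm_fit`.
#' @param level Confidence level (default 0.95).
#' @return Data frame: term, or, ci_low, ci_high, extreme.
#' @export
odds_ratio_table <- function(fit, level = 0.95) {
  stop_if_not(inherits(fit, "glmm_fit"), "fit must be a glmm_fit")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  cf <- fit$coefficients
  lo <- exp(cf$estimate - zq * cf$se)
  hi <- exp(cf$estimate + zq * cf$se)
  data.frame(term = cf$term, or = exp(cf$estimate),
             ci_low = lo, ci_high = hi,
             extreme = hi / lo > 1e3)
}
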