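# Shared summary of a fitted (g)lmer model into the package's fit contract:
# fixed effects with Wald 95% CIs and p-values, random-intercept variance,
# ML log-likelihood, convergence flag.
summarize_merfit <- function(fit, response, family) {
  co <- lme4::fixef(fit)
  # vcov can fail on exactly-degenerate (zero-residual) fits
  se <- tryCatch(sqrt(diag(as.matrix(stats::vcov(fit)))),
                 error = function(e) rep(NA_real_, length(co)))
  zval <- co / se
  p <- 2 * pnorm(-abs(zval))
  vc <- as.data.frame(lme4::VarCorr(fit))
  grp_var <- vc$vcov[vc$grp != "Residual" & vc$var1 == "(Intercept)" &
                       is.na(vc$var2)][1L]
  msgs <- fit@optinfo$conv$lme4$messages
  # boundary/singular fits are converged fits at the edge of the parameter
  # space; flag them separately rather than as failures
  singular <- lme4::isSingular(fit)
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(msgs) == 0L && fit@optinfo$conv$opt == 0L
  structure(list(
    response = response,
    family = family,
    coefficients = tibble::tibble(
      term = names(co), estimate = unname(co), se = unname(se),
      ci_lower = unname(co - 1.96 * se), ci_upper = unname(co + 1.96 * se),
      z = unname(zval), p = unname(p)),
    group_variance = grp_var,
    log_likelihood = as.numeric(logLik(fit)),
    n_obs = stats::nobs(fit),
    n_groups = lme4::ngrps(fit)[[1L]],
    converged = conv,
    singular = singular,
    fit = fit
  ), class = "reinstatr_fit")
}

#' @export
print.reinstatr_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects %s model: %s ~ %s + (1 | group)\n", x$family,
              x$response,
              paste(setdiff(x$coefficients$term, "(Intercept)"),
                    collapse = " + ")))
  cat(sprintf("  n = %d observations, %d groups; logLik = %.2f%s\n",
              x$n_obs, x$n_groups, x$log_likelihood,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

check_model_inputs <- function(table, response, fixed, group) {
  stopifnot(is.data.frame(table))
  for (v in c(response, fixed, group)) {
    abort_if(!(v %in% names(table)), sprintf("column '%s' not found", v))
  }
  for (v in fixed) {
    x <- table[[v]]
    abort_if(any(!is.finite(x)), sprintf("predictor '%s' has non-finite values", v))
    abort_if(sd(x) == 0, sprintf("degenerate predictor '%s': zero variance", v))
  }
  abort_if(length(unique(table[[group]])) < 2L,
           "need at least 2 grouping levels")
}

model_formula <- function(response, fixed, group) {
  as.formula(paste(response, "~", paste(fixed, collapse = " + "),
                   "+ (1 |", group, ")"))
}

#' Mixed-effects logistic regression with a participant random intercept
#'
#' Fits a binomial GLMM (logit link, Laplace approximation, maximum
#' likelihood) predicting a binary outcome -- canonically temporal-memory
#' precision (high = 1, low = 0) -- from similarity and log-lag covariates,
#' with a random intercept per participant. Predictors enter unstandardized;
#' coefficients are on the log-odds scale with Wald z tests.
#'
#' @param table data frame holding response, predictors and grouping column.
#' @param response name of the binary response column (0/1).
#' @param fixed character vector of predictor column names.
#' @param group name of the grouping (participant) column.
#' @param standardize if `TRUE`, scale predictors to unit sd first.
#' @return A `reinstatr_fit` object; check `$converged` before use.
#' @export
fit_mixed_logistic <- function(table, response, fixed, group = "participant_id",
                               standardize = FALSE) {
  check_model_inputs(table, response, fixed, group)
  y <- table[[response]]
  abort_if(!all(y %in% c(0, 1)), "response must be binary 0/1")
  abort_if(length(unique(y)) < 2L, "response has a single class")
  # response constant within every group: the likelihood is maximized by a
  # diverging random-intercept spread; refuse rather than return a silent fit
  const_within <- tapply(y, table[[group]], function(v)
    length(unique(v)) == 1L)
  abort_if(all(const_within),
           "degenerate response: constant within every group")
  dat <- table[, c(response, fixed, group)]
  dat[[group]] <- factor(dat[[group]])
  if (standardize) for (v in fixed) dat[[v]] <- as.numeric(scale(dat[[v]]))
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(model_formula(response, fixed, group), data = dat,
                family = stats::binomial(),
                control = lme4::glmerControl(
                  optimizer = "bobyqa", optCtrl = list(maxfun = 1e5)))))
  summarize_merfit(fit, response, "binomial")
}

#' Mixed-effects linear regression with a participant random intercept
#'
#' Gaussian analogue of [fit_mixed_logistic()], canonically with recognition
#' confidence (1-6, treated as numeric) as the response. Fitted by maximum
#' likelihood (not REML) so that nested fits are comparable by likelihood
#' ratio.
#'
#' @inheritParams fit_mixed_logistic
#' @return A `reinstatr_fit` object.
#' @export
fit_mixed_linear <- function(table, response, fixed, group = "participant_id",
                             standardize = FALSE) {
  check_model_inputs(table, response, fixed, group)
  dat <- table[, c(response, fixed, group)]
  dat[[group]] <- factor(dat[[group]])
  if (standardize) for (v in fixed) dat[[v]] <- as.numeric(scale(dat[[v]]))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(model_formula(response, fixed, group), data = dat,
               REML = FALSE)))
  summarize_merfit(fit, response, "gaussian")
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' `chi2 = -2 (logL_reduced - logL_full)`, with degrees of freedom equal to
#' the difference in fixed-effect counts and an upper-tail chi-squared
#' p-value. Both fits must be maximum-likelihood fits of the same data with
#' nested fixed effects.
#'
#' @param full,reduced `reinstatr_fit` objects.
#' @return List of class `reinstatr_lrt`: `chi2`, `df`, `p`, model labels.
#' @export
likelihood_ratio <- function(full, reduced) {
  stopifnot(inherits(full, "reinstatr_fit"), inherits(reduced, "reinstatr_fit"))
  abort_if(full$n_obs != reduced$n_obs,
           "models were fitted to different numbers of observations")
  tf <- full$coefficients$term
  tr <- reduced$coefficients$term
  abort_if(!all(tr %in% tf), "models are not nested (reduced has extra terms)")
  abort_if(!full$converged || !reduced$converged,
           "both fits must have converged")
  chi2 <- -2 * (reduced$log_likelihood - full$log_likelihood)
  abort_if(chi2 < -1e-6,
           "negative likelihood-ratio statistic; fits are inconsistent")
  chi2 <- max(chi2, 0)
  df <- length(tf) - length(tr)
  # identical fixed-effect sets: a degenerate comparison with no evidence
  # either way (chi2 must be ~0, p = 1)
  abort_if(df == 0L && chi2 > 1e-6,
           "identical fixed effects but different likelihoods")
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  structure(list(chi2 = chi2, df = df, p = p,
                 full_model = paste(setdiff(tf, "(Intercept)"), collapse = "+"),
                 reduced_model = paste(setdiff(tr, "(Intercept)"),
                                       collapse = "+")),
            class = "reinstatr_lrt")
}

#' @export
print.reinstatr_lrt <- function(x, ...) {
  cat(sprintf("LRT [%s] vs [%s]: chi2(%d) = %.3f, p = %.4g\n",
              x$full_model, x$reduced_model, x$df, x$chi2, x$p))
  invisible(x)
}

#' Bonferroni adjustment of p-values
#'
#' @param p_values p-values in `[0, 1]`.
#' @param m number of tests (defaults to `length(p_values)`; must be at least
#'   that many).
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  abort_if(any(p_values < 0 | p_values > 1), "p-values must lie in [0, 1]")
  abort_if(m < length(p_values),
           "m must be at least the number of p-values")
  pmin(1, m * p_values)
}

#' @importFrom lme4 GHrule glFormula mkGlmerDevfun optimizeGlmer
NULL

# ---- fast refitting machinery for permutation nulls -------------------------
#
# A logistic GLMM permutation null needs hundreds of refits where only a few
# predictor columns change. We build the lme4 model structure once
# (glFormula), then per permutation overwrite the changed columns of the
# fixed-effects matrix and prior weights (weight 0 = excluded row) and
# re-optimize at nAGQ = 0. The estimator is identical for the observed and
# every null fit, preserving exchangeability.

perm_refitter_control <- function() {
  lme4::glmerControl(calc.derivs = FALSE,
                     check.conv.grad = "ignore",
                     check.conv.singular = "ignore",
                     check.conv.hess = "ignore")
}

# Build the reusable structure. `table` must contain response, fixed, group.
make_perm_refitter <- function(table, response, fixed, group) {
  dat <- table[, c(response, fixed, group)]
  dat[[group]] <- factor(dat[[group]])
  dat$`(wts)` <- 1
  ctrl <- perm_refitter_control()
  form <- as.formula(paste(response, "~", paste(fixed, collapse = " + "),
                           "+ (1 |", group, ")"))
  pf <- lme4::glFormula(form, data = dat, family = stats::binomial(),
                        weights = `(wts)`, control = ctrl)
  list(pf = pf, ctrl = ctrl, fixed = fixed)
}

# Refit with some columns replaced and/or row weights changed; returns the
# fixed-effect vector (named). `columns` is a named list of replacement
# vectors; `weights` a 0/1 vector (1 = keep row).
perm_refit <- function(rf, columns = list(), weights = NULL) {
  pf <- rf$pf
  for (nm in names(columns)) pf$X[, nm] <- columns[[nm]]
  if (!is.null(weights)) pf$fr[["(weights)"]] <- weights
  devfun <- do.call(lme4::mkGlmerDevfun, c(pf, list(control = rf$ctrl)))
  opt <- suppressWarnings(lme4::optimizeGlmer(devfun))
  beta <- environment(devfun)$pp$beta(1)
  names(beta) <- colnames(pf$X)
  beta
}
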