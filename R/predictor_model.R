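#' Logistic regression for profile membership
#'
#' Binary logistic regression fitted by iteratively reweighted least squares
#' (via [stats::glm()]), reported as a term table with odds ratios, Wald
#' standard errors, 95% confidence intervals `exp(coef +- 1.96*SE)` and Wald
#' p-values. Rank-deficient design matrices are rejected; (quasi-)complete
#' separation is flagged with the offending term names.
#'
#' @param data data.frame containing the outcome and covariates.
#' @param outcome Name of the binary (0/1 or logical) outcome column.
#' @param terms Character vector of covariate terms.
#' @return Object of class `pa_logistic`: list with `model` (the glm),
#'   `table` (term, estimate, SE, OR, CI, p), `intercept`, `AIC`, `BIC`,
#'   `separation_flags`.
#' @export
fit_logistic <- function(data, outcome, terms) {
  f <- stats::as.formula(paste(outcome, "~",
                               if (length(terms)) paste(terms, collapse = " + ")
                               else "1"))
  mm <- stats::model.matrix(f, data)
  if (qr(mm)$rank < ncol(mm)) {
    stop("design matrix is rank deficient; drop redundant covariates")
  }
  fit <- stats::glm(f, data = data, family = stats::binomial())
  cf <- summary(fit)$coefficients
  sep <- rownames(cf)[abs(cf[, "Estimate"]) > 10 | cf[, "Std. Error"] > 10]
  sep <- setdiff(sep, "(Intercept)")
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  tab <- data.frame(
    term = rownames(cf), estimate = est, se = se,
    or = exp(est),
    ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
    p = cf[, "Pr(>|z|)"], row.names = NULL)
  tab <- tab[tab$term != "(Intercept)", ]
  structure(list(model = fit, table = tab,
                 intercept = unname(est["(Intercept)"]),
                 AIC = stats::AIC(fit), BIC = stats::BIC(fit),
                 separation_flags = sep,
                 converged = fit$converged),
            class = "pa_logistic")
}

#' Backward elimination of candidate predictors
#'
#' Starting from the full model (forced terms plus all candidates),
#' repeatedly removes the candidate whose removal most improves the
#' information criterion, until no removal improves it. Forced terms are
#' never removed. The elimination trace records the criterion before and
#' after each step.
#'
#' @param data data.frame of outcome and covariates.
#' @param outcome Binary outcome column name.
#' @param forced Terms always retained (e.g. gender, age, randomisation).
#' @param candidates Terms subject to elimination.
#' @param criterion `"AIC"` (default) or `"BIC"`.
#' @return List: `fit` (final [fit_logistic()] object), `trace` (data.frame
#'   with step, dropped term, criterion before/after), `retained`,
#'   `eliminated`.
#' @export
backward_eliminate <- function(data, outcome, forced, candidates,
                               criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  ic <- function(f) f[[criterion]]
  current <- candidates
  fit <- fit_logistic(data, outcome, c(forced, current))
  trace <- data.frame(step = integer(0), dropped = character(0),
                      ic_before = numeric(0), ic_after = numeric(0))
  step <- 0L
  while (length(current)) {
    drops <- vapply(current, function(tm) {
      ic(fit_logistic(data, outcome, c(forced, setdiff(current, tm))))
    }, 0)
    if (min(drops) >= ic(fit)) break
    step <- step + 1L
    worst <- names(drops)[which.min(drops)]
    trace <- rbind(trace, data.frame(step = step, dropped = worst,
                                     ic_before = ic(fit),
                                     ic_after = min(drops)))
    current <- setdiff(current, worst)
    fit <- fit_logistic(data, outcome, c(forced, current))
  }
  list(fit = fit, trace = trace, retained = c(forced, current),
       eliminated = setdiff(candidates, current))
}

#' Regression diagnostics for a fitted logistic model
#'
#' Three conventional checks: (a) logit linearity per continuous covariate
#' via a Box-Tidwell interaction term `x * log(x)` (flagged when its Wald p
#' is below `alpha`; covariates with non-positive values are shifted to be
#' positive first); (b) predictor intercorrelation via variance inflation
#' factors on the linear design, flagged above `vif_limit`; (c) influence
#' via Cook's distance, flagged above `4/n`.
#'
#' @param fit A `pa_logistic` object.
#' @param data The data used to fit it.
#' @param continuous Names of continuous covariates to Box-Tidwell check;
#'   defaults to numeric model terms with more than 10 distinct values.
#' @param alpha Significance level for the linearity flag.
#' @param vif_limit VIF threshold.
#' @return List with `box_tidwell`, `vif`, `influence` components, each
#'   containing values and flags.
#' @export
logistic_diagnostics <- function(fit, data, continuous = NULL,
                                 alpha = 0.05, vif_limit = 5) {
  stopifnot(inherits(fit, "pa_logistic"))
  model <- fit$model
  terms_used <- attr(stats::terms(model), "term.labels")
  if (is.null(continuous)) {
    continuous <- terms_used[vapply(terms_used, function(tm) {
      tm %in% names(data) && is.numeric(data[[tm]]) &&
        length(unique(data[[tm]])) > 10
    }, TRUE)]
  }
  outcome <- as.character(stats::formula(model))[2]

  bt <- lapply(continuous, function(tm) {
    x <- data[[tm]]
    shift <- if (min(x) <= 0) 1 - min(x) else 0
    d2 <- data
    d2$.bt <- (x + shift) * log(x + shift)
    f2 <- stats::glm(
      stats::as.formula(paste(outcome, "~",
                              paste(c(terms_used, ".bt"), collapse = " + "))),
      data = d2, family = stats::binomial())
    p <- summary(f2)$coefficients[".bt", "Pr(>|z|)"]
    c(p = p)
  })
  bt_p <- vapply(bt, `[[`, 0, "p")
  names(bt_p) <- continuous

  mm <- stats::model.matrix(model)[, -1, drop = FALSE]
  vif <- if (ncol(mm) >= 2) {
    vapply(seq_len(ncol(mm)), function(j) {
      f <- stats::lm.fit(cbind(1, mm[, -j, drop = FALSE]), mm[, j])
      r2 <- 1 - sum(f$residuals^2) / sum((mm[, j] - mean(mm[, j]))^2)
      1 / (1 - min(r2, 1 - 1e-12))
    }, 0)
  } else rep(1, ncol(mm))
  names(vif) <- colnames(mm)

  cook <- stats::cooks.distance(model)
  n <- length(cook)
  list(
    box_tidwell = list(p = bt_p, flagged = names(bt_p)[bt_p < alpha]),
    vif = list(values = vif,
               flagged = names(vif)[vif > vif_limit]),
    influence = list(cooks = cook, cutoff = 4 / n,
                     flagged = which(cook > 4 / n)))
}
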