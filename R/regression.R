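#' @title Regression models for DGT-measured cadmium
#' @description Two ordinary-least-squares models link the DGT-measured
#'   cadmium concentration to intact soil properties and dose, with
#'   log10 [Cd_DGT] as the response:
#'
#'   * per-level: `log10(cd_dgt) = b1*cec + b2*ph + intercept`, fitted
#'     separately at each Cd addition level;
#'   * full interaction:
#'     `log10(cd_dgt) = b1*cec + b2*ph + b3*log10(cd_add) +
#'      b4*(ph*log10(cd_add)) + intercept`, fitted across levels; the
#'     interaction term carries the dose dependence of the pH effect.
#'
#'   [Cd_DGT] enters in ug/L, so only the intercept depends on the unit.
#'   Zero-addition control rows are excluded by the caller (the log of the
#'   dose is undefined there).
#' @name cd_dgt_regression
NULL

.check_positive_response <- function(data) {
  bad <- which(!(data$cd_dgt > 0))
  if (length(bad) > 0) {
    id <- if ("sample_id" %in% names(data)) data$sample_id[bad[1]] else bad[1]
    stop("cd_dgt must be > 0 to take logs; offending sample: ", id,
         call. = FALSE)
  }
}

.new_cd_dgt_fit <- function(lm_fit, model_tag, key_map, standardized,
                            scale_sd = NULL) {
  s <- summary(lm_fit)$coefficients
  rn <- rownames(s)
  keys <- unname(key_map[rn])
  fit <- list(
    coefficients = stats::setNames(s[, "Estimate"], keys),
    standard_errors = stats::setNames(s[, "Std. Error"], keys),
    t_values = stats::setNames(s[, "t value"], keys),
    p_values = stats::setNames(s[, "Pr(>|t|)"], keys),
    significance = stats::setNames(
      stats::symnum(s[, "Pr(>|t|)"], corr = FALSE, na = FALSE,
                    cutpoints = c(0, 0.001, 0.01, 0.05, 1),
                    symbols = c("***", "**", "*", "")), keys),
    n_obs = length(stats::residuals(lm_fit)),
    residual_df = stats::df.residual(lm_fit),
    r_squared = summary(lm_fit)$r.squared,
    model_tag = model_tag,
    standardized = standardized,
    scale_sd = scale_sd,
    lm = lm_fit
  )
  if (fit$residual_df == 0) {
    warning("saturated fit: zero residual degrees of freedom; standard ",
            "errors are undefined", call. = FALSE)
  }
  structure(fit, class = "cd_dgt_fit")
}

.check_full_rank <- function(lm_fit) {
  p <- length(stats::coef(lm_fit))
  if (lm_fit$rank < p || anyNA(stats::coef(lm_fit))) {
    stop("singular design: regressors are collinear", call. = FALSE)
  }
}

#' Fit the per-level CEC/pH model
#'
#' OLS of `log10(cd_dgt)` on `cec` and `ph` for the observations at one Cd
#' addition level.
#'
#' @param data data frame with columns `cec`, `ph`, `cd_dgt` (ug/L) and,
#'   if `cd_add_level` is given, `cd_add` (mg/kg).
#' @param cd_add_level optional addition level to filter `data` on.
#' @param standardize if `TRUE`, z-score the regressors (sample SD,
#'   denominator n-1) before fitting, so coefficients are per-SD effects.
#' @return a `cd_dgt_fit` with coefficient keys `b1_cec`, `b2_ph`,
#'   `intercept`.
#' @export
fit_per_level <- function(data, cd_add_level = NULL, standardize = FALSE) {
  if (!is.null(cd_add_level)) {
    data <- data[data$cd_add == cd_add_level, , drop = FALSE]
  }
  if (nrow(data) < 4) {
    stop("need at least 4 observations at this level", call. = FALSE)
  }
  .check_positive_response(data)
  d <- data.frame(y = log10(data$cd_dgt), cec = data$cec, ph = data$ph)
  scale_sd <- NULL
  if (standardize) {
    scale_sd <- c(b1_cec = stats::sd(d$cec), b2_ph = stats::sd(d$ph))
    if (any(scale_sd == 0)) stop("zero-variance regressor", call. = FALSE)
    d$cec <- as.numeric(scale(d$cec))
    d$ph <- as.numeric(scale(d$ph))
  }
  fit <- stats::lm(y ~ cec + ph, data = d)
  .check_full_rank(fit)
  .new_cd_dgt_fit(fit, "per_level",
                  c("(Intercept)" = "intercept", cec = "b1_cec",
                    ph = "b2_ph"),
                  standardize, scale_sd)
}

#' Fit the full interaction model
#'
#' OLS of `log10(cd_dgt)` on `cec`, `ph`, `log10(cd_add)` and the
#' `ph * log10(cd_add)` interaction, pooling all addition levels.
#'
#' @param data data frame with columns `cec`, `ph`, `cd_add` (mg/kg, all
#'   strictly positive; filter out zero-addition controls first) and
#'   `cd_dgt` (ug/L).
#' @param standardize as in [fit_per_level()]; the interaction column is
#'   the product of the two standardized parents.
#' @return a `cd_dgt_fit` with coefficient keys `b1_cec`, `b2_ph`,
#'   `b3_logcd`, `b4_interaction`, `intercept`.
#' @export
fit_full <- function(data, standardize = FALSE) {
  if (any(!(data$cd_add > 0))) {
    stop("cd_add must be > 0 (zero-addition control rows are not part of ",
         "the dose-response model); filter them out first", call. = FALSE)
  }
  if (nrow(data) < 6 || length(unique(data$cd_add)) < 2) {
    stop("need >= 6 observations spanning >= 2 addition levels",
         call. = FALSE)
  }
  .check_positive_response(data)
  d <- data.frame(y = log10(data$cd_dgt), cec = data$cec, ph = data$ph,
                  logcd = log10(data$cd_add))
  scale_sd <- NULL
  if (standardize) {
    scale_sd <- c(b1_cec = stats::sd(d$cec), b2_ph = stats::sd(d$ph),
                  b3_logcd = stats::sd(d$logcd))
    if (any(scale_sd == 0)) stop("zero-variance regressor", call. = FALSE)
    d$cec <- as.numeric(scale(d$cec))
    d$ph <- as.numeric(scale(d$ph))
    d$logcd <- as.numeric(scale(d$logcd))
  }
  d$ph_logcd <- d$ph * d$logcd
  fit <- stats::lm(y ~ cec + ph + logcd + ph_logcd, data = d)
  .check_full_rank(fit)
  .new_cd_dgt_fit(fit, "full_interaction",
                  c("(Intercept)" = "intercept", cec = "b1_cec",
                    ph = "b2_ph", logcd = "b3_logcd",
                    ph_logcd = "b4_interaction"),
                  standardize, scale_sd)
}

#' @export
print.cd_dgt_fit <- function(x, digits = 3, ...) {
  cat("log10[Cd_DGT] regression (", x$model_tag,
      if (x$standardized) ", standardized regressors", "), n = ", x$n_obs,
      ", R2 = ", round(x$r_squared, 3), "\n", sep = "")
  tab <- data.frame(estimate = round(x$coefficients, digits),
                    se = round(x$standard_errors, digits),
                    t = round(x$t_values, digits),
                    sig = unname(as.character(x$significance)))
  print(tab)
  invisible(x)
}

#' Predict [Cd_DGT] for a soil and dose
#'
#' Evaluates the full interaction model at the given intact CEC, intact pH
#' and Cd addition, returning the prediction on the concentration scale
#' (10^linear predictor, ug/L) with an interval computed from the fit's
#' covariance on the log10 scale and back-transformed.
#'
#' @param fit a `cd_dgt_fit` with `model_tag == "full_interaction"` fitted
#'   on raw (unstandardized) regressors.
#' @param cec cation exchange capacity, cmol/kg; vectorized.
#' @param ph intact soil pH.
#' @param cd_add cadmium addition, mg/kg (> 0).
#' @param level coverage of the interval.
#' @param interval `"prediction"` (default, includes residual noise) or
#'   `"confidence"` (mean response only).
#' @return data frame with `cd_dgt` (ug/L), `lower`, `upper` and
#'   `log10_cd_dgt`.
#' @export
predict_cd_dgt <- function(fit, cec, ph, cd_add, level = 0.95,
                           interval = c("prediction", "confidence")) {
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "cd_dgt_fit"))
  if (fit$model_tag != "full_interaction") {
    stop("prediction requires a full_interaction fit, not '",
         fit$model_tag, "'", call. = FALSE)
  }
  if (fit$standardized) {
    stop("predict on the raw-scale fit, not the standardized one",
         call. = FALSE)
  }
  if (any(!(cd_add > 0))) stop("cd_add must be > 0", call. = FALSE)
  nd <- data.frame(cec = cec, ph = ph, logcd = log10(cd_add))
  nd$ph_logcd <- nd$ph * nd$logcd
  pr <- stats::predict(fit$lm, newdata = nd, interval = interval,
                       level = level)
  data.frame(cd_dgt = 10^pr[, "fit"], lower = 10^pr[, "lwr"],
             upper = 10^pr[, "upr"], log10_cd_dgt = pr[, "fit"])
}
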