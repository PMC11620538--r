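# Total-effect estimation and the sensitivity analyses around it.

# Internal: covariate design matrix (no intercept column) for a study frame.
# Cohort enters as a covariate only when the study has >1 cohort and cohort
# is listed (or covariates = NULL meaning "all").
study_design <- function(study, covariates = covariate_names(study)) {
  covariates <- covariates %||% character(0)
  bad <- setdiff(covariates, c(covariate_names(study), "cohort"))
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  df <- as.data.frame(study)[, setdiff(covariates, "cohort"), drop = FALSE]
  if ("cohort" %in% covariates && nlevels(study$cohort) > 1)
    df$cohort <- study$cohort
  if (ncol(df) == 0) return(matrix(nrow = nrow(study), ncol = 0))
  model.matrix(~ ., data = df)[, -1, drop = FALSE]
}

#' Total effect of exposure on outcome
#'
#' Fits the covariate-adjusted linear model `outcome ~ exposure + covariates`
#' by OLS and returns the exposure coefficient gamma -- the total effect, in
#' SD-outcome per SD-exposure when both are standardized -- with its Wald
#' 95% confidence interval (t critical values) and two-sided p-value. This
#' gamma is the denominator of every percent-total-effect-mediated value
#' downstream.
#'
#' @param study a [study_frame()].
#' @param covariates character vector of covariate names to adjust for
#'   (may include `"cohort"`); default: all covariates in the study frame.
#' @param conf confidence level (default 0.95).
#' @return object of class `"total_effect"`: list with `gamma`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n`, `df`.
#' @export
total_effect <- function(study, covariates = covariate_names(study),
                         conf = 0.95) {
  W <- study_design(study, covariates)
  X <- cbind(`(Intercept)` = 1, exposure = study$exposure, W)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("collinear design: rank ", qrX$rank, " < ", ncol(X), " columns")
  y <- study$outcome
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  n <- nrow(X); df <- n - ncol(X)
  sigma2 <- sum(res^2) / df
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * XtX_inv[2, 2])
  gamma <- unname(beta["exposure"])
  tcrit <- qt(1 - (1 - conf) / 2, df)
  p <- if (se > 0) 2 * pt(-abs(gamma / se), df) else as.numeric(gamma == 0)
  structure(list(gamma = gamma, se = se,
                 ci_low = gamma - tcrit * se, ci_high = gamma + tcrit * se,
                 p = p, n = n, df = df),
            class = "total_effect")
}

#' @export
print.total_effect <- function(x, ...) {
  cat(sprintf("total effect gamma = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n = %d\n",
              x$gamma, x$se, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Forward selection of covariates by change-in-estimate
#'
#' Starting from the base adjustment set, iteratively adds the candidate
#' covariate that produces the largest relative change in the exposure
#' coefficient gamma; a candidate is retained only if the change exceeds
#' `threshold` (default 10%). Ties are broken by covariate name. Stops when
#' no remaining candidate qualifies.
#'
#' @param study a [study_frame()].
#' @param base covariates always retained (the minimal adjustment set).
#' @param candidates covariates to test.
#' @param threshold relative change-in-estimate needed for retention
#'   (default 0.10).
#' @return character vector: base covariates followed by retained
#'   candidates, with attribute `trace` (data.frame of decisions).
#' @export
forward_select_covariates <- function(study, base = character(0),
                                      candidates, threshold = 0.10) {
  selected <- base
  remaining <- setdiff(candidates, base)
  trace <- list()
  gamma_cur <- total_effect(study, selected)$gamma
  while (length(remaining)) {
    gammas <- vapply(remaining, function(cand)
      total_effect(study, c(selected, cand))$gamma, numeric(1))
    if (abs(gamma_cur) > 1e-12) {
      change <- abs(gammas - gamma_cur) / abs(gamma_cur)
    } else {
      message("current gamma ~ 0; using absolute change in estimate")
      change <- abs(gammas - gamma_cur)
    }
    ord <- order(-change, remaining)
    best <- remaining[ord[1]]
    trace[[length(trace) + 1]] <-
      data.frame(candidate = best, change = change[ord[1]],
                 retained = change[ord[1]] > threshold)
    if (change[ord[1]] <= threshold) break
    selected <- c(selected, best)
    gamma_cur <- gammas[best]
    remaining <- setdiff(remaining, best)
  }
  structure(selected,
            trace = if (length(trace)) do.call(rbind, trace) else
              data.frame(candidate = character(0), change = numeric(0),
                         retained = logical(0)))
}

#' Fixed-effects meta-analysis with Cochran's Q heterogeneity test
#'
#' Pools per-group (per-cohort) estimates by inverse-variance weighting and
#' tests between-group heterogeneity with Cochran's Q against a chi-squared
#' distribution on groups-1 degrees of freedom.
#'
#' @param estimates numeric vector of per-group effect estimates.
#' @param ses positive numeric vector of their standard errors.
#' @param labels optional group labels.
#' @return object of class `"meta_result"`: list with `per_group`
#'   (data.frame), `pooled`, `pooled_se`, `Q`, `df_Q`, `p_het`.
#' @export
fixed_effects_meta <- function(estimates, ses, labels = NULL) {
  k <- length(estimates)
  if (k < 2) stop("need at least 2 groups to meta-analyze")
  if (length(ses) != k) stop("estimates and ses must have equal length")
  if (any(ses <= 0)) stop("standard errors must be positive")
  if (is.null(labels)) labels <- paste0("group", seq_len(k))
  w <- 1 / ses^2
  pooled <- sum(w * estimates) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  Q <- sum(w * (estimates - pooled)^2)
  df_Q <- k - 1L
  structure(list(per_group = data.frame(label = labels,
                                        estimate = estimates, se = ses),
                 pooled = pooled, pooled_se = pooled_se,
                 Q = Q, df_Q = df_Q,
                 p_het = pchisq(Q, df_Q, lower.tail = FALSE)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("fixed-effects pooled = %.4f (SE %.4f); Q = %.3f on %d df, p_het = %.3g\n",
              x$pooled, x$pooled_se, x$Q, x$df_Q, x$p_het))
  invisible(x)
}

#' Robustness value for unmeasured confounding
#'
#' The robustness value is the minimum strength of association (partial
#' R-squared, identical with the residual variance of the exposure and of
#' the outcome) that an unmeasured confounder would need with both in order
#' to reduce the observed exposure coefficient to a fraction `1 - q` of
#' itself (q = 1: to zero). Computed from the t statistic of the exposure
#' coefficient via the partial Cohen's f: `f = q |t| / sqrt(df)`, then
#' `RV = (sqrt(f^4 + 4 f^2) - f^2) / 2`.
#'
#' @param t t statistic of the exposure coefficient (gamma / se).
#' @param df residual degrees of freedom of the model.
#' @param q fraction of the estimate to be explained away (default 1).
#' @return robustness value as a fraction in `[0, 1)`.
#' @export
#' @examples
#' robustness_value(t = sqrt(415), df = 415)  # f = 1 -> (sqrt(5) - 1) / 2
robustness_value <- function(t, df, q = 1) {
  if (df <= 0) stop("df must be positive")
  f <- q * abs(t) / sqrt(df)
  0.5 * (sqrt(f^4 + 4 * f^2) - f^2)
}
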