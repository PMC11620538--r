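# High-dimensional mediation: early / intermediate / late integration.
#
# Early and late integration follow the screen -> penalized outcome model ->
# debiased refit -> joint-significance recipe; intermediate integration uses
# layer-specific penalty multipliers (group-lasso-type shrinkage per layer)
# with bootstrap SEs for the penalized coefficients.

# Vectorized per-feature exposure->feature OLS (alpha) with SE and p, via
# Frisch-Waugh-Lovell on the covariate-residualized exposure.
.alpha_ols <- function(feats, study, covariates) {
  W <- study_design(study, covariates)
  n <- nrow(feats)
  X <- cbind(1, W, exposure = study$exposure)
  qrX <- qr(X)
  ex <- .resid_on(study$exposure, W)
  sxx <- sum(ex^2)
  alpha <- as.vector(crossprod(ex, feats) / sxx)
  E <- feats - X %*% qr.coef(qrX, feats)
  df <- n - qrX$rank
  s2 <- colSums(E^2) / df
  se <- sqrt(s2 / sxx)
  p <- 2 * pt(-abs(alpha / se), df)
  data.frame(alpha = alpha, se_alpha = se, p_alpha = p)
}

# Penalized outcome model: lasso on features with exposure (and covariates)
# unpenalized. pf_features: per-feature penalty multipliers.
.penalized_outcome_fit <- function(feats, study, covariates, pf_features,
                                   foldid) {
  W <- study_design(study, covariates)
  Z <- cbind(feats, exposure = study$exposure, W)
  pf <- c(pf_features, rep(0, 1 + ncol(W)))
  cv <- glmnet::cv.glmnet(Z, study$outcome, foldid = foldid,
                          penalty.factor = pf, standardize = FALSE)
  co <- coef(cv, s = "lambda.1se")
  beta_feat <- as.vector(co)[1 + seq_len(ncol(feats))]
  list(cv = cv, lambda = cv$lambda.1se,
       cvm_min = min(cv$cvm),
       beta = setNames(beta_feat, colnames(feats)),
       design = Z, n_unpen = 1 + ncol(W))
}

.seeded_foldid <- function(n, nfolds, seed) {
  set.seed(seed)
  sample(rep(seq_len(nfolds), length.out = n))
}

.as_feature_matrix <- function(omics) {
  if (inherits(omics, "multi_omics")) {
    feats <- concat_layers(omics)
  } else {
    feats <- as.matrix(omics)
    if (is.null(colnames(feats)))
      colnames(feats) <- paste0("f", seq_len(ncol(feats)))
    attr(feats, "layer_of") <- rep("omics", ncol(feats))
  }
  feats
}

.mediation_table <- function(feats, ao, beta, se_beta, p_beta, selected,
                             gamma, fdr = 0.05, conf = 0.95) {
  p <- ncol(feats)
  layer_of <- attr(feats, "layer_of")
  ids <- colnames(feats)
  tab <- data.frame(layer = layer_of, feature_id = ids,
                    alpha = ao$alpha, se_alpha = ao$se_alpha,
                    beta = NA_real_, se_beta = NA_real_,
                    indirect = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, fdr_q = NA_real_,
                    pct_te = NA_real_, selected = selected,
                    significant = FALSE, row.names = NULL)
  if (any(selected)) {
    sel <- which(selected)
    tab$beta[sel] <- beta[sel]
    tab$se_beta[sel] <- se_beta[sel]
    tab$indirect[sel] <- tab$alpha[sel] * beta[sel]
    cis <- t(vapply(sel, function(j)
      prodclin_ci(tab$alpha[j], tab$se_alpha[j], beta[j], se_beta[j],
                  conf = conf), numeric(2)))
    tab$ci_low[sel] <- cis[, 1]
    tab$ci_high[sel] <- cis[, 2]
    # joint significance: a mediated path needs both legs nonzero
    tab$p[sel] <- pmax(ao$p_alpha[sel], p_beta[sel])
    tab$fdr_q[sel] <- p.adjust(tab$p[sel], method = "BH")
    tab$significant[sel] <- tab$fdr_q[sel] < fdr
    if (abs(gamma) > .Machine$double.eps) {
      tab$pct_te[sel] <- 100 * tab$indirect[sel] / gamma
    } else {
      attr(tab, "pct_te_defined") <- FALSE
    }
  }
  attr(tab, "gamma") <- gamma
  tab
}

#' High-dimensional mediation with early integration
#'
#' Concatenates all (preselected, standardized) omics layers and fits one
#' penalized regression of the outcome on every feature plus the exposure
#' and covariates, with only the features penalized (lasso; 10-fold
#' cross-validation, one-standard-error rule, seeded folds). Features with
#' a nonzero penalized coefficient are refit jointly by OLS to obtain
#' debiased mediator-to-outcome coefficients and standard errors; the
#' exposure-to-mediator coefficients come from per-feature OLS. Indirect
#' effects `alpha * beta` get distribution-of-the-product confidence
#' intervals, joint-significance p-values (max of the two marginal
#' p-values) with Benjamini-Hochberg correction across selected features,
#' and a percent-total-effect-mediated relative to the total effect gamma.
#'
#' @param omics a [multi_omics()] (preselected layers) or a single numeric
#'   feature matrix.
#' @param study a [study_frame()] with scaled exposure/outcome.
#' @param covariates covariate names to adjust for (default: all).
#' @param seed integer seed controlling the cross-validation folds.
#' @param nfolds CV folds (default 10).
#' @param fdr FDR level for the significance flag (default 0.05).
#' @param conf confidence level for the indirect-effect CIs.
#' @return a mediation table: data.frame with one row per feature and
#'   columns `layer`, `feature_id`, `alpha`, `se_alpha`, `beta`, `se_beta`,
#'   `indirect`, `ci_low`, `ci_high`, `p`, `fdr_q`, `pct_te`, `selected`,
#'   `significant`; attribute `gamma` carries the total effect. Rows for
#'   unselected features keep `NA` in the outcome-side columns.
#' @export
mediate_early <- function(omics, study,
                          covariates = covariate_names(study),
                          seed = 1, nfolds = 10, fdr = 0.05, conf = 0.95) {
  feats <- .as_feature_matrix(omics)
  gamma <- total_effect(study, covariates)$gamma
  ao <- .alpha_ols(feats, study, covariates)
  foldid <- .seeded_foldid(nrow(feats), nfolds, seed)
  fit <- .penalized_outcome_fit(feats, study, covariates,
                                pf_features = rep(1, ncol(feats)),
                                foldid = foldid)
  selected <- fit$beta != 0
  beta <- se_beta <- p_beta <- rep(NA_real_, ncol(feats))
  if (any(selected)) {
    W <- study_design(study, covariates)
    X <- cbind(1, feats[, selected, drop = FALSE],
               exposure = study$exposure, W)
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop("selected-feature refit design is collinear")
    cf <- qr.coef(qrX, study$outcome)
    res <- study$outcome - X %*% cf
    df <- nrow(X) - ncol(X)
    s2 <- sum(res^2) / df
    covm <- s2 * chol2inv(qr.R(qrX))
    idx <- 1 + seq_len(sum(selected))
    beta[selected] <- cf[idx]
    se_beta[selected] <- sqrt(diag(covm)[idx])
    p_beta[selected] <- 2 * pt(-abs(beta[selected] / se_beta[selected]), df)
  }
  tab <- .mediation_table(feats, ao, beta, se_beta, p_beta, selected,
                          gamma, fdr, conf)
  attr(tab, "lambda") <- fit$lambda
  tab
}

#' High-dimensional mediation with intermediate integration
#'
#' A two-step product-of-coefficients procedure in which all layers are
#' modeled jointly but the lasso penalty is allowed to differ between
#' layers (group-lasso-type shrinkage per layer). Step 1 estimates each
#' exposure-to-mediator coefficient by OLS. Step 2 fits a single penalized
#' regression of the outcome on all features (exposure and covariates
#' unpenalized) with one penalty multiplier per layer, tuned over a 5-point
#' log-spaced grid by coordinate search against the cross-validation error;
#' the penalized coefficients are reported as-is, with standard errors from
#' a nonparametric (case-resampling) bootstrap at the tuned penalty. Step 3
#' forms indirect effects and distribution-of-the-product CIs per feature.
#'
#' @inheritParams mediate_early
#' @param omics a [multi_omics()] with at least two layers.
#' @param bootstrap_B bootstrap resamples for the coefficient SEs
#'   (default 200; fewer than 50 triggers a warning).
#' @param multipliers optional fixed per-layer penalty multipliers
#'   (named or in layer order); `NULL` tunes them. Forcing all multipliers
#'   equal reproduces the early-integration selection exactly.
#' @param mult_grid candidate multipliers for tuning.
#' @return a mediation table as in [mediate_early()], with attributes
#'   `multipliers` (per layer) and `lambda`.
#' @export
mediate_intermediate <- function(omics, study,
                                 covariates = covariate_names(study),
                                 bootstrap_B = 200, multipliers = NULL,
                                 mult_grid = c(0.25, 0.5, 1, 2, 4),
                                 seed = 1, nfolds = 10, fdr = 0.05,
                                 conf = 0.95) {
  if (!inherits(omics, "multi_omics") || length(omics) < 2)
    stop("intermediate integration needs a multi_omics with >= 2 layers")
  empty <- vapply(omics, ncol, integer(1)) == 0
  if (any(empty)) {
    message("layer(s) with no retained features skipped: ",
            paste(names(omics)[empty], collapse = ", "))
    omics <- multi_omics(omics[!empty],
                         sample_ids = attr(omics, "sample_ids"))
  }
  if (bootstrap_B < 50)
    warning("bootstrap_B < 50: bootstrap standard errors will be unstable")
  feats <- .as_feature_matrix(omics)
  layer_of <- attr(feats, "layer_of")
  layers <- names(omics)
  gamma <- total_effect(study, covariates)$gamma
  ao <- .alpha_ols(feats, study, covariates)
  foldid <- .seeded_foldid(nrow(feats), nfolds, seed)

  pf_of <- function(mult) mult[match(layer_of, layers)]
  if (is.null(multipliers)) {
    mult <- setNames(rep(1, length(layers)), layers)
    for (l in layers) {
      scores <- vapply(mult_grid, function(v) {
        m <- mult; m[l] <- v
        .penalized_outcome_fit(feats, study, covariates, pf_of(m),
                               foldid)$cvm_min
      }, numeric(1))
      # deterministic tie-break: least-shrunk (smallest multiplier) wins
      mult[l] <- mult_grid[which.min(round(scores, 12))]
    }
  } else {
    mult <- multipliers
    if (is.null(names(mult))) mult <- setNames(rep_len(mult, length(layers)),
                                               layers)
  }
  fit <- .penalized_outcome_fit(feats, study, covariates, pf_of(mult),
                                foldid)
  beta <- fit$beta
  selected <- beta != 0

  # case-resampling bootstrap of the penalized fit at the tuned penalty
  W <- study_design(study, covariates)
  Z <- cbind(feats, exposure = study$exposure, W)
  pf <- c(pf_of(mult), rep(0, 1 + ncol(W)))
  lam_seq <- fit$cv$lambda
  set.seed(seed + 1L)
  n <- nrow(Z)
  boot <- matrix(NA_real_, bootstrap_B, ncol(feats))
  for (bi in seq_len(bootstrap_B)) {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- glmnet::glmnet(Z[idx, , drop = FALSE], study$outcome[idx],
                         lambda = lam_seq, penalty.factor = pf,
                         standardize = FALSE)
    boot[bi, ] <- as.vector(coef(bf, s = fit$lambda))[1 + seq_len(ncol(feats))]
  }
  se_beta <- apply(boot, 2, sd)
  p_beta <- 2 * pnorm(-abs(beta / se_beta))
  p_beta[se_beta == 0] <- NA_real_
  tab <- .mediation_table(feats, ao, beta, se_beta, p_beta, selected,
                          gamma, fdr, conf)
  attr(tab, "multipliers") <- mult
  attr(tab, "lambda") <- fit$lambda
  tab
}

#' High-dimensional mediation with late integration
#'
#' Runs [mediate_early()] independently on each omics layer (no cross-layer
#' conditioning) and tags each result with its layer. With a single layer
#' this is identical to early integration on that layer.
#'
#' @inheritParams mediate_early
#' @param omics a [multi_omics()] (each layer already preselected).
#' @return named list of per-layer mediation tables (class
#'   `"mediation_by_layer"`); combine with [combine_mediation_tables()].
#' @export
mediate_late <- function(omics, study,
                         covariates = covariate_names(study),
                         seed = 1, nfolds = 10, fdr = 0.05, conf = 0.95) {
  if (!inherits(omics, "multi_omics"))
    omics <- multi_omics(list(omics = as.matrix(omics)))
  out <- lapply(names(omics), function(nm) {
    sub <- multi_omics(unclass(omics)[nm],
                       sample_ids = attr(omics, "sample_ids"))
    mediate_early(sub, study, covariates, seed = seed, nfolds = nfolds,
                  fdr = fdr, conf = conf)
  })
  names(out) <- names(omics)
  class(out) <- "mediation_by_layer"
  out
}

#' Combine per-layer mediation tables into one table
#' @param tables a `"mediation_by_layer"` list from [mediate_late()].
#' @return single mediation data.frame.
#' @export
combine_mediation_tables <- function(tables) {
  out <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(out) <- NULL
  out
}
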