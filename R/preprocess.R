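#' Harmonize cord-blood mercury to maternal whole-blood scale
#'
#' Cord whole-blood total mercury runs systematically higher than maternal
#' whole-blood mercury; dividing cord values by 1.7 places both matrices on
#' a common scale so cohorts measured in different compartments can be
#' analyzed together.
#'
#' @param values non-negative numeric vector of total mercury concentrations.
#' @param is_cord logical vector, `TRUE` where the measurement comes from
#'   cord blood.
#' @return numeric vector: cord entries divided by 1.7, others unchanged.
#' @export
#' @examples
#' harmonize_cord_mercury(c(1.7, 3.4, 5), c(TRUE, TRUE, FALSE))
harmonize_cord_mercury <- function(values, is_cord) {
  if (!is.numeric(values)) stop("values must be numeric")
  if (anyNA(values) || anyNA(is_cord)) stop("missing values not allowed")
  if (any(values < 0)) stop("mercury concentrations must be non-negative")
  if (length(is_cord) != length(values))
    stop("is_cord must match values in length")
  values[is_cord] <- values[is_cord] / 1.7
  values
}

#' Scale a variable to mean 0, SD 1 within groups
#'
#' Standardizes within each group (typically cohort) so that between-group
#' location/scale differences cannot confound downstream associations. The
#' SD uses the n-1 denominator.
#'
#' @param x numeric vector.
#' @param groups group labels, one per element of `x`.
#' @return numeric vector with per-group mean 0 and SD 1.
#' @export
scale_within_groups <- function(x, groups) {
  if (length(groups) != length(x)) stop("groups must match x in length")
  if (anyNA(x)) stop("missing values not allowed")
  groups <- as.factor(groups)
  out <- x
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2)
      stop("group '", g, "' has fewer than 2 observations")
    s <- sd(x[idx])
    if (s == 0)
      stop("variable is constant within group '", g, "'")
    out[idx] <- (x[idx] - mean(x[idx])) / s
  }
  out
}

#' Residualize omics features on covariates and standardize
#'
#' Replaces each feature column by the residual of an OLS regression of the
#' feature on the covariates (with intercept), studentized by the residual
#' standard error, and rescales each column to mean 0, SD 1. The output
#' columns are exactly uncorrelated with every covariate column, and the
#' operation is idempotent. Features with (near-)zero residual variance are
#' dropped with a warning; features with < `impute_max` fraction missing are
#' mean-imputed first, features above it are dropped.
#'
#' Categorical covariates are dummy-coded against their first factor level.
#' The studentization uses a constant leverage factor (the average hat
#' value); a per-row factor is absorbed by the final rescaling only up to
#' that row weighting, and would break the exact orthogonality to the
#' covariates that downstream mediation models assume.
#'
#' @param layer numeric matrix, samples x features.
#' @param covariates data.frame of covariates (rows matching `layer`), or
#'   `NULL`/zero-column for intercept-only (plain column z-scoring).
#' @param impute_max maximum tolerated missing fraction per feature before
#'   the feature is dropped instead of mean-imputed (default 0.05).
#' @return numeric matrix with the retained features, each column mean 0,
#'   SD 1 and uncorrelated with the covariates.
#' @export
residualize_features <- function(layer, covariates = NULL,
                                 impute_max = 0.05) {
  layer <- as.matrix(layer)
  n <- nrow(layer)

  # missingness policy: mean-impute light missingness, drop heavy
  miss_frac <- colMeans(is.na(layer))
  if (any(miss_frac > impute_max)) {
    drop <- which(miss_frac > impute_max)
    warning(length(drop), " feature(s) dropped: missing fraction > ",
            impute_max)
    layer <- layer[, -drop, drop = FALSE]
    miss_frac <- miss_frac[-drop]
  }
  if (any(miss_frac > 0)) {
    for (j in which(miss_frac > 0)) {
      nas <- is.na(layer[, j])
      layer[nas, j] <- mean(layer[!nas, j])
    }
  }

  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1)
  } else {
    covariates <- as.data.frame(covariates)
    chr <- vapply(covariates, is.character, logical(1))
    covariates[chr] <- lapply(covariates[chr], factor)
    X <- model.matrix(~ ., data = covariates)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("covariate design matrix is rank deficient")
  if (n <= ncol(X) + 1)
    stop("need more samples than covariate columns + 1")

  E <- layer - X %*% qr.coef(qrX, layer)   # residuals, exactly orthogonal to X
  df <- n - qrX$rank
  rss <- colSums(E^2)
  keep <- rss / n > 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " feature(s) dropped: zero residual variance ",
            "(collinear with covariates)")
    E <- E[, keep, drop = FALSE]
    rss <- rss[keep]
  }
  h_bar <- qrX$rank / n                     # average leverage
  E <- sweep(E, 2, sqrt(rss / df) * sqrt(1 - h_bar), "/")
  # final column standardization (residuals already have mean 0)
  E <- sweep(E, 2, colMeans(E), "-")
  E <- sweep(E, 2, apply(E, 2, sd), "/")
  E
}

#' Standardize exposure, outcome and all omics layers for mediation
#'
#' Convenience wrapper applying the canonical preprocessing pipeline:
#' within-cohort scaling of exposure and (continuous) outcome, optional
#' log-transform of the exposure beforehand, and covariate residualization
#' + standardization of every omics layer.
#'
#' @param study a [study_frame()].
#' @param omics a [multi_omics()] aligned to `study` (see [align_samples()]).
#' @param log_exposure log-transform the exposure before scaling (mercury
#'   and similar biomonitoring measures are right-skewed; default FALSE).
#' @param scale_outcome scale the outcome within cohorts (set FALSE for a
#'   binary outcome; default TRUE).
#' @return list with elements `study` (scaled) and `omics` (residualized).
#' @export
preprocess_study <- function(study, omics, log_exposure = FALSE,
                             scale_outcome = TRUE) {
  omics <- align_samples(study, omics)
  x <- study$exposure
  if (log_exposure) {
    if (any(x <= 0)) stop("log transform requires positive exposure values")
    x <- log(x)
  }
  study$exposure <- scale_within_groups(x, study$cohort)
  if (scale_outcome)
    study$outcome <- scale_within_groups(study$outcome, study$cohort)
  covs <- as.data.frame(study)[, covariate_names(study), drop = FALSE]
  if (nlevels(study$cohort) > 1)
    covs <- cbind(covs, cohort = study$cohort)
  layers <- lapply(omics, residualize_features, covariates = covs)
  list(study = study, omics = multi_omics(layers,
                                          sample_ids = study$sample_id))
}
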