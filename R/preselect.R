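# Meet-in-the-middle screening with a sure-independence-screening budget.

#' Sure-independence-screening feature budget
#'
#' The total number of omics features carried into the final mediation
#' models is `2 n / log(n)` (natural log, n = study sample size), rounded up
#' to the nearest multiple of five, then divided across layers with a
#' per-layer ceiling so each layer receives an equal integer share.
#'
#' @param n study sample size (>= 8).
#' @param n_layers number of omics layers (>= 1).
#' @return list with `raw` (2n/log(n)), `total` (final budget =
#'   `per_layer * n_layers`) and `per_layer`.
#' @export
#' @examples
#' sis_feature_budget(420, 5)  # 140 features overall, 28 per layer
sis_feature_budget <- function(n, n_layers) {
  if (n_layers < 1) stop("n_layers must be >= 1")
  if (n < 8) stop("n must be >= 8")
  raw <- 2 * n / log(n)
  total0 <- 5 * ceiling(raw / 5)
  per_layer <- as.integer(ceiling(total0 / n_layers))
  list(raw = raw, total = per_layer * as.integer(n_layers),
       per_layer = per_layer)
}

# Internal: residualize a vector/matrix on [1, W].
.resid_on <- function(M, W) {
  X <- cbind(1, W)
  M - X %*% qr.coef(qr(X), M)
}

#' Meet-in-the-middle feature screening
#'
#' Ranks the features of one omics layer by the product of their
#' exposure-side and outcome-side regression coefficients: alpha is the
#' exposure coefficient in `feature ~ exposure + covariates`, beta the
#' feature coefficient in `outcome ~ feature + exposure + covariates`. The
#' product alpha*beta estimates each feature's potential mediating effect;
#' features are ranked by `|alpha * beta|` descending (ties by feature ID)
#' and the top `k` retained.
#'
#' @param layer numeric matrix samples x features (residualized).
#' @param study a [study_frame()] with scaled exposure/outcome.
#' @param covariates covariate names to adjust for (default: all).
#' @param k number of features to retain (e.g. the per-layer
#'   [sis_feature_budget()]); if `k >= p` all features are retained.
#' @param layer_name label recorded in the output table.
#' @return data.frame ("screen table") with columns `layer`, `feature_id`,
#'   `alpha`, `beta`, `product`, `rank`, `retained`, ordered by rank.
#' @export
meet_in_middle_rank <- function(layer, study,
                                covariates = covariate_names(study),
                                k, layer_name = "layer") {
  layer <- as.matrix(layer)
  p <- ncol(layer)
  if (k < 1) stop("k must be >= 1")
  if (k > p)
    message("k = ", k, " exceeds p = ", p, "; retaining all features")
  W <- study_design(study, covariates)
  # Frisch-Waugh-Lovell: coefficients via residualized regressors
  ex <- .resid_on(study$exposure, W)                 # exposure | covariates
  alpha <- as.vector(crossprod(ex, layer) / sum(ex^2))
  WX <- cbind(W, exposure = study$exposure)
  rm_feat <- .resid_on(layer, WX)                    # feature | covs+exposure
  ry <- .resid_on(study$outcome, WX)
  beta <- as.vector(crossprod(rm_feat, ry) / colSums(rm_feat^2))
  prod_ab <- alpha * beta
  ids <- colnames(layer) %||% paste0("f", seq_len(p))
  ord <- order(-abs(prod_ab), ids)
  rank <- integer(p); rank[ord] <- seq_len(p)
  data.frame(layer = layer_name, feature_id = ids,
             alpha = alpha, beta = beta, product = prod_ab,
             rank = rank, retained = rank <= k,
             row.names = NULL)[ord, , drop = FALSE]
}

#' Screen every layer of a multi-omics container
#'
#' Applies [meet_in_middle_rank()] per layer with the per-layer
#' [sis_feature_budget()] (or an explicit budget) and returns both the
#' combined screen table and the pruned `multi_omics` of retained features.
#'
#' @param omics a [multi_omics()] aligned with `study`.
#' @param study a [study_frame()].
#' @param covariates covariate names to adjust for.
#' @param budget `"auto"` (SIS rule) or an integer per-layer budget.
#' @return list with `table` (combined screen table), `omics` (retained
#'   features only) and `budget` (the budget actually used).
#' @export
preselect_features <- function(omics, study,
                               covariates = covariate_names(study),
                               budget = "auto") {
  if (identical(budget, "auto")) {
    b <- sis_feature_budget(nrow(study), length(omics))
    k <- b$per_layer
  } else {
    k <- as.integer(budget)
    b <- list(total = k * length(omics), per_layer = k)
  }
  tabs <- lapply(names(omics), function(nm)
    meet_in_middle_rank(omics[[nm]], study, covariates, k = k,
                        layer_name = nm))
  tab <- do.call(rbind, tabs)
  kept <- lapply(names(omics), function(nm) {
    ids <- tab$feature_id[tab$layer == nm & tab$retained]
    omics[[nm]][, ids, drop = FALSE]
  })
  names(kept) <- names(omics)
  list(table = tab,
       omics = multi_omics(kept, sample_ids = attr(omics, "sample_ids")),
       budget = b)
}
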