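# Mediation with latent factors: PCA (early/late) and joint-and-individual
# variance decomposition (intermediate), followed by component-level
# mediation and feature-component correlation export.

.fix_signs <- function(scores, loadings) {
  # component signs are arbitrary; anchor the largest-|loading| feature > 0
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

.factor_model <- function(scores, loadings, source, explained_variance,
                          ranks, objective_trace = NULL, converged = TRUE) {
  structure(list(scores = scores, loadings = loadings, source = source,
                 explained_variance = explained_variance, ranks = ranks,
                 objective_trace = objective_trace, converged = converged),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("factor_model: ", ncol(x$scores), " component(s) [",
      paste(unique(x$source), collapse = ", "), "], ",
      nrow(x$scores), " samples\n", sep = "")
  invisible(x)
}

#' Principal-component factors retaining a variance threshold
#'
#' SVD-based principal components of a (column-standardized) matrix; the
#' smallest leading set of components whose cumulative explained variance
#' reaches `var_threshold` is retained. Component signs are anchored so the
#' largest-magnitude loading is positive.
#'
#' @param X numeric matrix, samples x features (columns standardized).
#' @param var_threshold fraction of variance to capture, in (0, 1]
#'   (default 0.80).
#' @param source_name label recorded for these components (default
#'   `"joint"`; use the layer name for per-layer/late integration).
#' @return a `"factor_model"`: list with `scores` (samples x components),
#'   `loadings` (list, one matrix per source), `source` (per component),
#'   `explained_variance` (per component, fractions of total), `ranks`.
#' @export
pca_factors <- function(X, var_threshold = 0.80, source_name = "joint") {
  if (var_threshold <= 0 || var_threshold > 1)
    stop("var_threshold must be in (0, 1]")
  X <- as.matrix(X)
  X <- sweep(X, 2, colMeans(X), "-")
  sv <- svd(X)
  ev <- sv$d^2 / sum(sv$d^2)
  r <- which(cumsum(ev) >= var_threshold - 1e-12)[1]
  scores <- sv$u[, seq_len(r), drop = FALSE] %*%
    diag(sv$d[seq_len(r)], r, r)
  loadings <- sv$v[, seq_len(r), drop = FALSE]
  rownames(loadings) <- colnames(X)
  comp_ids <- paste0(source_name, "_c", seq_len(r))
  colnames(scores) <- colnames(loadings) <- comp_ids
  rownames(scores) <- rownames(X)
  fs <- .fix_signs(scores, loadings)
  .factor_model(fs$scores, setNames(list(fs$loadings), source_name),
                rep(source_name, r), setNames(ev[seq_len(r)], comp_ids),
                ranks = setNames(list(r), source_name))
}

# Largest singular values of a column-bound list of matrices.
.stack_sv <- function(mats) svd(do.call(cbind, mats), nu = 0, nv = 0)$d

#' Joint-and-individual variance decomposition across omics layers
#'
#' Decomposes multiple column-centered layers sharing one sample index into
#' a rank-`r_J` joint component (sample-space structure common to all
#' layers), rank-`r_i` layer-individual components orthogonal to the joint
#' sample space, and residual: `X_i = J_i + A_i + E_i`. Layers are scaled
#' to unit Frobenius norm first so high-dimensional layers do not dominate
#' the joint fit. Estimation alternates a truncated SVD of the concatenated
#' joint-candidate matrix with per-layer truncated SVDs of the
#' joint-orthogonalized residuals until the total residual sum of squares
#' stabilizes.
#'
#' Ranks may be given explicitly or selected by permutation: sample order
#' is permuted independently within each layer (destroying cross-layer
#' alignment while preserving within-layer covariance) and the observed
#' singular values of the concatenation are compared with the 95th
#' percentile of the permuted leading singular value; individual ranks use
#' the analogous within-column permutation of the joint-residual layer.
#'
#' @param layers a [multi_omics()] or list of >= 2 numeric matrices
#'   (samples x features) sharing sample order.
#' @param ranks `"permutation"` (default) or a list
#'   `list(joint = r_J, individual = c(r_1, ..., r_L))`.
#' @param n_perm permutations for rank selection (default 100).
#' @param seed integer seed for the permutations.
#' @param tol relative residual-sum-of-squares convergence tolerance.
#' @param max_iter maximum alternations (default 500).
#' @return a `"factor_model"` whose components are tagged `"joint"` or with
#'   their layer name; `objective_trace` records the (non-increasing)
#'   residual sum of squares per iteration and `converged` the convergence
#'   status.
#' @export
jive_decompose <- function(layers, ranks = "permutation", n_perm = 100,
                           seed = 1, tol = 1e-6, max_iter = 500) {
  if (inherits(layers, "multi_omics")) layers <- unclass(layers)
  if (!is.list(layers) || length(layers) < 2)
    stop("need at least 2 layers")
  if (is.null(names(layers)))
    names(layers) <- paste0("layer", seq_along(layers))
  n <- unique(vapply(layers, nrow, integer(1)))
  if (length(n) != 1) stop("layers must share the sample count")
  X <- lapply(layers, function(m) {
    m <- as.matrix(m)
    m <- sweep(m, 2, colMeans(m), "-")
    m / sqrt(sum(m^2))
  })
  L <- length(X)
  max_rank <- min(n - 1, sum(vapply(X, ncol, integer(1))))

  if (identical(ranks, "permutation")) {
    set.seed(seed)
    obs <- .stack_sv(X)
    null1 <- replicate(n_perm, {
      .stack_sv(lapply(X, function(m) m[sample.int(n), , drop = FALSE]))[1]
    })
    r_J <- sum(obs > quantile(null1, 0.95))
    r_J <- min(r_J, max_rank)
    U_J <- if (r_J > 0) svd(do.call(cbind, X), nu = r_J, nv = 0)$u else
      matrix(0, n, 0)
    r_i <- vapply(seq_len(L), function(i) {
      R <- X[[i]] - U_J %*% crossprod(U_J, X[[i]])
      obs_i <- svd(R, nu = 0, nv = 0)$d
      null_i <- replicate(n_perm, {
        Rp <- apply(R, 2, sample)
        svd(Rp, nu = 0, nv = 0)$d[1]
      })
      min(sum(obs_i > quantile(null_i, 0.95)), min(n - 1, ncol(R)))
    }, numeric(1))
    r_i <- as.integer(r_i)
  } else {
    r_J <- as.integer(ranks$joint)
    r_i <- as.integer(rep_len(ranks$individual, L))
  }

  # alternating estimation
  A <- lapply(X, function(m) m * 0)
  J <- A
  obj <- numeric(0)
  converged <- FALSE
  U_J <- matrix(0, n, 0)
  D_J <- numeric(0)
  V_J <- matrix(0, sum(vapply(X, ncol, integer(1))), 0)
  ind_sv <- vector("list", L)
  for (it in seq_len(max_iter)) {
    C <- do.call(cbind, Map(`-`, X, A))
    if (r_J > 0) {
      sv <- svd(C, nu = r_J, nv = r_J)
      U_J <- sv$u
      D_J <- sv$d[seq_len(r_J)]
      V_J <- sv$v
      Jfull <- U_J %*% (D_J * t(V_J))
    } else {
      Jfull <- C * 0
    }
    p_idx <- split(seq_len(ncol(C)),
                   rep(seq_len(L), vapply(X, ncol, integer(1))))
    for (i in seq_len(L)) {
      J[[i]] <- Jfull[, p_idx[[i]], drop = FALSE]
      R <- X[[i]] - J[[i]]
      if (r_J > 0) R <- R - U_J %*% crossprod(U_J, R)
      if (r_i[i] > 0) {
        svi <- svd(R, nu = r_i[i], nv = r_i[i])
        ind_sv[[i]] <- svi
        A[[i]] <- svi$u %*% (svi$d[seq_len(r_i[i])] * t(svi$v))
      } else {
        A[[i]] <- R * 0
        ind_sv[[i]] <- NULL
      }
    }
    obj <- c(obj, sum(vapply(seq_len(L), function(i)
      sum((X[[i]] - J[[i]] - A[[i]])^2), numeric(1))))
    if (it > 1 && abs(obj[it - 1] - obj[it]) <=
        tol * max(obj[it - 1], .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("joint/individual decomposition did not converge in ",
            max_iter, " iterations; returning last iterate")

  total_ss <- L  # each layer scaled to unit Frobenius norm
  scores <- matrix(0, n, 0)
  loadings <- list()
  source <- character(0)
  ev <- numeric(0)
  feat_ids <- unlist(lapply(names(X), function(nm)
    paste(nm, colnames(X[[nm]]) %||% paste0("f", seq_len(ncol(X[[nm]]))),
          sep = ".")))
  if (r_J > 0) {
    ld <- V_J * 1  # loadings in concatenated feature space
    rownames(ld) <- feat_ids
    ids <- paste0("joint_c", seq_len(r_J))
    sc <- U_J %*% diag(D_J, r_J, r_J)
    colnames(sc) <- colnames(ld) <- ids
    fs <- .fix_signs(sc, ld)
    scores <- cbind(scores, fs$scores)
    loadings$joint <- fs$loadings
    source <- c(source, rep("joint", r_J))
    ev <- c(ev, setNames(D_J^2 / total_ss, ids))
  }
  for (i in seq_len(L)) {
    if (r_i[i] == 0) next
    nm <- names(X)[i]
    svi <- ind_sv[[i]]
    d <- svi$d[seq_len(r_i[i])]
    sc <- svi$u %*% diag(d, r_i[i], r_i[i])
    ld <- svi$v
    rownames(ld) <- colnames(X[[i]]) %||% paste0("f", seq_len(ncol(X[[i]])))
    ids <- paste0(nm, "_c", seq_len(r_i[i]))
    colnames(sc) <- colnames(ld) <- ids
    fs <- .fix_signs(sc, ld)
    scores <- cbind(scores, fs$scores)
    loadings[[nm]] <- fs$loadings
    source <- c(source, rep(nm, r_i[i]))
    ev <- c(ev, setNames(d^2 / total_ss, ids))
  }
  rownames(scores) <- rownames(layers[[1]])
  .factor_model(scores, loadings, source, ev,
                ranks = list(joint = r_J,
                             individual = setNames(r_i, names(X))),
                objective_trace = obj, converged = converged)
}

#' Latent factors under early, intermediate or late integration
#'
#' Early: PCA of the concatenated layers. Intermediate: joint-and-individual
#' decomposition ([jive_decompose()]). Late: PCA per layer, components
#' tagged by layer.
#'
#' @param omics a [multi_omics()].
#' @param mode `"early"`, `"intermediate"` or `"late"`.
#' @param var_threshold PCA variance threshold (early/late; default 0.80).
#' @param ... further arguments passed to [jive_decompose()]
#'   (intermediate).
#' @return a `"factor_model"`.
#' @export
latent_factors <- function(omics, mode = c("early", "intermediate", "late"),
                           var_threshold = 0.80, ...) {
  mode <- match.arg(mode)
  if (mode == "early")
    return(pca_factors(concat_layers(omics), var_threshold, "joint"))
  if (mode == "intermediate")
    return(jive_decompose(omics, ...))
  fms <- lapply(names(omics), function(nm)
    pca_factors(omics[[nm]], var_threshold, source_name = nm))
  scores <- do.call(cbind, lapply(fms, `[[`, "scores"))
  .factor_model(scores,
                do.call(c, lapply(fms, `[[`, "loadings")),
                unlist(lapply(fms, `[[`, "source")),
                unlist(lapply(fms, `[[`, "explained_variance")),
                ranks = do.call(c, lapply(fms, `[[`, "ranks")))
}

#' Component-level mediation of the exposure-outcome association
#'
#' Treats the (standardized) factor scores as candidate mediators: alpha is
#' the exposure-to-score OLS coefficient; the score-to-outcome side uses
#' the penalized joint fit of [mediate_early()] over all components
#' (exposure and covariates unpenalized) with an OLS refit of the selected
#' components. Joint-significance p-values are Benjamini-Hochberg corrected
#' across selected components. Two percent-mediated summaries are reported:
#' `pct_te` = 100 * alpha * beta / gamma, and `pct_mediated` = each
#' significant component's share of the summed significant indirect effect.
#'
#' @param factors a `"factor_model"`.
#' @param study a [study_frame()].
#' @param covariates covariate names to adjust for.
#' @param fdr FDR threshold for the significance flag (default 0.05).
#' @param seed seed for the cross-validated penalized fit.
#' @return data.frame with one row per component: `component`, `source`,
#'   `alpha`, `se_alpha`, `beta`, `se_beta`, `indirect`, `ci_low`,
#'   `ci_high`, `p`, `fdr_q`, `pct_te`, `pct_mediated`, `significant`;
#'   attribute `gamma`.
#' @export
mediate_components <- function(factors, study,
                               covariates = covariate_names(study),
                               fdr = 0.05, seed = 1) {
  S <- factors$scores
  if (ncol(S) == 0) {
    out <- data.frame(component = character(0), source = character(0),
                      alpha = numeric(0), se_alpha = numeric(0),
                      beta = numeric(0), se_beta = numeric(0),
                      indirect = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), p = numeric(0),
                      fdr_q = numeric(0), pct_te = numeric(0),
                      pct_mediated = numeric(0), significant = logical(0))
    return(out)
  }
  S <- scale(S)
  tab <- mediate_early(S, study, covariates, seed = seed, fdr = fdr)
  out <- data.frame(component = tab$feature_id,
                    source = factors$source,
                    tab[, c("alpha", "se_alpha", "beta", "se_beta",
                            "indirect", "ci_low", "ci_high", "p",
                            "fdr_q", "pct_te")],
                    significant = tab$significant,
                    row.names = NULL)
  out$pct_mediated <- NA_real_
  if (any(out$significant)) {
    tot <- sum(out$indirect[out$significant])
    if (abs(tot) > .Machine$double.eps)
      out$pct_mediated[out$significant] <-
        100 * out$indirect[out$significant] / tot
  }
  attr(out, "gamma") <- attr(tab, "gamma")
  out
}

#' Pearson correlations between omics features and factor components
#'
#' For every (feature, component) pair, the Pearson correlation and its
#' two-sided p-value. Features from other layers than a layer-individual
#' component's own are flagged not applicable (`applicable = FALSE`,
#' correlation `NA`); joint components apply to all features. Constant
#' features get `NA` with `applicable = FALSE`. The resulting ranked table
#' is the input for external pathway-enrichment tools.
#'
#' @param factors a `"factor_model"`.
#' @param omics a [multi_omics()] on the same samples.
#' @return data.frame with columns `layer`, `feature_id`, `component`,
#'   `r`, `p`, `applicable`.
#' @export
component_feature_correlations <- function(factors, omics) {
  S <- factors$scores
  n <- nrow(S)
  res <- vector("list", length(omics) * ncol(S))
  k <- 0
  for (nm in names(omics)) {
    M <- omics[[nm]]
    const <- apply(M, 2, sd) == 0
    ids <- colnames(M) %||% paste0("f", seq_len(ncol(M)))
    for (ci in seq_len(ncol(S))) {
      src <- factors$source[ci]
      applicable <- (src == "joint" | src == nm) & !const
      r <- rep(NA_real_, ncol(M))
      if (any(applicable))
        r[applicable] <- as.vector(cor(M[, applicable, drop = FALSE],
                                       S[, ci]))
      tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tstat), n - 2)
      k <- k + 1
      res[[k]] <- data.frame(layer = nm, feature_id = ids,
                             component = colnames(S)[ci],
                             r = r, p = p, applicable = applicable,
                             row.names = NULL)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
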