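# Latent-unknown-cluster quasi-mediation: an EM algorithm for the
# generative model  exposure -> latent cluster -> (omics features, outcome),
# with early (concatenated), parallel (per-layer clusters, one joint model)
# and serial (chained through posterior inclusion probabilities) variants.

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1, max)
  mx + log(rowSums(exp(M - mx)))
}

# Weighted multinomial-logistic fit of soft cluster labels on exposure(s).
# Returns a (K-1) x (1 + q) coefficient matrix (reference = cluster 1).
.fit_cluster_logistic <- function(x, pips) {
  K <- ncol(pips)
  q <- ncol(x)
  if (K == 1) return(matrix(numeric(0), 0, 1 + q))
  if (K == 2) {
    fit <- suppressWarnings(
      glm.fit(cbind(1, x), pips[, 2], family = quasibinomial()))
    co <- matrix(coef(fit), 1, 1 + q)
  } else {
    dat <- as.data.frame(x)
    names(dat) <- paste0("x", seq_len(q))
    fml <- stats::as.formula(paste("pips ~", paste(names(dat),
                                                   collapse = " + ")))
    capture <- utils::capture.output(
      fit <- nnet::multinom(fml, data = dat, trace = FALSE, maxit = 500))
    co <- coef(fit)
    if (is.null(dim(co))) co <- matrix(co, 1)
  }
  rownames(co) <- paste0("cluster", 2:K)
  colnames(co) <- c("(Intercept)", colnames(x) %||% paste0("x", seq_len(q)))
  co
}

# log P(L = k | x) for all samples/clusters under reference-coded logits
.cluster_logprior <- function(x, delta, K) {
  n <- nrow(x)
  if (K == 1) return(matrix(0, n, 1))
  eta <- cbind(0, cbind(1, x) %*% t(delta))   # n x K logits
  eta - .logsumexp_rows(eta)
}

# One complete EM fit from a given initial posterior matrix.
.lucid_em_run <- function(x, Z, y, K, pips, supervised, tol, max_iter) {
  n <- nrow(Z); p <- ncol(Z)
  trace <- numeric(0)
  converged <- FALSE
  delta <- NULL
  for (it in seq_len(max_iter)) {
    wk <- colSums(pips)
    if (any(wk < 1)) return(list(failed = TRUE, reason = "empty cluster"))
    # --- M step
    delta <- .fit_cluster_logistic(x, pips)
    mu <- crossprod(pips, Z) / wk                        # K x p
    sigma2 <- numeric(p)
    for (k in seq_len(K))
      sigma2 <- sigma2 +
        colSums(pips[, k] * sweep(Z, 2, mu[k, ], "-")^2)
    sigma2 <- pmax(sigma2 / n, 1e-8)
    if (supervised) {
      m <- as.vector(crossprod(pips, y) / wk)
      sy2 <- max(sum(pips * outer(y, m, "-")^2) / n, 1e-8)
    } else {
      m <- NULL; sy2 <- NULL
    }
    # --- E step / log-likelihood
    lp <- .cluster_logprior(x, delta, K)
    for (k in seq_len(K)) {
      lp[, k] <- lp[, k] -
        0.5 * colSums((t(Z) - mu[k, ])^2 / sigma2) -
        0.5 * sum(log(2 * pi * sigma2))
      if (supervised)
        lp[, k] <- lp[, k] + dnorm(y, m[k], sqrt(sy2), log = TRUE)
    }
    ll <- .logsumexp_rows(lp)
    trace <- c(trace, sum(ll))
    pips <- exp(lp - ll)
    if (it > 1 && abs(trace[it] - trace[it - 1]) <=
        tol * abs(trace[it - 1])) {
      converged <- TRUE
      break
    }
  }
  list(failed = FALSE, delta = delta, mu = mu, sigma2 = sigma2,
       outcome_means = m, sy2 = sy2, pips = pips,
       loglik_trace = trace, converged = converged)
}

# Core single-cluster-variable EM with k-means initialization and restarts.
# x: exposure matrix (n x q); Z: features; y: outcome (may be NULL).
.lucid_em <- function(x, Z, y, K, supervised, seed, tol = 1e-6,
                      max_iter = 500, n_restarts = 5) {
  n <- nrow(Z)
  x <- as.matrix(x)
  if (K == 1) {
    mu <- matrix(colMeans(Z), 1, ncol(Z),
                 dimnames = list("cluster1", colnames(Z)))
    sigma2 <- apply(Z, 2, function(z) mean((z - mean(z))^2))
    ll <- sum(vapply(seq_len(ncol(Z)), function(j)
      sum(dnorm(Z[, j], mu[1, j], sqrt(max(sigma2[j], 1e-8)), log = TRUE)),
      numeric(1)))
    eta <- if (supervised) mean(y) else NA_real_
    if (supervised)
      ll <- ll + sum(dnorm(y, eta, sqrt(max(mean((y - eta)^2), 1e-8)),
                           log = TRUE))
    return(structure(list(K = 1L, delta = matrix(numeric(0), 0, 1 + ncol(x)),
                          mu = mu, sigma2 = sigma2, eta = eta,
                          outcome_means = if (supervised) eta else NULL,
                          sy2 = if (supervised) mean((y - eta)^2) else NULL,
                          pips = matrix(1, n, 1), loglik_trace = ll,
                          converged = TRUE, supervised = supervised),
                     class = "lucid_fit"))
  }
  best <- NULL
  failures <- character(0)
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000L + r)
    km <- suppressWarnings(kmeans(Z, centers = K, nstart = 1,
                                  iter.max = 50))
    pips0 <- matrix(0, n, K)
    pips0[cbind(seq_len(n), km$cluster)] <- 1
    fit <- .lucid_em_run(x, Z, y, K, pips0, supervised, tol, max_iter)
    if (fit$failed) {
      failures <- c(failures, sprintf("restart %d: %s", r, fit$reason))
      next
    }
    if (is.null(best) || max(fit$loglik_trace) > max(best$loglik_trace))
      best <- fit
  }
  if (is.null(best))
    stop("EM failed in all ", n_restarts, " restarts (",
         paste(failures, collapse = "; "), "); n = ", n, ", K = ", K)
  fit <- best

  # canonical labeling: reference cluster = lowest outcome mean
  # (supervised) or lowest first-feature mean (unsupervised)
  ord <- if (supervised) order(fit$outcome_means) else order(fit$mu[, 1])
  fit$pips <- fit$pips[, ord, drop = FALSE]
  fit$mu <- fit$mu[ord, , drop = FALSE]
  if (supervised) fit$outcome_means <- fit$outcome_means[ord]
  fit$delta <- .fit_cluster_logistic(x, fit$pips)
  rownames(fit$mu) <- paste0("cluster", seq_len(K))
  colnames(fit$pips) <- paste0("cluster", seq_len(K))
  eta <- if (supervised) fit$outcome_means - fit$outcome_means[1] else
    rep(NA_real_, K)
  structure(list(K = as.integer(K), delta = fit$delta, mu = fit$mu,
                 sigma2 = fit$sigma2, eta = eta,
                 outcome_means = fit$outcome_means, sy2 = fit$sy2,
                 pips = fit$pips, loglik_trace = fit$loglik_trace,
                 converged = fit$converged, supervised = supervised),
            class = "lucid_fit")
}

#' @export
print.lucid_fit <- function(x, ...) {
  cat("lucid_fit: K = ", x$K, ", ", nrow(x$pips), " samples, ",
      ncol(x$mu), " features, ",
      if (x$supervised) "supervised" else "unsupervised",
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  if (x$K > 1) {
    cat("exposure -> cluster log-odds (vs reference cluster1):\n")
    print(x$delta)
    if (x$supervised) {
      cat("cluster -> outcome effects (eta, reference 0):\n")
      print(setNames(x$eta, paste0("cluster", seq_len(x$K))))
    }
  }
  invisible(x)
}

#' Latent-cluster quasi-mediation with early integration
#'
#' Fits, by EM, the latent-unknown-cluster model on the concatenated omics
#' matrix: the latent cluster depends on the exposure through a
#' multinomial-logistic model, features are conditionally independent
#' normals with cluster-specific means and a shared per-feature variance,
#' and (in the supervised variant) the outcome is normal with a
#' cluster-specific mean. Initialization is by seeded k-means with random
#' restarts keeping the best log-likelihood; clusters are relabeled so the
#' reference cluster has the lowest outcome mean (supervised) or lowest
#' first-feature mean (unsupervised).
#'
#' @param study a [study_frame()] with scaled exposure (and outcome).
#' @param omics a [multi_omics()] or a numeric feature matrix
#'   (standardized).
#' @param K number of latent clusters (default 2).
#' @param supervised include the outcome in the likelihood (default TRUE).
#' @param seed integer seed (initialization).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @param n_restarts k-means restarts (default 5).
#' @return object of class `"lucid_fit"`: list with `K`, `delta`
#'   (exposure-to-cluster log-odds, reference-coded), `mu` (cluster-specific
#'   feature means), `sigma2`, `eta` (cluster-to-outcome effects vs the
#'   reference), `outcome_means`, `pips` (posterior inclusion
#'   probabilities, rows summing to 1), `loglik_trace` (non-decreasing),
#'   `converged`.
#' @export
lucid_early <- function(study, omics, K = 2, supervised = TRUE, seed = 1,
                        tol = 1e-6, max_iter = 500, n_restarts = 5) {
  Z <- if (inherits(omics, "multi_omics")) concat_layers(omics) else
    as.matrix(omics)
  .lucid_em(matrix(study$exposure, ncol = 1,
                   dimnames = list(NULL, "exposure")),
            Z, study$outcome, K, supervised, seed, tol, max_iter,
            n_restarts)
}

#' Enumerate cluster configurations across layers
#'
#' All joint assignments of one latent cluster per layer: with `K` clusters
#' in each of `L` layers there are `K^L` configurations.
#'
#' @param K_per_layer integer vector (or scalar) of clusters per layer.
#' @param layer_names optional layer names.
#' @return data.frame, one row per configuration, one column per layer.
#' @export
#' @examples
#' nrow(enumerate_configurations(rep(2, 3)))  # 8
#' nrow(enumerate_configurations(rep(2, 5)))  # 32
enumerate_configurations <- function(K_per_layer, layer_names = NULL) {
  if (is.null(layer_names))
    layer_names <- paste0("layer", seq_along(K_per_layer))
  grid <- expand.grid(lapply(K_per_layer, seq_len),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- layer_names
  grid
}

#' Latent-cluster quasi-mediation with intermediate (parallel) integration
#'
#' One latent cluster variable per omics layer, fit jointly in a single EM:
#' given the clusters, the complete-data likelihood factorizes across
#' layers (no cross-layer correlation is modeled), the exposure acts on
#' each layer's cluster through its own logistic model, and the outcome
#' mean is additive in the layers' cluster indicators. The E step
#' enumerates all `prod(K)` cluster configurations; with one layer the
#' model reduces to (and is fit by) [lucid_early()].
#'
#' @param study a [study_frame()].
#' @param layers a [multi_omics()].
#' @param K_per_layer clusters per layer (default 2).
#' @param seed,tol,max_iter,n_restarts as in [lucid_early()].
#' @return object of class `"lucid_parallel"`: list with `fits` (per-layer
#'   `"lucid_fit"`-like objects carrying layer-marginal PIPs), `subgroups`
#'   (one row per configuration: labels, sample count by maximum-posterior
#'   assignment, mean exposure, mean outcome), `configurations`,
#'   `outcome_intercept`, `loglik_trace`, `converged`.
#' @export
lucid_parallel <- function(study, layers, K_per_layer = 2, seed = 1,
                           tol = 1e-6, max_iter = 500, n_restarts = 5) {
  if (!inherits(layers, "multi_omics"))
    stop("layers must be a multi_omics")
  L <- length(layers)
  Kl <- as.integer(rep_len(K_per_layer, L))
  if (L == 1) {
    fit <- lucid_early(study, layers, K = Kl, supervised = TRUE,
                       seed = seed, tol = tol, max_iter = max_iter,
                       n_restarts = n_restarts)
    sub <- .subgroup_table(list(fit$pips), setNames(Kl, names(layers)),
                           study)
    return(structure(list(fits = setNames(list(fit), names(layers)),
                          subgroups = sub,
                          configurations = enumerate_configurations(
                            Kl, names(layers)),
                          outcome_intercept = fit$outcome_means[1],
                          loglik_trace = fit$loglik_trace,
                          converged = fit$converged),
                     class = "lucid_parallel"))
  }
  if (prod(Kl) > 1024)
    stop("configuration space has ", prod(Kl), " cells; use lucid_serial ",
         "for this many layers")
  x <- matrix(study$exposure, ncol = 1, dimnames = list(NULL, "exposure"))
  y <- study$outcome
  n <- nrow(x)
  Z <- lapply(layers, as.matrix)
  configs <- as.matrix(enumerate_configurations(Kl, names(layers)))
  C <- nrow(configs)
  # outcome design over configurations: intercept + non-reference indicators
  D <- cbind(1, do.call(cbind, lapply(seq_len(L), function(l) {
    sapply(2:Kl[l], function(k) as.numeric(configs[, l] == k))
  })))
  colnames(D) <- c("(Intercept)",
                   unlist(lapply(seq_len(L), function(l)
                     paste0(names(layers)[l], "_cluster", 2:Kl[l]))))

  run_once <- function(marg0) {
    marg <- marg0
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      for (l in seq_len(L)) if (any(colSums(marg[[l]]) < 1))
        return(list(failed = TRUE, reason = "empty cluster"))
      # --- M step (layer models use layer-marginal posteriors)
      delta <- lapply(seq_len(L), function(l)
        .fit_cluster_logistic(x, marg[[l]]))
      mu <- lapply(seq_len(L), function(l)
        crossprod(marg[[l]], Z[[l]]) / colSums(marg[[l]]))
      sigma2 <- lapply(seq_len(L), function(l) {
        s <- numeric(ncol(Z[[l]]))
        for (k in seq_len(Kl[l]))
          s <- s + colSums(marg[[l]][, k] *
                             sweep(Z[[l]], 2, mu[[l]][k, ], "-")^2)
        pmax(s / n, 1e-8)
      })
      post <- attr(marg, "post")
      if (is.null(post)) {
        # first M step from hard init: build config posterior as the
        # product of layer marginals
        post <- matrix(1, n, C)
        for (l in seq_len(L)) post <- post * marg[[l]][, configs[, l]]
        post <- post / rowSums(post)
      }
      cs <- colSums(post)
      b <- solve(crossprod(D, cs * D), crossprod(D, crossprod(post, y)))
      m_c <- as.vector(D %*% b)
      sy2 <- max(sum(post * outer(y, m_c, "-")^2) / n, 1e-8)
      # --- E step over configurations
      ld <- lapply(seq_len(L), function(l) {
        lp <- .cluster_logprior(x, delta[[l]], Kl[l])
        for (k in seq_len(Kl[l]))
          lp[, k] <- lp[, k] -
            0.5 * colSums((t(Z[[l]]) - mu[[l]][k, ])^2 / sigma2[[l]]) -
            0.5 * sum(log(2 * pi * sigma2[[l]]))
        lp
      })
      lw <- matrix(0, n, C)
      for (l in seq_len(L)) lw <- lw + ld[[l]][, configs[, l]]
      lw <- lw + outer(y, m_c, function(yy, mm)
        dnorm(yy, mm, sqrt(sy2), log = TRUE))
      ll <- .logsumexp_rows(lw)
      trace <- c(trace, sum(ll))
      post <- exp(lw - ll)
      marg <- lapply(seq_len(L), function(l) {
        mg <- matrix(0, n, Kl[l])
        for (k in seq_len(Kl[l]))
          mg[, k] <- rowSums(post[, configs[, l] == k, drop = FALSE])
        mg
      })
      attr(marg, "post") <- post
      if (it > 1 && abs(trace[it] - trace[it - 1]) <=
          tol * abs(trace[it - 1])) {
        converged <- TRUE
        break
      }
    }
    list(failed = FALSE, delta = delta, mu = mu, sigma2 = sigma2, b = b,
         sy2 = sy2, post = post, marg = marg, loglik_trace = trace,
         converged = converged)
  }

  best <- NULL
  failures <- character(0)
  for (r in seq_len(n_restarts)) {
    set.seed(seed * 1000L + r)
    marg0 <- lapply(seq_len(L), function(l) {
      km <- suppressWarnings(kmeans(Z[[l]], centers = Kl[l], nstart = 1,
                                    iter.max = 50))
      mg <- matrix(0, n, Kl[l])
      mg[cbind(seq_len(n), km$cluster)] <- 1
      mg
    })
    fit <- run_once(marg0)
    if (fit$failed) {
      failures <- c(failures, sprintf("restart %d: %s", r, fit$reason))
      next
    }
    if (is.null(best) || max(fit$loglik_trace) > max(best$loglik_trace))
      best <- fit
  }
  if (is.null(best))
    stop("EM failed in all ", n_restarts, " restarts (",
         paste(failures, collapse = "; "), ")")
  fit <- best

  # canonical labels per layer: reference = lowest outcome effect
  b_layer <- vector("list", L)
  pos <- 2
  for (l in seq_len(L)) {
    b_layer[[l]] <- c(0, fit$b[pos:(pos + Kl[l] - 2)])
    pos <- pos + Kl[l] - 1
  }
  intercept <- fit$b[1]
  fits <- vector("list", L)
  for (l in seq_len(L)) {
    ord <- order(b_layer[[l]])
    eta <- b_layer[[l]][ord] - b_layer[[l]][ord[1]]
    intercept <- intercept + b_layer[[l]][ord[1]]
    marg <- fit$marg[[l]][, ord, drop = FALSE]
    colnames(marg) <- paste0("cluster", seq_len(Kl[l]))
    mu <- fit$mu[[l]][ord, , drop = FALSE]
    rownames(mu) <- paste0("cluster", seq_len(Kl[l]))
    fits[[l]] <- structure(
      list(K = Kl[l], delta = .fit_cluster_logistic(x, marg), mu = mu,
           sigma2 = fit$sigma2[[l]], eta = eta, outcome_means = NULL,
           sy2 = fit$sy2, pips = marg, loglik_trace = fit$loglik_trace,
           converged = fit$converged, supervised = TRUE),
      class = "lucid_fit")
    fit$marg[[l]] <- marg
  }
  names(fits) <- names(layers)
  sub <- .subgroup_table(lapply(fits, `[[`, "pips"),
                         setNames(Kl, names(layers)), study)
  structure(list(fits = fits, subgroups = sub,
                 configurations = enumerate_configurations(Kl,
                                                           names(layers)),
                 outcome_intercept = intercept,
                 loglik_trace = fit$loglik_trace,
                 converged = fit$converged),
            class = "lucid_parallel")
}

# Subgroup bookkeeping: each sample assigned its maximum-posterior cluster
# per layer; one row per configuration.
.subgroup_table <- function(pips_list, Kl, study) {
  configs <- enumerate_configurations(Kl, names(Kl))
  hard <- vapply(pips_list, function(pp) max.col(pp, ties.method = "first"),
                 integer(nrow(study)))
  hard <- matrix(hard, nrow = nrow(study))
  key_s <- apply(hard, 1, paste, collapse = "|")
  key_c <- apply(as.matrix(configs), 1, paste, collapse = "|")
  out <- configs
  out$configuration <- vapply(seq_len(nrow(configs)), function(i)
    paste(paste0(names(Kl), "=", as.integer(configs[i, seq_along(Kl)])),
          collapse = "|"), character(1))
  out$n <- as.integer(table(factor(key_s, levels = key_c)))
  out$mean_exposure <- vapply(key_c, function(kk)
    if (any(key_s == kk)) mean(study$exposure[key_s == kk]) else NA_real_,
    numeric(1))
  out$mean_outcome <- vapply(key_c, function(kk)
    if (any(key_s == kk)) mean(study$outcome[key_s == kk]) else NA_real_,
    numeric(1))
  rownames(out) <- NULL
  out
}

#' @export
print.lucid_parallel <- function(x, ...) {
  cat("lucid_parallel: ", length(x$fits), " layer(s), ",
      nrow(x$subgroups), " configurations",
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  print(x$subgroups[, c("configuration", "n", "mean_exposure",
                        "mean_outcome")])
  invisible(x)
}

#' Latent-cluster quasi-mediation with late (serial) integration
#'
#' Chains single-layer latent-cluster models along a user-supplied layer
#' order reflecting a biological hypothesis (e.g. methylation -> miRNA ->
#' transcripts). The first model clusters layer 1 on the study exposure
#' (unsupervised); each subsequent model uses the previous model's
#' posterior inclusion probabilities for the non-reference cluster(s) as
#' its exposure; the final model is supervised (includes the outcome).
#'
#' @param study a [study_frame()].
#' @param layers a [multi_omics()] in chaining order.
#' @param K clusters per model (default 2).
#' @param seed,tol,max_iter,n_restarts as in [lucid_early()].
#' @return named list of `"lucid_fit"` objects, one per layer, in chain
#'   order (class `"lucid_serial"`).
#' @export
lucid_serial <- function(study, layers, K = 2, seed = 1, tol = 1e-6,
                         max_iter = 500, n_restarts = 5) {
  if (!inherits(layers, "multi_omics"))
    stop("layers must be a multi_omics")
  L <- length(layers)
  if (L == 1)
    message("chain of length 1: equivalent to lucid_early")
  fits <- vector("list", L)
  expo <- matrix(study$exposure, ncol = 1,
                 dimnames = list(NULL, "exposure"))
  for (i in seq_len(L)) {
    last <- i == L
    fits[[i]] <- .lucid_em(expo, as.matrix(layers[[i]]),
                           if (last) study$outcome else NULL,
                           K = K, supervised = last,
                           seed = seed + i - 1L, tol = tol,
                           max_iter = max_iter, n_restarts = n_restarts)
    pp <- fits[[i]]$pips
    expo <- pp[, -1, drop = FALSE]  # non-reference-cluster PIPs
    colnames(expo) <- paste0("pip_", colnames(pp)[-1])
  }
  names(fits) <- names(layers)
  class(fits) <- "lucid_serial"
  fits
}

#' Cluster-wise expected omics profiles
#'
#' The expected value of each omics feature within each latent cluster,
#' computed as the PIP-weighted sample mean. At convergence this equals the
#' model's `mu`, but it is recomputed from the data for auditability.
#'
#' @param fit a `"lucid_fit"`.
#' @param omics the omics matrix (or [multi_omics()]) the model was fit to.
#' @return data.frame with columns `feature_id`, `cluster`,
#'   `expected_value`.
#' @export
cluster_omics_profile <- function(fit, omics) {
  Z <- if (inherits(omics, "multi_omics")) concat_layers(omics) else
    as.matrix(omics)
  w <- colSums(fit$pips)
  prof <- crossprod(fit$pips, Z) / w
  ids <- colnames(Z) %||% paste0("f", seq_len(ncol(Z)))
  data.frame(feature_id = rep(ids, each = nrow(prof)),
             cluster = rep(paste0("cluster", seq_len(nrow(prof))),
                           ncol(Z)),
             expected_value = as.vector(prof),
             row.names = NULL)
}
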