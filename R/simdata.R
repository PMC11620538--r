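# Seeded generators of synthetic multi-omic studies with known truth.
#
# The default layer dimensions (500 / 300 / 100 / 36 / 177) keep the
# relative ordering of real methylome / transcriptome / miRNA / proteome /
# metabolome panel sizes while staying desk-scale; block-exchangeable
# correlation within layers emulates the within-layer correlation
# structure of array data.

.default_layer_specs <- function() list(
  methylome    = list(p = 500, block_size = 10, rho = 0.3),
  transcriptome = list(p = 300, block_size = 10, rho = 0.3),
  mirna        = list(p = 100, block_size = 5,  rho = 0.3),
  proteome     = list(p = 36,  block_size = 4,  rho = 0.3),
  metabolome   = list(p = 177, block_size = 10, rho = 0.3))

#' Specification of a synthetic multi-omic study
#'
#' Collects every knob of the synthetic generators: sample size, cohort
#' structure, per-layer dimensions and within-layer block correlation,
#' number of active (signal-carrying) features per layer, effect sizes and
#' noise level, the generator mode, and the seed from which all randomness
#' flows.
#'
#' @param n sample size.
#' @param mode `"mediation"`, `"latent_factor"` or `"latent_cluster"`.
#' @param cohorts list with `k` (count) and optional `proportions`.
#' @param layer_specs named list per layer: `p`, `block_size`, `rho`
#'   (within-block correlation in `[0, 1)`).
#' @param n_active active features per layer (recycled; mediation mode).
#' @param alpha_effect exposure-to-mediator effect per active feature.
#' @param beta_effect mediator-to-outcome effect per active feature.
#' @param gamma_direct direct exposure-to-outcome effect.
#' @param noise_sd outcome noise SD.
#' @param seed integer seed.
#' @param ... mode-specific extras: `r_joint`, `r_individual`,
#'   `exposure_loading`, `outcome_loading`, `noise_level` (latent_factor);
#'   `delta`, `mu_sep`, `eta` (latent_cluster).
#' @return object of class `"sim_spec"`.
#' @export
sim_spec <- function(n = 420, mode = c("mediation", "latent_factor",
                                       "latent_cluster"),
                     cohorts = list(k = 4), layer_specs = NULL,
                     n_active = c(5, 3, 2, 1, 1), alpha_effect = 0.4,
                     beta_effect = 0.4, gamma_direct = 0.1, noise_sd = 1,
                     seed = 1, ...) {
  mode <- match.arg(mode)
  if (is.null(layer_specs)) layer_specs <- .default_layer_specs()
  if (is.null(cohorts$proportions))
    cohorts$proportions <- rep(1 / cohorts$k, cohorts$k)
  if (abs(sum(cohorts$proportions) - 1) > 1e-8)
    stop("cohort proportions must sum to 1")
  n_active <- rep_len(n_active, length(layer_specs))
  for (i in seq_along(layer_specs)) {
    ls <- layer_specs[[i]]
    if (is.null(ls$p) || ls$p < 1) stop("each layer needs p >= 1")
    if (ls$rho < 0 || ls$rho >= 1) stop("rho must be in [0, 1)")
    if (mode == "mediation" && n_active[i] > ls$p)
      stop("n_active exceeds p in layer ", names(layer_specs)[i])
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(c(list(n = as.integer(n), mode = mode, cohorts = cohorts,
                   layer_specs = layer_specs, n_active = n_active,
                   alpha_effect = alpha_effect, beta_effect = beta_effect,
                   gamma_direct = gamma_direct, noise_sd = noise_sd,
                   seed = as.integer(seed)), list(...)),
            class = "sim_spec")
}

# block-exchangeable noise matrix: cor(z_a, z_b) = rho within a block
.block_noise <- function(n, p, block_size, rho) {
  n_blocks <- ceiling(p / block_size)
  U <- matrix(rnorm(n * n_blocks), n, n_blocks)
  block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(p)]
  sqrt(rho) * U[, block_of, drop = FALSE] +
    sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
}

.sim_exposure <- function(spec) {
  k <- spec$cohorts$k
  cohort <- factor(sample(seq_len(k), spec$n, replace = TRUE,
                          prob = spec$cohorts$proportions),
                   levels = seq_len(k),
                   labels = paste0("cohort", seq_len(k)))
  shifts <- spec$cohorts$shifts %||% seq(-0.5, 0.5, length.out = k)
  exposure <- shifts[as.integer(cohort)] + rnorm(spec$n)
  list(cohort = cohort, exposure = exposure)
}

#' Simulate a mediation-structured multi-omic study
#'
#' Exposure is normal with cohort-specific mean shifts; in each layer the
#' first `n_active` features are true mediators
#' (`M_j = alpha_effect * X +` block-correlated noise), the remainder pure
#' block-correlated noise; the outcome is
#' `Y = gamma_direct * X + sum(beta_effect * M_j) + N(0, noise_sd)`.
#'
#' @param spec a [sim_spec()] with `mode = "mediation"`.
#' @return list with `study` ([study_frame()]), `omics` ([multi_omics()])
#'   and `truth` (data.frame of active features with true alpha, beta).
#' @export
simulate_mediation_study <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$mode != "mediation") stop("spec$mode must be 'mediation'")
  set.seed(spec$seed)
  ce <- .sim_exposure(spec)
  x <- ce$exposure
  layers <- list()
  truth <- list()
  y_med <- 0
  for (i in seq_along(spec$layer_specs)) {
    nm <- names(spec$layer_specs)[i]
    ls <- spec$layer_specs[[i]]
    M <- .block_noise(spec$n, ls$p, ls$block_size, ls$rho)
    na_i <- spec$n_active[i]
    if (na_i > 0) {
      M[, seq_len(na_i)] <- M[, seq_len(na_i)] + spec$alpha_effect * x
      y_med <- y_med + spec$beta_effect * rowSums(M[, seq_len(na_i),
                                                    drop = FALSE])
      truth[[nm]] <- data.frame(layer = nm,
                                feature_id = paste0(nm, "_f",
                                                    seq_len(na_i)),
                                alpha = spec$alpha_effect,
                                beta = spec$beta_effect)
    }
    colnames(M) <- paste0(nm, "_f", seq_len(ls$p))
    layers[[nm]] <- M
  }
  y <- spec$gamma_direct * x + y_med + rnorm(spec$n, sd = spec$noise_sd)
  ids <- sprintf("s%04d", seq_len(spec$n))
  layers <- lapply(layers, function(m) { rownames(m) <- ids; m })
  study <- study_frame(ids, x, y, cohort = ce$cohort)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(layer = character(0), feature_id = character(0),
               alpha = numeric(0), beta = numeric(0))
  rownames(truth) <- NULL
  list(study = study, omics = multi_omics(layers, ids), truth = truth)
}

#' Simulate a latent-factor multi-omic study
#'
#' Latent joint factors load on every layer; layer-individual factors load
#' only on their own layer; the exposure and the outcome load on the first
#' joint factor. The truth records the factor ranks and loadings, so rank
#' recovery of a joint/individual decomposition can be checked against a
#' known generative structure.
#'
#' @param spec a [sim_spec()] with `mode = "latent_factor"`. Extras:
#'   `r_joint` (default 1), `r_individual` (per layer, default 0),
#'   `exposure_loading` / `outcome_loading` on joint factor 1 (default
#'   0.5), `noise_level` (feature noise SD relative to factor signal,
#'   default 0.3; the factor-to-feature signal-to-noise ratio is
#'   `1 / noise_level^2`).
#' @return list with `study`, `omics`, `truth` (list: `r_joint`,
#'   `r_individual`, `joint_scores`, `loadings`).
#' @export
simulate_factor_study <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$mode != "latent_factor") stop("spec$mode must be 'latent_factor'")
  set.seed(spec$seed)
  r_J <- spec$r_joint %||% 1
  r_I <- rep_len(spec$r_individual %||% 0, length(spec$layer_specs))
  lam_x <- spec$exposure_loading %||% 0.5
  lam_y <- spec$outcome_loading %||% 0.5
  noise <- spec$noise_level %||% 0.3
  ce <- .sim_exposure(spec)
  n <- spec$n
  FJ <- matrix(rnorm(n * r_J), n, r_J)
  layers <- list()
  loadings <- list()
  for (i in seq_along(spec$layer_specs)) {
    nm <- names(spec$layer_specs)[i]
    p <- spec$layer_specs[[i]]$p
    WJ <- matrix(rnorm(r_J * p), r_J, p)
    M <- FJ %*% WJ
    WI <- NULL
    if (r_I[i] > 0) {
      FI <- matrix(rnorm(n * r_I[i]), n, r_I[i])
      WI <- matrix(rnorm(r_I[i] * p), r_I[i], p)
      M <- M + FI %*% WI
    }
    M <- M + noise * sqrt(r_J + r_I[i]) * matrix(rnorm(n * p), n, p)
    colnames(M) <- paste0(nm, "_f", seq_len(p))
    layers[[nm]] <- M
    loadings[[nm]] <- list(joint = WJ, individual = WI)
  }
  x <- ce$exposure + if (r_J > 0) lam_x * FJ[, 1] else 0
  y <- (if (r_J > 0) lam_y * FJ[, 1] else 0) +
    spec$gamma_direct * x + rnorm(n, sd = spec$noise_sd)
  ids <- sprintf("s%04d", seq_len(n))
  layers <- lapply(layers, function(m) { rownames(m) <- ids; m })
  list(study = study_frame(ids, x, y, cohort = ce$cohort),
       omics = multi_omics(layers, ids),
       truth = list(r_joint = r_J,
                    r_individual = setNames(r_I,
                                            names(spec$layer_specs)),
                    joint_scores = FJ, loadings = loadings))
}

#' Simulate a latent-cluster multi-omic study
#'
#' Per layer, a latent binary (or `K`-ary via `delta` rows) cluster whose
#' log-odds depend on the exposure; features are normal around
#' cluster-specific means separated by `mu_sep` SD units; the outcome is
#' additive in per-layer cluster effects `eta` plus noise.
#'
#' @param spec a [sim_spec()] with `mode = "latent_cluster"`. Extras:
#'   `delta` exposure-to-cluster log-odds slope (default 0.8), `mu_sep`
#'   separation between cluster feature means in SD units (default 2),
#'   `eta` outcome effect of the high cluster per layer (default 1).
#' @return list with `study`, `omics`, `truth` (list: `membership` matrix
#'   (1 = reference/low cluster, 2 = high), `delta`, `mu`, `eta`).
#' @export
simulate_cluster_study <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (spec$mode != "latent_cluster") stop("spec$mode must be 'latent_cluster'")
  set.seed(spec$seed)
  delta <- spec$delta %||% 0.8
  mu_sep <- spec$mu_sep %||% 2
  eta <- rep_len(spec$eta %||% 1, length(spec$layer_specs))
  ce <- .sim_exposure(spec)
  n <- spec$n
  x <- ce$exposure
  layers <- list()
  membership <- matrix(NA_integer_, n, length(spec$layer_specs))
  colnames(membership) <- names(spec$layer_specs)
  mu_truth <- list()
  y <- rep(0, n)
  for (i in seq_along(spec$layer_specs)) {
    nm <- names(spec$layer_specs)[i]
    p <- spec$layer_specs[[i]]$p
    pr <- 1 / (1 + exp(-(delta * x)))      # P(high cluster | x)
    cl <- rbinom(n, 1, pr) + 1L            # 1 = low/reference, 2 = high
    membership[, i] <- cl
    mu <- rbind(low = rep(-mu_sep / 2, p), high = rep(mu_sep / 2, p))
    M <- mu[cl, , drop = FALSE] + matrix(rnorm(n * p), n, p)
    colnames(M) <- paste0(nm, "_f", seq_len(p))
    layers[[nm]] <- M
    mu_truth[[nm]] <- mu
    y <- y + eta[i] * (cl == 2)
  }
  y <- y + rnorm(n, sd = spec$noise_sd)
  ids <- sprintf("s%04d", seq_len(n))
  layers <- lapply(layers, function(m) { rownames(m) <- ids; m })
  list(study = study_frame(ids, x, y, cohort = ce$cohort),
       omics = multi_omics(layers, ids),
       truth = list(membership = membership, delta = delta, mu = mu_truth,
                    eta = setNames(eta, names(spec$layer_specs))))
}
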