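test_that("PCA retains the smallest set crossing the variance threshold", {
  # single column: one component explaining everything
  x1 <- matrix(rnorm(50), dimnames = list(NULL, "a"))
  fm <- pca_factors(x1)
  expect_equal(ncol(fm$scores), 1)
  expect_equal(unname(fm$explained_variance), 1)
  # two orthogonal factors at ~70/30 variance: both needed for 80%
  set.seed(3)
  n <- 400
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(outer(f1, rep(sqrt(0.7), 5)) + outer(f2, rep(sqrt(0.3), 5)),
             outer(f1, rep(sqrt(0.7), 5)) - outer(f2, rep(sqrt(0.3), 5)))
  X <- X + 0.01 * matrix(rnorm(n * 10), n, 10)
  expect_equal(ncol(pca_factors(X, 0.8)$scores), 2)
  # rank-1 + tiny noise: one component suffices
  set.seed(4)
  R1 <- outer(rnorm(100), rnorm(8)) + 1e-3 * matrix(rnorm(800), 100, 8)
  expect_equal(ncol(pca_factors(R1, 0.8)$scores), 1)
  expect_error(pca_factors(R1, 1.2), "var_threshold")
})

test_that("PCA of duplicated layers spans the same leading subspace", {
  set.seed(5)
  X <- outer(rnorm(80), rnorm(10)) + 0.3 * matrix(rnorm(800), 80, 10)
  colnames(X) <- paste0("f", 1:10)
  one <- pca_factors(X, 0.5)$scores
  two <- pca_factors(cbind(X, X), 0.5)$scores
  # principal angle between the leading subspaces ~ 0
  ang <- svd(crossprod(qr.Q(qr(one)), qr.Q(qr(two))))$d[1]
  expect_lt(abs(ang - 1), 1e-6)
})

test_that("joint/individual decomposition honors its algebraic contract", {
  set.seed(6)
  n <- 60
  fj <- rnorm(n)
  layers <- multi_omics(list(
    a = outer(fj, rnorm(20)) + outer(rnorm(n), rnorm(20)) +
      0.3 * matrix(rnorm(n * 20), n, 20),
    b = outer(fj, rnorm(15)) + 0.3 * matrix(rnorm(n * 15), n, 15)),
    sample_ids = as.character(1:n))
  fm <- jive_decompose(layers, ranks = list(joint = 1, individual = c(1, 1)),
                       seed = 2)
  expect_equal(fm$ranks$joint, 1L)
  # objective non-increasing every iteration
  expect_true(all(diff(fm$objective_trace) <=
                    1e-10 * abs(fm$objective_trace[-1]) + 1e-12))
  # joint scores orthogonal among themselves and to every layer's
  # individual scores (the decomposition's defining constraint)
  S <- fm$scores
  joint <- fm$source == "joint"
  G <- crossprod(S[, joint, drop = FALSE], S)
  off <- G; off[, seq_len(sum(joint))][diag(sum(joint)) == 1] <- 0
  expect_lt(max(abs(off)) / max(diag(crossprod(S))), 1e-6)
  # reconstruction J + A + E is exact by construction: residual bounded
  # by total scaled variance
  expect_lt(max(fm$objective_trace), length(layers))
  # explained variance fractions bounded
  expect_true(all(fm$explained_variance >= 0))
  expect_lte(sum(fm$explained_variance), 1 * length(layers))
})

test_that("permutation rank selection recovers planted and null structure", {
  recovered <- 0
  for (s in 1:6) {
    spec <- sim_spec(n = 60, mode = "latent_factor",
                     layer_specs = list(a = list(p = 30, block_size = 5,
                                                 rho = 0),
                                        b = list(p = 25, block_size = 5,
                                                 rho = 0),
                                        c = list(p = 20, block_size = 5,
                                                 rho = 0)),
                     r_joint = 1, r_individual = 0,
                     noise_level = sqrt(0.1), seed = s)
    sim <- simulate_factor_study(spec)
    fm <- jive_decompose(sim$omics, "permutation", n_perm = 100, seed = s)
    if (fm$ranks$joint == 1 && all(fm$ranks$individual == 0))
      recovered <- recovered + 1
  }
  expect_gte(recovered, 4)
  nulls <- 0
  for (s in 1:6) {
    set.seed(100 + s)
    layers <- multi_omics(list(
      a = matrix(rnorm(50 * 30), 50, 30),
      b = matrix(rnorm(50 * 25), 50, 25)),
      sample_ids = as.character(1:50))
    fm <- jive_decompose(layers, "permutation", n_perm = 100,
                         seed = 100 + s)
    if (fm$ranks$joint == 0) nulls <- nulls + 1
  }
  expect_gte(nulls, 4)
})

test_that("a latent factor mediating the whole effect is detected", {
  spec <- sim_spec(n = 400, mode = "latent_factor",
                   layer_specs = list(a = list(p = 25, block_size = 5,
                                               rho = 0),
                                      b = list(p = 20, block_size = 5,
                                               rho = 0)),
                   r_joint = 1, r_individual = 0, exposure_loading = 0.6,
                   outcome_loading = 0.6, gamma_direct = 0,
                   noise_level = 0.3, seed = 21)
  sim <- simulate_factor_study(spec)
  pp <- preprocess_study(sim$study, sim$omics)
  fm <- latent_factors(pp$omics, "early", 0.8)
  cm <- mediate_components(fm, pp$study, seed = 3)
  top <- cm[which.max(abs(cm$indirect)), ]
  expect_true(top$significant)
  expect_equal(top$pct_mediated, 100, tolerance = 1e-8)
  expect_gt(top$pct_te, 60)
  ok <- !is.na(cm$fdr_q)
  expect_true(all(cm$fdr_q[ok] >= cm$p[ok]))
  # single-component model: pct_te is exactly 100 * alpha * beta / gamma
  fm1 <- list(scores = fm$scores[, 1, drop = FALSE], source = "joint")
  class(fm1) <- "factor_model"
  cm1 <- mediate_components(fm1, pp$study, seed = 3)
  expect_equal(cm1$pct_te,
               100 * cm1$indirect / attr(cm1, "gamma"))
})

test_that("exposure-independent components yield no significant mediation", {
  sig <- 0
  for (s in 1:5) {
    study <- make_study(300, seed = 200 + s, rho_xy = 0.3,
                        covariates = FALSE)
    omics <- make_noise_omics(300, 30, seed = 300 + s)
    fm <- pca_factors(omics[[1]], 0.5)
    cm <- mediate_components(fm, study, seed = s)
    sig <- sig + sum(cm$significant)
  }
  expect_lte(sig, 1)
})

test_that("feature-component correlations behave like Pearson r", {
  set.seed(31)
  n <- 400
  omics <- make_noise_omics(n, 6, seed = 32, name = "a")
  M <- omics[[1]]
  # a component that IS feature 1, and a planted r = 0.5 with feature 2
  s2 <- 0.5 * scale(M[, 2]) + sqrt(0.75) * rnorm(n)
  fm <- list(scores = cbind(c1 = M[, 1], c2 = as.vector(s2)),
             source = c("joint", "joint"))
  class(fm) <- "factor_model"
  cc <- component_feature_correlations(fm, omics)
  dup <- cc[cc$feature_id == "f1" & cc$component == "c1", ]
  expect_equal(dup$r, 1, tolerance = 1e-12)
  expect_lt(dup$p, 1e-10)
  planted <- cc[cc$feature_id == "f2" & cc$component == "c2", ]
  expect_gt(planted$r, 0.41)
  expect_lt(planted$r, 0.58)
  null_r <- cc$r[cc$feature_id %in% paste0("f", 3:6) & cc$component == "c1"]
  expect_lt(max(abs(null_r)), 3 / sqrt(n))
})

test_that("individual components are flagged not-applicable across layers", {
  set.seed(41)
  layers <- multi_omics(list(a = matrix(rnorm(200), 20, 10,
                                        dimnames = list(NULL,
                                                        paste0("a", 1:10))),
                             b = matrix(rnorm(100), 20, 5,
                                        dimnames = list(NULL,
                                                        paste0("b", 1:5)))),
                        sample_ids = as.character(1:20))
  fm <- latent_factors(layers, "late", 0.5)
  cc <- component_feature_correlations(fm, layers)
  across <- cc[cc$layer == "b" & grepl("^a_", cc$component), ]
  expect_true(all(!across$applicable))
  expect_true(all(is.na(across$r)))
  own <- cc[cc$layer == "a" & grepl("^a_", cc$component), ]
  expect_true(all(own$applicable))
  # constant feature flagged
  layers2 <- multi_omics(list(a = cbind(layers[["a"]],
                                        const = rep(1, 20))),
                         sample_ids = as.character(1:20))
  cc2 <- component_feature_correlations(fm, layers2)
  expect_true(all(!cc2$applicable[cc2$feature_id == "const"]))
})
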