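plant_study <- function(n = 300, p = 60, n_active = 5, seed = 1,
                        alpha = 0.4, beta = 0.4, gamma = 0.1,
                        layers = 1) {
  specs <- lapply(seq_len(layers), function(i)
    list(p = p %/% layers, block_size = 5, rho = 0.3))
  names(specs) <- paste0("l", seq_len(layers))
  spec <- sim_spec(n = n, mode = "mediation", layer_specs = specs,
                   n_active = c(n_active, rep(0, layers - 1)),
                   alpha_effect = alpha, beta_effect = beta,
                   gamma_direct = gamma, seed = seed)
  sim <- simulate_mediation_study(spec)
  pp <- preprocess_study(sim$study, sim$omics)
  list(study = pp$study, omics = pp$omics,
       truth = paste0(sim$truth$layer, ".", sim$truth$feature_id))
}

test_that("early integration recovers planted mediators with few false hits", {
  px <- plant_study(n = 400, p = 80, n_active = 5, seed = 42)
  tab <- mediate_early(px$omics, px$study, seed = 42)
  hits <- sum(tab$feature_id[tab$significant] %in% px$truth)
  false <- sum(!tab$feature_id[tab$significant] %in% px$truth)
  expect_gte(hits, 4)
  expect_lte(false, 2)
  sel <- tab[tab$selected, ]
  expect_true(all(sel$beta != 0))
  expect_true(all(sel$ci_low <= sel$indirect & sel$indirect <= sel$ci_high))
  expect_true(all(sel$fdr_q >= sel$p))
})

test_that("a lone complete mediator carries the whole total effect", {
  set.seed(55)
  n <- 500
  x <- rnorm(n)
  M <- matrix(rnorm(n * 30), n, 30,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:30)))
  M[, 1] <- 0.6 * x + rnorm(n, sd = 0.5)
  y <- 0.5 * M[, 1] + rnorm(n, sd = 0.5)   # no direct effect
  study <- study_frame(sprintf("s%03d", 1:n), x, y)
  tab <- mediate_early(M, study, seed = 5)
  gamma <- attr(tab, "gamma")
  f1 <- tab[tab$feature_id == "f1", ]
  expect_true(f1$selected && f1$significant)
  # complete mediation: the indirect-effect CI covers the total effect
  expect_true(f1$ci_low <= gamma && gamma <= f1$ci_high)
  expect_equal(f1$pct_te, 100 * f1$indirect / gamma)
  expect_gt(f1$pct_te, 70)
})

test_that("zero total effect flags percent-mediated as undefined", {
  set.seed(66)
  n <- 300
  x <- rnorm(n)
  M <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  M[, 1] <- 0.3 * x + rnorm(n)
  y0 <- 0.8 * M[, 1] + rnorm(n, sd = 0.5)
  y <- as.vector(residuals(lm(y0 ~ x)))   # gamma exactly 0 by construction
  study <- study_frame(seq_len(n), x, y)
  tab <- mediate_early(M, study, seed = 5)
  expect_false(isTRUE(attr(tab, "pct_te_defined")))
  expect_true(all(is.na(tab$pct_te)))
  expect_false(all(is.na(tab$indirect[tab$selected])))
})

test_that("penalized selection is invariant to feature order", {
  px <- plant_study(n = 250, p = 40, n_active = 3, seed = 10)
  M <- concat_layers(px$omics)
  t1 <- mediate_early(M, px$study, seed = 4)
  set.seed(99)
  perm <- sample(ncol(M))
  t2 <- mediate_early(M[, perm], px$study, seed = 4)
  o1 <- t1[order(t1$feature_id), ]
  o2 <- t2[order(t2$feature_id), ]
  expect_equal(o1$selected, o2$selected)
  expect_equal(o1$beta, o2$beta, tolerance = 1e-8)
})

test_that("intermediate integration with equal multipliers reduces to early", {
  px <- plant_study(n = 250, p = 50, n_active = 3, seed = 3, layers = 2)
  early <- mediate_early(px$omics, px$study, seed = 6)
  suppressWarnings(
    im <- mediate_intermediate(px$omics, px$study, multipliers = c(2.5, 2.5),
                               bootstrap_B = 50, seed = 6))
  expect_identical(early$feature_id[early$selected],
                   im$feature_id[im$selected])
  # glmnet rescales penalty factors internally, so only relative
  # multipliers matter and the selected path coincides with early's
  expect_equal(attr(early, "lambda"), attr(im, "lambda"),
               tolerance = 1e-8)
})

test_that("tuning shrinks the signal layer less than the noise layer", {
  wins <- 0
  for (s in 1:15) {
    px <- plant_study(n = 150, p = 30, n_active = 4, seed = s, layers = 2,
                      alpha = 0.5, beta = 0.5)
    im <- mediate_intermediate(px$omics, px$study, bootstrap_B = 50,
                               seed = s)
    m <- attr(im, "multipliers")
    if (m["l2"] > m["l1"]) wins <- wins + 1
  }
  expect_gte(wins, 12)
})

test_that("bootstrap SEs stabilize with the number of resamples", {
  px <- plant_study(n = 150, p = 20, n_active = 2, seed = 8, layers = 2,
                    alpha = 0.6, beta = 0.6)
  im1 <- mediate_intermediate(px$omics, px$study, multipliers = c(1, 1),
                              bootstrap_B = 200, seed = 2)
  im2 <- mediate_intermediate(px$omics, px$study, multipliers = c(1, 1),
                              bootstrap_B = 2000, seed = 2)
  sel <- which(im1$selected & im2$selected & im1$se_beta > 0)
  expect_gt(length(sel), 0)
  rel <- abs(im1$se_beta[sel] - im2$se_beta[sel]) / im2$se_beta[sel]
  expect_lt(max(rel), 0.25)
})

test_that("late integration runs per layer and matches early on one layer", {
  px <- plant_study(n = 200, p = 40, n_active = 3, seed = 12, layers = 2)
  late <- mediate_late(px$omics, px$study, seed = 7)
  expect_named(late, c("l1", "l2"))
  comb <- combine_mediation_tables(late)
  expect_setequal(unique(comb$layer), c("l1", "l2"))
  sub <- multi_omics(unclass(px$omics)["l1"])
  expect_identical(mediate_early(sub, px$study, seed = 7),
                   mediate_late(sub, px$study, seed = 7)[["l1"]])
})
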