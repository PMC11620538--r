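cluster_sim <- function(n = 400, p = 5, delta = 0.8, mu_sep = 2, eta = 1,
                        seed = 1, layers = 1) {
  specs <- lapply(seq_len(layers), function(i)
    list(p = p, block_size = p, rho = 0))
  names(specs) <- paste0("l", seq_len(layers))
  spec <- sim_spec(n = n, mode = "latent_cluster", layer_specs = specs,
                   delta = delta, mu_sep = mu_sep, eta = eta,
                   noise_sd = 0.5, seed = seed)
  simulate_cluster_study(spec)
}

test_that("EM recovers well-separated clusters with monotone likelihood", {
  sim <- cluster_sim(n = 400, mu_sep = 2, seed = 11)
  fit <- lucid_early(sim$study, sim$omics, K = 2, seed = 3)
  expect_true(fit$converged)
  expect_true(is_nondecreasing(fit$loglik_trace))
  expect_equal(rowSums(fit$pips), rep(1, 400), tolerance = 1e-10)
  hard <- max.col(fit$pips)
  acc <- mean(hard == sim$truth$membership[, 1])
  expect_gte(max(acc, 1 - acc), 0.95)
  # canonical labels: cluster 2 is the high-outcome cluster
  expect_true(all(diff(fit$outcome_means) >= 0))
  expect_equal(fit$eta[1], 0)
})

test_that("exposure-to-cluster log-odds are recovered at large n", {
  errs <- vapply(1:5, function(s) {
    sim <- cluster_sim(n = 2000, seed = s)
    fit <- lucid_early(sim$study, sim$omics, K = 2, seed = s,
                       n_restarts = 2)
    fit$delta[1, "exposure"] - 0.8
  }, numeric(1))
  expect_lte(median(abs(errs)), 0.25)
})

test_that("a single cluster degenerates to grand means", {
  sim <- cluster_sim(n = 100, seed = 7)
  fit <- lucid_early(sim$study, sim$omics, K = 1, seed = 1)
  expect_true(all(fit$pips == 1))
  expect_equal(fit$eta, mean(sim$study$outcome))
  expect_equal(nrow(fit$delta), 0)
  expect_equal(as.vector(fit$mu),
               unname(colMeans(concat_layers(sim$omics))))
})

test_that("parallel integration enumerates configurations and finds signal", {
  expect_equal(nrow(enumerate_configurations(rep(2, 3))), 8L)
  expect_equal(nrow(enumerate_configurations(rep(2, 5))), 32L)
  # signal only in layer 1: its exposure-cluster odds should dominate
  wins <- 0
  for (s in 1:5) {
    spec <- sim_spec(n = 300, mode = "latent_cluster",
                     layer_specs = list(l1 = list(p = 4, block_size = 4,
                                                  rho = 0),
                                        l2 = list(p = 4, block_size = 4,
                                                  rho = 0)),
                     delta = c(1.2), mu_sep = 2, eta = c(1, 0.3),
                     noise_sd = 0.5, seed = s)
    sim <- simulate_cluster_study(spec)
    # break the exposure-cluster link in layer 2 by permuting that layer
    set.seed(1000 + s)
    perm <- sample(300)
    layers <- multi_omics(list(l1 = sim$omics[["l1"]],
                               l2 = sim$omics[["l2"]][perm, ]),
                          sample_ids = sim$study$sample_id)
    fit <- lucid_parallel(sim$study, layers, 2, seed = s)
    d1 <- abs(fit$fits$l1$delta[1, "exposure"])
    d2 <- abs(fit$fits$l2$delta[1, "exposure"])
    if (d1 > d2) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("parallel subgroup bookkeeping is complete and consistent", {
  sim <- cluster_sim(n = 200, seed = 9, layers = 3, p = 4)
  fit <- lucid_parallel(sim$study, sim$omics, 2, seed = 2)
  expect_equal(nrow(fit$subgroups), 8L)
  expect_equal(sum(fit$subgroups$n), 200L)
  expect_true(is_nondecreasing(fit$loglik_trace))
  for (f in fit$fits)
    expect_equal(rowSums(f$pips), rep(1, 200), tolerance = 1e-10)
})

test_that("parallel with one layer reproduces the early fit exactly", {
  sim <- cluster_sim(n = 150, seed = 13)
  par1 <- lucid_parallel(sim$study, sim$omics, 2, seed = 4)
  early <- lucid_early(sim$study, sim$omics, 2, seed = 4)
  expect_identical(par1$fits[[1]], early)
})

test_that("serial chaining passes PIPs forward and is reproducible", {
  sim <- cluster_sim(n = 200, seed = 15, layers = 2, p = 4)
  ch1 <- lucid_serial(sim$study, sim$omics, K = 2, seed = 5)
  ch2 <- lucid_serial(sim$study, sim$omics, K = 2, seed = 5)
  expect_identical(ch1, ch2)
  expect_false(ch1[[1]]$supervised)
  expect_true(ch1[[2]]$supervised)
})

test_that("a separable first layer makes serial equal hard-label chaining", {
  # near-noiseless first layer: PIPs collapse to 0/1
  spec <- sim_spec(n = 250, mode = "latent_cluster",
                   layer_specs = list(l1 = list(p = 6, block_size = 6,
                                                rho = 0),
                                      l2 = list(p = 4, block_size = 4,
                                                rho = 0)),
                   delta = 0.8, mu_sep = 8, eta = c(1, 0.5),
                   noise_sd = 0.5, seed = 17)
  sim <- simulate_cluster_study(spec)
  ch <- lucid_serial(sim$study, sim$omics, K = 2, seed = 6)
  pip1 <- ch[[1]]$pips[, 2]
  expect_true(all(pmin(pip1, 1 - pip1) < 1e-3))
  # downstream model on hard labels matches the PIP-chained one
  hard <- round(pip1)
  study2 <- sim$study
  study2$exposure <- hard
  ref <- lucid_early(study2, sim$omics[["l2"]], K = 2, supervised = TRUE,
                     seed = 7)
  alt <- lucid_early(sim$study, sim$omics[["l2"]], K = 2, seed = 7)
  # compare cluster means of the chained fit against the hard-label fit
  chained <- lucid_serial(sim$study, sim$omics, K = 2, seed = 6)[[2]]
  expect_equal(chained$mu, ref$mu, tolerance = 1e-3)
  expect_equal(chained$eta, ref$eta, tolerance = 1e-3)
})

test_that("chains over pure noise do not beat their permutation null", {
  ok <- 0
  for (s in 1:4) {
    study <- make_study(150, seed = 500 + s, rho_xy = 0,
                        covariates = FALSE)
    set.seed(600 + s)
    layers <- multi_omics(list(
      l1 = matrix(rnorm(150 * 4), 150, 4),
      l2 = matrix(rnorm(150 * 4), 150, 4)),
      sample_ids = study$sample_id)
    ch <- lucid_serial(study, layers, K = 2, seed = s)
    eta_obs <- abs(ch[[2]]$eta[2])
    # permutation null: same chain, outcome decoupled from everything
    # (permutations drawn up front: the fits reset the RNG internally)
    set.seed(700 + s)
    perms <- replicate(15, sample(nrow(study)))
    eta_null <- vapply(1:15, function(b) {
      st2 <- study
      st2$outcome <- study$outcome[perms[, b]]
      abs(lucid_serial(st2, layers, K = 2, seed = s)[[2]]$eta[2])
    }, numeric(1))
    if (eta_obs <= quantile(eta_null, 0.95)) ok <- ok + 1
  }
  expect_gte(ok, 3)
})

test_that("cluster omics profiles are PIP-weighted means", {
  sim <- cluster_sim(n = 100, seed = 19)
  fit <- lucid_early(sim$study, sim$omics, K = 2, seed = 2)
  Z <- concat_layers(sim$omics)
  prof <- cluster_omics_profile(fit, sim$omics)
  # hard-assignment limit: profile equals per-group sample means
  fit_hard <- fit
  hard <- max.col(fit$pips)
  fit_hard$pips <- cbind(as.numeric(hard == 1), as.numeric(hard == 2))
  prof_hard <- cluster_omics_profile(fit_hard, sim$omics)
  ref <- rbind(colMeans(Z[hard == 1, , drop = FALSE]),
               colMeans(Z[hard == 2, , drop = FALSE]))
  expect_equal(prof_hard$expected_value, as.vector(ref), tolerance = 1e-12)
  # uniform PIPs: both profiles collapse to the grand mean
  fit_unif <- fit
  fit_unif$pips <- matrix(0.5, 100, 2)
  prof_unif <- cluster_omics_profile(fit_unif, sim$omics)
  expect_equal(prof_unif$expected_value,
               rep(colMeans(Z), each = 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # converged model: mu matches the weighted profile (cluster-major order)
  # up to the final E-step half-step at the convergence tolerance
  expect_equal(prof$expected_value, as.vector(fit$mu), tolerance = 5e-3)
})

test_that("the outcome term changes few assignments under a null outcome", {
  study <- make_study(300, seed = 23, rho_xy = 0, covariates = FALSE)
  spec <- sim_spec(n = 300, mode = "latent_cluster",
                   layer_specs = list(l1 = list(p = 5, block_size = 5,
                                                rho = 0)),
                   delta = 0.8, mu_sep = 2, eta = 0, noise_sd = 1,
                   seed = 23)
  sim <- simulate_cluster_study(spec)
  study$sample_id <- sim$study$sample_id
  sup <- lucid_early(sim$study, sim$omics, K = 2, supervised = TRUE,
                     seed = 5)
  uns <- lucid_early(sim$study, sim$omics, K = 2, supervised = FALSE,
                     seed = 5)
  h_s <- max.col(sup$pips); h_u <- max.col(uns$pips)
  flips <- min(mean(h_s != h_u), mean(h_s != (3 - h_u)))
  expect_lt(flips, 0.05)
})
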