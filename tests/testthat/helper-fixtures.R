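# Small in-code fixtures shared across the suite.

# a minimal study frame with seeded exposure/outcome and two cohorts
make_study <- function(n = 100, seed = 1, rho_xy = 0.3, covariates = TRUE) {
  set.seed(seed)
  x <- rnorm(n)
  y <- rho_xy * x + rnorm(n, sd = sqrt(1 - rho_xy^2))
  covs <- if (covariates)
    data.frame(age = rnorm(n, 7, 0.5),
               sex = factor(sample(c("F", "M"), n, replace = TRUE)))
  else NULL
  study_frame(sprintf("s%04d", seq_len(n)), x, y, covariates = covs,
              cohort = rep(c("A", "B"), length.out = n))
}

# one-layer multi_omics of pure standard-normal noise
make_noise_omics <- function(n = 100, p = 20, seed = 1, name = "omics") {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%04d", seq_len(n)),
                              paste0("f", seq_len(p))))
  multi_omics(setNames(list(m), name))
}

# relative monotonicity check for log-likelihood traces
is_nondecreasing <- function(trace, tol = 1e-8) {
  if (length(trace) < 2) return(TRUE)
  all(diff(trace) >= -tol * pmax(abs(trace[-length(trace)]), 1))
}
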