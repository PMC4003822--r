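# shared fixture builders; everything is generated in code

# tiny dataset with exactly known values
toy_dataset <- function(centered = FALSE) {
  a <- matrix(c(1, 2, 3,
                4, 5, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("snp1", "snp2"), c("s1", "s2", "s3")))
  b <- a + 0.5
  intensity_dataset(a, b, centered = centered)
}

# a dataset whose three clusters lie exactly on known lines (no noise)
noiseless_dataset <- function(n_snps = 20, n_samples = 60, seed = 1) {
  cfg <- sim_config(n_snps = n_snps, n_samples = n_samples,
                    sigma_het = 1e-9, sigma_snp_sd = 0, sigma_x = 0.3,
                    snp_affinity_sd = 0, mono_frac = 0, seed = seed)
  simulate_dataset(cfg)
}

# default unit prior used where the exact prior values do not matter
unit_prior <- function(v = c(intercept = 0.01, slope = 0.005),
                       pi = c(0.375, 0.25, 0.375)) {
  bcr_prior(cbind(intercept = c(-3, 0, 3), slope = c(1, 1, 1)), v = v,
            pi = pi)
}

# independent OLS via the normal equations (oracle)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# independent augmented-least-squares solution of the Bayesian posterior
# mean: append one pseudo-observation per coefficient encoding the prior
augmented_ls_oracle <- function(X, y, beta_prior, v, w = rep(1, length(y))) {
  Xa <- rbind(X * sqrt(w), diag(1 / sqrt(v), ncol(X)))
  ya <- c(y * sqrt(w), beta_prior / sqrt(v))
  qr.solve(Xa, ya)
}

expect_dataset_equal <- function(a, b, tol = 1e-8) {
  expect_equal(a$snp_ids, b$snp_ids)
  expect_equal(a$sample_ids, b$sample_ids)
  expect_equal(unname(a$a_log), unname(b$a_log), tolerance = tol)
  expect_equal(unname(a$b_log), unname(b$b_log), tolerance = tol)
}
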