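test_that("posterior mean matches closed-form limits and the augmented oracle", {
  set.seed(1)
  X <- cbind(1, rnorm(10))
  y <- 7 + X[, 2] + rnorm(10, 0, 0.3)

  # flat-prior limit: huge prior variances recover OLS
  ols <- drop(solve(crossprod(X), crossprod(X, y)))
  flat <- bayes_posterior_mean(X, y, beta_prior = c(0, 0), v = c(1e12, 1e12))
  expect_equal(flat, ols, tolerance = 1e-6, ignore_attr = TRUE)

  # a prior mean equal to the OLS estimate is a fixed point of shrinkage
  fx <- bayes_posterior_mean(X, y, beta_prior = ols, v = c(0.5, 0.5))
  expect_equal(fx, ols, tolerance = 1e-10, ignore_attr = TRUE)

  # a very tight prior pins the estimate at its mean
  tight <- bayes_posterior_mean(X, y, beta_prior = c(7, 1),
                                v = c(1e-6, 1e-6))
  expect_equal(tight, c(7, 1), tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(tight,
               augmented_ls_oracle(X, y, c(7, 1), c(1e-6, 1e-6)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # weighted case against the augmented-least-squares oracle
  for (r in 1:25) {
    set.seed(100 + r)
    n <- sample(5:40, 1)
    Xr <- cbind(1, rnorm(n), rnorm(n))
    yr <- rnorm(n)
    w <- runif(n, 0, 2)
    bp <- rnorm(3)
    v <- runif(3, 0.01, 10)
    expect_equal(bayes_posterior_mean(Xr, yr, bp, v, weights = w),
                 augmented_ls_oracle(Xr, yr, bp, v, w),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the E step equals direct evaluation of scaled normal densities", {
  beta <- cbind(intercept = c(-3, 0, 3), slope = c(1, 1, 1))
  rownames(beta) <- c("AA", "AB", "BB")
  pi <- c(0.3, 0.3, 0.4)
  sigma <- 0.2
  x <- c(1.5, 0.2, -1.1, 0.0, 2.2)
  y <- c(-1.4, 0.3, 1.9, -3.0, 0.9)
  resp <- bcr_e_step(x, y, beta, sigma, pi)
  # direct per-point oracle
  for (i in seq_along(x)) {
    dens <- pi * dnorm(y[i], beta[, "intercept"] + beta[, "slope"] * x[i],
                       c(2, 1, 2) * sigma)
    expect_equal(unname(resp[i, ]), unname(dens / sum(dens)),
                 tolerance = 1e-12)
  }
  expect_equal(rowSums(resp), rep(1, 5), tolerance = 1e-9)

  # dominance: a point on one line with the others >= 10 sigma away
  r1 <- bcr_e_step(0, -3, beta, 0.2, c(1, 1, 1) / 3)
  expect_equal(unname(r1[1, ]), c(1, 0, 0), tolerance = 1e-9)

  # symmetry: coincident cluster lines and equal weights split the point
  # by the density heights alone -- the homozygote components carry twice
  # the spread, so the split is (1/4, 1/2, 1/4), equal for AA and BB
  beta_same <- cbind(intercept = c(0, 0, 0), slope = c(1, 1, 1))
  r2 <- bcr_e_step(1, 1, beta_same, 0.5, c(1, 1, 1) / 3)
  expect_equal(unname(r2[1, ]), c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(r2[1, 1], r2[1, 3])
})

test_that("the M step reduces to weighted OLS under hard responsibilities", {
  set.seed(5)
  n_per <- 30
  x <- c(rnorm(n_per, 2, 0.5), rnorm(n_per, 0, 0.5), rnorm(n_per, -2, 0.5))
  truth_k <- rep(1:3, each = n_per)
  y <- c(-3, 0, 3)[truth_k] + x + rnorm(3 * n_per, 0, 0.1)
  resp <- matrix(0, 3 * n_per, 3)
  resp[cbind(seq_along(x), truth_k)] <- 1
  flat <- bcr_prior(cbind(intercept = c(-3, 0, 3), slope = c(1, 1, 1)),
                    v = c(intercept = 1e9, slope = 1e9))
  up <- bcr_m_step(x, y, resp, flat)
  # per-cluster OLS oracle and a hand-loop for the de-scaled pooled variance
  ss <- 0
  for (k in 1:3) {
    sel <- truth_k == k
    oracle <- ols_oracle(x[sel], y[sel])
    expect_equal(unname(up$beta[k, ]), unname(oracle), tolerance = 1e-5)
    ss <- ss + sum((y[sel] - oracle[1] - oracle[2] * x[sel])^2) /
      c(2, 1, 2)[k]^2
  }
  expect_equal(up$sigma, sqrt(ss / (3 * n_per + 6)), tolerance = 1e-4)
  expect_equal(unname(up$pi), rep(1 / 3, 3))

  # an empty cluster keeps its prior mean
  resp0 <- resp
  resp0[, 2] <- 0
  resp0[truth_k == 2, 1] <- 1
  up0 <- bcr_m_step(x, y, resp0, flat)
  expect_equal(unname(up0$beta[2, ]), c(0, 1))
})

test_that("EM converges, recovers parameters and respects its controls", {
  prior <- unit_prior()
  sim <- noiseless_dataset(n_snps = 4, n_samples = 90, seed = 2)
  ds <- center_snps(sim$dataset)

  # near-noiseless data at the prior means: fast convergence, exact lines
  fit <- bcr_fit(ds$a_log[1, ], ds$b_log[1, ], prior,
                 control = bcr_control(tol = 1e-4))
  expect_true(fit$converged)
  expect_lte(fit$n_iter, 5)
  expect_equal(unname(fit$beta[, "intercept"]), c(-3, 0, 3), tolerance = 0.01)

  # infinite tolerance stops after exactly one iteration
  fit1 <- bcr_fit(ds$a_log[1, ], ds$b_log[1, ], prior,
                  control = bcr_control(tol = Inf))
  expect_equal(fit1$n_iter, 1L)

  # iteration cap is honoured
  fitc <- bcr_fit(ds$a_log[1, ], ds$b_log[1, ], prior,
                  control = bcr_control(tol = 0 + 1e-300, max_iter = 7))
  expect_lte(fitc$n_iter, 7L)

  # penalized objective is non-decreasing along the trace
  sim2 <- simulate_dataset(sim_config(n_snps = 30, n_samples = 100, seed = 3))
  ds2 <- center_snps(sim2$dataset)
  for (j in 1:30) {
    f <- bcr_fit(ds2$a_log[j, ], ds2$b_log[j, ], prior)
    expect_lte(f$n_iter, 30L)
    if (f$n_iter > 1)
      expect_gte(min(diff(f$objective)), -1e-8)
  }
})

test_that("genotype labels follow intercept order and the call threshold", {
  prior <- unit_prior()
  sim <- simulate_dataset(sim_config(n_snps = 10, n_samples = 80, seed = 6))
  ds <- center_snps(sim$dataset)
  fit <- bcr_fit(ds$a_log[2, ], ds$b_log[2, ], prior)

  # direct threshold arithmetic
  fit_fake <- fit
  fit_fake$resp <- matrix(c(0.9995, 0.0005, 0,
                            0.6, 0.4, 0), 2, 3, byrow = TRUE)
  g <- call_genotypes(fit_fake, threshold = 0.999)
  expect_equal(g$call, c("AA", "NoCall"))
  expect_equal(call_genotypes(fit_fake, threshold = 0)$call, c("AA", "AA"))

  # threshold 0 yields full call rate; thresholding trades calls for
  # concordance
  calls0 <- bcr_genotype(ds, prior, threshold = 0)
  calls9 <- bcr_genotype(ds, prior, threshold = 0.999)
  expect_equal(calls0$call_rate, 1)
  expect_gte(calls0$call_rate, calls9$call_rate)
  m0 <- evaluate_concordance(calls0, sim$truth)
  m9 <- evaluate_concordance(calls9, sim$truth)
  expect_gte(m9$concordance, m0$concordance)

  # permuting the prior's cluster rows changes nothing (label invariance)
  perm <- bcr_prior(prior$beta[c(2, 3, 1), ], v = prior$v,
                    pi = prior$pi[c(2, 3, 1)])
  calls_perm <- bcr_genotype(ds, perm, threshold = 0.999)
  expect_identical(calls_perm$calls, calls9$calls)

  # swapping the A and B channels maps AA calls to BB calls
  swapped <- intensity_dataset(sim$dataset$b_log, sim$dataset$a_log)
  calls_sw <- bcr_genotype(center_snps(swapped), prior, threshold = 0.999)
  flip <- c(AA = "BB", AB = "AB", BB = "AA", NoCall = "NoCall")
  expect_gte(mean(flip[calls9$calls] == calls_sw$calls), 0.99)
})

test_that("fit objects support the standard model-object methods", {
  prior <- unit_prior()
  sim <- simulate_dataset(sim_config(n_snps = 5, n_samples = 60, seed = 12))
  ds <- center_snps(sim$dataset)
  fit <- bcr_fit(ds$a_log[1, ], ds$b_log[1, ], prior)

  expect_s3_class(fit, "bcr_fit")
  expect_output(print(fit), "cluster-regression")
  expect_equal(dim(coef(fit)), c(3L, 2L))
  expect_equal(length(fitted(fit)), 60L)
  expect_equal(residuals(fit), fit$y - fitted(fit))
  expect_equal(dim(predict(fit)), c(60L, 3L))
  expect_lt(max(abs(residuals(fit))), 10 * fit$sigma)
  expect_s3_class(summary(fit), "summary.bcr_fit")
  expect_output(print(summary(fit)), "call rate")
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_equal(dim(sims), c(60L, 2L))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()

  # degenerate SNPs (< 4 samples) classify against the prior lines
  tiny <- bcr_fit(c(1.4, -1.6), c(-1.6, 1.4), prior)
  expect_true(tiny$degenerate)
  expect_equal(call_genotypes(tiny, threshold = 0.9)$call, c("AA", "BB"))
})
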