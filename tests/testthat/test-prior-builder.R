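test_that("pooling draws reproducible uniform subsets", {
  sim <- simulate_dataset(sim_config(n_snps = 50, n_samples = 40, seed = 8))
  ds <- center_snps(sim$dataset)

  # exhaustive draw returns every pair, any seed
  all1 <- pool_intensity_pairs(ds, size = NULL, seed = 1)
  all2 <- pool_intensity_pairs(ds, size = 2000, seed = 99)
  expect_equal(length(all1$x), 2000L)
  expect_equal(sort(all1$x), sort(all2$x))
  expect_equal(all1$d, all1$x - all1$y)

  # determinism under seed
  s1 <- pool_intensity_pairs(ds, 500, seed = 7)
  s2 <- pool_intensity_pairs(ds, 500, seed = 7)
  expect_identical(s1, s2)
  expect_error(pool_intensity_pairs(ds, 5000), "available")

  # genotype composition of a subset reflects the cohort's within 3 SE
  sim2 <- simulate_dataset(sim_config(n_snps = 500, n_samples = 60,
                                      mono_frac = 0, seed = 10))
  ds2 <- center_snps(sim2$dataset)
  sub <- pool_intensity_pairs(ds2, 5000, seed = 3)
  truth_g <- sim2$truth$genotype[cbind(sub$snp, sub$sample)]
  for (g in c("AA", "AB", "BB")) {
    p <- mean(sim2$truth$genotype == g)
    se <- sqrt(p * (1 - p) / 5000)
    expect_lt(abs(mean(truth_g == g) - p), 3 * se + 0.01)
  }

  # with a CNA matrix only copy-number normal pairs are pooled
  simt <- simulate_dataset(sim_config_tumor(n_snps = 100, n_samples = 30,
                                            seed = 4))
  dst <- center_snps(simt$dataset)
  subt <- pool_intensity_pairs(dst, 800, seed = 5, cna = simt$cna)
  expect_true(all(simt$cna[cbind(subt$snp, subt$sample)] == 0L))
})

test_that("first-difference splitter cuts the toy series at its two jumps", {
  # sorted d = (0,0,0, 5,5,5, 10,10,10); window 1; first differences are
  # zero except 5 at order positions 4 and 7, whose lower points sit at
  # rank fractions 3/9 and 6/9 -- inside the two percentile bands
  pts <- structure(list(x = numeric(9), y = numeric(9),
                        d = c(10, 0, 5, 0, 5, 10, 0, 5, 10),
                        labels = NULL, cuts = NULL),
                   class = "pooled_points")
  out <- split_clusters(pts, window = 1L)
  expect_equal(unname(table(out$labels)[c("BB", "AB", "AA")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_equal(out$labels[pts$d == 0], rep("BB", 3))
  expect_equal(out$labels[pts$d == 5], rep("AB", 3))
  expect_equal(out$labels[pts$d == 10], rep("AA", 3))
  expect_equal(out$cuts$lower, 2.5)
  expect_equal(out$cuts$upper, 7.5)
})

test_that("splitter separates well-separated blobs at >= 99% agreement", {
  set.seed(21)
  n_per <- 1000
  d <- c(rnorm(n_per, -2, 0.15), rnorm(n_per, 0, 0.15), rnorm(n_per, 2, 0.15))
  truth <- rep(c("BB", "AB", "AA"), each = n_per)
  pts <- structure(list(x = d / 2, y = -d / 2, d = d,
                        labels = NULL, cuts = NULL),
                   class = "pooled_points")
  out <- split_clusters(pts, window = 25L)
  expect_gte(mean(out$labels == truth), 0.99)

  # with gaps ten times the noise SD the cuts land inside the gaps: no
  # point of any blob is mislabelled
  d2 <- c(rnorm(n_per, -3, 0.1), rnorm(n_per, 0, 0.1), rnorm(n_per, 3, 0.1))
  truth2 <- rep(c("BB", "AB", "AA"), each = n_per)
  pts2 <- structure(list(x = d2 / 2, y = -d2 / 2, d = d2,
                         labels = NULL, cuts = NULL),
                    class = "pooled_points")
  out2 <- split_clusters(pts2, window = 25L)
  expect_equal(mean(out2$labels == truth2), 1)
  expect_gt(out2$cuts$lower, max(d2[truth2 == "BB"]))
  expect_lt(out2$cuts$lower, min(d2[truth2 == "AB"]))
})

test_that("generic prior estimation reproduces the cluster lines", {
  # exact fit: points on y = 2 + x give intercept 2, slope 1
  x <- c(seq(-1, 1, length.out = 30), rnorm(30, 4), rnorm(30, -4))
  y <- c(2 + x[1:30], x[31:60] - 5, x[61:90] + 5)
  labels <- rep(c("AB", "AA", "BB"), each = 30)
  pts <- structure(list(x = x, y = y, d = x - y, labels = labels),
                   class = "pooled_points")
  pr <- estimate_generic_prior(pts, slope_mode = "fitted")
  expect_equal(unname(pr$beta["AB", ]), c(2, 1), tolerance = 1e-10)

  # unit mode forces all slopes to 1 regardless of the data
  pr_unit <- estimate_generic_prior(pts, slope_mode = "unit")
  expect_equal(unname(pr_unit$beta[, "slope"]), c(1, 1, 1))

  # mixing proportions are the label proportions (reordered by intercept)
  expect_equal(unname(pr$pi), c(1 / 3, 1 / 3, 1 / 3))

  # simulated clusters: OLS matches the normal-equations oracle and lands
  # within 0.05 of the generating parameters
  set.seed(17)
  xs <- rnorm(6000, rep(c(2, 0, -2), each = 2000), 0.6)
  ys <- rep(c(-3, 0, 3), each = 2000) + xs + rnorm(6000, 0, 0.2)
  lab <- rep(c("AA", "AB", "BB"), each = 2000)
  pts2 <- structure(list(x = xs, y = ys, d = xs - ys, labels = lab),
                    class = "pooled_points")
  pr2 <- estimate_generic_prior(pts2, slope_mode = "fitted")
  for (k in 1:3) {
    sel <- lab == c("AA", "AB", "BB")[k]
    oracle <- ols_oracle(xs[sel], ys[sel])
    expect_equal(unname(pr2$beta[k, ]), unname(oracle), tolerance = 1e-10)
    expect_lt(abs(pr2$beta[k, "intercept"] - c(-3, 0, 3)[k]), 0.05)
    expect_lt(abs(pr2$beta[k, "slope"] - 1), 0.05)
  }

  expect_error(estimate_generic_prior(
    structure(list(x = 1:5, y = 1:5, d = numeric(5),
                   labels = c("AA", "AA", "AA", "AB", "BB")),
              class = "pooled_points")), "fewer than 3")
})

test_that("prior variance calibration follows the 1/3 and 3x rules", {
  # two hand-built monomorphic SNPs with known OLS sampling variances
  x1 <- seq(-1.5, 1.5, length.out = 12)
  y1 <- rep(c(0.1, -0.1), 6) + x1 - 3
  x2 <- seq(-2, 2, length.out = 12)
  y2 <- rep(c(0.2, -0.2), 6) + x2 - 3
  a <- matrix(c(x1, x2), 2, 12, byrow = TRUE)
  b <- matrix(c(y1, y2), 2, 12, byrow = TRUE)
  med <- apply(a, 1, median)
  a <- a - med
  b <- b - med
  ds <- intensity_dataset(a, b, centered = TRUE)
  ols_var <- function(x, y) {
    n <- length(x); X <- cbind(1, x)
    beta <- solve(crossprod(X), crossprod(X, y))
    s2 <- sum((y - X %*% beta)^2) / (n - 2)
    sxx <- sum((x - mean(x))^2)
    c(int = s2 * (1 / n + mean(x)^2 / sxx), slope = s2 / sxx)
  }
  v1 <- ols_var(a[1, ], b[1, ])
  v2 <- ols_var(a[2, ], b[2, ])
  v <- estimate_prior_variances(ds, cuts = list(lower = -1, upper = 1),
                                n_mono = 2)
  # hand-checkable arithmetic consequences of the rules
  expect_equal(unname(v["slope"]), unname(v1["slope"] + v2["slope"]) / 6)
  expect_equal(unname(v["intercept"]), 3 * unname(v1["int"] + v2["int"]) / 2)
  # a single repeated SNP gives exactly (that variance)/3 and 3x
  ds1 <- intensity_dataset(a[c(1, 1), ], b[c(1, 1), ], centered = TRUE)
  vv <- estimate_prior_variances(ds1, cuts = list(lower = -1, upper = 1),
                                 n_mono = 2)
  expect_equal(unname(vv["slope"]), unname(v1["slope"]) / 3)
  expect_equal(unname(vv["intercept"]), 3 * unname(v1["int"]))
  expect_error(
    estimate_prior_variances(ds, cuts = list(lower = -10, upper = 10)),
    "fewer than 10")
})

test_that("prior variances scale with the noise variance", {
  # doubling the noise SD multiplies both calibrated variances by ~4
  make <- function(sig, seed) {
    set.seed(seed)
    n_snp <- 120; n <- 80
    a <- matrix(rnorm(n_snp * n, 0, 0.4), n_snp, n)
    b <- a - 3 + matrix(rnorm(n_snp * n, 0, sig), n_snp, n)
    intensity_dataset(a - apply(a, 1, median), b - apply(a, 1, median),
                      centered = TRUE)
  }
  cuts <- list(lower = -1, upper = 1)
  v1 <- suppressWarnings(estimate_prior_variances(make(0.2, 1), cuts))
  v2 <- suppressWarnings(estimate_prior_variances(make(0.4, 1), cuts))
  expect_equal(unname(v2["slope"] / v1["slope"]), 4, tolerance = 0.25)
  expect_equal(unname(v2["intercept"] / v1["intercept"]), 4, tolerance = 0.25)
  # the 1/3 vs 3x rule ordering under equal underlying OLS variances
  expect_lt(v1["slope"], v1["intercept"])
})

test_that("per-SNP trained priors fit observed clusters and fall back", {
  gen <- unit_prior()
  # noiseless training: per-SNP priors equal the generating lines
  x <- c(rnorm(20, 2, 0.5), rnorm(20, 0, 0.5), rnorm(20, -2, 0.5))
  shift <- 0.7   # per-SNP offset a generic prior cannot know
  y <- rep(c(-3, 0, 3) + shift, each = 20) + x
  ds <- intensity_dataset(matrix(x, 1), matrix(y, 1), snp_ids = "snpA",
                          centered = TRUE)
  g <- matrix(rep(c("AA", "AB", "BB"), each = 20), 1)
  pri <- train_snp_priors(ds, g, gen)
  expect_equal(unname(pri$snpA$beta[, "intercept"]), c(-3, 0, 3) + shift,
               tolerance = 1e-8)
  expect_equal(unname(pri$snpA$beta[, "slope"]), rep(1, 3), tolerance = 1e-8)

  # monomorphic training SNP: absent clusters keep the generic entries
  ds_m <- intensity_dataset(matrix(rnorm(30, 2, 0.5), 1),
                            matrix(rnorm(30, -1, 0.5), 1),
                            snp_ids = "snpM", centered = TRUE)
  g_m <- matrix(rep("AA", 30), 1)
  pri_m <- train_snp_priors(ds_m, g_m, gen)
  expect_equal(pri_m$snpM$beta["AB", ], gen$beta["AB", c("intercept", "slope")])
  expect_equal(pri_m$snpM$beta["BB", ], gen$beta["BB", c("intercept", "slope")])
  # proportions floored so unseen genotypes stay callable
  expect_true(all(pri_m$snpM$pi > 0))

  # training/target sample overlap is refused
  expect_error(train_snp_priors(ds, g, gen, target_ids = ds$sample_ids[1]),
               "overlap")
  expect_silent(train_snp_priors(ds, g, gen, target_ids = ds$sample_ids[1],
                                 allow_overlap = TRUE))
})

test_that("priors round-trip through the plain-text serialization", {
  dir <- withr::local_tempdir()
  pr <- extend_prior_cn(unit_prior())
  f <- file.path(dir, "prior.tsv")
  write_prior(pr, f)
  back <- read_prior(f)
  expect_equal(back$beta, pr$beta)
  expect_equal(back$v, pr$v)
  expect_equal(back$pi, pr$pi)
})

test_that("cluster labels are assigned by intercept order", {
  # constructing a prior with shuffled rows yields the same object
  beta <- cbind(intercept = c(3, -3, 0), slope = c(1, 1, 1))
  pr <- bcr_prior(beta, v = c(intercept = 0.01, slope = 0.01),
                  pi = c(0.3, 0.4, 0.3))
  expect_equal(unname(pr$beta[, "intercept"]), c(-3, 0, 3))
  expect_equal(rownames(pr$beta), c("AA", "AB", "BB"))
  expect_equal(unname(pr$pi), c(0.4, 0.3, 0.3))
})
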