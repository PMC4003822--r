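#' Posterior mean of Bayesian linear regression coefficients
#'
#' Conjugate normal prior `N(beta_prior, sigma^2 V)` on the coefficients with
#' `V` diagonal and a frequentist error scale gives the closed-form posterior
#' mean `(V^-1 + X'WX)^-1 (V^-1 beta_prior + X'Wy)`, where `W` is a diagonal
#' matrix of non-negative observation weights (all ones recovers the
#' unweighted formula).  As the prior variances grow the result approaches
#' the weighted least-squares solution; a prior mean equal to the OLS
#' estimate is a fixed point of the shrinkage.
#'
#' @param X design matrix including the intercept column.
#' @param y response vector.
#' @param weights non-negative observation weights (default all ones).
#' @param beta_prior prior mean vector, one entry per column of `X`.
#' @param v positive prior variance scales (diagonal of `V`).
#' @return Numeric coefficient vector.
#' @export
bayes_posterior_mean <- function(X, y, beta_prior, v,
                                 weights = rep(1, length(y))) {
  X <- as.matrix(X)
  stopifnot(length(beta_prior) == ncol(X), length(v) == ncol(X),
            all(v > 0), all(weights >= 0))
  vinv <- diag(1 / v, ncol(X))
  wX <- X * weights
  A <- vinv + crossprod(X, wX)
  b <- vinv %*% beta_prior + crossprod(wX, y)
  drop(solve(A, b))
}

CLUSTER_SCALE <- c(2, 1, 2)  # homozygote error SD is twice the heterozygote's

cluster_means <- function(x, cn, beta) {
  mu <- outer(x, beta[, "slope"]) +
    rep(beta[, "intercept"], each = length(x))
  if (!is.null(cn) && "cn" %in% colnames(beta))
    mu <- mu + outer(cn, beta[, "cn"])
  mu
}

estep_internal <- function(x, y, cn, beta, sigma, pi) {
  mu <- cluster_means(x, cn, beta)
  logd <- stats::dnorm(y, mu, rep(CLUSTER_SCALE * sigma, each = length(y)),
                       log = TRUE)
  logd <- logd + rep(log(pi), each = length(y))
  m <- apply(logd, 1L, max)
  bad <- !is.finite(m)
  if (any(bad)) logd[bad, ] <- 0   # total underflow: uniform responsibilities
  w <- exp(logd - apply(logd, 1L, max))
  resp <- w / rowSums(w)
  attr(resp, "n_underflow") <- sum(bad)
  resp
}

#' Expectation step: cluster responsibilities
#'
#' Posterior probability that each sample's observation belongs to each
#' genotype cluster, `resp_ik` proportional to
#' `pi_k * N(y_i; x_i' beta_k, (c_k sigma)^2)` with the cluster error scale
#' factors `c = (2, 1, 2)` for (AA, AB, BB).  Densities are evaluated in log
#' space; if all three underflow for a sample it receives uniform
#' responsibilities.
#'
#' @param x,y A/B allele log-intensities for one SNP across samples.
#' @param beta 3 x p coefficient matrix (columns `intercept`, `slope`,
#'   optionally `cn`).
#' @param sigma base (heterozygote) error SD, positive.
#' @param pi mixing proportions.
#' @param cn optional fixed copy-number covariate vector.
#' @return n x 3 responsibility matrix, rows summing to one.
#' @export
bcr_e_step <- function(x, y, beta, sigma, pi, cn = NULL) {
  stopifnot(sigma > 0, all(is.finite(beta)))
  estep_internal(x, y, cn, beta, sigma, pi)
}

mstep_internal <- function(x, y, cn, resp, prior, ab_weight = NULL) {
  n <- length(y)
  has_cn <- !is.null(cn)
  coefs <- if (has_cn) c("intercept", "slope", "cn") else
    c("intercept", "slope")
  X <- if (has_cn) cbind(1, x, cn) else cbind(1, x)
  v <- prior$v[coefs]                  # the diagonal of V in the formula
  beta <- matrix(NA_real_, 3L, length(coefs),
                 dimnames = list(GT_LABELS, coefs))
  for (k in 1:3) {
    nk <- sum(resp[, k])
    if (nk < 1e-8) {                     # empty cluster: prior dominates
      beta[k, ] <- prior$beta[k, coefs]
    } else {
      beta[k, ] <- bayes_posterior_mean(
        X, y, beta_prior = prior$beta[k, coefs], v = v,
        weights = resp[, k] / CLUSTER_SCALE[k]^2)
    }
  }
  mu <- cluster_means(x, cn, beta)
  res2 <- (y - mu)^2
  # the conditional maximizer of the penalized objective: the prior
  # N(beta_prior, sigma^2 V) contributes its quadratic form and 3p
  # normalization terms; both corrections are O(p/n) against the
  # de-scaled pooled residual sum
  S <- sum(resp * res2 / rep(CLUSTER_SCALE^2, each = n))
  P <- sum((beta - prior$beta[, coefs, drop = FALSE])^2 /
             rep(v, each = 3L))
  sigma2 <- (S + P) / (sum(resp) + 3L * length(coefs))
  pi <- colSums(resp) / sum(resp)
  list(beta = beta, sigma = sqrt(sigma2), pi = stats::setNames(pi, GT_LABELS))
}

#' Maximization step: update coefficients, error scale and proportions
#'
#' Each cluster's coefficients are the Bayesian posterior mean
#' ([bayes_posterior_mean()]) under observation weights
#' `resp_ik / c_k^2`; the base error variance is the conditional maximizer
#' of the penalized objective (a frequentist pooling of the de-scaled
#' responsibility-weighted squared residuals, with the prior's quadratic
#' form as an `O(p/n)` correction); the mixing proportions are the
#' responsibility totals.  A cluster with essentially zero total
#' responsibility keeps its prior mean.  Every update is the exact
#' conditional maximizer, so each EM iteration cannot decrease the
#' penalized observed-data log-likelihood.
#'
#' @inheritParams bcr_e_step
#' @param resp n x 3 responsibility matrix.
#' @param prior a [bcr_prior()] (with a `cn` column if `cn` is supplied).
#' @return List with `beta`, `sigma`, `pi`.
#' @export
bcr_m_step <- function(x, y, resp, prior, cn = NULL) {
  stopifnot(inherits(prior, "bcr_prior"),
            nrow(resp) == length(y), ncol(resp) == 3L)
  mstep_internal(x, y, cn, resp, prior, NULL)
}

#' EM control parameters for [bcr_fit()]
#'
#' @param tol convergence tolerance on the maximum absolute change of any
#'   parameter (coefficients, proportions, error SD) between iterations.
#' @param max_iter iteration cap; parameters from the last iteration are the
#'   final estimates even without convergence.
#' @param ab_weight heterozygote weight applied to the initial mixing
#'   proportions: the prior proportions are multiplied by
#'   `(1, ab_weight, 1)` and renormalized before the first E step, starting
#'   the fit with the heterozygote down-weighted (AB observations are less
#'   frequent than homozygotes, and a homozygote-leaning start protects
#'   against spurious AB calls); subsequent proportion updates are the
#'   exact EM maximizers.
#' @return List of class `bcr_control`.
#' @export
bcr_control <- function(tol = 1e-6, max_iter = 30L, ab_weight = 0.5) {
  stopifnot(tol > 0 || is.infinite(tol), max_iter >= 1L,
            ab_weight > 0, ab_weight <= 1)
  structure(list(tol = tol, max_iter = max_iter, ab_weight = ab_weight),
            class = "bcr_control")
}

log_posterior <- function(x, y, cn, beta, sigma, pi, prior) {
  mu <- cluster_means(x, cn, beta)
  logd <- stats::dnorm(y, mu, rep(CLUSTER_SCALE * sigma, each = length(y)),
                       log = TRUE) + rep(log(pi), each = length(y))
  m <- apply(logd, 1L, max)
  ll <- sum(m + log(rowSums(exp(logd - m))))
  v <- prior$v[colnames(beta)]           # prior covariance is sigma^2 V
  lp <- sum(stats::dnorm(beta, prior$beta[, colnames(beta), drop = FALSE],
                         rep(sigma * sqrt(v), each = 3L), log = TRUE))
  ll + lp
}

#' Fit the per-SNP Bayesian cluster-regression mixture
#'
#' Fits a three-component mixture of linear regressions of the B-allele
#' log-intensity `y` on the A-allele log-intensity `x` (one component per
#' genotype cluster AA/AB/BB) by an EM algorithm.  Cluster coefficients get
#' conjugate normal priors `N(beta_prior_k, sigma^2 V)`; the base error SD
#' `sigma` is estimated frequentistically and scaled per cluster by
#' `c = (2, 1, 2)` so the homozygote clouds are allowed twice the
#' heterozygote spread.  An optional copy-number covariate (see
#' [cn_covariate()]) enters each cluster's regression as a fixed term, which
#' moves the heterozygote prediction line away from hemizygous observations
#' in copy-loss regions.
#'
#' Coefficients start at the prior means, proportions at the prior
#' proportions, and `sigma` at 1.4826 times the median absolute residual
#' from each point's nearest prior line.  Iteration stops when the largest
#' absolute parameter change drops below `control$tol` or after
#' `control$max_iter` (default 30) iterations; the last iteration's
#' parameters are the estimates.  SNPs with fewer than 4 samples skip EM and
#' are classified against the prior lines directly.
#'
#' @param x,y numeric vectors of centred A/B allele log-intensities for one
#'   SNP across samples.
#' @param prior a [bcr_prior()]; if `cn` is supplied and the prior lacks a
#'   `cn` column it is extended by [extend_prior_cn()].
#' @param cn optional copy-number covariate vector (log-intensity units),
#'   zero for samples without an alteration at this SNP.
#' @param control a [bcr_control()] list.
#' @return An object of class `bcr_fit` with elements `beta`, `sigma`,
#'   `pi`, `resp`, `n_iter`, `converged`, `objective` (per-iteration
#'   penalized log-likelihood trace), plus the inputs.  Standard methods
#'   (`print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, `plot`,
#'   `simulate`, `logLik`) are available.
#' @seealso [call_genotypes()] to turn a fit into calls, [bcr_genotype()]
#'   for whole datasets.
#' @export
bcr_fit <- function(x, y, prior, cn = NULL, control = bcr_control()) {
  stopifnot(inherits(prior, "bcr_prior"), length(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite log-intensities")
  if (length(y) < 2L) stop("need at least 2 samples per SNP")
  if (!is.null(cn)) {
    stopifnot(length(cn) == length(y))
    if (all(cn == 0)) cn <- NULL        # no alteration: identical to no-CN fit
  }
  if (!is.null(cn) && !("cn" %in% colnames(prior$beta)))
    prior <- extend_prior_cn(prior)
  coefs <- if (is.null(cn)) c("intercept", "slope") else
    c("intercept", "slope", "cn")
  beta <- prior$beta[, coefs, drop = FALSE]
  pi <- prior$pi * c(1, control$ab_weight, 1)
  pi <- pi / sum(pi)
  mu0 <- cluster_means(x, cn, beta)
  sigma <- 1.4826 * stats::median(apply(abs(y - mu0), 1L, min))
  sigma <- max(sigma, 1e-4)

  degenerate <- length(y) < 4L
  if (degenerate) {
    resp <- estep_internal(x, y, cn, beta, sigma, pi)
    fit <- list(beta = beta, sigma = sigma, pi = pi, resp = resp,
                n_iter = 0L, converged = TRUE, degenerate = TRUE,
                objective = log_posterior(x, y, cn, beta, sigma, pi, prior))
  } else {
    objective <- numeric(control$max_iter)
    converged <- FALSE
    iter <- 0L
    resp <- NULL
    while (iter < control$max_iter) {
      iter <- iter + 1L
      resp <- estep_internal(x, y, cn, beta, sigma, pi)
      up <- mstep_internal(x, y, cn, resp, prior, control$ab_weight)
      delta <- max(abs(up$beta - beta), abs(up$pi - pi),
                   abs(up$sigma - sigma))
      beta <- up$beta; sigma <- up$sigma; pi <- up$pi
      if (!all(is.finite(beta)) || !is.finite(sigma) || sigma <= 0)
        stop("non-finite parameter during EM")
      objective[iter] <- log_posterior(x, y, cn, beta, sigma, pi, prior)
      if (delta < control$tol) { converged <- TRUE; break }
    }
    resp <- estep_internal(x, y, cn, beta, sigma, pi)
    fit <- list(beta = beta, sigma = sigma, pi = pi, resp = resp,
                n_iter = iter, converged = converged, degenerate = FALSE,
                objective = objective[seq_len(iter)])
  }
  fit$x <- x
  fit$y <- y
  fit$cn <- cn
  fit$prior <- prior
  fit$scale <- CLUSTER_SCALE
  fit$n_underflow <- attr(fit$resp, "n_underflow")
  attr(fit$resp, "n_underflow") <- NULL
  class(fit) <- "bcr_fit"
  fit
}

#' Turn a fitted SNP model into genotype calls
#'
#' Each sample is assigned the cluster with the highest responsibility,
#' mapped through intercept order (lowest fitted intercept is `AA`).  When
#' no cluster posterior reaches `threshold` the sample gets `NoCall`;
#' withholding uncertain calls lowers the call rate but raises concordance.
#' For samples flagged as copy-number loss only one allele is present, so
#' with `hemizygous_notation = TRUE` their homozygote calls are rendered
#' `A`/`B`.
#'
#' @param fit a [bcr_fit()].
#' @param threshold minimum posterior probability for a call (default
#'   0.999); use 0 for a 100% call rate.
#' @param cn_status optional per-sample status codes (-1 loss, 0 normal,
#'   1 gain) used only for hemizygous notation.
#' @param hemizygous_notation render calls in loss samples as `A`/`B`.
#' @return Data frame with columns `call` and `posterior`.
#' @export
call_genotypes <- function(fit, threshold = 0.999, cn_status = NULL,
                           hemizygous_notation = FALSE) {
  stopifnot(inherits(fit, "bcr_fit"))
  ord <- order(fit$beta[, "intercept"])
  labels <- character(3L)
  labels[ord] <- GT_LABELS
  best <- max.col(fit$resp, ties.method = "first")
  post <- fit$resp[cbind(seq_along(best), best)]
  call <- labels[best]
  call[post < threshold] <- "NoCall"
  if (hemizygous_notation && !is.null(cn_status)) {
    loss <- cn_status == -1L
    call[loss & call == "AA"] <- "A"
    call[loss & call == "BB"] <- "B"
  }
  data.frame(call = call, posterior = post, stringsAsFactors = FALSE)
}

#' @export
print.bcr_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian cluster-regression fit: %d samples, sigma = %.4f, %s after %d iteration(s)\n",
    length(x$y), x$sigma,
    if (x$converged) "converged" else "iteration cap reached", x$n_iter))
  print(round(cbind(x$beta, pi = x$pi), 4))
  invisible(x)
}

#' @export
coef.bcr_fit <- function(object, ...) object$beta

#' @export
logLik.bcr_fit <- function(object, ...) {
  mu <- cluster_means(object$x, object$cn, object$beta)
  logd <- stats::dnorm(object$y, mu,
                       rep(object$scale * object$sigma,
                           each = length(object$y)), log = TRUE) +
    rep(log(object$pi), each = length(object$y))
  m <- apply(logd, 1L, max)
  val <- sum(m + log(rowSums(exp(logd - m))))
  structure(val, df = length(object$beta) + 3L,
            nobs = length(object$y), class = "logLik")
}

#' @export
predict.bcr_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata$x
  cn <- if (is.null(newdata)) object$cn else newdata$cn
  if (!is.null(object$cn) && is.null(cn))
    cn <- rep(0, length(x))
  cluster_means(x, cn, object$beta)
}

#' @export
fitted.bcr_fit <- function(object, ...) {
  mu <- cluster_means(object$x, object$cn, object$beta)
  mu[cbind(seq_along(object$y), max.col(object$resp, ties.method = "first"))]
}

#' @export
residuals.bcr_fit <- function(object, ...) object$y - fitted(object)

#' @export
summary.bcr_fit <- function(object, threshold = 0.999, ...) {
  calls <- call_genotypes(object, threshold = threshold)
  out <- list(beta = object$beta, sigma = object$sigma, pi = object$pi,
              n_iter = object$n_iter, converged = object$converged,
              threshold = threshold,
              call_table = table(factor(calls$call,
                                        levels = c(GT_LABELS, "NoCall"))),
              call_rate = mean(calls$call != "NoCall"))
  class(out) <- "summary.bcr_fit"
  out
}

#' @export
print.summary.bcr_fit <- function(x, ...) {
  cat("Per-SNP Bayesian cluster regression\n")
  print(round(cbind(x$beta, pi = x$pi), 4))
  cat(sprintf("sigma = %.4f (het; hom scale x2), %d iteration(s)%s\n",
              x$sigma, x$n_iter, if (x$converged) "" else " (cap reached)"))
  cat(sprintf("calls at threshold %.4g (call rate %.3f):\n",
              x$threshold, x$call_rate))
  print(x$call_table)
  invisible(x)
}

#' @export
plot.bcr_fit <- function(x, threshold = 0.999, ...) {
  calls <- call_genotypes(x, threshold = threshold)
  cols <- c(AA = "#1b61a6", AB = "#1a9641", BB = "#d7191c",
            NoCall = "grey60")
  graphics::plot(x$x, x$y, col = cols[calls$call], pch = 19, cex = 0.7,
                 xlab = "A-allele log-intensity (centred)",
                 ylab = "B-allele log-intensity (centred)", ...)
  graphics::abline(0, 1, lwd = 2)
  for (k in 1:3)
    graphics::abline(x$beta[k, "intercept"], x$beta[k, "slope"],
                     lty = 3, col = cols[k])
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
simulate.bcr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$y)
  mu <- cluster_means(object$x, object$cn, object$beta)
  out <- as.data.frame(matrix(NA_real_, n, nsim))
  names(out) <- paste0("sim_", seq_len(nsim))
  for (s in seq_len(nsim)) {
    k <- sample.int(3L, n, replace = TRUE, prob = object$pi)
    out[[s]] <- stats::rnorm(n, mu[cbind(seq_len(n), k)],
                             object$scale[k] * object$sigma)
  }
  out
}
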