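new_bcr_calls <- function(calls, posterior, threshold, diag = NULL) {
  structure(list(calls = calls, posterior = posterior,
                 threshold = threshold,
                 call_rate = mean(calls != "NoCall"),
                 diag = diag),
            class = "bcr_calls")
}

#' Genotype a whole dataset by per-SNP Bayesian cluster regression
#'
#' Runs [bcr_fit()] and [call_genotypes()] for every SNP of a centred
#' dataset.  SNPs are modelled independently, so the result does not depend
#' on processing order.  When a CNA status matrix is supplied the fixed
#' copy-number covariate is built with [cn_covariate()] and the prior is
#' extended with a weak copy-number coefficient; SNPs whose samples are all
#' copy-number normal are fitted without the covariate, so an all-normal
#' status matrix reproduces the CNA-naive run exactly.
#'
#' @param dataset a centred [intensity_dataset()].
#' @param prior either a single generic [bcr_prior()] used for every SNP or
#'   a named list of per-SNP priors (see [train_snp_priors()]); defaults to
#'   [build_prior()] on the dataset itself.
#' @param cna optional integer SNP x sample CNA status matrix (-1 loss,
#'   0 normal, 1 gain).
#' @param threshold posterior-probability call threshold (default 0.999);
#'   0 forces a 100% call rate.
#' @param control a [bcr_control()].
#' @param hemizygous_notation render homozygote calls in loss samples as
#'   `A`/`B`.
#' @param constant covariate magnitude; defaults to [cn_constant()].
#' @return An object of class `bcr_calls`: call and posterior matrices, the
#'   overall call rate and a per-SNP diagnostic data frame (`n_iter`,
#'   `converged`, `sigma`, `failed`).
#' @export
bcr_genotype <- function(dataset, prior = NULL, cna = NULL,
                         threshold = 0.999, control = bcr_control(),
                         hemizygous_notation = FALSE,
                         constant = NULL) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  if (!dataset$centered) stop("dataset must be centred first (center_snps)")
  if (is.null(prior)) prior <- build_prior(dataset, cna = cna)
  n_snps <- nrow(dataset$a_log)
  n_samp <- ncol(dataset$a_log)

  cnv <- NULL
  if (!is.null(cna)) {
    if (is.null(constant)) constant <- cn_constant(dataset)
    cnv <- cn_covariate(dataset, cna, constant)
  }
  per_snp <- is.list(prior) && !inherits(prior, "bcr_prior")
  if (per_snp && !all(dataset$snp_ids %in% names(prior)))
    stop("per-SNP prior list is missing entries for some SNPs")

  calls <- matrix("NoCall", n_snps, n_samp,
                  dimnames = list(dataset$snp_ids, dataset$sample_ids))
  post <- matrix(0, n_snps, n_samp,
                 dimnames = list(dataset$snp_ids, dataset$sample_ids))
  diag <- data.frame(snp_id = dataset$snp_ids, n_iter = NA_integer_,
                     converged = NA, sigma = NA_real_, failed = FALSE,
                     stringsAsFactors = FALSE)
  for (j in seq_len(n_snps)) {
    pj <- if (per_snp) prior[[dataset$snp_ids[j]]] else prior
    cnj <- if (is.null(cnv)) NULL else cnv[j, ]
    res <- tryCatch({
      fit <- bcr_fit(dataset$a_log[j, ], dataset$b_log[j, ], pj,
                     cn = cnj, control = control)
      gc <- call_genotypes(fit, threshold = threshold,
                           cn_status = if (is.null(cna)) NULL else cna[j, ],
                           hemizygous_notation = hemizygous_notation)
      list(fit = fit, gc = gc)
    }, error = function(e) e)
    if (inherits(res, "error")) {        # abort this SNP: NoCall everywhere
      diag$failed[j] <- TRUE
      next
    }
    calls[j, ] <- res$gc$call
    post[j, ] <- res$gc$posterior
    diag$n_iter[j] <- res$fit$n_iter
    diag$converged[j] <- res$fit$converged
    diag$sigma[j] <- res$fit$sigma
  }
  if (any(diag$failed))
    warning(sprintf("%d SNP(s) failed to fit and were set to NoCall",
                    sum(diag$failed)))
  new_bcr_calls(calls, post, threshold, diag)
}

#' @export
print.bcr_calls <- function(x, ...) {
  cat(sprintf("Genotype calls: %d SNPs x %d samples, call rate %.4f",
              nrow(x$calls), ncol(x$calls), x$call_rate))
  if (is.finite(x$threshold))
    cat(sprintf(" (threshold %.4g)", x$threshold))
  cat("\n")
  invisible(x)
}

#' @export
summary.bcr_calls <- function(object, ...) {
  tab <- table(factor(object$calls,
                      levels = c("AA", "AB", "BB", "A", "B", "NoCall")))
  tab <- tab[tab > 0 | names(tab) %in% c("AA", "AB", "BB", "NoCall")]
  conv <- if (!is.null(object$diag))
    mean(object$diag$converged, na.rm = TRUE) else NA_real_
  out <- list(n_snps = nrow(object$calls), n_samples = ncol(object$calls),
              call_rate = object$call_rate, threshold = object$threshold,
              genotype_table = tab, converged_frac = conv)
  class(out) <- "summary.bcr_calls"
  out
}

#' @export
print.summary.bcr_calls <- function(x, ...) {
  cat(sprintf("Genotype calls for %d SNPs x %d samples\n",
              x$n_snps, x$n_samples))
  cat(sprintf("call rate %.4f at threshold %.4g\n",
              x$call_rate, x$threshold))
  print(x$genotype_table)
  if (!is.na(x$converged_frac))
    cat(sprintf("EM converged within the iteration cap for %.1f%% of SNPs\n",
                100 * x$converged_frac))
  invisible(x)
}
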