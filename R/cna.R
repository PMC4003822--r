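#' Estimate the copy-number covariate magnitude ("constant")
#'
#' The covariate magnitude is the larger of the absolute values of the 2.5th
#' and 97.5th percentiles of the log-ratios `d = x - y` pooled over all SNPs
#' and samples — roughly the full one-allele signal range, which is the
#' vertical scale on which an allele loss moves an observation.
#'
#' @param dataset a centred [intensity_dataset()].
#' @return Positive scalar (log-intensity units).
#' @export
cn_constant <- function(dataset) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  if (!dataset$centered) stop("dataset must be centred first (center_snps)")
  d <- dataset$a_log - dataset$b_log
  if (length(d) < 40L)
    stop("need at least 40 observations for stable percentile estimates")
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
  max(abs(q))
}

#' Build the fixed copy-number covariate from status calls
#'
#' Maps upstream copy-number status codes to the per-observation covariate
#' value entering the cluster regressions.  For a copy-loss sample the
#' remaining allele is the brighter one: if the A log-intensity exceeds the
#' B log-intensity the B allele was lost (`+constant`), otherwise the A
#' allele (`-constant`); ties count as B-allele loss.  Gains are coded
#' analogously with the brighter allele gained, at one fifth of the
#' magnitude (`+constant/5` for A gain, `-constant/5` for B gain) because
#' probe saturation compresses the intensity increase of extra copies.
#' Normal two-copy observations get zero.  The covariate is held fixed
#' during EM; only its per-cluster coefficient is estimated.
#'
#' @param dataset a centred [intensity_dataset()].
#' @param status integer SNP x sample matrix of codes (-1 loss, 0 normal,
#'   1 gain), as from [read_cna_tsv()].
#' @param constant positive covariate magnitude; defaults to
#'   [cn_constant()] of `dataset`.
#' @return Numeric SNP x sample matrix of covariate values in
#'   `{0, +-constant, +-constant/5}`.
#' @export
cn_covariate <- function(dataset, status, constant = cn_constant(dataset)) {
  stopifnot(inherits(dataset, "intensity_dataset"), constant > 0)
  status <- as.matrix(status)
  if (!identical(dim(status), dim(dataset$a_log)))
    stop("status matrix shape does not match the dataset")
  if (!all(status %in% c(-1L, 0L, 1L)))
    stop("CNA status codes must be -1, 0 or 1")
  a_brighter <- dataset$a_log >= dataset$b_log
  cn <- matrix(0, nrow(status), ncol(status), dimnames = dimnames(status))
  cn[status == -1L & a_brighter] <- constant        # B allele loss
  cn[status == -1L & !a_brighter] <- -constant      # A allele loss
  cn[status == 1L & a_brighter] <- constant / 5     # A allele gain
  cn[status == 1L & !a_brighter] <- -constant / 5   # B allele gain
  attr(cn, "constant") <- constant
  cn
}

#' Extend a prior with a weak copy-number coefficient entry
#'
#' Adds a `cn` column to the prior coefficient means (value 1 for every
#' cluster, so the covariate initially acts as a literal vertical shift of
#' the cluster line) with a weak prior variance of 100 times the slope
#' variance scale, letting the data dominate wherever the covariate varies.
#' Because the prior is weak, the pre-set values barely affect calls.
#'
#' @param prior a [bcr_prior()] without a `cn` entry (extending twice is an
#'   error).
#' @param cn_mean prior mean of the copy-number coefficient.
#' @param v_factor prior variance scale factor relative to the slope's.
#' @return The extended [bcr_prior()].
#' @export
extend_prior_cn <- function(prior, cn_mean = 1, v_factor = 100) {
  stopifnot(inherits(prior, "bcr_prior"))
  if ("cn" %in% colnames(prior$beta))
    stop("prior already has a copy-number entry")
  beta <- cbind(prior$beta, cn = rep(cn_mean, 3L))
  v <- c(prior$v, cn = unname(v_factor * prior$v[["slope"]]))
  bcr_prior(beta, v = v, pi = prior$pi)
}

#' Retrospective heterozygosity check of copy-loss regions
#'
#' In a true copy-loss region only one allele remains, so heterozygous (AB)
#' calls should be essentially absent.  For each sample the proportion of AB
#' calls among the called SNPs that the status matrix marks as loss is
#' computed; a proportion above 1% flags the sample and suggests the
#' upstream copy-number calls should be re-examined.  Samples with no
#' called loss-region SNPs report `NA` and are not flagged.
#'
#' @param calls a `bcr_calls` object (or a character call matrix).
#' @param status integer SNP x sample CNA status matrix (-1 loss).
#' @param flag_threshold proportion above which a sample is flagged.
#' @return Data frame with columns `sample_id`, `n_loss_snps` (called ones),
#'   `prop_ab`, `flagged`.
#' @export
het_check <- function(calls, status, flag_threshold = 0.01) {
  cm <- if (inherits(calls, "bcr_calls")) calls$calls else as.matrix(calls)
  status <- as.matrix(status)
  if (!identical(dim(cm), dim(status)))
    stop("calls and status matrices are not aligned")
  n_s <- ncol(cm)
  n_loss <- integer(n_s)
  prop <- rep(NA_real_, n_s)
  for (i in seq_len(n_s)) {
    sel <- status[, i] == -1L & cm[, i] != "NoCall"
    n_loss[i] <- sum(sel)
    if (n_loss[i] > 0L)
      prop[i] <- mean(cm[sel, i] %in% c("AB"))
  }
  data.frame(sample_id = colnames(cm) %||% as.character(seq_len(n_s)),
             n_loss_snps = n_loss, prop_ab = prop,
             flagged = !is.na(prop) & prop > flag_threshold,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
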