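#' Quantile-normalize arrays of a CNA-free cohort
#'
#' Forces every array (sample) to share one raw-intensity distribution.  The
#' A- and B-allele intensities of one sample come from the same physical
#' array, so they are pooled into a single per-sample vector; the stored
#' log-intensities are exponentiated, normalized on the raw scale (each rank
#' receives the mean across samples of the sorted values at that rank, the
#' classical reference-distribution construction of
#' [limma::normalizeQuantiles()]), and re-logged.  Tied values receive the
#' reference value at their average rank (interpolated), limma's convention.
#'
#' Quantile normalization assumes all samples share one underlying DNA
#' abundance distribution, which fails for samples with copy-number
#' alterations; the function therefore refuses to run when a CNA status
#' matrix is supplied unless `force = TRUE`.
#'
#' @param dataset an uncentred [intensity_dataset()] of log-intensities.
#' @param cna optional CNA status matrix; its presence signals a cohort with
#'   CNAs, for which QN is not recommended.
#' @param force logical, normalize even though `cna` was supplied.
#' @return The normalized dataset (still uncentred).
#' @export
quantile_normalize <- function(dataset, cna = NULL, force = FALSE) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  if (dataset$centered)
    stop("quantile normalization operates on uncentred intensities")
  if (!is.null(cna) && !force)
    stop("a CNA status matrix is present: quantile normalization is not ",
         "recommended for cohorts with copy-number alterations ",
         "(use force = TRUE to override)")
  n <- nrow(dataset$a_log)
  pooled <- rbind(exp(dataset$a_log), exp(dataset$b_log))
  norm <- limma::normalizeQuantiles(pooled, ties = TRUE)
  dataset$a_log <- log(norm[seq_len(n), , drop = FALSE])
  dataset$b_log <- log(norm[n + seq_len(n), , drop = FALSE])
  dimnames(dataset$a_log) <- dimnames(dataset$b_log) <-
    list(dataset$snp_ids, dataset$sample_ids)
  dataset
}
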