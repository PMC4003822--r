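#' Configuration for the synthetic allelic-intensity simulator
#'
#' Describes a cohort of SNP-array samples with known genotypes, optional
#' copy-number alteration (CNA) segments and normal-cell contamination.
#'
#' Geometry: per SNP a minor-allele frequency is drawn uniformly from
#' `maf_range` (the minor allele is A or B with equal probability) and
#' genotypes follow Hardy-Weinberg proportions.  Each allele channel has a
#' saturating copies-to-log-signal map with one copy step equal to
#' `loss_shift` (zero copies at `-loss_shift`, one at 0, two at
#' `+loss_shift`, a third copy adding only `gain_shift` because of probe
#' saturation), so with unit slopes the three diploid clusters sit on lines
#' `y = x + b` with intercepts `cluster_intercepts = (-2, 0, +2) *
#' loss_shift`.  A shared per-observation array effect spreads points along
#' the cluster line (`sigma_x`), and the response noise SD is `sigma_het`
#' for observations with both alleles present and `2 * sigma_het` otherwise,
#' matching the wider homozygote clouds on real arrays.
#'
#' CNAs: a loss makes the sample hemizygous at the SNP — the point moves to
#' the remaining allele's one-copy position (AB samples lose either allele
#' with equal probability, creating loss of heterozygosity).  A gain of one
#' copy of the brighter allele displaces the observation vertically by
#' `+-gain_shift`, one fifth of the per-copy loss scale and proportional to
#' the loss displacement as the regression model assumes (probe saturation
#' keeps the change of an extra copy small).  Normal-cell contamination
#' mixes the tumor and germline signal on the raw intensity scale before
#' logging, dragging CNA-affected points back toward their diploid
#' position — the main reason CNA-naive callers produce heterozygous calls
#' in loss regions.
#'
#' @param n_snps,n_samples cohort dimensions.
#' @param maf_range minor-allele frequency interval in (0, 0.5] for the
#'   polymorphic SNPs.
#' @param mono_frac fraction of SNPs that are monomorphic in the cohort
#'   (every sample AA, or every sample BB, with equal probability), as a
#'   sizeable fraction of array SNPs is in any one population; these SNPs
#'   are what calibrates the prior variance scales.
#' @param cluster_intercepts diploid cluster intercepts (AA, AB, BB), log
#'   units, strictly increasing; with the default copy map these are
#'   `(-3, 0, 3)`.
#' @param slopes per-cluster slopes; non-unit slopes are only supported for
#'   cohorts without CNAs or contamination.
#' @param sigma_het response noise SD of the heterozygote cluster;
#'   homozygotes get twice this value.
#' @param sigma_snp_sd SD of the per-SNP log noise multiplier: SNP `j` uses
#'   `sigma_het * exp(N(0, sigma_snp_sd^2))`, reflecting the wide quality
#'   differences between probe sets on real arrays; low-quality SNPs are
#'   where genotyping errors and NoCalls concentrate.
#' @param sigma_x spread of points along the cluster line.
#' @param snp_affinity_sd SD of per-SNP probe-affinity offsets, one per
#'   allele channel, shared by all samples of that SNP.  Probe sequences
#'   differ between SNPs, so each SNP's cluster lines sit at slightly
#'   different intercepts (shifted by the B-minus-A affinity difference);
#'   this is the per-SNP structure that a training step can learn and a
#'   generic prior cannot.
#' @param loss_shift per-copy log-signal step of the channel map.
#' @param gain_shift vertical displacement of a one-copy gain (saturated;
#'   one fifth of the loss scale).
#' @param cna_segments `NULL`, or a list with one entry per sample, each a
#'   data frame with columns `start`, `end`, `status` (-1 or 1) of
#'   non-overlapping SNP-index segments; see [random_cna_segments()].
#' @param contamination normal-cell fraction in `[0, 1)`, a scalar or one
#'   value per sample.
#' @param base baseline log-intensity added to both channels so raw
#'   intensities are positive and realistic.
#' @param seed integer seed making [simulate_dataset()] deterministic.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 1000L, n_samples = 100L,
                       maf_range = c(0.05, 0.5), mono_frac = 0.1,
                       cluster_intercepts = c(-3, 0, 3),
                       slopes = c(1, 1, 1),
                       sigma_het = 0.15, sigma_snp_sd = 0.3,
                       sigma_x = 0.3, snp_affinity_sd = 0.2,
                       loss_shift = (cluster_intercepts[3L] -
                                       cluster_intercepts[1L]) / 4,
                       gain_shift = loss_shift / 5,
                       cna_segments = NULL, contamination = 0,
                       base = 8, seed = 1L) {
  stopifnot(n_snps >= 1L, n_samples >= 1L,
            maf_range[1L] > 0, maf_range[2L] <= 0.5,
            mono_frac >= 0, mono_frac < 1,
            all(diff(cluster_intercepts) > 0),
            sigma_het > 0, sigma_snp_sd >= 0,
            sigma_x >= 0, snp_affinity_sd >= 0,
            loss_shift > 0, gain_shift >= 0)
  if (length(contamination) == 1L)
    contamination <- rep(contamination, n_samples)
  stopifnot(length(contamination) == n_samples,
            all(contamination >= 0 & contamination < 1))
  has_cna <- !is.null(cna_segments)
  if ((has_cna || any(contamination > 0)) && any(slopes != 1))
    stop("non-unit slopes are only supported without CNAs or contamination")
  if (has_cna) {
    stopifnot(length(cna_segments) == n_samples)
    for (segs in cna_segments) {
      if (is.null(segs) || nrow(segs) == 0L) next
      segs <- segs[order(segs$start), , drop = FALSE]
      stopifnot(all(segs$start >= 1L), all(segs$end <= n_snps),
                all(segs$end >= segs$start),
                all(segs$status %in% c(-1L, 1L)))
      if (nrow(segs) > 1L && any(segs$start[-1L] <= segs$end[-nrow(segs)]))
        stop("overlapping CNA segments for a sample")
    }
  }
  structure(list(n_snps = as.integer(n_snps),
                 n_samples = as.integer(n_samples),
                 maf_range = maf_range, mono_frac = mono_frac,
                 cluster_intercepts = cluster_intercepts, slopes = slopes,
                 sigma_het = sigma_het, sigma_snp_sd = sigma_snp_sd,
                 sigma_x = sigma_x, snp_affinity_sd = snp_affinity_sd,
                 loss_shift = loss_shift, gain_shift = gain_shift,
                 cna_segments = cna_segments,
                 contamination = contamination,
                 base = base, seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw random per-sample CNA segments
#'
#' Places, for every sample, non-overlapping contiguous SNP-index segments of
#' copy loss covering about `loss_frac` of the SNPs (in two segments) and of
#' copy gain covering about `gain_frac` (one segment).  Uses the current RNG
#' state.
#'
#' @param n_snps,n_samples cohort dimensions.
#' @param loss_frac,gain_frac fractions of SNPs covered per sample.
#' @return A list suitable for the `cna_segments` field of [sim_config()].
#' @export
random_cna_segments <- function(n_snps, n_samples, loss_frac = 0.2,
                                gain_frac = 0.1) {
  lens <- c(rep(ceiling(loss_frac * n_snps / 2), 2L),
            if (gain_frac > 0) ceiling(gain_frac * n_snps))
  stats <- c(-1L, -1L, if (gain_frac > 0) 1L)
  lapply(seq_len(n_samples), function(i) {
    for (try in 1:200) {
      starts <- sort(sample.int(n_snps - max(lens) + 1L, length(lens)))
      ends <- starts + lens[order(order(starts))] - 1L
      segs <- data.frame(start = starts, end = ends,
                         status = stats[order(order(starts))])
      if (all(segs$start[-1L] > segs$end[-nrow(segs)]) &&
          all(segs$end <= n_snps))
        return(segs)
    }
    stop("could not place non-overlapping CNA segments; lower the fractions")
  })
}

#' The canonical clean (CNA-free) and tumor study cohorts
#'
#' `sim_config_clean()` emulates a HapMap-like reference cohort: no CNAs, no
#' contamination.  `sim_config_tumor()` emulates a tumor cohort: per sample,
#' loss segments covering about 20% of the SNPs and one gain segment
#' covering about 10%, with normal-cell contamination drawn uniformly
#' between 10% and 40% per sample (tumor specimens are rarely pure, and
#' contamination is what drags hemizygous observations toward the
#' heterozygote cluster).
#'
#' @param n_snps,n_samples cohort dimensions.
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_config()].
#' @return A [sim_config()].
#' @export
sim_config_clean <- function(n_snps = 5000L, n_samples = 100L, seed = 1L,
                             ...) {
  sim_config(n_snps = n_snps, n_samples = n_samples, seed = seed, ...)
}

#' @rdname sim_config_clean
#' @export
sim_config_tumor <- function(n_snps = 2000L, n_samples = 80L, seed = 1L,
                             ...) {
  set.seed(seed)
  segs <- random_cna_segments(n_snps, n_samples,
                              loss_frac = 0.2, gain_frac = 0.1)
  contam <- stats::runif(n_samples, 0.10, 0.40)
  sim_config(n_snps = n_snps, n_samples = n_samples, cna_segments = segs,
             contamination = contam, seed = seed + 1L, ...)
}

#' Simulate an allelic-intensity dataset with known truth
#'
#' Generates A/B allele log-intensities, the CNA status matrix and the truth
#' needed to score calls, under the model described in [sim_config()].
#' Deterministic for a given configuration (including its seed).
#'
#' @param config a [sim_config()].
#' @return List of class `bcr_sim` with elements `dataset` (uncentred
#'   [intensity_dataset()]), `cna` (integer status matrix, all zero when the
#'   configuration has no segments), and `truth`: a list with `genotype`
#'   (germline genotypes), `expected` (the call a perfect caller would make:
#'   the remaining-allele homozygote in loss regions, the germline genotype
#'   elsewhere), `maf`, and the configuration.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_snps
  m <- config$n_samples
  step <- config$loss_shift
  copy_map <- c(-step, 0, step)                   # copies 0..2
  lvl <- function(copies) copy_map[copies + 1L]

  snp_ids <- sprintf("snp%05d", seq_len(n))
  sample_ids <- sprintf("s%03d", seq_len(m))

  status <- matrix(0L, n, m, dimnames = list(snp_ids, sample_ids))
  if (!is.null(config$cna_segments)) {
    for (i in seq_len(m)) {
      segs <- config$cna_segments[[i]]
      if (is.null(segs) || nrow(segs) == 0L) next
      for (r in seq_len(nrow(segs)))
        status[segs$start[r]:segs$end[r], i] <- segs$status[r]
    }
  }

  maf <- stats::runif(n, config$maf_range[1L], config$maf_range[2L])
  mono <- stats::runif(n) < config$mono_frac
  maf[mono] <- 0
  freq_b <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)
  geno <- matrix(NA_character_, n, m, dimnames = list(snp_ids, sample_ids))
  for (j in seq_len(n)) {
    p <- freq_b[j]
    geno[j, ] <- sample(GT_LABELS, m, replace = TRUE,
                        prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }

  nb_g <- matrix(match(geno, GT_LABELS) - 1L, n, m)   # germline B copies
  na_g <- 2L - nb_g
  na_t <- na_g
  nb_t <- nb_g
  expected <- geno

  loss <- which(status == -1L)
  if (length(loss)) {
    # remaining allele: the one the sample has more of; AB loses either
    keep_a <- na_g[loss] > nb_g[loss] |
      (na_g[loss] == nb_g[loss] & stats::runif(length(loss)) < 0.5)
    na_t[loss] <- ifelse(keep_a, 1L, 0L)
    nb_t[loss] <- ifelse(keep_a, 0L, 1L)
    expected[loss] <- ifelse(keep_a, "AA", "BB")
  }
  delta_b <- matrix(0, n, m)                      # tumor-only vertical shift
  gain <- which(status == 1L)
  if (length(gain)) {
    # one extra copy of the brighter (more abundant) allele; AB gains either
    add_a <- na_g[gain] > nb_g[gain] |
      (na_g[gain] == nb_g[gain] & stats::runif(length(gain)) < 0.5)
    delta_b[gain] <- ifelse(add_a, config$gain_shift, -config$gain_shift)
  }

  aff_a <- stats::rnorm(n, 0, config$snp_affinity_sd)
  aff_b <- stats::rnorm(n, 0, config$snp_affinity_sd)
  sigma_snp <- config$sigma_het * exp(stats::rnorm(n, 0, config$sigma_snp_sd))

  f <- rep(config$contamination, each = n)            # recycled per column
  a_mu <- log((1 - f) * exp(lvl(na_t)) + f * exp(lvl(na_g))) + aff_a
  b_mu <- log((1 - f) * exp(lvl(nb_t) + delta_b) + f * exp(lvl(nb_g))) + aff_b

  s <- stats::rnorm(n * m, 0, config$sigma_x)
  hom_like <- na_t == 0L | nb_t == 0L             # by allele presence
  eps <- stats::rnorm(n * m, 0, rep(sigma_snp, m) * ifelse(hom_like, 2, 1))

  if (all(config$slopes == 1)) {
    x <- a_mu + s
    y <- b_mu + s + eps
  } else {
    # textbook path (diploid cohorts only): x around a genotype centre,
    # y on the cluster line
    k <- match(geno, GT_LABELS)
    centre <- c(step, 0, -step)[k]
    x <- centre + s
    y <- config$cluster_intercepts[k] + config$slopes[k] * x + eps
  }
  a_log <- matrix(x + config$base, n, m, dimnames = list(snp_ids, sample_ids))
  b_log <- matrix(y + config$base, n, m, dimnames = list(snp_ids, sample_ids))

  structure(list(
    dataset = intensity_dataset(a_log, b_log, centered = FALSE),
    cna = status,
    truth = list(genotype = geno, expected = expected, maf = maf,
                 status = status,
                 intercept_shift = aff_b - aff_a,
                 sigma_snp = sigma_snp,
                 affinity = data.frame(snp_id = snp_ids, aff_a = aff_a,
                                       aff_b = aff_b),
                 config = config)),
    class = "bcr_sim")
}

#' @export
print.bcr_sim <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d SNPs x %d samples; %.1f%% loss, %.1f%% gain entries\n",
              nrow(x$cna), ncol(x$cna),
              100 * mean(x$cna == -1L), 100 * mean(x$cna == 1L)))
  invisible(x)
}

rate <- function(num, den) if (den > 0) num / den else NA_real_

#' Score genotype calls against simulation truth
#'
#' Computes call rates and concordance rates overall and separately for
#' truth-homozygous and truth-heterozygous entries (stratified by the
#' germline genotype), plus per-copy-number-stratum summaries: the
#' proportion of heterozygous calls among called entries and the genotyping
#' error rate — an error being a germline-homozygous entry called AB, or
#' called the opposite homozygote (a germline-heterozygous entry called
#' homozygous in a loss region is *not* an error: the allele really is
#' gone).  Concordance compares against the expected call (remaining-allele
#' homozygote in loss regions, germline genotype elsewhere).  Hemizygous
#' notation calls `A`/`B` are treated as `AA`/`BB`.
#'
#' @param calls a `bcr_calls` object (or character call matrix).
#' @param truth the `truth` element of a [simulate_dataset()] result.
#' @param status optional status matrix; defaults to the truth's.
#' @return List of class `bcr_concordance`; rates are fractions in `[0, 1]`
#'   (`NA` when a stratum is empty).
#' @export
evaluate_concordance <- function(calls, truth, status = NULL) {
  cm <- if (inherits(calls, "bcr_calls")) calls$calls else as.matrix(calls)
  if (is.null(status)) status <- truth$status
  stopifnot(identical(dim(cm), dim(truth$genotype)),
            identical(dim(cm), dim(status)))
  cm[cm == "A"] <- "AA"
  cm[cm == "B"] <- "BB"
  called <- cm != "NoCall"
  germ <- truth$genotype
  expd <- truth$expected
  hom <- germ != "AB"

  res <- list(
    call_rate = mean(called),
    call_rate_hom = rate(sum(called & hom), sum(hom)),
    call_rate_het = rate(sum(called & !hom), sum(!hom)),
    concordance = rate(sum(called & cm == expd), sum(called)),
    concordance_hom = rate(sum(called & hom & cm == expd),
                           sum(called & hom)),
    concordance_het = rate(sum(called & !hom & cm == expd),
                           sum(called & !hom)))

  strata <- c(loss = -1L, normal = 0L, gain = 1L)
  res$strata <- do.call(rbind, lapply(names(strata), function(nm) {
    sel <- status == strata[[nm]]
    nc <- sum(sel & called)
    err <- sel & called & hom &
      (cm == "AB" | (cm != "AB" & cm != germ))
    data.frame(stratum = nm, n = sum(sel), n_called = nc,
               call_rate = rate(sum(sel & called), sum(sel)),
               ab_prop = rate(sum(sel & called & cm == "AB"), nc),
               error_rate = rate(sum(err), nc),
               concordance = rate(sum(sel & called & cm == expd), nc),
               stringsAsFactors = FALSE)
  }))
  class(res) <- "bcr_concordance"
  res
}

#' @export
print.bcr_concordance <- function(x, ...) {
  cat(sprintf("call rate %.4f (hom %.4f, het %.4f)\n",
              x$call_rate, x$call_rate_hom, x$call_rate_het))
  cat(sprintf("concordance %.4f (hom %.4f, het %.4f)\n",
              x$concordance, x$concordance_hom, x$concordance_het))
  df <- x$strata
  df[, 4:7] <- round(df[, 4:7], 4)
  print(df, row.names = FALSE)
  invisible(x)
}
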