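GT_LABELS <- c("AA", "AB", "BB")

#' Construct a cluster-regression prior specification
#'
#' Holds the prior means of the per-cluster regression coefficients, the
#' diagonal prior variance scales and the initial mixing proportions used by
#' [bcr_fit()].  Clusters are labelled by intercept order: the cluster with
#' the lowest intercept (B-allele signal far below A) is `AA`, the highest is
#' `BB`.
#'
#' @param beta numeric matrix with one row per cluster (`AA`, `AB`, `BB`) and
#'   columns `intercept`, `slope` and optionally `cn`.
#' @param v named numeric vector of prior variance scales, one per
#'   coefficient column; all entries must be positive.  These are the
#'   diagonal entries of `V` in the conjugate prior `N(beta_prior,
#'   sigma^2 V)` and enter the posterior-mean formula as `V^-1` directly.
#' @param pi initial mixing proportions, positive, summing to one.
#' @return An object of class `bcr_prior`.
#' @export
bcr_prior <- function(beta, v, pi = c(0.375, 0.25, 0.375)) {
  beta <- as.matrix(beta)
  if (nrow(beta) != 3L) stop("exactly three clusters are required")
  if (is.null(colnames(beta)))
    colnames(beta) <- c("intercept", "slope", "cn")[seq_len(ncol(beta))]
  ord <- order(beta[, "intercept"])
  beta <- beta[ord, , drop = FALSE]
  pi <- pi[ord]
  rownames(beta) <- GT_LABELS
  if (is.unsorted(beta[, "intercept"], strictly = TRUE))
    stop("cluster intercepts must be distinct to assign genotype labels")
  v <- v[colnames(beta)]
  if (anyNA(v) || any(v <= 0))
    stop("prior variance scales must be positive for every coefficient")
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-8)
    stop("mixing proportions must be positive and sum to one")
  names(pi) <- GT_LABELS
  structure(list(beta = beta, v = v, pi = pi), class = "bcr_prior")
}

#' @export
print.bcr_prior <- function(x, ...) {
  cat("Cluster-regression prior\n")
  print(round(cbind(x$beta, pi = x$pi), 4))
  cat("prior variance scales:",
      paste(sprintf("%s=%.4g", names(x$v), x$v), collapse = ", "), "\n")
  invisible(x)
}

#' Pool a random subset of (A, B) log-intensity pairs across SNPs and samples
#'
#' Draws `size` (SNP, sample) pairs uniformly without replacement from a
#' centred dataset and records their A/B log-intensities together with the
#' log-ratio `d = x - y` that separates the three genotype clusters.  Subsets
#' of roughly 5,000 to 50,000 pairs are ample for prior construction.
#'
#' @param dataset a centred [intensity_dataset()].
#' @param size number of pairs to draw; `NULL` or the total count pools
#'   everything.
#' @param seed optional integer seed for a reproducible draw.
#' @param cna optional CNA status matrix; when given, only copy-number
#'   normal (status 0) pairs are pooled, since CNA-affected observations do
#'   not sit on the diploid cluster lines the prior describes.
#' @return An object of class `pooled_points` with elements `x`, `y`, `d`
#'   and (after [split_clusters()]) `labels` and `cuts`.
#' @export
pool_intensity_pairs <- function(dataset, size = 5000L, seed = NULL,
                                 cna = NULL) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  if (!dataset$centered) stop("dataset must be centred first (center_snps)")
  pool <- if (is.null(cna)) seq_along(dataset$a_log) else which(cna == 0L)
  total <- length(pool)
  if (is.null(size)) size <- total
  if (size > total)
    stop(sprintf("requested %d pairs but only %d are available", size, total))
  if (!is.null(seed)) set.seed(seed)
  idx <- if (size == total) pool else pool[sample.int(total, size)]
  x <- dataset$a_log[idx]
  y <- dataset$b_log[idx]
  structure(list(x = x, y = y, d = x - y,
                 snp = ((idx - 1L) %% nrow(dataset$a_log)) + 1L,
                 sample = ((idx - 1L) %/% nrow(dataset$a_log)) + 1L,
                 labels = NULL, cuts = NULL),
            class = "pooled_points")
}

#' Split pooled intensity pairs into the three genotype clusters
#'
#' Sorts the log-ratios `d = x - y` and computes the first differences
#' `d_(t) - d_(t-1)` of the sorted values.  The two cluster boundaries sit in
#' the two widest gaps, located by a trailing un-weighted moving average of
#' the first differences: the maximum smoothed value is searched once among
#' gaps whose lower point lies between the 25th (exclusive) and 50th
#' (inclusive) percentile of the sorted order, and once between the 50th
#' (exclusive) and 75th (inclusive).  Ties in the smoothed maximum are broken
#' toward the band centre, and within the trailing window of the winning
#' smoothed value the single largest raw difference is taken as the cut so
#' the boundary falls inside the gap itself.  Points below the lower cut are
#' labelled `BB`, points above the upper cut `AA`, the rest `AB`.
#'
#' @param points a [pool_intensity_pairs()] result.
#' @param window moving-average window length (number of previous first
#'   differences averaged); default 25.
#' @return `points` with `labels` (in the original point order) and `cuts`,
#'   a list with the two cut values of `d` (`lower` = BB/AB, `upper` =
#'   AB/AA) and the cut indices in sort order.
#' @export
split_clusters <- function(points, window = 25L) {
  stopifnot(inherits(points, "pooled_points"))
  n <- length(points$d)
  if (n < 3L * window)
    stop("need at least 3*window pooled points; draw a larger subset")
  ord <- order(points$d)
  ds <- points$d[ord]
  gaps <- diff(ds)                      # gap t sits between ds[t] and ds[t+1]
  ma <- stats::filter(gaps, rep(1 / window, window), sides = 1L)
  ma <- as.numeric(ma)                  # NA for the first window-1 gaps

  locate <- function(lo, hi) {
    # gaps whose lower point rank fraction lies in (lo, hi]
    band <- which(seq_along(gaps) / n > lo & seq_along(gaps) / n <= hi)
    band <- band[!is.na(ma[band])]
    if (!length(band))
      stop("no candidate cut in the ", lo * 100, "-", hi * 100,
           " percentile band; draw a larger subset")
    best <- band[ma[band] == max(ma[band])]
    if (length(best) > 1L) {           # tie: prefer the gap nearest band centre
      centre <- (lo + hi) / 2 * n
      best <- best[which.min(abs(best - centre))]
    }
    win <- max(1L, best - window + 1L):best
    win[which.max(gaps[win])]
  }

  g1 <- locate(0.25, 0.50)
  g2 <- locate(0.50, 0.75)
  labs_sorted <- rep("AB", n)
  labs_sorted[seq_len(g1)] <- "BB"
  labs_sorted[(g2 + 1L):n] <- "AA"
  labels <- character(n)
  labels[ord] <- labs_sorted
  points$labels <- labels
  points$cuts <- list(lower = (ds[g1] + ds[g1 + 1L]) / 2,
                      upper = (ds[g2] + ds[g2 + 1L]) / 2,
                      index = c(g1, g2))
  points
}

ols_line <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("degenerate cluster: no spread in the predictor")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  s2 <- if (n > 2L) sum(res^2) / (n - 2L) else NA_real_
  list(intercept = intercept, slope = slope, s2 = s2,
       var_slope = s2 / sxx, var_intercept = s2 * (1 / n + mean(x)^2 / sxx))
}

#' Estimate the generic (pooled) prior means from labelled pooled points
#'
#' Fits an ordinary least-squares line of `y` on `x` within each labelled
#' cluster; the fitted intercept and slope become the prior means for that
#' cluster, and the label proportions become the initial mixing proportions.
#' Since allelic log-intensity clouds are close to symmetric about the
#' 45-degree line, `slope_mode = "unit"` (the default) replaces all fitted
#' slopes by 1, which works well in practice; `"fitted"` keeps the OLS
#' slopes.
#'
#' @param points labelled pooled points from [split_clusters()].
#' @param slope_mode `"unit"` or `"fitted"`.
#' @param v prior variance scales to attach (see
#'   [estimate_prior_variances()]); a loose default is used if omitted.
#' @return A [bcr_prior()].
#' @export
estimate_generic_prior <- function(points, slope_mode = c("unit", "fitted"),
                                   v = c(intercept = 0.01, slope = 0.01)) {
  slope_mode <- match.arg(slope_mode)
  if (is.null(points$labels)) stop("points must be labelled (split_clusters)")
  beta <- matrix(NA_real_, 3L, 2L,
                 dimnames = list(GT_LABELS, c("intercept", "slope")))
  pi <- numeric(3L)
  for (k in seq_along(GT_LABELS)) {
    sel <- points$labels == GT_LABELS[k]
    if (sum(sel) < 3L)
      stop("cluster ", GT_LABELS[k], " has fewer than 3 points")
    fit <- ols_line(points$x[sel], points$y[sel])
    beta[k, ] <- c(fit$intercept, fit$slope)
    pi[k] <- mean(sel)
  }
  if (slope_mode == "unit") beta[, "slope"] <- 1
  bcr_prior(beta, v = v, pi = pi)
}

#' Calibrate the prior variance scales from monomorphic SNPs
#'
#' Selects SNPs carrying a single genotype (all samples AA or all BB), fits
#' an ordinary least-squares line per SNP and averages the sampling variances
#' of the slope and intercept estimates.  One third of the average slope
#' variance is used as the prior variance scale for the slope, so the slope
#' prior exerts substantial shrinkage; three times the average intercept
#' variance is used for the intercept, so the intercepts are driven mostly by
#' the data.
#'
#' A SNP is considered monomorphic when at least 99% of its log-ratios
#' `d = x - y` fall beyond the AB/homozygote cut on one side (the cuts come
#' from [split_clusters()] on pooled data).
#'
#' @param dataset a centred [intensity_dataset()].
#' @param cuts the `cuts` element of a [split_clusters()] result (or a list
#'   with numeric `lower` and `upper` log-ratio thresholds).
#' @param n_mono number of monomorphic SNPs to average over (default 100);
#'   if fewer are found a warning is issued and all available ones are used
#'   (at least 10, otherwise an error).
#' @param seed optional seed for the random choice of SNPs.
#' @param cna optional CNA status matrix; when given, only copy-number
#'   normal observations of a SNP take part in the monomorphic screen and
#'   the per-SNP fits.
#' @return Named numeric vector `c(intercept = ..., slope = ...)` of prior
#'   variance scales.
#' @export
estimate_prior_variances <- function(dataset, cuts, n_mono = 100L,
                                     seed = NULL, cna = NULL) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  if (!dataset$centered) stop("dataset must be centred first (center_snps)")
  d <- dataset$a_log - dataset$b_log
  normal <- if (is.null(cna)) matrix(TRUE, nrow(d), ncol(d)) else cna == 0L
  n_normal <- rowSums(normal)
  frac_aa <- rowSums((d > cuts$upper) & normal) / pmax(n_normal, 1L)
  frac_bb <- rowSums((d < cuts$lower) & normal) / pmax(n_normal, 1L)
  mono <- which(pmax(frac_aa, frac_bb) >= 0.99 & n_normal >= 4L)
  if (length(mono) < min(n_mono, 10L))
    stop("fewer than 10 monomorphic SNPs found; cannot calibrate prior ",
         "variances")
  if (length(mono) < n_mono) {
    warning(sprintf("only %d monomorphic SNPs found (requested %d)",
                    length(mono), n_mono))
  } else {
    if (!is.null(seed)) set.seed(seed)
    mono <- sample(mono, n_mono)
  }
  vs <- vi <- numeric(length(mono))
  for (i in seq_along(mono)) {
    sel <- normal[mono[i], ]
    fit <- ols_line(dataset$a_log[mono[i], sel], dataset$b_log[mono[i], sel])
    vs[i] <- fit$var_slope
    vi[i] <- fit$var_intercept
  }
  c(intercept = 3 * mean(vi), slope = mean(vs) / 3)
}

#' Build a generic prior from a centred dataset in one step
#'
#' Convenience wrapper: pools a subset of intensity pairs, splits it into the
#' three genotype clusters by the first-difference search, estimates the
#' cluster prior means and mixing proportions, and calibrates the prior
#' variance scales from monomorphic SNPs.
#'
#' @param dataset a centred [intensity_dataset()].
#' @param subset_size pooled subset size (default 5000).
#' @param ma_window moving-average window for [split_clusters()].
#' @param slope_mode `"unit"` (default) or `"fitted"`.
#' @param n_mono monomorphic SNPs used for variance calibration.
#' @param seed optional integer seed.
#' @param cna optional CNA status matrix: restricts pooling and the
#'   monomorphic screen to copy-number normal observations.
#' @return A [bcr_prior()] with an attached `cuts` attribute (the log-ratio
#'   cluster boundaries, reused by the monomorphic screen).
#' @export
build_prior <- function(dataset, subset_size = 5000L, ma_window = 25L,
                        slope_mode = c("unit", "fitted"), n_mono = 100L,
                        seed = NULL, cna = NULL) {
  slope_mode <- match.arg(slope_mode)
  if (!is.null(seed)) set.seed(seed)
  avail <- if (is.null(cna)) length(dataset$a_log) else sum(cna == 0L)
  subset_size <- min(subset_size, avail)
  points <- pool_intensity_pairs(dataset, subset_size, cna = cna)
  points <- split_clusters(points, window = ma_window)
  v <- estimate_prior_variances(dataset, points$cuts, n_mono = n_mono,
                                cna = cna)
  prior <- estimate_generic_prior(points, slope_mode = slope_mode, v = v)
  attr(prior, "cuts") <- points$cuts
  prior
}

#' Train per-SNP priors from samples with known genotypes
#'
#' For each SNP, fits an ordinary least-squares line per observed genotype
#' cluster of the training samples; the fitted intercepts and slopes become
#' that SNP's prior means.  Clusters with fewer than three training points
#' (or no predictor spread) fall back to the generic prior entries.  Mixing
#' proportions are the per-SNP training label proportions, floored at 0.01
#' and renormalized so that a genotype absent from the training set can
#' still be called in the target set.
#'
#' Training and target samples must be disjoint: reusing the same biological
#' samples for training and calling inflates apparent accuracy.
#'
#' @param training a centred [intensity_dataset()] of the training samples.
#' @param genotypes character matrix (SNP x training sample) of known
#'   genotypes `AA`/`AB`/`BB` (`NoCall` entries are ignored).
#' @param generic the generic [bcr_prior()] used for fallback entries and
#'   variance scales.
#' @param target_ids sample ids that will later be genotyped with these
#'   priors; supplying them enables the disjointness check.
#' @param allow_overlap set `TRUE` to skip the disjointness check.
#' @return A named list of [bcr_prior()] objects, one per SNP.
#' @export
train_snp_priors <- function(training, genotypes, generic,
                             target_ids = NULL, allow_overlap = FALSE) {
  stopifnot(inherits(training, "intensity_dataset"),
            inherits(generic, "bcr_prior"))
  if (!training$centered) stop("training dataset must be centred")
  if (!is.null(target_ids) && !allow_overlap) {
    overlap <- intersect(training$sample_ids, target_ids)
    if (length(overlap))
      stop("training and target samples overlap (e.g. ",
           overlap[1L], "); use allow_overlap = TRUE to override")
  }
  genotypes <- as.matrix(genotypes)
  if (!identical(dim(genotypes), dim(training$a_log)))
    stop("genotype matrix shape does not match the training dataset")
  out <- vector("list", nrow(training$a_log))
  names(out) <- training$snp_ids
  for (j in seq_along(out)) {
    beta <- generic$beta[, c("intercept", "slope"), drop = FALSE]
    counts <- numeric(3L)
    for (k in seq_along(GT_LABELS)) {
      sel <- which(genotypes[j, ] == GT_LABELS[k])
      counts[k] <- length(sel)
      if (length(sel) >= 3L) {
        x <- training$a_log[j, sel]
        y <- training$b_log[j, sel]
        if (sum((x - mean(x))^2) > 0)
          beta[k, ] <- unlist(ols_line(x, y)[c("intercept", "slope")])
      }
    }
    pi <- pmax(counts / max(sum(counts), 1L), 0.01)
    pi <- pi / sum(pi)
    # guard against rare label inversions in noisy training fits
    if (is.unsorted(beta[, "intercept"], strictly = TRUE))
      beta <- generic$beta[, c("intercept", "slope"), drop = FALSE]
    out[[j]] <- bcr_prior(beta, v = generic$v[c("intercept", "slope")],
                          pi = pi)
  }
  out
}

#' Write / read a prior specification as a plain-text table
#'
#' Serializes a [bcr_prior()] to a tab-delimited key-value table with
#' columns `record` (`beta`, `v` or `pi`), `cluster`, `coefficient` and
#' `value`, so priors can be inspected and versioned as text.
#'
#' @param prior a [bcr_prior()].
#' @param file path.
#' @export
write_prior <- function(prior, file) {
  stopifnot(inherits(prior, "bcr_prior"))
  rows <- list()
  for (k in rownames(prior$beta))
    for (cf in colnames(prior$beta))
      rows[[length(rows) + 1L]] <-
        data.frame(record = "beta", cluster = k, coefficient = cf,
                   value = prior$beta[k, cf])
  for (cf in names(prior$v))
    rows[[length(rows) + 1L]] <-
      data.frame(record = "v", cluster = ".", coefficient = cf,
                 value = prior$v[[cf]])
  for (k in names(prior$pi))
    rows[[length(rows) + 1L]] <-
      data.frame(record = "pi", cluster = k, coefficient = ".",
                 value = prior$pi[[k]])
  df <- do.call(rbind, rows)
  df$value <- sprintf("%.12g", df$value)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_prior
#' @export
read_prior <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  bet <- df[df$record == "beta", ]
  coefs <- unique(bet$coefficient)
  beta <- matrix(NA_real_, 3L, length(coefs),
                 dimnames = list(GT_LABELS, coefs))
  beta[cbind(match(bet$cluster, GT_LABELS),
             match(bet$coefficient, coefs))] <- as.numeric(bet$value)
  vdf <- df[df$record == "v", ]
  v <- stats::setNames(as.numeric(vdf$value), vdf$coefficient)
  pdf <- df[df$record == "pi", ]
  pi <- as.numeric(pdf$value)[match(GT_LABELS, pdf$cluster)]
  bcr_prior(beta, v = v, pi = pi)
}
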