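#' Construct an allelic intensity dataset
#'
#' Container for SNP x sample matrices of summarized A- and B-allele
#' log-intensities.  The A-allele log-intensity `x` is used as the predictor
#' and the B-allele log-intensity `y` as the response throughout the package.
#'
#' @param a_log numeric matrix of A-allele log-intensities (SNPs in rows,
#'   samples in columns).
#' @param b_log numeric matrix of B-allele log-intensities, same shape.
#' @param snp_ids,sample_ids character identifiers; default to the dimnames of
#'   `a_log`.
#' @param centered logical; `TRUE` once every SNP row has been centred at the
#'   median of its A-allele log-intensities (see [center_snps()]).
#' @return An object of class `intensity_dataset`: a list with elements
#'   `a_log`, `b_log`, `snp_ids`, `sample_ids`, `centered`.
#' @seealso [summarize_probes()], [center_snps()], [read_intensity_tsv()]
#' @export
intensity_dataset <- function(a_log, b_log, snp_ids = rownames(a_log),
                              sample_ids = colnames(a_log), centered = FALSE) {
  a_log <- as.matrix(a_log)
  b_log <- as.matrix(b_log)
  if (!identical(dim(a_log), dim(b_log)))
    stop("A and B log-intensity matrices must have identical dimensions")
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(a_log)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(a_log)))
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (length(snp_ids) != nrow(a_log) || length(sample_ids) != ncol(a_log))
    stop("identifier lengths do not match matrix dimensions")
  if (anyNA(a_log) || anyNA(b_log))
    stop("intensity matrices must not contain missing values")
  dimnames(a_log) <- dimnames(b_log) <- list(snp_ids, sample_ids)
  structure(list(a_log = a_log, b_log = b_log,
                 snp_ids = as.character(snp_ids),
                 sample_ids = as.character(sample_ids),
                 centered = isTRUE(centered)),
            class = "intensity_dataset")
}

#' @export
print.intensity_dataset <- function(x, ...) {
  cat(sprintf("Intensity dataset: %d SNPs x %d samples (%s)\n",
              nrow(x$a_log), ncol(x$a_log),
              if (x$centered) "centred" else "not centred"))
  invisible(x)
}

#' @export
dim.intensity_dataset <- function(x) dim(x$a_log)

#' Summarize probe-level measurements into one value per SNP, sample and allele
#'
#' Affymetrix-style arrays interrogate each SNP with several (typically 6-10)
#' probe pairs per allele.  The replicate raw intensities are averaged on the
#' raw scale and the mean is then log-transformed (natural log), giving one
#' A and one B log-intensity per (SNP, sample).
#'
#' (SNP, sample) pairs for which one allele has no measurement are dropped
#' with a warning reporting the number of dropped records.  Non-positive raw
#' intensities are an error (the row is named in the message).
#'
#' @param probe_table data frame with columns `snp_id`, `sample_id`, `allele`
#'   (`"A"` or `"B"`) and `intensity` (raw scale, strictly positive).
#' @return An uncentred [intensity_dataset()].
#' @export
summarize_probes <- function(probe_table) {
  need <- c("snp_id", "sample_id", "allele", "intensity")
  if (!all(need %in% names(probe_table)))
    stop("probe_table must have columns ", paste(need, collapse = ", "))
  bad <- which(!is.finite(probe_table$intensity) | probe_table$intensity <= 0)
  if (length(bad))
    stop("non-positive or non-finite intensity at probe_table row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (!all(probe_table$allele %in% c("A", "B")))
    stop("allele must be 'A' or 'B'")

  key <- interaction(probe_table$snp_id, probe_table$sample_id,
                     probe_table$allele, drop = TRUE, sep = "\r")
  means <- tapply(probe_table$intensity, key, mean)
  parts <- do.call(rbind, strsplit(names(means), "\r", fixed = TRUE))
  df <- data.frame(snp_id = parts[, 1L], sample_id = parts[, 2L],
                   allele = parts[, 3L], log_mean = log(as.numeric(means)),
                   stringsAsFactors = FALSE)

  snps <- unique(probe_table$snp_id)
  samples <- unique(probe_table$sample_id)
  a <- matrix(NA_real_, length(snps), length(samples),
              dimnames = list(snps, samples))
  b <- a
  ia <- df$allele == "A"
  a[cbind(match(df$snp_id[ia], snps), match(df$sample_id[ia], samples))] <-
    df$log_mean[ia]
  b[cbind(match(df$snp_id[!ia], snps), match(df$sample_id[!ia], samples))] <-
    df$log_mean[!ia]

  # pairs missing one allele are unusable; drop whole SNP rows that end up
  # with missing cells so the matrices stay rectangular
  miss <- is.na(a) | is.na(b)
  if (any(miss)) {
    drop_rows <- unique(which(miss, arr.ind = TRUE)[, 1L])
    warning(sprintf("dropped %d SNP row(s) with missing allele measurements",
                    length(drop_rows)))
    keep <- setdiff(seq_along(snps), drop_rows)
    a <- a[keep, , drop = FALSE]
    b <- b[keep, , drop = FALSE]
  }
  intensity_dataset(a, b, centered = FALSE)
}

#' Centre each SNP at the median of its A-allele log-intensities
#'
#' For every SNP the median of the A-allele log-intensities across samples is
#' subtracted from both the A and the B log-intensities of that SNP, so only
#' the relative position of the two channels matters downstream.  Applying
#' the function to an already centred dataset changes nothing (the median is
#' already zero).
#'
#' @param dataset an [intensity_dataset()].
#' @return The centred dataset (`centered = TRUE`).
#' @export
center_snps <- function(dataset) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  if (ncol(dataset$a_log) < 1L) stop("dataset has no samples")
  med <- apply(dataset$a_log, 1L, stats::median)
  dataset$a_log <- dataset$a_log - med
  dataset$b_log <- dataset$b_log - med
  dataset$centered <- TRUE
  dataset
}

read_matrix_tsv <- function(file, integer = FALSE) {
  raw <- utils::read.delim(file, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("'", file, "' has no sample columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicate SNP ids in '", file, "'")
  m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
              dimnames = list(ids, colnames(raw)[-1L]))
  for (j in seq_len(ncol(m))) {
    chr <- raw[[j + 1L]]
    missing_cell <- is.na(chr) | chr == "" | chr == "NA"
    val <- suppressWarnings(as.numeric(chr))
    bad <- which(is.na(val) & !missing_cell)
    if (length(bad))
      stop(sprintf("unparseable cell '%s' at row %d, column '%s' of '%s'",
                   chr[bad[1L]], bad[1L], colnames(m)[j], file))
    m[, j] <- val
  }
  if (integer) storage.mode(m) <- "integer"
  m
}

write_matrix_tsv <- function(m, file, id_col = "snp_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write allelic log-intensity matrices
#'
#' `read_intensity_tsv()` reads a pair of tab-delimited SNP x sample matrices
#' of A- and B-allele log-intensities (header row of sample ids, first column
#' of SNP ids).  Rows with missing cells in either matrix are dropped with a
#' warning; unparseable cells are an error naming the offending row and
#' column.  `write_intensity_tsv()` writes the pair `<prefix>_A.tsv`,
#' `<prefix>_B.tsv`; reading them back reproduces the dataset.
#'
#' @param a_file,b_file paths of the A and B matrices.  `a_file` may instead
#'   be a prefix: if `b_file` is missing, `<a_file>_A.tsv` and
#'   `<a_file>_B.tsv` are read.
#' @param centered logical, whether the stored values are already centred.
#' @return An [intensity_dataset()].
#' @export
read_intensity_tsv <- function(a_file, b_file = NULL, centered = FALSE) {
  if (is.null(b_file)) {
    b_file <- paste0(a_file, "_B.tsv")
    a_file <- paste0(a_file, "_A.tsv")
  }
  a <- read_matrix_tsv(a_file)
  b <- read_matrix_tsv(b_file)
  if (!identical(dim(a), dim(b)) || !identical(dimnames(a), dimnames(b)))
    stop("A and B matrices disagree in shape or identifiers")
  miss <- which(rowSums(is.na(a) | is.na(b)) > 0L)
  if (length(miss)) {
    warning(sprintf("dropped %d row(s) with missing cells", length(miss)))
    a <- a[-miss, , drop = FALSE]
    b <- b[-miss, , drop = FALSE]
  }
  intensity_dataset(a, b, centered = centered)
}

#' @rdname read_intensity_tsv
#' @param dataset an [intensity_dataset()].
#' @param prefix output path prefix.
#' @export
write_intensity_tsv <- function(dataset, prefix) {
  stopifnot(inherits(dataset, "intensity_dataset"))
  write_matrix_tsv(format_num(dataset$a_log), paste0(prefix, "_A.tsv"))
  write_matrix_tsv(format_num(dataset$b_log), paste0(prefix, "_B.tsv"))
  invisible(prefix)
}

format_num <- function(m) {
  out <- matrix(sprintf("%.10g", m), nrow(m), ncol(m), dimnames = dimnames(m))
  out
}

#' Read / write copy-number status matrices
#'
#' Copy-number alteration status from an upstream CNA caller, one integer
#' code per SNP and sample: `-1` loss, `0` normal two-copy, `+1` gain.
#'
#' @param file path of a tab-delimited SNP x sample matrix of codes.
#' @return `read_cna_tsv()`: an integer matrix with SNP row names and sample
#'   column names.
#' @export
read_cna_tsv <- function(file) {
  m <- read_matrix_tsv(file, integer = TRUE)
  if (anyNA(m)) stop("missing cells in CNA status matrix '", file, "'")
  if (!all(m %in% c(-1L, 0L, 1L)))
    stop("CNA status codes must be -1 (loss), 0 (normal) or 1 (gain)")
  m
}

#' @rdname read_cna_tsv
#' @param status integer matrix of codes in \{-1, 0, 1\}.
#' @export
write_cna_tsv <- function(status, file) {
  stopifnot(all(status %in% c(-1L, 0L, 1L)))
  write_matrix_tsv(status, file)
  invisible(file)
}

#' Read / write genotype call tables
#'
#' Calls are stored long-form with columns `snp_id`, `sample_id`, `call`
#' (`AA`, `AB`, `BB` or `NoCall`; `A`/`B` when hemizygous notation is used)
#' and `posterior` (the maximum cluster posterior probability).
#'
#' @param calls a `bcr_calls` object as returned by [bcr_genotype()].
#' @param file output path.
#' @export
write_calls_tsv <- function(calls, file) {
  stopifnot(inherits(calls, "bcr_calls"))
  df <- data.frame(
    snp_id = rep(rownames(calls$calls), times = ncol(calls$calls)),
    sample_id = rep(colnames(calls$calls), each = nrow(calls$calls)),
    call = as.vector(calls$calls),
    posterior = sprintf("%.6f", as.vector(calls$posterior)),
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_calls_tsv
#' @export
read_calls_tsv <- function(file) {
  df <- utils::read.delim(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  snps <- unique(df$snp_id)
  samples <- unique(df$sample_id)
  cm <- matrix(NA_character_, length(snps), length(samples),
               dimnames = list(snps, samples))
  pm <- matrix(NA_real_, length(snps), length(samples),
               dimnames = list(snps, samples))
  idx <- cbind(match(df$snp_id, snps), match(df$sample_id, samples))
  cm[idx] <- df$call
  pm[idx] <- df$posterior
  new_bcr_calls(cm, pm, threshold = NA_real_)
}
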