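## Joint preprocessing: background correction, duplicate-spot aggregation,
## log2 transform with joint quantile normalization, and the replicate
## reproducibility QC (pairwise Pearson r on log data, average per-spot CV
## on raw data).

#' Background-correct a spot-level cohort
#'
#' Subtracts the local background median from the foreground median and
#' floors the result at 1 so the log2 transform is defined. Spots carrying
#' a negative (bad) GenePix flag are replaced by the mean of the feature's
#' unflagged replicate spots in the same sample; if every replicate of a
#' feature is flagged the value falls back to 1 and a warning is issued.
#'
#' @param cohort a `spot_cohort` from [assemble_cohort()] or
#'   [generate_cohort()].
#' @return An object of class `spot_matrix`: background-corrected spot
#'   `values` (spots x samples) plus the spot/feature bookkeeping of the
#'   input.
#' @export
background_correct <- function(cohort) {
  stopifnot(inherits(cohort, "spot_cohort"))
  values <- pmax(cohort$fg - cohort$bg, 1)
  bad <- cohort$flags < 0L
  if (any(bad)) {
    f <- factor(cohort$feature_ids, levels = unique(cohort$feature_ids))
    n_dead <- 0L
    for (s in which(colSums(bad) > 0L)) {
      for (ft in unique(f[bad[, s]])) {
        rows <- which(f == ft)
        ok <- rows[!bad[rows, s]]
        repl <- if (length(ok)) mean(values[ok, s]) else NA_real_
        if (is.na(repl)) {
          repl <- 1
          n_dead <- n_dead + 1L
        }
        values[rows[bad[rows, s]], s] <- repl
      }
    }
    if (n_dead > 0L)
      warning(sprintf("%d feature/sample cell(s) had all replicates flagged; set to 1",
                      n_dead), call. = FALSE)
  }
  structure(list(values = values,
                 feature_ids = cohort$feature_ids,
                 replicate = cohort$replicate,
                 feature_names = cohort$feature_names,
                 sample_ids = cohort$sample_ids,
                 groups = cohort$groups),
            class = "spot_matrix")
}

#' Average duplicate spots into feature-level intensities
#'
#' @param spot_matrix a `spot_matrix` from [background_correct()].
#' @return A raw-scale `intensity_matrix` (`log_scale = FALSE`) with one
#'   row per feature (arithmetic mean over its replicate spots).
#' @export
aggregate_duplicates <- function(spot_matrix) {
  stopifnot(inherits(spot_matrix, "spot_matrix"))
  f <- factor(spot_matrix$feature_ids,
              levels = unique(spot_matrix$feature_ids))
  counts <- tabulate(f)
  if (any(counts == 0L))
    stop("feature with no usable spots", call. = FALSE)
  sums <- rowsum(spot_matrix$values, f)  # rows in factor-level order
  sums <- sums[levels(f), , drop = FALSE]
  values <- sums / counts
  rownames(values) <- levels(f)
  colnames(values) <- spot_matrix$sample_ids
  intensity_matrix(values, spot_matrix$groups, log_scale = FALSE)
}

#' Log2-transform and jointly quantile-normalize a cohort
#'
#' All samples (cases and controls together) are normalized against the
#' common reference distribution formed by averaging the per-sample sorted
#' log2 vectors. After normalization every sample's sorted value vector is
#' identical; tied input values receive the mean of the reference values
#' their ranks span, so within-sample rank order is preserved.
#'
#' @param im raw-scale `intensity_matrix` (positive values,
#'   `log_scale = FALSE`).
#' @return A log2-scale `intensity_matrix`.
#' @export
log_quantile_normalize <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (im$log_scale)
    stop("input is already on the log scale", call. = FALSE)
  if (any(im$values <= 0))
    stop("quantile normalization requires strictly positive intensities",
         call. = FALSE)
  l <- log2(im$values)
  ref <- rowMeans(apply(l, 2L, sort))
  out <- l
  for (s in seq_len(ncol(l))) {
    col <- l[, s]
    o <- order(col)
    tmp <- numeric(length(col))
    tmp[o] <- ref
    out[, s] <- ave(tmp, col, FUN = mean)  # ties share the spanned reference mean
  }
  intensity_matrix(out, im$groups, log_scale = TRUE)
}

#' Replicate-reproducibility quality control
#'
#' For each pair of technical replicate arrays, computes Pearson's
#' correlation on log2 data and the average per-spot coefficient of
#' variation (sd/mean, in percent) on raw data — the two headline
#' reproducibility metrics of a replicate study.
#'
#' @param pairs list of replicate pairs; each element is a list or
#'   two-column matrix holding the two raw spot-intensity vectors of one
#'   replicated sample.
#' @param stratum label for the comparison stratum: `"intra_lot"`,
#'   `"inter_lot"` or `"overall"`.
#' @return An object of class `qc_report`: `pairwise_r` (one Pearson r per
#'   pair, log2 data), `avg_cv` (mean per-spot CV in percent, raw data,
#'   pooled over pairs), `mean_r`, `stratum`.
#' @export
replicate_qc <- function(pairs, stratum = c("overall", "intra_lot", "inter_lot")) {
  stratum <- match.arg(stratum)
  if (!is.list(pairs) || length(pairs) < 1L)
    stop("'pairs' must be a non-empty list of replicate pairs", call. = FALSE)
  rs <- numeric(length(pairs))
  cvs <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (is.matrix(p)) p <- list(p[, 1L], p[, 2L])
    a <- as.numeric(p[[1L]]); b <- as.numeric(p[[2L]])
    if (length(a) != length(b) || length(a) < 2L)
      stop("replicate arrays must have equal length >= 2", call. = FALSE)
    if (any(a <= 0) || any(b <= 0))
      stop("raw replicate intensities must be positive", call. = FALSE)
    if (sd(a) == 0 || sd(b) == 0)
      stop("constant replicate array: correlation undefined", call. = FALSE)
    rs[i] <- cor(log2(a), log2(b))
    m <- (a + b) / 2
    s <- abs(a - b) / sqrt(2)  # sd of two values
    cvs[[i]] <- 100 * s / m
  }
  structure(list(pairwise_r = rs,
                 mean_r = mean(rs),
                 avg_cv = mean(unlist(cvs)),
                 stratum = stratum),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("replicate QC (%s): mean r = %.4f, average CV = %.2f%% (%d pair(s))\n",
              x$stratum, x$mean_r, x$avg_cv, length(x$pairwise_r)))
  invisible(x)
}

#' Export an intensity matrix as a tab-separated table
#'
#' Features in rows (first column `feature_id`), samples in columns.
#'
#' @param im an `intensity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(im, path) {
  stopifnot(inherits(im, "intensity_matrix"))
  df <- data.frame(feature_id = im$feature_ids, im$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
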