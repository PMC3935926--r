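#' Construct a feature-by-sample intensity matrix
#'
#' The central container of the pipeline: a numeric features x samples
#' matrix with feature ids as rownames, sample ids as colnames and a
#' per-sample group factor (levels `ALS`, `NDC`; ALS is the case class).
#' `log_scale = TRUE` marks jointly preprocessed log2 intensities,
#' `log_scale = FALSE` raw-scale (background-corrected, duplicate-averaged)
#' fluorescence used e.g. for the report's group medians.
#'
#' @param values numeric matrix, features in rows, samples in columns,
#'   dimnames set, no missing values.
#' @param groups per-sample labels, `"ALS"` or `"NDC"`.
#' @param log_scale logical; are values on the log2 scale?
#' @return An object of class `intensity_matrix` with elements `values`,
#'   `feature_ids`, `sample_ids`, `groups`, `log_scale`.
#' @export
intensity_matrix <- function(values, groups, log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  if (anyNA(values))
    stop("intensity matrix must not contain missing values", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("feature ids must be unique", call. = FALSE)
  g <- as_group_factor(groups)
  if (length(g) != ncol(values))
    stop("length of 'groups' must equal the number of samples", call. = FALSE)
  structure(list(values = values,
                 feature_ids = rownames(values),
                 sample_ids = colnames(values),
                 groups = g,
                 log_scale = isTRUE(log_scale)),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d features x %d samples (%d ALS, %d NDC), %s scale\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "ALS"), sum(x$groups == "NDC"),
              if (x$log_scale) "log2" else "raw"))
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

## column subset preserving metadata
subset_samples <- function(im, sample_ids) {
  keep <- match(sample_ids, im$sample_ids)
  if (anyNA(keep)) stop("unknown sample id(s)", call. = FALSE)
  intensity_matrix(im$values[, keep, drop = FALSE], im$groups[keep],
                   log_scale = im$log_scale)
}
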