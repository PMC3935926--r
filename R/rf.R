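#' Random-forest classifier (bagged CART) for two-group cohorts
#'
#' Fits a bagged ensemble of fully grown classification trees with Gini
#' splits and `mtry` randomly sampled candidate features per node, the
#' classifier wrapped by the gene-shaving selection and used for subrun
#' and panel verification. Out-of-bag (OOB) samples provide an internal
#' error estimate and permutation importance (mean decrease in OOB
#' accuracy when a feature's values are permuted among the OOB samples of
#' each tree). Implemented in compiled code; all randomness flows through
#' R's RNG, so results are reproducible under `set.seed()` or the `seed`
#' argument.
#'
#' @param x numeric samples x features matrix (training data).
#' @param y group labels (`ALS`/`NDC`), one per training sample; ALS is
#'   the positive class.
#' @param ntree number of trees.
#' @param mtry candidate features per split; default
#'   `max(1, floor(sqrt(ncol(x))))`.
#' @param xtest optional samples x features matrix to classify with the
#'   fitted forest.
#' @param importance compute permutation importance (default `TRUE`).
#' @param seed optional integer; if given, `set.seed(seed)` is called
#'   before fitting.
#' @return An object of class `rf_fit`: `oob_error`, named `importance`
#'   vector, `test_pred` (factor, if `xtest` given), `ntree`, `mtry`.
#' @export
rf_fit <- function(x, y, ntree = 500, mtry = NULL, xtest = NULL,
                   importance = TRUE, seed = NULL) {
  if (!is.matrix(x)) x <- as.matrix(x)
  g <- as_group_factor(y)
  if (length(g) != nrow(x))
    stop("length of 'y' must equal nrow(x)", call. = FALSE)
  if (length(unique(g)) < 2L)
    stop("degenerate labels: training data must contain both classes",
         call. = FALSE)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (!is.null(seed)) set.seed(seed)
  yt <- as.integer(g == "ALS")  # class 1 = ALS (case)
  xt <- if (is.null(xtest)) matrix(numeric(0), 0L, ncol(x)) else as.matrix(xtest)
  if (ncol(xt) != ncol(x) && nrow(xt) > 0L)
    stop("'xtest' must have the same features as 'x'", call. = FALSE)
  res <- cpp_rf(x, yt, as.integer(ntree), as.integer(mtry), xt,
                isTRUE(importance))
  pred <- NULL
  if (!is.null(xtest)) {
    pred <- factor(ifelse(res$test_pred == 1L, "ALS", "NDC"),
                   levels = c("ALS", "NDC"))
    names(pred) <- rownames(xtest)
  }
  structure(list(oob_error = res$oob_error,
                 importance = setNames(res$importance,
                                       colnames(x) %||% seq_len(ncol(x))),
                 test_pred = pred,
                 ntree = ntree, mtry = mtry),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("rf_fit: %d trees, mtry %d, OOB error %.3f\n",
              x$ntree, x$mtry, x$oob_error))
  invisible(x)
}
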