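## Panel verification by repeated random-forest classification, nearest
## shrunken centroids (NSC) re-ranking of all features, and the final
## per-feature panel report.

#' Verify a fixed panel by repeated random-forest classification
#'
#' For each run, draws a fresh stratified train/test split, trains a
#' random forest on the panel features of the training samples and scores
#' the held-out samples. ALS is the positive class: sensitivity is the
#' fraction of ALS test samples classified ALS, specificity the fraction
#' of NDC test samples classified NDC.
#'
#' @param im preprocessed log2 `intensity_matrix` for the full cohort.
#' @param panel character vector of panel feature ids (non-empty, all
#'   present in `im`).
#' @param n_runs number of redrawn splits (default 100).
#' @param seed integer master seed; per-run seeds are derived from it.
#' @param n_test_per_group held-out samples per group (default 6).
#' @param ntree trees per verification forest (default 500).
#' @return An object of class `verification_summary`: per-run
#'   `accuracies`, `sensitivities`, `specificities` and their means.
#' @export
verify_panel <- function(im, panel, n_runs = 100L, seed = 1L,
                         n_test_per_group = 6L, ntree = 500L) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (length(panel) == 0L)
    stop("panel must be non-empty", call. = FALSE)
  missing <- setdiff(panel, im$feature_ids)
  if (length(missing))
    stop(sprintf("panel feature(s) not in the matrix: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  acc <- sens <- spec <- numeric(n_runs)
  x <- t(im$values[panel, , drop = FALSE])
  for (r in seq_len(n_runs)) {
    rs <- derive_seed(seed, r)
    split <- stratified_split(im$sample_ids, im$groups, rs, n_test_per_group)
    tr <- match(split$train_ids, im$sample_ids)
    te <- match(split$test_ids, im$sample_ids)
    # the split consumed the RNG via set.seed(rs); the forest continues
    # that per-run stream, so each run is reproducible in isolation
    fit <- rf_fit(x[tr, , drop = FALSE], im$groups[tr], ntree = ntree,
                  xtest = x[te, , drop = FALSE], importance = FALSE)
    truth <- im$groups[te]
    acc[r] <- mean(fit$test_pred == truth)
    sens[r] <- mean(fit$test_pred[truth == "ALS"] == "ALS")
    spec[r] <- mean(fit$test_pred[truth == "NDC"] == "NDC")
  }
  structure(list(n_runs = n_runs,
                 accuracies = acc, sensitivities = sens,
                 specificities = spec,
                 mean_accuracy = mean(acc),
                 mean_sensitivity = mean(sens),
                 mean_specificity = mean(spec)),
            class = "verification_summary")
}

#' @export
print.verification_summary <- function(x, ...) {
  cat(sprintf(paste0("panel verification over %d runs: mean accuracy %.1f%%, ",
                     "mean sensitivity %.1f%%, mean specificity %.1f%%\n"),
              x$n_runs, 100 * x$mean_accuracy, 100 * x$mean_sensitivity,
              100 * x$mean_specificity))
  invisible(x)
}

#' Nearest-shrunken-centroids feature ranking
#'
#' Computes, for every feature j and class k, the standardized centroid
#' difference `d_jk = (xbar_jk - xbar_j) / (m_k * (s_j + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_j` the pooled within-class standard
#' deviation and `s0` the median of all `s_j`. Features are ranked by
#' descending `max_k |d_jk|` (ties by id). The shrinkage threshold Delta
#' is chosen by stratified cross-validation of the shrunken-centroid
#' classifier: among thresholds minimizing the CV error, the largest
#' (smallest surviving feature set) is taken, and the number of features
#' with a nonzero shrunken difference at that threshold is the model's
#' selection level.
#'
#' @param im log2 `intensity_matrix`, both classes with >= 2 samples.
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold assignment.
#' @param n_delta size of the threshold grid (default 30).
#' @return An object of class `nsc_model`: `d` (features x classes),
#'   `s`, `s0`, `overall_centroid`, `class_centroids`, `rank_position`
#'   (named permutation of 1..n), `delta`, `selection_level`, `cv`
#'   (data frame: delta, cv_error, n_surviving).
#' @export
nsc_rank <- function(im, cv_folds = 10L, seed = 1L, n_delta = 30L) {
  stopifnot(inherits(im, "intensity_matrix"))
  g <- require_both_groups(im$groups)
  if (any(table(g) < 2L))
    stop("both classes need at least two samples", call. = FALSE)
  x <- im$values
  stats <- nsc_statistics(x, g)
  if (all(stats$s == 0))
    stop("zero within-class variance everywhere: NSC undefined", call. = FALSE)

  score <- apply(abs(stats$d), 1L, max)
  pos <- rank_features(-score, im$feature_ids)

  deltas <- seq(0, max(score), length.out = n_delta)
  set.seed(seed)
  folds <- integer(ncol(x))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    folds[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
  }
  errs <- matrix(NA_real_, cv_folds, length(deltas))
  for (f in seq_len(cv_folds)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    if (length(te) == 0L || length(unique(g[tr])) < 2L) next
    st <- nsc_statistics(x[, tr, drop = FALSE], g[tr])
    prior <- table(g[tr]) / length(tr)
    for (d in seq_along(deltas)) {
      pred <- nsc_classify(x[, te, drop = FALSE], st, deltas[d], prior)
      errs[f, d] <- mean(pred != g[te])
    }
  }
  cv_error <- colMeans(errs, na.rm = TRUE)
  surviving <- vapply(deltas, function(dl)
    sum(apply(abs(stats$d) > dl, 1L, any)), integer(1))
  best <- which(cv_error == min(cv_error))
  pick <- best[length(best)]  # largest Delta among minima -> smallest set

  structure(list(overall_centroid = stats$overall,
                 class_centroids = stats$centroids,
                 s = stats$s, s0 = stats$s0,
                 d = stats$d,
                 rank_position = pos,
                 delta = deltas[pick],
                 selection_level = surviving[pick],
                 cv = data.frame(delta = deltas, cv_error = cv_error,
                                 n_surviving = surviving)),
            class = "nsc_model")
}

## centroid statistics shared by ranking, CV and classification
nsc_statistics <- function(x, g) {
  n <- ncol(x)
  levs <- levels(g)
  nk <- table(g)
  overall <- rowMeans(x)
  centroids <- vapply(levs, function(lev)
    rowMeans(x[, g == lev, drop = FALSE]), numeric(nrow(x)))
  ss <- 0
  for (lev in levs)
    ss <- ss + rowSums((x[, g == lev, drop = FALSE] - centroids[, lev])^2)
  s <- sqrt(ss / (n - length(levs)))
  s0 <- median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- (centroids - overall) / outer(s + s0, mk)
  colnames(d) <- levs
  list(overall = overall, centroids = centroids, s = s, s0 = s0,
       d = d, mk = setNames(mk, levs))
}

## shrunken-centroid classification of columns of xnew
nsc_classify <- function(xnew, st, delta, prior) {
  dshr <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  levs <- colnames(st$d)
  disc <- matrix(NA_real_, ncol(xnew), length(levs),
                 dimnames = list(NULL, levs))
  denom <- (st$s + st$s0)^2
  for (lev in levs) {
    cshr <- st$overall + st$mk[lev] * (st$s + st$s0) * dshr[, lev]
    disc[, lev] <- colSums((xnew - cshr)^2 / denom) - 2 * log(prior[[lev]])
  }
  factor(levs[max.col(-disc, ties.method = "first")], levels = levs)
}

#' Build the final per-feature panel report
#'
#' One row per panel feature with the report columns of the study design:
#' raw-scale group intensity medians, selection frequency (percent of
#' subruns), NSC rank position, and whole-cohort M-score and Welch-t
#' p-values with genome-wide Benjamini-Hochberg FDR and M-score rank
#' position. All statistics are computed independently on the full cohort
#' (no splitting), with FDR and positions adjusted over all features, not
#' just the panel. Rows are ordered by descending selection frequency.
#'
#' @param im_raw raw-scale `intensity_matrix` (for group medians).
#' @param im_log log2 `intensity_matrix` (for M and t statistics).
#' @param panel character vector of panel feature ids.
#' @param freq `frequency_table` from [run_selection()].
#' @param nsc `nsc_model` from [nsc_rank()].
#' @param annotations optional data frame with columns `id` and `name`
#'   mapping feature ids to protein names.
#' @return A data frame of class `panel_report` with columns
#'   `database_id`, `gene_name`, `ndc_median`, `als_median`,
#'   `frequency`, `pam_position`, `m_p`, `m_fdr`, `m_position`,
#'   `t_p`, `t_fdr`.
#' @export
build_panel_report <- function(im_raw, im_log, panel, freq, nsc,
                               annotations = NULL) {
  stopifnot(inherits(im_raw, "intensity_matrix"),
            inherits(im_log, "intensity_matrix"),
            inherits(freq, "frequency_table"),
            inherits(nsc, "nsc_model"))
  if (!identical(im_raw$feature_ids, im_log$feature_ids) ||
      !setequal(names(nsc$rank_position), im_log$feature_ids) ||
      !setequal(names(freq$counts), im_log$feature_ids))
    stop("inconsistent feature sets between report components", call. = FALSE)
  if (length(panel) == 0L || !all(panel %in% im_log$feature_ids))
    stop("panel must be a non-empty subset of the matrix features",
         call. = FALSE)

  ms <- m_score_matrix(im_log)
  m_p <- setNames(ms$p_value, ms$feature_id)
  m_fdr <- bh_fdr(m_p)
  m_pos <- rank_features(m_p)
  t_p <- welch_t_matrix(im_log)
  t_fdr <- bh_fdr(t_p)

  als <- im_raw$groups == "ALS"
  ndc_median <- apply(im_raw$values[panel, !als, drop = FALSE], 1L, median)
  als_median <- apply(im_raw$values[panel, als, drop = FALSE], 1L, median)

  name <- panel
  if (!is.null(annotations))
    name <- annotations$name[match(panel, annotations$id)]

  rep <- data.frame(database_id = panel,
                    gene_name = name,
                    ndc_median = ndc_median,
                    als_median = als_median,
                    frequency = 100 * freq$counts[panel] / freq$n_subruns,
                    pam_position = nsc$rank_position[panel],
                    m_p = m_p[panel],
                    m_fdr = m_fdr[panel],
                    m_position = m_pos[panel],
                    t_p = t_p[panel],
                    t_fdr = t_fdr[panel],
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  rep <- rep[order(-rep$frequency, rep$m_p, rep$database_id), , drop = FALSE]
  rownames(rep) <- NULL
  class(rep) <- c("panel_report", "data.frame")
  rep
}

#' Write a panel report as a tab-separated file
#'
#' @param report a `panel_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
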