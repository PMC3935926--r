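## The resampling feature-selection protocol: repeated stratified
## train/test subruns, each performing M-score preselection and
## random-forest gene shaving on the training samples only, verified on
## the held-out test samples; the final panel is built from the frequency
## of selection across subruns.

#' Tuning parameters of the selection protocol
#'
#' @param k_preselect number of features kept by the univariate M-score
#'   preselection (default 300).
#' @param n_test_per_group held-out test samples per group in each
#'   stratified split (default 6, i.e. 6 ALS + 6 NDC test vs 14 + 14
#'   train on a 20 vs 20 cohort).
#' @param drop_frac fraction of remaining features dropped per
#'   gene-shaving iteration (default 0.2).
#' @param c_se multiplier of the OOB-error standard error in the
#'   smallest-set selection rule (default 1).
#' @param n_trees_init trees for the first random-forest fit of a shave
#'   and for verification forests (default 500).
#' @param n_trees_iter trees for subsequent shaving iterations
#'   (default 200).
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(k_preselect = 300L, n_test_per_group = 6L,
                             drop_frac = 0.2, c_se = 1,
                             n_trees_init = 500L, n_trees_iter = 200L) {
  stopifnot(k_preselect >= 2L, n_test_per_group >= 1L,
            drop_frac > 0, drop_frac < 1, c_se >= 0,
            n_trees_init >= 1L, n_trees_iter >= 1L)
  structure(list(k_preselect = as.integer(k_preselect),
                 n_test_per_group = as.integer(n_test_per_group),
                 drop_frac = drop_frac, c_se = c_se,
                 n_trees_init = as.integer(n_trees_init),
                 n_trees_iter = as.integer(n_trees_iter)),
            class = "selection_params")
}

#' Stratified random train/test split
#'
#' Draws `n_test_per_group` samples per group uniformly at random without
#' replacement as the test set; the remainder is the training set.
#' Deterministic given `seed`.
#'
#' @param sample_ids character vector of sample ids.
#' @param groups group labels, parallel to `sample_ids`.
#' @param seed integer seed.
#' @param n_test_per_group test-set size per group (default 6).
#' @return List with `train_ids` and `test_ids`.
#' @export
stratified_split <- function(sample_ids, groups, seed, n_test_per_group = 6L) {
  g <- require_both_groups(groups)
  stopifnot(length(sample_ids) == length(g))
  set.seed(seed)
  test <- character(0)
  for (lev in levels(g)) {
    ids <- sample_ids[g == lev]
    if (length(ids) <= n_test_per_group)
      stop(sprintf("group %s has only %d sample(s); need > %d for a split",
                   lev, length(ids), n_test_per_group), call. = FALSE)
    test <- c(test, sample(ids, n_test_per_group))
  }
  list(train_ids = setdiff(sample_ids, test),
       test_ids = sample_ids[sample_ids %in% test])
}

#' Univariate M-score preselection
#'
#' Keeps the `k` features with the smallest M scores on the training
#' samples (ties resolved by the deterministic [rank_features()] order)
#' and reports the k-th smallest p — the subrun's M-score cutoff, whose
#' cross-subrun average is a standard summary of the screening stringency.
#'
#' @param im training-sample `intensity_matrix` (both groups present).
#' @param k number of features to keep (default 300).
#' @return List: `features` (ids, in increasing M-score order),
#'   `cutoff_p` (k-th smallest M score), `p_values` (all features).
#' @export
preselect_m <- function(im, k = 300L) {
  stopifnot(inherits(im, "intensity_matrix"))
  if (k > length(im$feature_ids))
    stop(sprintf("k = %d exceeds the number of features (%d)",
                 k, length(im$feature_ids)), call. = FALSE)
  ms <- m_score_matrix(im)
  pos <- rank_features(ms$p_value, ms$feature_id)
  keep <- order(pos)[seq_len(k)]
  list(features = ms$feature_id[keep],
       cutoff_p = sort(ms$p_value)[k],
       p_values = setNames(ms$p_value, ms$feature_id))
}

#' Random-forest gene shaving (backward elimination)
#'
#' Iteratively fits a random forest, records its out-of-bag error and
#' drops the `ceiling(drop_frac * m)` least important features
#' (permutation importance) until two features remain. The selected set is
#' the smallest one whose OOB error does not exceed the minimum observed
#' OOB error by more than `c_se` standard errors, with
#' `SE = sqrt(err * (1 - err) / n_train)` evaluated at the minimum.
#'
#' @param x numeric training samples x features matrix (column names are
#'   feature ids).
#' @param y training group labels (both classes required).
#' @param seed integer seed; the whole shave is deterministic given it.
#' @param params a [selection_params()] object.
#' @return List of class `shave_result`: `selected` (feature ids),
#'   `trace` (data frame with per-iteration `size` and `oob_error`),
#'   `sets` (feature sets per iteration), `dropped` (ids dropped per
#'   iteration).
#' @export
gene_shave <- function(x, y, seed, params = selection_params()) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (ncol(x) < 2L) stop("gene shaving needs at least two features", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- as.character(seq_len(ncol(x)))
  g <- require_both_groups(y)
  set.seed(seed)
  current <- colnames(x)
  sizes <- integer(0); oobs <- numeric(0)
  sets <- list(); dropped <- list()
  ntree <- params$n_trees_init
  repeat {
    fit <- rf_fit(x[, current, drop = FALSE], g, ntree = ntree)
    it <- length(sizes) + 1L
    sizes[it] <- length(current); oobs[it] <- fit$oob_error
    sets[[it]] <- current
    if (length(current) <= 2L) {
      dropped[[it]] <- character(0)
      break
    }
    ndrop <- min(ceiling(params$drop_frac * length(current)),
                 length(current) - 2L)
    worst <- order(fit$importance)[seq_len(ndrop)]
    dropped[[it]] <- current[worst]
    current <- current[-worst]
    ntree <- params$n_trees_iter
  }
  min_oob <- min(oobs)
  se <- sqrt(min_oob * (1 - min_oob) / nrow(x))
  ok <- which(oobs <= min_oob + params$c_se * se)
  chosen <- ok[which.min(sizes[ok])]  # smallest qualifying set
  structure(list(selected = sets[[chosen]],
                 trace = data.frame(size = sizes, oob_error = oobs),
                 sets = sets, dropped = dropped,
                 min_oob = min_oob, se = se),
            class = "shave_result")
}

#' Execute one selection subrun
#'
#' One iteration of the resampling protocol: (1) stratified split into
#' train and test, (2) M-score preselection of `k_preselect` features on
#' the training samples, (3) gene shaving on the training samples
#' restricted to the preselected features, (4) a fresh random forest
#' trained on the shaved selection, (5) classification of the held-out
#' test samples. Preselection and shaving never see test-set columns.
#'
#' @param im preprocessed log2 `intensity_matrix` for the full cohort.
#' @param subrun_index index of this subrun (1-based).
#' @param master_seed integer master seed; the subrun's seed is derived
#'   from it with [derive_seed()].
#' @param params a [selection_params()] object.
#' @return List of class `subrun_result`: `subrun_index`, `seed`,
#'   `train_ids`, `test_ids`, `preselected`, `cutoff_p`, `selected`,
#'   `test_accuracy`.
#' @export
run_subrun <- function(im, subrun_index, master_seed,
                       params = selection_params()) {
  stopifnot(inherits(im, "intensity_matrix"))
  seed <- derive_seed(master_seed, subrun_index)
  split <- stratified_split(im$sample_ids, im$groups, derive_seed(seed, 1L),
                            params$n_test_per_group)
  train <- subset_samples(im, split$train_ids)
  pre <- preselect_m(train, params$k_preselect)
  xtrain <- t(train$values[pre$features, , drop = FALSE])
  shave <- gene_shave(xtrain, train$groups, derive_seed(seed, 2L), params)
  test <- subset_samples(im, split$test_ids)
  set.seed(derive_seed(seed, 3L))
  fit <- rf_fit(xtrain[, shave$selected, drop = FALSE], train$groups,
                ntree = params$n_trees_init,
                xtest = t(test$values[shave$selected, , drop = FALSE]),
                importance = FALSE)
  structure(list(subrun_index = subrun_index,
                 seed = seed,
                 train_ids = split$train_ids,
                 test_ids = split$test_ids,
                 preselected = pre$features,
                 cutoff_p = pre$cutoff_p,
                 selected = shave$selected,
                 test_accuracy = mean(fit$test_pred == test$groups)),
            class = "subrun_result")
}

#' Run the full resampling selection
#'
#' Executes `n_subruns` independent subruns (per-subrun seeds derived from
#' `master_seed` with a counter-based generator, so any subrun is
#' reproducible in isolation) and tallies how often each feature was
#' selected.
#'
#' @param im preprocessed log2 `intensity_matrix`.
#' @param n_subruns number of subruns (default 100).
#' @param master_seed integer master seed.
#' @param params a [selection_params()] object.
#' @param verbose print per-subrun progress.
#' @return List of class `selection_result`: `subruns` (list of
#'   `subrun_result`), `freq` (a `frequency_table`: per-feature selection
#'   `counts` and `n_subruns`), `accuracy` (per-subrun test accuracies),
#'   `mean_accuracy`, `accuracy_range`, `n_selected_once`,
#'   `mean_cutoff_p` (average M-score preselection cutoff).
#' @export
run_selection <- function(im, n_subruns = 100L, master_seed = 1L,
                          params = selection_params(), verbose = FALSE) {
  stopifnot(inherits(im, "intensity_matrix"), n_subruns >= 1L)
  subruns <- vector("list", n_subruns)
  for (i in seq_len(n_subruns)) {
    subruns[[i]] <- run_subrun(im, i, master_seed, params)
    if (verbose)
      message(sprintf("subrun %3d: %2d features, accuracy %.3f",
                      i, length(subruns[[i]]$selected),
                      subruns[[i]]$test_accuracy))
  }
  counts <- setNames(integer(length(im$feature_ids)), im$feature_ids)
  for (s in subruns)
    counts[s$selected] <- counts[s$selected] + 1L
  acc <- vapply(subruns, function(s) s$test_accuracy, numeric(1))
  structure(list(subruns = subruns,
                 freq = structure(list(counts = counts,
                                       n_subruns = n_subruns),
                                  class = "frequency_table"),
                 accuracy = acc,
                 mean_accuracy = mean(acc),
                 accuracy_range = range(acc),
                 n_selected_once = sum(counts > 0L),
                 mean_cutoff_p = mean(vapply(subruns, function(s) s$cutoff_p,
                                             numeric(1))),
                 params = params,
                 master_seed = master_seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(paste0("selection over %d subruns: accuracy %.1f%%-%.1f%%, ",
                     "mean %.1f%%; %d features selected at least once; ",
                     "average M-score cutoff %.6g\n"),
              x$freq$n_subruns, 100 * x$accuracy_range[1L],
              100 * x$accuracy_range[2L], 100 * x$mean_accuracy,
              x$n_selected_once, x$mean_cutoff_p))
  invisible(x)
}

#' Build the final biomarker panel from selection frequencies
#'
#' Keeps every feature selected in at least `threshold` of the subruns,
#' ordered by descending frequency (ties by ascending whole-cohort M score
#' if supplied, then by feature id), truncated to `panel_size` features.
#'
#' @param freq a `frequency_table` (from [run_selection()]`$freq`).
#' @param threshold minimum selection frequency (fraction of subruns,
#'   default 0.10).
#' @param panel_size maximum panel size (default 20).
#' @param tiebreak_p optional named vector of whole-cohort M-score
#'   p-values used to break frequency ties.
#' @return Character vector of panel feature ids (possibly shorter than
#'   `panel_size`; empty with a warning if nothing qualifies).
#' @export
final_panel <- function(freq, threshold = 0.10, panel_size = 20L,
                        tiebreak_p = NULL) {
  stopifnot(inherits(freq, "frequency_table"))
  counts <- freq$counts
  qual <- names(counts)[counts > 0L &
                          counts / freq$n_subruns >= threshold]
  if (length(qual) == 0L) {
    warning("no feature reaches the selection-frequency threshold",
            call. = FALSE)
    return(character(0))
  }
  p <- if (is.null(tiebreak_p)) rep(0, length(qual)) else tiebreak_p[qual]
  qual <- qual[order(-counts[qual], p, qual)]
  head(qual, panel_size)
}
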