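make_spot_cohort <- function(fg, bg, flags, feature_ids, groups) {
  n <- ncol(fg)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(fg) <- dimnames(bg) <- dimnames(flags) <-
    list(paste(feature_ids, ave(feature_ids, feature_ids,
                                FUN = seq_along), sep = "."), ids)
  reps <- as.integer(ave(feature_ids, feature_ids, FUN = seq_along))
  structure(list(fg = fg, bg = bg, flags = flags,
                 feature_ids = feature_ids, replicate = reps,
                 feature_names = feature_ids,
                 sample_ids = ids,
                 groups = factor(groups, levels = c("ALS", "NDC")),
                 layout_feature_ids = unique(feature_ids)),
            class = "spot_cohort")
}

test_that("background correction subtracts, floors and repairs flagged spots", {
  fg <- matrix(c(1000, 1100, 50, 500), 4L, 1L)
  bg <- matrix(c(100, 100, 100, 100), 4L, 1L)
  fl <- matrix(0L, 4L, 1L)
  cohort <- make_spot_cohort(fg, bg, fl, c("A", "A", "B", "B"), "ALS")
  sm <- background_correct(cohort)
  expect_equal(unname(sm$values[, 1L]), c(900, 1000, 1, 400))  # floor at 1

  # one flagged replicate is replaced by its partner
  fl2 <- matrix(c(-100L, 0L, 0L, 0L), 4L, 1L)
  sm2 <- background_correct(make_spot_cohort(fg, bg, fl2,
                                             c("A", "A", "B", "B"), "ALS"))
  expect_equal(unname(sm2$values[1L, 1L]), 1000)

  # all replicates flagged: value 1 with a warning
  fl3 <- matrix(c(-50L, -50L, 0L, 0L), 4L, 1L)
  expect_warning(
    sm3 <- background_correct(make_spot_cohort(fg, bg, fl3,
                                               c("A", "A", "B", "B"), "ALS")),
    "all replicates flagged")
  expect_equal(unname(sm3$values[1:2, 1L]), c(1, 1))
})

test_that("aggregate_duplicates averages replicates per feature", {
  fg <- matrix(c(940, 1140, 240, 240), 4L, 1L)
  bg <- matrix(40, 4L, 1L)
  cohort <- make_spot_cohort(fg, bg, matrix(0L, 4L, 1L),
                             c("A", "A", "B", "B"), "NDC")
  fm <- aggregate_duplicates(background_correct(cohort))
  expect_s3_class(fm, "intensity_matrix")
  expect_false(fm$log_scale)
  expect_equal(unname(fm$values[, 1L]), c(1000, 200))  # (900+1100)/2, single mean
  expect_equal(fm$feature_ids, c("A", "B"))

  # commutes with sample reordering
  gen <- make_test_cohort(n_features = 30L, n_per_group = 4L, seed = 3L)
  sm <- background_correct(gen$cohort)
  fm1 <- aggregate_duplicates(sm)
  perm <- c(5:8, 1:4)
  sm2 <- sm
  sm2$values <- sm$values[, perm]
  sm2$sample_ids <- sm$sample_ids[perm]
  sm2$groups <- sm$groups[perm]
  fm2 <- aggregate_duplicates(sm2)
  expect_equal(fm2$values[, fm1$sample_ids], fm1$values)
})

test_that("log-quantile normalization matches the definitional contract", {
  x <- matrix(c(1, 2, 3, 2, 4, 6), 3L, 2L,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  im <- intensity_matrix(x, c("ALS", "NDC"), log_scale = FALSE)
  nm <- log_quantile_normalize(im)
  ref <- c(0.5, 1.5, mean(log2(c(3, 6))))
  expect_equal(unname(nm$values[, 1L]), ref)
  expect_equal(unname(nm$values[, 2L]), ref)

  # identical samples are unchanged by normalization (only logged)
  y <- matrix(rep(c(2, 8, 32), 2L), 3L, 2L,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  nm2 <- log_quantile_normalize(intensity_matrix(y, c("ALS", "NDC"),
                                                 log_scale = FALSE))
  expect_equal(nm2$values, log2(y))

  # column-sorted vectors all equal; idempotent; ranks preserved
  set.seed(8)
  z <- matrix(2^rnorm(60, 10, 1), 10L, 6L,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:6)))
  imz <- intensity_matrix(z, rep(c("ALS", "NDC"), each = 3L),
                          log_scale = FALSE)
  n1 <- log_quantile_normalize(imz)
  sorted <- apply(n1$values, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1L]) < 1e-12))
  n1_raw <- intensity_matrix(2^n1$values, n1$groups, log_scale = FALSE)
  n2 <- log_quantile_normalize(n1_raw)
  expect_equal(n2$values, n1$values)
  for (s in 1:6)
    expect_equal(rank(n1$values[, s]), rank(z[, s]))

  # ties share the mean of the spanned reference values
  tied <- matrix(c(1, 1, 4, 1, 2, 4), 3L, 2L,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  nt <- log_quantile_normalize(intensity_matrix(tied, c("ALS", "NDC"),
                                                log_scale = FALSE))
  ref2 <- rowMeans(cbind(sort(log2(tied[, 1L])), sort(log2(tied[, 2L]))))
  expect_equal(unname(nt$values[, 1L]),
               unname(c(mean(ref2[1:2]), mean(ref2[1:2]), ref2[3L])))

  expect_error(log_quantile_normalize(
    intensity_matrix(x - 1, c("ALS", "NDC"), log_scale = FALSE)),
    "positive")
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  set.seed(21)
  z <- matrix(2^rnorm(200, 10, 1.5), 25L, 8L,
              dimnames = list(sprintf("f%d", 1:25), sprintf("s%d", 1:8)))
  im <- intensity_matrix(z, rep(c("ALS", "NDC"), each = 4L),
                         log_scale = FALSE)
  ours <- log_quantile_normalize(im)$values
  theirs <- limma::normalizeQuantiles(log2(z))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("replicate QC computes log-scale r and raw-scale CV", {
  qc <- replicate_qc(list(list(c(1, 2, 3), c(2, 4, 6))))
  expect_equal(qc$pairwise_r, 1)          # log of proportional arrays is affine
  expect_equal(qc$avg_cv, 100 * (1 / sqrt(2)) / 1.5)

  # identical replicates: CV 0
  qc2 <- replicate_qc(list(list(c(5, 9, 2), c(5, 9, 2))))
  expect_equal(qc2$avg_cv, 0)

  expect_error(replicate_qc(list(list(c(1, 1, 1), c(2, 4, 6)))), "constant")
  expect_error(replicate_qc(list()), "non-empty")
})
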