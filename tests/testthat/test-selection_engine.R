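test_that("stratified splits are reproducible, disjoint and exhaustive", {
  ids <- sprintf("s%02d", 1:20)
  grp <- rep(c("ALS", "NDC"), each = 10L)
  s1 <- stratified_split(ids, grp, seed = 7, n_test_per_group = 3L)
  s2 <- stratified_split(ids, grp, seed = 7, n_test_per_group = 3L)
  expect_identical(s1, s2)
  expect_length(s1$test_ids, 6L)
  expect_setequal(c(s1$train_ids, s1$test_ids), ids)
  expect_length(intersect(s1$train_ids, s1$test_ids), 0L)
  # stratification: 3 per group in the test set
  expect_equal(sum(grp[match(s1$test_ids, ids)] == "ALS"), 3L)
  # different seeds give different splits (collision probability ~1/C(10,3)^2)
  s3 <- stratified_split(ids, grp, seed = 8, n_test_per_group = 3L)
  expect_false(setequal(s1$test_ids, s3$test_ids))
  small <- c(1:4, 11:14)  # 4 per group, too few for a 6+6 test set
  expect_error(stratified_split(ids[small], grp[small], 1,
                                n_test_per_group = 6L),
               "only 4")
})

test_that("preselect_m keeps the k best M scores and reports the cutoff", {
  # feature A separates perfectly, B is constant
  x <- rbind(A = c(9, 8, 7, 1, 2, 3), B = rep(5, 6))
  colnames(x) <- sprintf("s%d", 1:6)
  im <- intensity_matrix(x, rep(c("ALS", "NDC"), each = 3L))
  pre <- preselect_m(im, k = 1L)
  expect_equal(pre$features, "A")
  expect_equal(pre$cutoff_p, 0.05)

  # k = n_features returns everything, ordered by M score
  pre2 <- preselect_m(im, k = 2L)
  expect_setequal(pre2$features, c("A", "B"))
  expect_equal(pre2$cutoff_p, 1)
  expect_error(preselect_m(im, k = 3L), "exceeds")

  # on a planted cohort, all planted features reach the top of the ranking
  gen <- make_test_cohort(n_features = 200L, n_planted = 6L, seed = 5L)
  pp <- preprocess_cohort(gen$cohort)
  pre3 <- preselect_m(pp$log, k = 30L)
  expect_true(all(gen$truth$planted_ids %in% pre3$features))
})

test_that("gene shaving keeps separating features and honors the size rule", {
  set.seed(20)
  n <- 20L
  x <- matrix(rnorm(n * 30), n, 30L,
              dimnames = list(NULL, sprintf("f%02d", 1:30)))
  y <- rep(c("ALS", "NDC"), each = 10L)
  x[y == "ALS", 1L] <- x[y == "ALS", 1L] + 6  # f01 separates perfectly
  sh <- gene_shave(x, y, seed = 3)
  expect_true("f01" %in% sh$selected)
  expect_true(all(diff(sh$trace$size) < 0))
  expect_gte(min(sh$trace$size), 2L)
  # the selected set is the smallest within one SE of the minimum OOB error
  thr <- sh$min_oob + sh$se
  qual_sizes <- sh$trace$size[sh$trace$oob_error <= thr]
  expect_equal(length(sh$selected), min(qual_sizes))

  # all-noise input still returns the smallest qualifying size
  xn <- matrix(rnorm(n * 20), n, 20L,
               dimnames = list(NULL, sprintf("g%02d", 1:20)))
  shn <- gene_shave(xn, y, seed = 4)
  thrn <- shn$min_oob + shn$se
  expect_equal(length(shn$selected),
               min(shn$trace$size[shn$trace$oob_error <= thrn]))

  expect_error(gene_shave(x, rep("ALS", n), seed = 1), "both groups")
  expect_error(gene_shave(x[, 1L, drop = FALSE], y, seed = 1),
               "at least two")
})

test_that("run_subrun is deterministic and never leaks test columns", {
  gen <- make_test_cohort(n_features = 150L, n_planted = 5L, seed = 6L)
  pp <- preprocess_cohort(gen$cohort)
  params <- selection_params(k_preselect = 40L, n_trees_init = 150L,
                             n_trees_iter = 100L)
  r1 <- run_subrun(pp$log, 3L, master_seed = 11L, params = params)
  r2 <- run_subrun(pp$log, 3L, master_seed = 11L, params = params)
  expect_identical(r1[names(r1) != "subrun_index"],
                   r2[names(r2) != "subrun_index"])
  expect_length(r1$test_ids, 12L)
  expect_length(r1$train_ids, 8L)
  expect_true(all(r1$selected %in% r1$preselected))
  expect_length(r1$preselected, 40L)

  # spy: corrupting the subrun's test columns must not change the selection
  poisoned <- pp$log
  te <- match(r1$test_ids, poisoned$sample_ids)
  set.seed(99)
  poisoned$values[, te] <- matrix(rnorm(length(te) * nrow(poisoned$values),
                                        10, 3), ncol = length(te))
  imp <- intensity_matrix(poisoned$values, poisoned$groups)
  r3 <- run_subrun(imp, 3L, master_seed = 11L, params = params)
  expect_identical(r3$preselected, r1$preselected)
  expect_identical(r3$selected, r1$selected)
  expect_identical(r3$cutoff_p, r1$cutoff_p)
})

test_that("run_selection tallies frequencies consistently", {
  gen <- make_test_cohort(n_features = 120L, n_planted = 4L, seed = 7L,
                          n_per_group = 10L)
  pp <- preprocess_cohort(gen$cohort)
  params <- selection_params(k_preselect = 30L, n_trees_init = 120L,
                             n_trees_iter = 80L)
  sel <- run_selection(pp$log, n_subruns = 8L, master_seed = 2L,
                       params = params)
  expect_length(sel$subruns, 8L)
  # conservation: sum of counts equals the sum of selection sizes
  expect_equal(sum(sel$freq$counts),
               sum(vapply(sel$subruns, function(s) length(s$selected),
                          integer(1))))
  expect_true(all(sel$freq$counts <= 8L))
  expect_equal(sel$n_selected_once, sum(sel$freq$counts > 0L))
  expect_equal(sel$mean_accuracy, mean(sel$accuracy))
  # determinism of the whole resampling protocol
  sel2 <- run_selection(pp$log, n_subruns = 8L, master_seed = 2L,
                        params = params)
  expect_identical(sel$freq, sel2$freq)
  expect_identical(sel$accuracy, sel2$accuracy)
})

test_that("final_panel applies threshold, ordering and truncation", {
  freq <- structure(list(counts = c(A = 36L, B = 28L, C = 9L, D = 0L),
                         n_subruns = 100L),
                    class = "frequency_table")
  expect_equal(final_panel(freq, threshold = 0.10), c("A", "B"))
  # truncation by panel_size with deterministic tie-breaks
  freq2 <- structure(list(counts = c(b = 100L, a = 100L, c = 100L),
                          n_subruns = 100L),
                     class = "frequency_table")
  expect_equal(final_panel(freq2, panel_size = 2L), c("a", "b"))
  # M-score tie-break overrides id order
  expect_equal(final_panel(freq2, panel_size = 2L,
                           tiebreak_p = c(a = 0.5, b = 0.01, c = 0.2)),
               c("b", "c"))
  expect_warning(empty <- final_panel(freq, threshold = 0.5),
                 "no feature")
  expect_length(empty, 0L)
})

test_that("derived seeds stay in range and are order-independent", {
  s <- vapply(0:500, function(i) derive_seed(42L, i), integer(1))
  expect_true(all(s >= 1L & s <= 2147483646L))
  expect_lt(max(table(s)), 2L)  # no collisions in a short stream
  expect_identical(derive_seed(42L, 7L), derive_seed(42L, 7L))
})
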