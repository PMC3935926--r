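test_that("read_gal groups duplicate spots into features", {
  td <- withr::local_tempdir()
  gal <- write_test_gal(tiny_spots(), file.path(td, "a.gal"))
  layout <- read_gal(gal)
  expect_s3_class(layout, "array_layout")
  expect_length(layout$feature_ids, 4L)
  expect_equal(unname(lengths(layout$spot_map)), rep(2L, 4L))
  expect_equal(layout$lot_id, "LOT-A")

  # two spots sharing one ID collapse to a single feature
  two <- tiny_spots()[1:2, ]
  layout2 <- read_gal(write_test_gal(two, file.path(td, "b.gal")))
  expect_length(layout2$feature_ids, 1L)
  expect_length(layout2$spot_map[[1L]], 2L)

  # one spot each: as many features as spots
  four <- tiny_spots()[c(1, 3, 5, 7), ]
  layout3 <- read_gal(write_test_gal(four, file.path(td, "c.gal")))
  expect_length(layout3$feature_ids, 4L)
})

test_that("read_gal enforces format and integrity contracts", {
  td <- withr::local_tempdir()
  # missing required column is named in the error
  lines <- c("ATF\t1.0", "0\t4",
             "\"Block\"\t\"Column\"\t\"Row\"\t\"Name\"",
             "1\t1\t1\t\"x\"")
  bad <- file.path(td, "bad.gal"); writeLines(lines, bad)
  expect_error(read_gal(bad), "ID")

  # duplicate position
  dup <- tiny_spots(); dup$row[2L] <- dup$row[1L]; dup$column[2L] <- dup$column[1L]
  expect_error(read_gal(write_test_gal(dup, file.path(td, "dup.gal"))),
               "duplicate spot position")

  # not an ATF file at all
  notatf <- file.path(td, "x.gal")
  writeLines(c("hello", "world", "!"), notatf)
  expect_error(read_gal(notatf), "ATF")
})

test_that("read_gpr parses records non-destructively and validates", {
  td <- withr::local_tempdir()
  spots <- tiny_spots()
  layout <- read_gal(write_test_gal(spots, file.path(td, "a.gal")))
  fg <- c(1000, 1100, 50, 80, 900.25, 901.5, 2000, 2100)
  bg <- rep(40, 8L)
  flags <- c(0L, -100L, 0L, 0L, 0L, 0L, 0L, 0L)
  gpr <- write_test_gpr(spots, fg, bg, flags, file.path(td, "s1.gpr"))
  tab <- read_gpr(gpr, layout, sample_id = "s1")
  expect_s3_class(tab, "spot_table")
  expect_equal(nrow(tab$records), 8L)
  expect_equal(tab$records$fg_median, fg)
  expect_equal(tab$records$flag[2L], -100L)  # retained, not filtered

  # unknown extra columns are ignored
  gpr2 <- write_test_gpr(spots, fg, bg, flags, file.path(td, "s2.gpr"),
                         extra_column = TRUE)
  expect_equal(read_gpr(gpr2, layout)$records$fg_median, fg)

  # non-numeric signal names the row
  lines <- readLines(gpr)
  lines[5L] <- sub("1000", "oops", lines[5L])  # first data row
  bad <- file.path(td, "bad.gpr"); writeLines(lines, bad)
  expect_error(read_gpr(bad, layout), "non-numeric.*row 1")

  # position absent from layout
  off <- spots; off$row[1L] <- 99L
  gpr3 <- write_test_gpr(off, fg, bg, flags, file.path(td, "s3.gpr"))
  expect_error(read_gpr(gpr3, layout), "not present in layout")

  # ID mismatch against the layout
  wrong <- spots; wrong$id[1L] <- "NM_999999.9"
  gpr4 <- write_test_gpr(wrong, fg, bg, flags, file.path(td, "s4.gpr"))
  expect_error(read_gpr(gpr4, layout), "disagrees with layout")
})

test_that("write_gpr/read_gpr round trip is the identity on records", {
  td <- withr::local_tempdir()
  spots <- tiny_spots()
  layout <- read_gal(write_test_gal(spots, file.path(td, "a.gal")))
  set.seed(4)
  fg <- 2^runif(8L, 5, 14)  # awkward full-precision doubles
  tab <- read_gpr(write_test_gpr(spots, fg, rep(40.5, 8L),
                                 rep(0L, 8L), file.path(td, "s.gpr")),
                  layout, sample_id = "s")
  out <- file.path(td, "rt.gpr")
  write_gpr(tab, out)
  back <- read_gpr(out, layout, sample_id = "s")
  expect_identical(back$records, tab$records)

  # empty table refuses to write; single record gives one data line
  empty <- tab; empty$records <- tab$records[0L, ]
  expect_error(write_gpr(empty, file.path(td, "e.gpr")), "no spot records")
  one <- tab; one$records <- tab$records[1L, , drop = FALSE]
  write_gpr(one, file.path(td, "one.gpr"))
  expect_length(readLines(file.path(td, "one.gpr")), 6L)  # 4 header + cols + 1
})

test_that("assemble_cohort stacks samples in ALS-then-NDC order", {
  td <- withr::local_tempdir()
  spots <- tiny_spots()
  layout <- read_gal(write_test_gal(spots, file.path(td, "a.gal")))
  mk <- function(id, group, shift) {
    tab <- read_gpr(write_test_gpr(spots, 100 + shift + 1:8, rep(10, 8L),
                                   rep(0L, 8L),
                                   file.path(td, paste0(id, ".gpr"))),
                    layout, sample_id = id)
    tab$group <- group
    tab
  }
  tables <- list(mk("zz", "NDC", 0), mk("b", "ALS", 10), mk("a", "ALS", 20))
  cohort <- assemble_cohort(tables, layout)
  expect_equal(cohort$sample_ids, c("a", "b", "zz"))
  expect_equal(as.character(cohort$groups), c("ALS", "ALS", "NDC"))
  expect_equal(dim(cohort$fg), c(8L, 3L))  # sum of duplicates x samples
  expect_equal(cohort$feature_ids, rep(layout$feature_ids, each = 2L))
  # values landed in the right columns
  expect_equal(unname(cohort$fg[1L, "a"]), 121)

  # single table: single-column matrix
  expect_equal(ncol(assemble_cohort(tables[2L], layout)$fg), 1L)

  # a sample missing a layout spot is an integrity error naming it
  short <- mk("c", "ALS", 0)
  short$records <- short$records[-3L, ]
  expect_error(assemble_cohort(list(short), layout),
               "missing spot position")

  # unlabeled tables are rejected
  unl <- mk("d", "ALS", 0); unl$group <- NA_character_
  expect_error(assemble_cohort(list(unl), layout), "group label")
})

test_that("sample sheets are read and validated", {
  td <- withr::local_tempdir()
  sheet <- file.path(td, "samples.tsv")
  writeLines(c("sample_id\tgroup", "s1\tALS", "s2\tNDC"), sheet)
  df <- read_sample_sheet(sheet)
  expect_equal(df$group, c("ALS", "NDC"))
  writeLines(c("sample_id\tgroup", "s1\tALS", "s1\tNDC"), sheet)
  expect_error(read_sample_sheet(sheet), "duplicate")
  writeLines(c("sample_id\tgroup", "s1\tcase"), sheet)
  expect_error(read_sample_sheet(sheet), "ALS")
})
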