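# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk except files the tests themselves write.

# a small planted cohort for pipeline-level tests
make_test_cohort <- function(n_features = 120L, n_planted = 5L,
                             n_per_group = 10L, delta = 1.0, seed = 1L, ...) {
  generate_cohort(cohort_spec(n_cases = n_per_group,
                              n_controls = n_per_group,
                              n_features = n_features,
                              n_planted = n_planted,
                              delta = delta, seed = seed, ...))
}

# write a minimal GAL file; spots is a data frame with columns
# block, column, row, name, id
write_test_gal <- function(spots, path, lot = "LOT-A") {
  lines <- c("ATF\t1.0", "2\t5",
             "\"Type=GenePix ArrayList V1.0\"",
             sprintf("\"Lot=%s\"", lot),
             "\"Block\"\t\"Column\"\t\"Row\"\t\"Name\"\t\"ID\"",
             sprintf("%d\t%d\t%d\t\"%s\"\t\"%s\"", spots$block, spots$column,
                     spots$row, spots$name, spots$id))
  writeLines(lines, path)
  path
}

# write a minimal GPR file for the same spots with given signals
write_test_gpr <- function(spots, fg, bg, flags, path,
                           extra_column = FALSE) {
  ncol <- if (extra_column) 9L else 8L
  head_cols <- c("Block", "Column", "Row", "Name", "ID",
                 "F635 Median", "B635 Median", "Flags")
  if (extra_column) head_cols <- c(head_cols, "F532 Median")
  body <- sprintf("%d\t%d\t%d\t\"%s\"\t\"%s\"\t%s\t%s\t%d", spots$block,
                  spots$column, spots$row, spots$name, spots$id,
                  format(fg, digits = 17), format(bg, digits = 17), flags)
  if (extra_column) body <- paste0(body, "\t500")
  lines <- c("ATF\t1.0", sprintf("1\t%d", ncol),
             "\"Type=GenePix Results 3\"",
             paste(sprintf("\"%s\"", head_cols), collapse = "\t"),
             body)
  writeLines(lines, path)
  path
}

# four distinct features printed in duplicate: the standard tiny layout
tiny_spots <- function() {
  data.frame(block = 1L,
             column = rep(1:4, each = 2L),
             row = rep(1:2, times = 4L),
             name = rep(sprintf("protein %d", 1:4), each = 2L),
             id = rep(sprintf("NM_%06d.1", 1:4), each = 2L),
             stringsAsFactors = FALSE)
}
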