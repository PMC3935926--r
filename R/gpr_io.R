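## GenePix ATF dialect I/O: GAL array layouts, GPR spot results, sample
## sheets, and assembly of per-sample spot tables into a cohort.
##
## The dialect is tab-separated Axon Text File (ATF) 1.0: a first line
## "ATF <tab> 1.0", a second line giving the number of optional header
## records and the number of data columns, the optional header records
## (quoted "Key=Value" strings), one column-header line, then data rows.
## Real GenePix exports carry many more columns; unknown columns are
## ignored on input.

atf_read <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || !grepl("^ATF\\t", lines[1L]))
    stop(sprintf("'%s' is not an ATF file (missing 'ATF' header line)",
                 path), call. = FALSE)
  counts <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop(sprintf("'%s': malformed ATF record-count line", path), call. = FALSE)
  n_opt <- counts[1L]
  opt <- if (n_opt > 0L) gsub("^\"|\"$", "", lines[2L + seq_len(n_opt)]) else character(0)
  body <- lines[-seq_len(2L + n_opt)]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   quote = "\"", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  list(header = opt, data = df)
}

atf_require_columns <- function(df, cols, path, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s file '%s' is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

atf_numeric_column <- function(df, col, path) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !is.na(df[[col]]))
  if (length(bad))
    stop(sprintf("'%s': non-numeric value in column '%s' at data row %d",
                 path, col, bad[1L]), call. = FALSE)
  x
}

pos_key <- function(block, row, column) paste(block, row, column, sep = ":")

#' Read a GenePix Array List (GAL) file
#'
#' Parses the lot-specific spot layout of the array: every printed spot's
#' block/row/column position, its protein description (`Name`) and its
#' database id (`ID`). Duplicate spots of the same protein share an `ID`
#' and are grouped into one feature with several positions.
#'
#' @param path path to a GAL file in the supported ATF 1.0 dialect.
#' @return An object of class `array_layout`: `feature_ids` (unique ids in
#'   order of first appearance), `spots` (data frame of all positions),
#'   `spot_map` (feature id -> integer indices into `spots`), `lot_id`.
#' @export
read_gal <- function(path) {
  atf <- atf_read(path)
  df <- atf$data
  atf_require_columns(df, c("Block", "Column", "Row", "Name", "ID"), path, "GAL")
  spots <- data.frame(
    block = atf_numeric_column(df, "Block", path),
    row = atf_numeric_column(df, "Row", path),
    column = atf_numeric_column(df, "Column", path),
    name = df[["Name"]],
    id = df[["ID"]],
    stringsAsFactors = FALSE)
  key <- pos_key(spots$block, spots$row, spots$column)
  if (anyDuplicated(key))
    stop(sprintf("GAL file '%s': duplicate spot position %s",
                 path, key[duplicated(key)][1L]), call. = FALSE)
  feature_ids <- unique(spots$id)
  spot_map <- split(seq_len(nrow(spots)),
                    factor(spots$id, levels = feature_ids))
  lot <- grep("^Lot=", atf$header, value = TRUE)
  structure(list(feature_ids = feature_ids,
                 spots = spots,
                 spot_map = spot_map,
                 lot_id = if (length(lot)) sub("^Lot=", "", lot[1L]) else NA_character_),
            class = "array_layout")
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("array_layout: %d features, %d spots, lot %s\n",
              length(x$feature_ids), nrow(x$spots), x$lot_id))
  invisible(x)
}

#' Read a GenePix Results (GPR) file against a layout
#'
#' Reads the per-spot quantification of one probed array. The reader is
#' non-destructive: flagged spots are retained with their flag and acted
#' on only during preprocessing. Phenotype (ALS/NDC) is never taken from
#' the GPR; it comes from the sample sheet.
#'
#' @param path path to a GPR file.
#' @param layout `array_layout` from [read_gal()]; every GPR position must
#'   occur in the layout with the same `ID`.
#' @param sample_id sample identifier; defaults to the file name without
#'   extension.
#' @return An object of class `spot_table`: `sample_id`, `group`
#'   (`NA` until assigned from a sample sheet) and `records`, a data frame
#'   with one row per spot (block, column, row, name, id, fg_median,
#'   bg_median, flag).
#' @export
read_gpr <- function(path, layout, sample_id = NULL) {
  stopifnot(inherits(layout, "array_layout"))
  atf <- atf_read(path)
  df <- atf$data
  atf_require_columns(df, c("Block", "Column", "Row", "Name", "ID",
                            "F635 Median", "B635 Median", "Flags"),
                      path, "GPR")
  rec <- data.frame(
    block = atf_numeric_column(df, "Block", path),
    column = atf_numeric_column(df, "Column", path),
    row = atf_numeric_column(df, "Row", path),
    name = df[["Name"]],
    id = df[["ID"]],
    fg_median = atf_numeric_column(df, "F635 Median", path),
    bg_median = atf_numeric_column(df, "B635 Median", path),
    flag = as.integer(atf_numeric_column(df, "Flags", path)),
    stringsAsFactors = FALSE)
  if (any(rec$fg_median < 0) || any(rec$bg_median < 0))
    stop(sprintf("'%s': negative spot intensities", path), call. = FALSE)
  key <- pos_key(rec$block, rec$row, rec$column)
  if (anyDuplicated(key))
    stop(sprintf("GPR file '%s': duplicate spot position %s",
                 path, key[duplicated(key)][1L]), call. = FALSE)
  lkey <- pos_key(layout$spots$block, layout$spots$row, layout$spots$column)
  at <- match(key, lkey)
  if (anyNA(at))
    stop(sprintf("GPR file '%s': spot position %s not present in layout",
                 path, key[which(is.na(at))[1L]]), call. = FALSE)
  mism <- which(rec$id != layout$spots$id[at])
  if (length(mism))
    stop(sprintf("GPR file '%s': ID '%s' at position %s disagrees with layout ('%s')",
                 path, rec$id[mism[1L]], key[mism[1L]],
                 layout$spots$id[at[mism[1L]]]), call. = FALSE)
  structure(list(sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
                 group = NA_character_,
                 records = rec),
            class = "spot_table")
}

#' Write a spot table as a GPR (ATF 1.0) file
#'
#' Emits the 8-column dialect read by [read_gpr()]. Numeric signals are
#' written at full double precision so that a write/read round trip is the
#' identity on record content.
#'
#' @param table a `spot_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gpr <- function(table, path) {
  stopifnot(inherits(table, "spot_table"))
  rec <- table$records
  if (is.null(rec) || nrow(rec) == 0L)
    stop("cannot write a GPR file with no spot records", call. = FALSE)
  header <- c("ATF\t1.0",
              "2\t8",
              "\"Type=GenePix Results 3\"",
              sprintf("\"SampleID=%s\"", table$sample_id))
  cols <- paste(sprintf("\"%s\"", c("Block", "Column", "Row", "Name", "ID",
                                    "F635 Median", "B635 Median", "Flags")),
                collapse = "\t")
  rows <- paste(format(rec$block, trim = TRUE, scientific = FALSE),
                format(rec$column, trim = TRUE, scientific = FALSE),
                format(rec$row, trim = TRUE, scientific = FALSE),
                sprintf("\"%s\"", rec$name),
                sprintf("\"%s\"", rec$id),
                sprintf("%.17g", rec$fg_median),
                sprintf("%.17g", rec$bg_median),
                format(rec$flag, trim = TRUE, scientific = FALSE),
                sep = "\t")
  writeLines(c(header, cols, rows), path)
  invisible(path)
}

#' Write a GAL (ATF 1.0) layout file
#'
#' @param layout an `array_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(layout, path) {
  stopifnot(inherits(layout, "array_layout"))
  sp <- layout$spots
  header <- c("ATF\t1.0",
              "2\t5",
              "\"Type=GenePix ArrayList V1.0\"",
              sprintf("\"Lot=%s\"",
                      if (is.na(layout$lot_id)) "UNKNOWN" else layout$lot_id))
  cols <- paste(sprintf("\"%s\"", c("Block", "Column", "Row", "Name", "ID")),
                collapse = "\t")
  rows <- paste(format(sp$block, trim = TRUE, scientific = FALSE),
                format(sp$column, trim = TRUE, scientific = FALSE),
                format(sp$row, trim = TRUE, scientific = FALSE),
                sprintf("\"%s\"", sp$name),
                sprintf("\"%s\"", sp$id),
                sep = "\t")
  writeLines(c(header, cols, rows), path)
  invisible(path)
}

#' Read a two-column sample sheet
#'
#' Tab-separated file with header columns `sample_id` and `group`
#' (values `ALS` or `NDC`). GPR files carry no phenotype, so group labels
#' always come from this sheet.
#'
#' @param path path to the sheet.
#' @return data frame with columns `sample_id`, `group`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop(sprintf("sample sheet '%s' must have columns 'sample_id' and 'group'",
                 path), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  df$group <- as.character(as_group_factor(df$group))
  df[, c("sample_id", "group")]
}

#' Assemble per-sample spot tables into a spot-level cohort
#'
#' Stacks the probed arrays into spot-level foreground/background/flag
#' matrices keyed by (feature id, replicate index) in layout order.
#' Samples are ordered ALS first then NDC, each alphabetically by sample
#' id — the canonical column order used by the whole pipeline.
#'
#' @param tables list of `spot_table`s, each with its `group` assigned
#'   (see [read_sample_sheet()]).
#' @param layout the shared `array_layout`; every layout position must be
#'   present in every table.
#' @return An object of class `spot_cohort`: matrices `fg`, `bg`, `flags`
#'   (spots x samples), per-spot `feature_ids` and `replicate`, plus
#'   `sample_ids` and `groups`.
#' @export
assemble_cohort <- function(tables, layout) {
  stopifnot(inherits(layout, "array_layout"), length(tables) >= 1L)
  groups <- vapply(tables, function(t) as.character(t$group), character(1))
  ids <- vapply(tables, function(t) t$sample_id, character(1))
  if (anyNA(groups))
    stop("all spot tables need a group label before assembly", call. = FALSE)
  g <- as_group_factor(groups)
  ord <- order(g, ids)
  tables <- tables[ord]; ids <- ids[ord]; g <- g[ord]

  # spot order: features in layout order, duplicates by layout position order
  spot_idx <- unlist(layout$spot_map, use.names = FALSE)
  feature_of_spot <- rep(names(layout$spot_map),
                         lengths(layout$spot_map))
  replicate_of_spot <- unlist(lapply(lengths(layout$spot_map), seq_len),
                              use.names = FALSE)
  lkey <- pos_key(layout$spots$block, layout$spots$row,
                  layout$spots$column)[spot_idx]

  n_spot <- length(spot_idx)
  n_samp <- length(tables)
  fg <- bg <- matrix(NA_real_, n_spot, n_samp)
  fl <- matrix(NA_integer_, n_spot, n_samp)
  for (s in seq_len(n_samp)) {
    rec <- tables[[s]]$records
    at <- match(lkey, pos_key(rec$block, rec$row, rec$column))
    if (anyNA(at))
      stop(sprintf("sample '%s' is missing spot position %s required by the layout",
                   ids[s], lkey[which(is.na(at))[1L]]), call. = FALSE)
    fg[, s] <- rec$fg_median[at]
    bg[, s] <- rec$bg_median[at]
    fl[, s] <- rec$flag[at]
  }
  spot_names <- paste(feature_of_spot, replicate_of_spot, sep = ".")
  dimnames(fg) <- dimnames(bg) <- dimnames(fl) <- list(spot_names, ids)
  structure(list(fg = fg, bg = bg, flags = fl,
                 feature_ids = feature_of_spot,
                 replicate = replicate_of_spot,
                 feature_names = layout$spots$name[spot_idx],
                 sample_ids = ids, groups = g,
                 layout_feature_ids = layout$feature_ids),
            class = "spot_cohort")
}

#' @export
print.spot_cohort <- function(x, ...) {
  cat(sprintf("spot_cohort: %d spots (%d features) x %d samples (%d ALS, %d NDC)\n",
              nrow(x$fg), length(unique(x$feature_ids)), ncol(x$fg),
              sum(x$groups == "ALS"), sum(x$groups == "NDC")))
  invisible(x)
}
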