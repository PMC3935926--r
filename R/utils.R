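#' Derive a stage or subrun seed from a master seed
#'
#' Counter-based seed derivation: a Lehmer-style mix of the master seed and
#' an index produces a stream of per-stage seeds that is independent of
#' execution order, so any subrun can be reproduced in isolation. Values
#' stay below 2^31 - 1 and are valid arguments to [set.seed()].
#'
#' @param master integer master seed.
#' @param index nonnegative integer counter (e.g. subrun index).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(master, index) {
  stopifnot(length(master) == 1, length(index) == 1, is.finite(master),
            is.finite(index), index >= 0)
  m <- 2147483647  # 2^31 - 1
  s <- (abs(as.numeric(master)) %% m) * 48271 + (as.numeric(index) %% m) * 1013904223
  out <- as.integer(s %% m)
  if (out == 0L) out <- 1L
  out
}

## coerce and validate the case/control group labels; ALS is the case
## (positive) class throughout the package
as_group_factor <- function(groups) {
  g <- factor(as.character(groups), levels = c("ALS", "NDC"))
  if (anyNA(g))
    stop("group labels must be 'ALS' or 'NDC'", call. = FALSE)
  g
}

require_both_groups <- function(groups) {
  g <- as_group_factor(groups)
  if (length(unique(g)) < 2L)
    stop("both groups (ALS and NDC) must be present", call. = FALSE)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
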