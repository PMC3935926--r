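## Per-feature statistics: exact hypergeometric upper tail, the minimum
## M-statistic ("M score"), Welch's t test, Benjamini-Hochberg FDR and
## deterministic feature ranking.

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= a) for X ~ Hypergeometric(population n1 + n2, n1 successes,
#' k draws): the probability that at least `a` of the `k` samples above an
#' intensity cutoff are cases when group labels are exchangeable. Computed
#' by `phyper`, which works in log space and is exact to double precision.
#'
#' @param a observed number of cases above the cutoff.
#' @param k total number of samples above the cutoff.
#' @param n1 number of cases.
#' @param n2 number of controls.
#' @return The tail probability, a number in (0, 1].
#' @export
#' @examples
#' hypergeom_upper_tail(3, 3, 3, 3)  # 1/20
hypergeom_upper_tail <- function(a, k, n1, n2) {
  stopifnot(length(a) == 1, length(k) == 1, length(n1) == 1, length(n2) == 1)
  if (any(c(a, k, n1, n2) != floor(c(a, k, n1, n2))) || n1 < 1 || n2 < 1)
    stop("arguments must be integer counts with n1, n2 >= 1", call. = FALSE)
  if (a < 0 || a > min(k, n1) || (k - a) > n2 || k > n1 + n2)
    stop("inconsistent counts: need 0 <= a <= min(k, n1) and k - a <= n2",
         call. = FALSE)
  if (a == 0) return(1)
  phyper(a - 1, n1, n2, k, lower.tail = FALSE)
}

#' Minimum M-statistic (M score) for one feature
#'
#' One-sided threshold test for case-elevated reactivity. Candidate
#' cutoffs are the midpoints between consecutive distinct pooled
#' intensities plus one cutoff above the maximum; for each cutoff the
#' exact hypergeometric upper tail of the resulting 2x2 table (cases vs
#' controls above/below) is evaluated, and the minimum over cutoffs is the
#' M score. The minimum over cutoffs makes the score anti-conservative as
#' a p-value; it is used for screening and ranking, with FDR control
#' applied downstream. Ties in p are broken toward the largest cutoff.
#'
#' @param case_values numeric vector of case (ALS) intensities.
#' @param control_values numeric vector of control (NDC) intensities.
#' @return A list: `p_value`, `best_cutoff`, `cases_above`,
#'   `controls_above`.
#' @export
#' @examples
#' m_score(c(10, 9, 8), c(1, 2, 3))  # perfectly separated: p = 1/20
m_score <- function(case_values, control_values) {
  if (length(case_values) < 1L || length(control_values) < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(case_values) || anyNA(control_values))
    stop("missing values not allowed", call. = FALSE)
  x <- matrix(c(case_values, control_values), nrow = 1L)
  res <- cpp_mscore(x, c(rep(TRUE, length(case_values)),
                         rep(FALSE, length(control_values))))
  list(p_value = res$p_value[1L],
       best_cutoff = res$best_cutoff[1L],
       cases_above = res$cases_above[1L],
       controls_above = res$controls_above[1L])
}

#' M scores for every feature of an intensity matrix
#'
#' Vectorized equivalent of [m_score()] over all rows.
#'
#' @param im an `intensity_matrix` containing both groups.
#' @return A data frame with one row per feature: `feature_id`, `p_value`,
#'   `best_cutoff`, `cases_above`, `controls_above`.
#' @export
m_score_matrix <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  g <- require_both_groups(im$groups)
  res <- cpp_mscore(im$values, g == "ALS")
  data.frame(feature_id = im$feature_ids,
             p_value = res$p_value,
             best_cutoff = res$best_cutoff,
             cases_above = res$cases_above,
             controls_above = res$controls_above,
             stringsAsFactors = FALSE)
}

#' Welch's two-sample t test (two-sided p)
#'
#' Unequal-variance t test on (log2) intensities with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param case_values,control_values numeric vectors, each of length >= 2.
#' @return The two-sided p-value, with the t statistic and degrees of
#'   freedom attached as attributes `statistic` and `df`.
#' @export
welch_t <- function(case_values, control_values) {
  n1 <- length(case_values); n2 <- length(control_values)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need at least two observations", call. = FALSE)
  v1 <- var(case_values); v2 <- var(control_values)
  if (v1 == 0 && v2 == 0)
    stop("zero variance in both groups: t statistic undefined", call. = FALSE)
  se2 <- v1 / n1 + v2 / n2
  t <- (mean(case_values) - mean(control_values)) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * pt(-abs(t), df)
  structure(p, statistic = t, df = df)
}

#' Row-wise Welch t-test p-values
#'
#' Vectorized over all features of an intensity matrix. Rows where both
#' groups are exactly constant get p = 1 when the group means agree and
#' p = 0 otherwise (degenerate but defined, so genome-wide FDR adjustment
#' over all features remains possible).
#'
#' @param im an `intensity_matrix` containing both groups.
#' @return Named numeric vector of two-sided p-values, one per feature.
#' @export
welch_t_matrix <- function(im) {
  stopifnot(inherits(im, "intensity_matrix"))
  g <- require_both_groups(im$groups)
  x1 <- im$values[, g == "ALS", drop = FALSE]
  x2 <- im$values[, g == "NDC", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L)
    stop("both groups need at least two samples", call. = FALSE)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  t <- ifelse(degenerate, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(degenerate, 1,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- 2 * pt(-abs(t), df)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  setNames(p, im$feature_ids)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: the adjusted value of the i-th order statistic
#' is `min_{j >= i} p_(j) * m / j`, capped at 1, returned in the input
#' order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
  names(adj) <- names(p_values)
  adj
}

#' Deterministic rank positions of features by p-value
#'
#' Position 1 is the smallest p; ties are broken by lexicographic feature
#' id so the ranking is reproducible.
#'
#' @param p_values numeric vector of p-values.
#' @param feature_ids character vector of ids (defaults to
#'   `names(p_values)`).
#' @return Integer vector of positions (a permutation of `1..n`), named by
#'   feature id.
#' @export
rank_features <- function(p_values, feature_ids = names(p_values)) {
  if (is.null(feature_ids))
    feature_ids <- as.character(seq_along(p_values))
  stopifnot(length(feature_ids) == length(p_values))
  o <- order(p_values, feature_ids)
  pos <- integer(length(p_values))
  pos[o] <- seq_along(p_values)
  setNames(pos, feature_ids)
}
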