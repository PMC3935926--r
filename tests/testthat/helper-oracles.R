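# Independent oracles used by the unit and acceptance suites. They are
# deliberately brute-force (enumeration, direct definitions) and share no
# code with the implementation paths they check.

# hypergeometric upper tail by enumeration over all k-subsets of the
# population; memoized because the acceptance sweep reuses few distinct
# (a, k, n1, n2) tuples many times
.hyper_cache <- new.env(parent = emptyenv())
hyper_tail_oracle <- function(a, k, n1, n2) {
  key <- paste(a, k, n1, n2, sep = "_")
  hit <- .hyper_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (a <= 0) {
    1
  } else if (k == 0) {
    0
  } else {
    pop <- c(rep(1L, n1), rep(0L, n2))
    sets <- utils::combn(n1 + n2, k)
    mean(colSums(matrix(pop[sets], nrow = k)) >= a)
  }
  .hyper_cache[[key]] <- val
  val
}

# exhaustive-cutoff M-score oracle: every distinct pooled value acts as a
# strict cutoff (the largest value yields the empty table, p = 1)
m_score_oracle <- function(cases, controls) {
  pooled <- sort(unique(c(cases, controls)))
  n1 <- length(cases); n2 <- length(controls)
  best <- 1
  for (cut in pooled) {
    a <- sum(cases > cut)
    k <- a + sum(controls > cut)
    best <- min(best, hyper_tail_oracle(a, k, n1, n2))
  }
  best
}

# O(m^2) direct-definition Benjamini-Hochberg oracle
bh_oracle <- function(p) {
  m <- length(p)
  s <- sort(p)
  adj_sorted <- vapply(seq_len(m), function(i)
    min(1, min(s[i:m] * m / (i:m))), numeric(1))
  adj_sorted[match(p, s)]
}

# nearest-shrunken-centroid d-statistics straight from the defining
# formula, computed with explicit loops
nsc_d_oracle <- function(x, groups) {
  g <- factor(as.character(groups), levels = c("ALS", "NDC"))
  n <- ncol(x)
  levs <- levels(g)
  d <- matrix(NA_real_, nrow(x), length(levs),
              dimnames = list(rownames(x), levs))
  s <- numeric(nrow(x))
  for (j in seq_len(nrow(x))) {
    ss <- 0
    for (lev in levs) {
      xk <- x[j, g == lev]
      ss <- ss + sum((xk - mean(xk))^2)
    }
    s[j] <- sqrt(ss / (n - length(levs)))
  }
  s0 <- median(s)
  for (lev in levs) {
    nk <- sum(g == lev)
    mk <- sqrt(1 / nk - 1 / n)
    for (j in seq_len(nrow(x)))
      d[j, lev] <- (mean(x[j, g == lev]) - mean(x[j, ])) / (mk * (s[j] + s0))
  }
  d
}

# all multisets of the given size over a value alphabet, as a list of
# nondecreasing vectors
multisets <- function(vals, size) {
  grid <- expand.grid(rep(list(vals), size))
  keep <- apply(grid, 1L, function(r) all(diff(r) >= 0))
  lapply(which(keep), function(i) as.numeric(grid[i, ]))
}

# a random strictly increasing map defined on the values it will be
# applied to (piecewise over the sorted unique values)
random_monotone_map <- function(values) {
  u <- sort(unique(values))
  f <- cumsum(runif(length(u), min = 0.05, max = 2))
  function(x) f[match(x, u)]
}
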