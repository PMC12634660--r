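# Internal statistical helpers shared across modules.

# Vectorised two-sample Mann-Whitney U test over the columns of `x`.
# Normal approximation with tie correction and continuity correction,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE). Needed because
# the edge-modulation and type-I suites run thousands of tests.
# `group` is a logical vector over rows: TRUE = group 1.
mwu_test_cols <- function(x, group, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(group))
  n1 <- sum(group)
  n2 <- sum(!group)
  if (n1 < 2L || n2 < 2L) {
    abort("mann-whitney test needs at least 2 observations per group")
  }
  p <- ncol(x)
  stat <- pval <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    v <- x[, j]
    ok <- is.finite(v)
    g <- group[ok]
    v <- v[ok]
    m1 <- sum(g); m2 <- sum(!g)
    if (m1 < 2L || m2 < 2L) next
    r <- rank(v)
    U <- sum(r[g]) - m1 * (m1 + 1) / 2
    mu <- m1 * m2 / 2
    nties <- table(v)
    sig2 <- (m1 * m2 / 12) *
      ((m1 + m2 + 1) - sum(nties^3 - nties) / ((m1 + m2) * (m1 + m2 - 1)))
    stat[j] <- U
    if (sig2 <= 0) {
      pval[j] <- 1
      next
    }
    z <- U - mu
    corr <- switch(alternative,
      two.sided = sign(z) * 0.5,
      greater = 0.5,
      less = -0.5
    )
    z <- (z - corr) / sqrt(sig2)
    pval[j] <- switch(alternative,
      two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE), 0.5),
      greater = pnorm(z, lower.tail = FALSE),
      less = pnorm(z)
    )
  }
  list(statistic = stat, p_value = pmin(pval, 1))
}

# One test per row of a tibble-ready result, with multiplicity correction.
adjust_p <- function(p, method = c("benjamini_hochberg", "bonferroni", "none")) {
  method <- match.arg(method)
  switch(method,
    benjamini_hochberg = p.adjust(p, method = "BH"),
    bonferroni = p.adjust(p, method = "bonferroni"),
    none = p
  )
}

# Build the standard test-result tibble used throughout the package.
test_result_tbl <- function(statistic, p_raw, method, correction, alpha) {
  p_adj <- adjust_p(p_raw, correction)
  tibble(
    statistic = statistic,
    p_raw = p_raw,
    p_adjusted = p_adj,
    method = method,
    correction = correction,
    significant = !is.na(p_adj) & p_adj < alpha
  )
}

# Named substreams derived from one root seed, so modules can be regenerated
# independently and an extra draw in one module never shifts another.
derive_seeds <- function(seed, names) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  setNames(sample.int(.Machine$integer.max - 1L, length(names)), names)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# run-length encoding of an integer label vector into half-open intervals
rle_intervals <- function(labels) {
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  tibble(syllable = r$values, start = start, end = end)
}
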