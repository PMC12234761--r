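# Nonparametric comparison battery used for the outcome tables: Wilcoxon
# signed-rank (paired thresholds / outcomes), Kruskal-Wallis (across
# acquisition settings) and Mann-Whitney U with Bonferroni adjustment
# (pairwise follow-up), plus median/IQR summaries gated by Shapiro-Wilk.
#
# Small samples use exact enumeration (all sign patterns, all group
# assignments); larger samples use the usual tie-corrected normal or
# chi-square approximations.

signed_rank_statistic <- function(d) {
  r <- rank(abs(d))
  sum(r[d > 0])
}

#' Wilcoxon signed-rank test
#'
#' Paired test on differences. Zero differences are dropped (the common
#' convention; documented because software differs here). For `n <= exact_n`
#' the p value is computed by exact enumeration of all `2^n` sign patterns
#' (valid under ties); otherwise the normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x numeric vector: differences, or first member of the pairs.
#' @param y optional second member; the test then runs on `x - y`.
#' @param exact_n maximum n for exact enumeration.
#' @return list with `statistic` (V, sum of positive ranks), `n` (nonzero
#'   pairs), `p` (two-sided), and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_n = 12) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n = 0L, p = 1, method = "degenerate"))
  }
  v <- signed_rank_statistic(d)
  r <- rank(abs(d))
  if (n <= exact_n) {
    # all sign assignments are equally likely under H0, ties included
    stats <- vapply(0:(2^n - 1), function(mask) {
      sum(r[bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0])
    }, numeric(1))
    mu <- n * (n + 1) / 4
    p <- mean(abs(stats - mu) >= abs(v - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = v, n = as.integer(n), p = p, method = method)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square reference, or exact
#' enumeration of all assignments of the pooled sample to the group sizes
#' when the total n is small.
#'
#' @param groups list of numeric vectors.
#' @param exact enumerate all group assignments? Defaults to TRUE when the
#'   pooled size is at most `exact_n`.
#' @param exact_n pooled-size limit for the default exact switch.
#' @return list with `statistic` (H, tie-corrected), `df`, `p`, `method`.
#' @export
kruskal_wallis <- function(groups, exact = NULL, exact_n = 10) {
  groups <- lapply(groups, as.numeric)
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  n_i <- lengths(groups)
  n <- sum(n_i)
  if (is.null(exact)) exact <- n <= exact_n
  h_of <- function(values, sizes) {
    r <- rank(values)
    ends <- cumsum(sizes)
    starts <- c(1, head(ends, -1) + 1)
    rs <- vapply(seq_along(sizes), function(i) sum(r[starts[i]:ends[i]]), numeric(1))
    h <- 12 / (n * (n + 1)) * sum(rs^2 / sizes) - 3 * (n + 1)
    tie_tab <- table(r)
    corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
    if (corr > 0) h / corr else 0
  }
  pooled <- unlist(groups)
  h <- h_of(pooled, n_i)
  if (exact) {
    assignments <- group_assignments(n, n_i)
    stats <- vapply(assignments, function(idx) h_of(pooled[idx], n_i), numeric(1))
    p <- mean(stats >= h - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  list(statistic = h, df = k - 1, p = p, method = method)
}

# all distinct orderings of 1:n into consecutive blocks of sizes n_i,
# as index permutations (multinomial enumeration via nested combn)
group_assignments <- function(n, n_i) {
  rec <- function(remaining, sizes) {
    if (length(sizes) == 1) return(list(remaining))
    picks <- combn(remaining, sizes[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(remaining, p), sizes[-1])
      out <- c(out, lapply(rest, function(r) c(p, r)))
    }
    out
  }
  rec(seq_len(n), n_i)
}

#' Mann-Whitney U test with optional Bonferroni adjustment
#'
#' U is reported for the first sample (`U = sum over pairs of
#' I(a > b) + 0.5 I(a == b)`). Exact p by enumeration of all
#' `choose(n1 + n2, n1)` group assignments for small samples (valid under
#' ties); tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples.
#' @param bonferroni_m number of comparisons in the family; the adjusted p
#'   is `min(1, m * p)`.
#' @param exact enumerate? Defaults to TRUE when `choose(n1 + n2, n1)` is at
#'   most 20000.
#' @return list with `statistic` (U for `a`), `p` (two-sided),
#'   `p_adjusted`, `method`.
#' @export
mann_whitney_u <- function(a, b, bonferroni_m = 1, exact = NULL) {
  n1 <- length(a)
  n2 <- length(b)
  u_of <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  u <- u_of(a, b)
  if (is.null(exact)) exact <- choose(n1 + n2, n1) <= 20000
  mu <- n1 * n2 / 2
  if (exact) {
    pooled <- c(a, b)
    picks <- combn(n1 + n2, n1, simplify = FALSE)
    stats <- vapply(picks, function(idx)
      u_of(pooled[idx], pooled[-idx]), numeric(1))
    p <- mean(abs(stats - mu) >= abs(u - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(c(a, b))
    n <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p = p, p_adjusted = min(1, bonferroni_m * p),
       method = method)
}

#' Summarize an outcome table: medians, IQRs and normality flags
#'
#' Medians and interquartile ranges per (setting, outcome) cell, with a
#' Shapiro-Wilk p value flagging deviation from normality (the gate used to
#' justify nonparametric testing). Quartiles use linear interpolation
#' (`quantile` type 7); IQR conventions are software-dependent, so the
#' choice is part of the contract.
#'
#' @param table data.frame with at least `setting`, `outcome`, `value`.
#' @param alpha significance level for the normality flag.
#' @return data.frame with setting, outcome, n, median, iqr, shapiro_p,
#'   non_normal.
#' @export
summarize_outcomes <- function(table, alpha = 0.05) {
  stopifnot(all(c("setting", "outcome", "value") %in% names(table)))
  keys <- unique(table[, c("setting", "outcome")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    v <- table$value[table$setting == keys$setting[i] &
                     table$outcome == keys$outcome[i]]
    sw <- if (length(unique(v)) > 2 && length(v) >= 3 && length(v) <= 5000)
      tryCatch(shapiro.test(v)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(setting = keys$setting[i],
               outcome = keys$outcome[i],
               n = length(v),
               median = median(v),
               iqr = unname(diff(quantile(v, c(0.25, 0.75), type = 7))),
               shapiro_p = sw,
               non_normal = !is.na(sw) & sw < alpha)
  }))
  rownames(out) <- NULL
  out
}
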