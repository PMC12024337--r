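# Paired pre/post statistics: distribution-gated paired tests (paired t or
# Wilcoxon signed-rank, chosen by a Shapiro-Wilk normality gate on the
# paired differences) and Bland-Altman agreement analysis.

# signed ranks of the nonzero differences (zeros excluded, Wilcoxon's rule;
# midranks for ties)
signed_ranks <- function(d, zero = c("wilcoxon", "pratt")) {
  zero <- match.arg(zero)
  if (zero == "wilcoxon") {
    d <- d[d != 0]
    if (length(d) == 0) stop("all differences are zero")
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
    if (length(d) == 0) stop("all differences are zero")
  }
  list(w = sum(r[d > 0]), ranks = r, signs = sign(d))
}

#' Exact Wilcoxon signed-rank p-value by sign enumeration
#'
#' Enumerates all `2^n` sign assignments of the absolute-difference ranks
#' (midranks for ties; zero differences excluded by Wilcoxon's rule) and
#' returns the exact two-sided p-value
#' `min(1, 2 min(P(W+ <= w), P(W+ >= w)))`. Intended for small samples
#' (`n <= 20`); serves as the enumeration oracle for the distribution-based
#' and approximate implementations.
#'
#' @param differences paired differences.
#' @param zero zero-difference rule (`"wilcoxon"` exclusion or `"pratt"`).
#' @return Two-sided p-value.
#' @export
wilcoxon_exact <- function(differences, zero = c("wilcoxon", "pratt")) {
  sr <- signed_ranks(differences, zero)
  n <- length(sr$ranks)
  if (n > 20) stop("enumeration limited to n <= 20; use wilcoxon_signed()")
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wdist <- as.vector(signs %*% sr$ranks)
  w <- sr$w
  p <- 2 * min(mean(wdist <= w + 1e-9), mean(wdist >= w - 1e-9))
  min(1, p)
}

# Exact null distribution of W+ by dynamic programming over the (doubled,
# hence integer) rank lattice. Returns P(W+ <= w) and P(W+ >= w).
wilcoxon_dp_tail <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in r2) {
    shifted <- c(rep(0, r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts <- counts / 2^length(r2)
  w2 <- 2 * w
  vals <- 0:total
  c(le = sum(counts[vals <= w2 + 1e-9]), ge = sum(counts[vals >= w2 - 1e-9]))
}

#' Wilcoxon signed-rank test (exact or corrected large-sample)
#'
#' Two-sided one-sample (paired-difference) Wilcoxon signed-rank test.
#' With `method = "auto"` the exact null distribution is used up to
#' `exact_limit` nonzero differences (computed by dynamic programming over
#' the rank lattice, so ties are handled exactly); beyond that a normal
#' approximation with continuity correction, tie-corrected variance and a
#' fourth-cumulant Edgeworth term is used.
#'
#' @param differences paired differences.
#' @param method `"auto"`, `"exact"`, or `"normal"`.
#' @param exact_limit largest n handled exactly under `"auto"`.
#' @param zero zero-difference rule.
#' @return List: `statistic` (W+), `p_value`, `method`, `n`.
#' @export
wilcoxon_signed <- function(differences, method = c("auto", "exact", "normal"),
                            exact_limit = 25, zero = c("wilcoxon", "pratt")) {
  method <- match.arg(method)
  sr <- signed_ranks(differences, zero)
  n <- length(sr$ranks)
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "normal"
  if (method == "exact") {
    tails <- wilcoxon_dp_tail(sr$ranks, sr$w)
    p <- min(1, 2 * min(tails))
  } else {
    p <- wilcoxon_normal_p(sr$ranks, sr$w)
  }
  list(statistic = sr$w, p_value = p, method = method, n = n)
}

# Corrected normal approximation: continuity correction, tie-corrected
# variance, fourth-cumulant Edgeworth term.
wilcoxon_normal_p <- function(ranks, w) {
  mu <- sum(ranks) / 2
  sig2 <- sum(ranks^2) / 4
  sig <- sqrt(sig2)
  g2 <- (-sum(ranks^4) / 8) / sig2^2   # standardized excess kurtosis
  Fcdf <- function(x) {
    z <- x / sig
    stats::pnorm(z) - stats::dnorm(z) * g2 / 24 * (z^3 - 3 * z)
  }
  p_le <- Fcdf(w + 0.5 - mu)
  p_ge <- 1 - Fcdf(w - 0.5 - mu)
  p <- 2 * min(max(p_le, 0), max(p_ge, 0))
  min(1, max(p, 0))
}

#' Distribution-gated paired comparison
#'
#' The paired pre/post test used throughout the results tables: a
#' Shapiro-Wilk test on the paired differences selects between the paired
#' t-test (normality not rejected at `alpha`) and the Wilcoxon signed-rank
#' test. Identical vectors return p = 1 under the sign-symmetry
#' convention; constant nonzero differences are degenerate for both tests
#' and raise an error.
#'
#' @param x_pre,x_post paired samples (equal length, n >= 3).
#' @param alpha significance level of the normality gate.
#' @param variable label for the output row.
#' @return One-row data frame of class `paired_test_result`: `variable`,
#'   `n`, `mean_pre`, `mean_post`, `median_pre`, `median_post`,
#'   `delta_mean`, `test_used`, `statistic`, `p_value`, `normality_p`.
#' @export
paired_compare <- function(x_pre, x_post, alpha = 0.05, variable = "x") {
  if (length(x_pre) != length(x_post)) stop("paired samples must have equal length")
  n <- length(x_pre)
  if (n < 3) stop("paired comparison needs n >= 3")
  d <- x_post - x_pre
  row <- data.frame(variable = variable, n = n,
                    mean_pre = mean(x_pre), mean_post = mean(x_post),
                    median_pre = stats::median(x_pre),
                    median_post = stats::median(x_post),
                    delta_mean = mean(d),
                    test_used = NA_character_, statistic = NA_real_,
                    p_value = NA_real_, normality_p = NA_real_)
  if (all(d == 0)) {
    row$test_used <- "sign_symmetric"
    row$statistic <- 0
    row$p_value <- 1
    class(row) <- c("paired_test_result", class(row))
    return(row)
  }
  if (stats::sd(d) == 0)
    stop("degenerate data: paired differences are constant and nonzero")
  sw <- stats::shapiro.test(d)
  row$normality_p <- sw$p.value
  if (sw$p.value >= alpha) {
    tt <- stats::t.test(x_post, x_pre, paired = TRUE)
    row$test_used <- "paired_t"
    row$statistic <- unname(tt$statistic)
    row$p_value <- tt$p.value
  } else {
    wt <- wilcoxon_signed(d)
    row$test_used <- "wilcoxon"
    row$statistic <- wt$statistic
    row$p_value <- wt$p_value
  }
  class(row) <- c("paired_test_result", class(row))
  row
}

#' Bland-Altman agreement analysis
#'
#' Per-pair differences are `reference - test`, either absolute or as a
#' percentage of the pair mean (`100 (ref - test) / ((ref + test)/2)`, the
#' default). Bias is the mean difference, SD the sample (n-1) standard
#' deviation, and the limits of agreement are `bias +/- 1.96 SD`.
#'
#' @param reference reference measurements (e.g. invasive FFR).
#' @param test test-method measurements (e.g. model FFR).
#' @param type `"percent"` or `"absolute"`.
#' @return Object of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `pct_within_loa`, `type`, `n`, and the per-pair `means`
#'   and `diffs`.
#' @export
bland_altman <- function(reference, test, type = c("percent", "absolute")) {
  type <- match.arg(type)
  if (length(reference) != length(test)) stop("inputs must have equal length")
  n <- length(reference)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs")
  m <- (reference + test) / 2
  d <- reference - test
  if (type == "percent") {
    if (any(m == 0)) stop("pair mean of zero: percentage difference undefined")
    d <- 100 * d / m
  }
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  structure(list(bias = bias, sd = s, loa_low = loa[1], loa_high = loa[2],
                 pct_within_loa = mean(d >= loa[1] & d <= loa[2]),
                 type = type, n = n, means = m, diffs = d),
            class = "bland_altman")
}
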