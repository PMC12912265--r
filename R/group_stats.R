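#' Welch's unequal-variance t-test
#'
#' Welch statistic `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch-Satterthwaite degrees of freedom, the test applied to per-embryo
#' comet speeds, puncta counts and recoil velocities. Two-tailed by
#' default; the one-tailed variant tests `mean(a) > mean(b)`.
#'
#' @param a,b Numeric samples (each n >= 2, nonzero variance in at least
#'   one).
#' @param tails `"two"` or `"one"`.
#' @return A one-row tibble: `test`, `statistic`, `df`, `p_value`, `tails`,
#'   `n_a`, `n_b`.
#' @export
welch_t <- function(a, b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE,
                      alternative = if (tails == "two") "two.sided"
                                    else "greater")
  tibble::tibble(
    test = "Welch's t-test",
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    tails = tails,
    n_a = length(a),
    n_b = length(b)
  )
}

#' Mann-Whitney U test
#'
#' Unpaired rank-sum test: `U` computed from midranks; the p-value is exact
#' by enumeration when `n_a + n_b <= 12` and there are no ties, otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction. Two-tailed by default; the one-tailed variant tests whether
#' `a` is stochastically greater than `b`.
#'
#' @param a,b Numeric samples (each n >= 1).
#' @param tails `"two"` or `"one"`.
#' @return A one-row tibble: `test`, `statistic` (U for sample `a`),
#'   `p_value`, `tails`, `exact`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(a) < 1L || length(b) < 1L) {
    stop("samples must be non-empty", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  ranks <- rank(c(a, b))  # midranks for ties
  u <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- (na + nb <= 12) && !has_ties
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = if (tails == "two") "two.sided"
                                     else "greater")$p.value
  )
  if (!is.finite(p)) p <- 1  # degenerate (e.g. all observations tied)
  tibble::tibble(
    test = "Mann-Whitney U",
    statistic = u,
    p_value = min(1, p),
    tails = tails,
    exact = use_exact,
    n_a = na,
    n_b = nb
  )
}

#' @rdname compare_quadrants
#' @param ... Passed to [compare_quadrants()].
#' @export
chi_square_gof <- function(...) compare_quadrants(...)
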