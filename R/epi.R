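#' Sample size for a diagnostic accuracy study
#'
#' Total required sample size for estimating a test's sensitivity and
#' specificity to a given precision:
#' \deqn{N = \max\left( \frac{z_{\alpha/2}^2\, Se_e (1 - Se_e)}{d^2\, Prev},
#'   \frac{z_{\alpha/2}^2\, Sp_e (1 - Sp_e)}{d^2 (1 - Prev)} \right)}
#' rounded up, then split into control and case group sizes as
#' `n_controls = round(N (1 - Prev))`, `n_case = N - n_controls`. Supplying
#' `n` skips the first step and splits that total instead.
#'
#' @param se_e,sp_e anticipated sensitivity and specificity, in (0,1).
#' @param prev disease prevalence in the target population, in (0,1).
#' @param alpha significance level (default 0.05).
#' @param d precision (maximum marginal error) of the estimate (default
#'   0.05).
#' @param n optional externally fixed total sample size to split.
#' @return List: `N`, `n_case`, `n_controls`.
#' @examples
#' required_n(0.70, 0.77, prev = 0.4234, n = 725)  # -> 418 controls, 307 cases
#' @export
required_n <- function(se_e, sp_e, prev, alpha = 0.05, d = 0.05, n = NULL) {
  stopifnot(se_e > 0, se_e < 1, sp_e > 0, sp_e < 1, alpha > 0, alpha < 1, d > 0)
  if (prev <= 0 || prev >= 1) stop("prevalence must lie strictly in (0,1)")
  if (is.null(n)) {
    z <- stats::qnorm(1 - alpha / 2)
    n <- ceiling(max(z^2 * se_e * (1 - se_e) / (d^2 * prev),
                     z^2 * sp_e * (1 - sp_e) / (d^2 * (1 - prev))))
  }
  n_controls <- round(n * (1 - prev))
  list(N = as.integer(n), n_case = as.integer(n - n_controls),
       n_controls = as.integer(n_controls))
}

#' Odds ratio of a 2x2 exposure table
#'
#' `OR = (a d) / (b c)` with the Woolf log-normal confidence interval, where
#' a = exposed cases, b = exposed controls, c = unexposed cases,
#' d = unexposed controls. Zero cells trigger the Haldane-Anscombe 0.5
#' correction (flagged in the result).
#'
#' Counts may be given directly, or reconstructed from printed percentages
#' with [or_from_percent()].
#'
#' @param exposed_case,exposed_control,unexposed_case,unexposed_control
#'   non-negative cell counts.
#' @param ci_level confidence level (default 0.95).
#' @return List: `or`, `ci` (length 2), `corrected` flag.
#' @export
odds_ratio <- function(exposed_case, exposed_control,
                       unexposed_case, unexposed_control, ci_level = 0.95) {
  cells <- c(a = exposed_case, b = exposed_control,
             c = unexposed_case, d = unexposed_control)
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  if (any(cells == 0)) stop("zero margin even after correction")
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  se_log <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se_log)
  list(or = unname(or), ci = unname(ci), corrected = corrected)
}

#' @rdname odds_ratio
#' @param pct_case,pct_control percentage of each group that is exposed (0 to
#'   100).
#' @param n_case,n_control group sizes.
#' @param reconstruct_counts if TRUE (default) cell counts are reconstructed
#'   as `round(pct/100 * group size)` before computing the OR; if FALSE the
#'   raw percentages are used directly as proportions (both conventions occur
#'   in published tables).
#' @export
or_from_percent <- function(pct_case, pct_control, n_case, n_control,
                            reconstruct_counts = TRUE, ci_level = 0.95) {
  stopifnot(pct_case >= 0, pct_case <= 100, pct_control >= 0, pct_control <= 100)
  if (reconstruct_counts) {
    a <- round(pct_case / 100 * n_case)
    b <- round(pct_control / 100 * n_control)
    odds_ratio(a, b, n_case - a, n_control - b, ci_level = ci_level)
  } else {
    or <- (pct_case / (100 - pct_case)) / (pct_control / (100 - pct_control))
    list(or = or, ci = c(NA_real_, NA_real_), corrected = FALSE)
  }
}

#' Conditional odds of disease given an exposure category
#'
#' The ratio of exposed cases to exposed controls,
#' `(p_case * n_case) / (p_control * n_control)`, where the `p` are the
#' within-group frequencies of the category.
#'
#' @param p_case,p_control category proportion among cases / controls, in
#'   \[0,1\].
#' @param n_case,n_control group sizes.
#' @return The odds (numeric).
#' @export
conditional_odds <- function(p_case, n_case, p_control, n_control) {
  stopifnot(p_case >= 0, p_case <= 1, p_control >= 0, p_control <= 1)
  den <- p_control * n_control
  if (den == 0) stop("zero denominator: no exposed controls")
  (p_case * n_case) / den
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit of observed genotype counts (AA, Aa, aa) against
#' the Hardy-Weinberg expectation (p^2, 2pq, q^2) * n, with the allele
#' frequency p estimated from the counts; 1 degree of freedom.
#'
#' @param counts integer vector of length 3: (AA, Aa, aa).
#' @return List: `chi2`, `p_value`, `p_allele`, `expected`.
#' @export
hwe_chi2 <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0), sum(counts) > 0)
  n <- sum(counts)
  p <- (2 * counts[1L] + counts[2L]) / (2 * n)
  if (p == 0 || p == 1)  # monomorphic: trivially in equilibrium
    return(list(chi2 = 0, p_value = 1, p_allele = p,
                expected = c(p^2, 2 * p * (1 - p), (1 - p)^2) * n))
  expd <- c(p^2, 2 * p * (1 - p), (1 - p)^2) * n
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       p_allele = p, expected = expd)
}

#' Case-control frequency test with Cochran routing
#'
#' Pearson chi-square test of a 2 x k count table, falling back to Fisher's
#' exact test (Freeman-Halton for k > 2) when the Cochran conditions fail:
#' more than 20% of expected cells below 5, or any expected cell below 1.
#'
#' @param tab 2 x k matrix of non-negative counts (rows = groups, columns =
#'   categories).
#' @param method `"auto"` (Cochran routing, default), `"chi2"` or
#'   `"fisher"`.
#' @return List: `p_value`, `method` used, `statistic` (chi-square, NA for
#'   Fisher).
#' @export
allele_test <- function(tab, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), sum(tab) > 0, nrow(tab) == 2L)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L) return(list(p_value = 1, method = "degenerate",
                                  statistic = 0))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (mean(expd < 5) > 0.2 || any(expd < 1)) "fisher" else "chi2"
  }
  if (method == "fisher") {
    p <- stats::fisher.test(tab)$p.value
    list(p_value = p, method = "fisher", statistic = NA_real_)
  } else {
    chi2 <- sum((tab - expd)^2 / expd)
    df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
    list(p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE),
         method = "chi2", statistic = chi2)
  }
}
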