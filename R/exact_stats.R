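# Exact and rank statistics used across the package. The Fisher test is
# implemented directly (log-space over the conditional support) because the
# conditional-MLE odds ratio must satisfy the score equation
# E_psi[X11] = a to high precision, which stock optimizers do not guarantee
# on extreme tables.

as_table2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("table must be 2x2")
    x <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  }
  if (length(x) != 4L || any(x < 0) || any(x != round(x)))
    stop("a 2x2 table needs four non-negative integer counts")
  if (sum(x) == 0) stop("degenerate table: all counts zero")
  x
}

#' Fisher's exact test with conditional-MLE odds ratio
#'
#' Two-sided p-value by the minimum-likelihood convention: the sum of
#' probabilities, under the central hypergeometric distribution conditioned
#' on the table margins, of all tables no more probable than the observed
#' one (with the customary `1 + 1e-7` relative slack against floating-point
#' ties). The odds-ratio estimate is the conditional MLE: the value of
#' `psi` solving `E_psi[X11] = a` under the noncentral hypergeometric
#' distribution, found by bracketed root-finding in `log(psi)` and polished
#' by Newton steps so that `|E - a| < 1e-8`. A zero cell puts the estimate
#' on the boundary (0 or `Inf`), reported with `boundary = TRUE`.
#'
#' @param a,b,c,d Counts of the 2x2 table (row 1 = a, b; row 2 = c, d), or a
#'   2x2 matrix as `a` with the rest missing.
#' @return Object of class `fisher_result`: `or_cmle`, `p_two_sided`,
#'   `boundary`, `table`.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- if (is.null(b)) as_table2x2(a) else as_table2x2(c(a, b, c, d))
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b          # row 1 total
  n2 <- cc + d        # row 2 total
  k <- a + cc         # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0)
    stop("degenerate margins: a zero row or column")
  lo <- max(0, k - n2); hi <- min(k, m)
  supp <- lo:hi
  logdc <- lchoose(m, supp) + lchoose(n2, k - supp)
  # central (psi = 1) probabilities for the p-value
  logp <- logdc - max(logdc)
  p_all <- exp(logp); p_all <- p_all / sum(p_all)
  p_obs <- p_all[supp == a]
  p <- min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))

  expectation <- function(lpsi) {
    w <- logdc + supp * lpsi
    w <- exp(w - max(w))
    sw <- sum(w)
    mu <- sum(supp * w) / sw
    v <- sum((supp - mu)^2 * w) / sw
    list(mu = mu, var = v)
  }
  boundary <- FALSE
  if (a == lo) {
    or <- 0; boundary <- TRUE
  } else if (a == hi) {
    or <- Inf; boundary <- TRUE
  } else {
    g <- function(l) expectation(l)$mu - a
    width <- 1
    while (g(-width) > 0 || g(width) < 0) {
      width <- width * 2
      if (width > 1e4) stop("CMLE bracket expansion failed")
    }
    lpsi <- stats::uniroot(g, c(-width, width), tol = 1e-10)$root
    for (i in 1:5) {                     # Newton polish on the score
      e <- expectation(lpsi)
      if (abs(e$mu - a) < 1e-10 || e$var == 0) break
      lpsi <- lpsi + (a - e$mu) / e$var
    }
    or <- exp(lpsi)
  }
  structure(list(or_cmle = or, p_two_sided = p, boundary = boundary,
                 table = matrix(x, 2, 2, byrow = TRUE)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (2x2)\n")
  cat("  conditional-MLE odds ratio:",
      if (x$boundary) paste0(x$or_cmle, " (boundary)")
      else sprintf("%.4f", x$or_cmle), "\n")
  cat("  two-sided p:", format_pvalue(x$p_two_sided), "\n")
  invisible(x)
}

# mirrors the reporting convention for vanishingly small p-values
format_pvalue <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4)
}

#' Two-sided exact binomial test
#'
#' Minimum-likelihood two-sided convention (outcomes whose point probability
#' does not exceed that of the observed count are summed), as implemented in
#' \code{stats::binom.test}.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param p0 Null success probability (default 0.5).
#' @return The two-sided p-value.
#' @export
binom_test_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(n >= 1, k >= 0, k <= n)
  stats::binom.test(k, n, p = p0)$p.value
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' U from midranks; exact enumeration when the combined sample size is at
#' most 20 and there are no ties, otherwise the tie-corrected normal
#' approximation with continuity correction.
#'
#' @param x,y Numeric vectors.
#' @return List with `U` and `p_two_sided`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_two_sided = wt$p.value)
}

#' Hypergeometric enrichment (upper tail) with Bonferroni helper
#'
#' @param k Observed overlap.
#' @param K Category size in the universe.
#' @param n Draw size.
#' @param N Universe size.
#' @param m Number of tests for the Bonferroni multiplier (default 1).
#' @return List with `p` = P(X >= k) and `p_bonferroni` = min(1, m * p).
#' @export
hypergeom_enrichment <- function(k, K, n, N, m = 1) {
  if (k > min(K, n) || K > N || n > N || any(c(k, K, n, N) < 0))
    stop("inconsistent hypergeometric counts")
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, p_bonferroni = min(1, m * p))
}
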