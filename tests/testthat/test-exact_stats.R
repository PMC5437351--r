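test_that("fisher_exact handles symmetric and boundary tables", {
  res <- fisher_exact(5, 5, 5, 5)
  expect_equal(res$or_cmle, 1, tolerance = 1e-8)
  expect_equal(res$p_two_sided, 1)

  # margins (3,3)/(3,3): 4 tables, extremes have probability 1/20 each
  res <- fisher_exact(3, 0, 0, 3)
  expect_equal(res$p_two_sided, 0.1, tolerance = 1e-12)
  expect_true(res$boundary)
  expect_equal(res$or_cmle, Inf)
  expect_equal(fisher_exact(0, 3, 3, 0)$or_cmle, 0)

  expect_error(fisher_exact(0, 0, 1, 1), "degenerate margins")
  expect_error(fisher_exact(-1, 1, 1, 1), "non-negative")
})

test_that("fisher_exact p matches brute-force enumeration exhaustively for small totals", {
  # every 2x2 table with total <= 20 and nondegenerate margins
  worst <- 0; n_checked <- 0
  for (tot in 2:20) {
    for (a in 0:tot) for (b in 0:(tot - a)) for (cc in 0:(tot - a - b)) {
      d <- tot - a - b - cc
      if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
        next
      gap <- abs(fisher_exact(a, b, cc, d)$p_two_sided -
                   oracle_fisher_p(a, b, cc, d))
      worst <- max(worst, gap)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 9000)
  expect_lt(worst, 1e-12)
})

test_that("fisher_exact p matches enumeration on sampled larger tables", {
  set.seed(8)
  checked <- 0
  while (checked < 300) {
    tot <- sample(21:200, 1)
    cuts <- sort(sample(0:tot, 3, replace = TRUE))
    a <- cuts[1]; b <- cuts[2] - cuts[1]
    cc <- cuts[3] - cuts[2]; d <- tot - cuts[3]
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
      next
    ours <- fisher_exact(a, b, cc, d)
    expect_equal(ours$p_two_sided, oracle_fisher_p(a, b, cc, d),
                 tolerance = 1e-12)
    # independent cross-check of the p-value path
    expect_equal(ours$p_two_sided,
                 fisher.test(matrix(c(a, cc, b, d), 2))$p.value,
                 tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("the conditional-MLE odds ratio solves the score equation", {
  score_gap <- function(a, b, cc, d, or) {
    m <- a + b; n2 <- cc + d; k <- a + cc
    supp <- max(0, k - n2):min(k, m)
    w <- lchoose(m, supp) + lchoose(n2, k - supp) + supp * log(or)
    w <- exp(w - max(w))
    abs(sum(supp * w) / sum(w) - a)
  }
  tables <- list(c(328, 80, 1, 11), c(638, 182, 1, 11),
                 c(3085, 36, 21, 24), c(38355, 62, 15, 35),
                 c(7, 2, 3, 9), c(120, 40, 33, 71))
  for (tb in tables) {
    or <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$or_cmle
    expect_lt(score_gap(tb[1], tb[2], tb[3], tb[4], or), 1e-8)
  }
  # transposing the table preserves the p-value
  for (tb in tables) {
    expect_equal(fisher_exact(tb[1], tb[2], tb[3], tb[4])$p_two_sided,
                 fisher_exact(tb[1], tb[3], tb[2], tb[4])$p_two_sided,
                 tolerance = 1e-12)
  }
  # log-space computation is finite on the largest flux table
  res <- fisher_exact(38355, 62, 15, 35)
  expect_true(is.finite(res$or_cmle))
  expect_true(res$p_two_sided > 0)
})

test_that("binomial p equals brute-force outcome enumeration for n <= 100", {
  for (n in 1:100) {
    for (k in unique(c(0, 1, n %/% 3, n %/% 2, n - 1, n))) {
      expect_equal(binom_test_two_sided(k, n, 0.5),
                   oracle_binom_p(k, n, 0.5), tolerance = 1e-9)
    }
  }
  # asymmetric null, spot checks
  for (kn in list(c(3, 20), c(10, 40), c(50, 90))) {
    expect_equal(binom_test_two_sided(kn[1], kn[2], 0.3),
                 oracle_binom_p(kn[1], kn[2], 0.3), tolerance = 1e-9)
  }
  expect_equal(binom_test_two_sided(5, 5, 0.5), 2/32, tolerance = 1e-12)
  expect_equal(binom_test_two_sided(10, 20, 0.5), 1)
})

test_that("Mann-Whitney U and p behave as specified", {
  x <- c(1, 2, 3, 4)
  expect_equal(mann_whitney(x, x)$U, length(x)^2 / 2)
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_two_sided, 1/3, tolerance = 1e-12)
  set.seed(3)
  big <- mann_whitney(rnorm(200), rnorm(200) + 2)
  expect_lt(big$p_two_sided, 1e-6)
})

test_that("hypergeometric enrichment upper tail and Bonferroni", {
  expect_equal(hypergeom_enrichment(0, 5, 5, 10)$p, 1)
  expect_equal(hypergeom_enrichment(5, 5, 5, 10)$p, 1 / choose(10, 5),
               tolerance = 1e-12)
  h <- hypergeom_enrichment(3, 10, 10, 100, m = 1)
  expect_equal(h$p, h$p_bonferroni)
  expect_equal(hypergeom_enrichment(3, 10, 10, 100, m = 20)$p_bonferroni,
               min(1, 20 * h$p))
  expect_error(hypergeom_enrichment(6, 5, 5, 10), "inconsistent")
})
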