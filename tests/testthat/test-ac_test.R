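test_that("conditional mass matches closed-form values at tiny counts", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_probability(1, 0, 1e6, 1e6), 0.25)
  # frozen exact-rational value for unequal libraries
  expect_equal(ac_probability(30, 5, 1e6, 2e6), 0.00232234120239564,
               tolerance = 1e-12)
})

test_that("conditional mass equals the negative-binomial form", {
  # p(y|x) is NB(size = x + 1, prob = n1/(n1+n2)) -- independent route
  for (r in c(0.5, 1, 3)) {
    n1 <- 1e6
    n2 <- r * 1e6
    x <- c(0, 1, 5, 40, 200)
    y <- c(3, 0, 17, 40, 500)
    expect_equal(ac_probability(y, x, n1, n2),
                 dnbinom(y, size = x + 1, prob = n1 / (n1 + n2)),
                 tolerance = 1e-12)
  }
})

test_that("input domain is enforced", {
  expect_error(ac_probability(-1, 0, 10, 10), "non-negative integers")
  expect_error(ac_probability(0.5, 0, 10, 10), "non-negative integers")
  expect_error(ac_probability(0, 0, 0, 10), "positive integers")
  expect_error(ac_pvalue(1.5, 0, 10, 10), "non-negative integers")
  expect_error(ac_pvalue(0, 0, 10, 0), "positive integers")
})

test_that("two-sided p-value matches hand and oracle values", {
  expect_equal(ac_pvalue(0, 0, 123, 123), 1.0)
  expect_equal(ac_pvalue(0, 1, 1e6, 1e6), 0.5) # F = 0.75, complement branch
  # frozen exact-rational value, 10+ significant digits
  expect_equal(ac_pvalue(5, 30, 1e6, 1e6), 1.2913485988974571e-05,
               tolerance = 1e-10)
})

test_that("p-values stay in (0, 1] under extreme imbalance and deep counts", {
  p <- ac_pvalue(c(0, 10000, 2000), c(5000, 0, 16000), 1e6, 1e6)
  expect_true(all(p > 0 & p <= 1))
  expect_true(p[1] >= .Machine$double.xmin)
  # x + y of order 1e6 neither overflows nor hangs
  expect_gt(ac_pvalue(500000, 500500, 1e6, 1e6), 0.5)
})

test_that("equal libraries give a symmetric test", {
  set.seed(42)
  x <- sample(0:200, 40, replace = TRUE)
  y <- sample(0:200, 40, replace = TRUE)
  expect_equal(ac_pvalue(x, y, 5e5, 5e5), ac_pvalue(y, x, 5e5, 5e5),
               tolerance = 1e-12)
})

test_that("cumulative tail mass is non-decreasing in y", {
  for (x in c(0, 3, 25)) {
    tm <- ac_pvalue(rep(x, 61), 0:60, 1e6, 3e6, details = TRUE)$tail_mass
    expect_true(all(diff(tm) >= -1e-12))
    expect_true(all(tm >= 0 & tm <= 1))
  }
})

test_that("mass function sums to one across library ratios", {
  for (ratio in c(0.1, 0.5, 1, 2, 10)) {
    n1 <- 1e6
    n2 <- ratio * 1e6
    for (x in c(0, 7, 50)) {
      ymax <- qnbinom(1e-14, size = x + 1, prob = n1 / (n1 + n2),
                      lower.tail = FALSE) + 50
      s <- sum(ac_probability(0:ymax, x, n1, n2))
      expect_lt(abs(s - 1), 1e-9)
    }
  }
})

test_that("BH q-values reproduce the hand-computed step-up", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 10)), rep(1, 10))
  # step-up with a running minimum, computed by hand:
  # sorted p = .001,.01,.02,.5 -> m p/j = .004,.02,.0267,.5 -> q = same
  expect_equal(bh_fdr(c(0.02, 0.001, 0.5, 0.01)),
               c(0.02 * 4 / 3, 0.004, 0.5, 0.02), tolerance = 1e-12)
})

test_that("BH q-values are permutation-equivariant and domain-checked", {
  set.seed(7)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(numeric(0)), "non-empty")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("run_ac_tests adjusts jointly and preserves gene order", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    x = c(0, 50, 10), y = c(30, 50, 9))
  res <- run_ac_tests(tab, 1e5, 1e5)
  expect_equal(res$gene_id, tab$gene_id)
  expect_equal(res$p_value, ac_pvalue(tab$x, tab$y, 1e5, 1e5))
  expect_equal(res$q_value, bh_fdr(res$p_value))
  # single gene: q equals p
  one <- run_ac_tests(tab[1, ], 1e5, 1e5)
  expect_equal(one$q_value, one$p_value)
  expect_error(run_ac_tests(rbind(tab, tab[1, ]), 1e5, 1e5), "duplicate")
})

test_that("an empty-difference table yields no significant calls", {
  set.seed(11)
  x <- rpois(100, lambda = 30)
  tab <- data.frame(gene_id = sprintf("g%03d", 1:100), x = x, y = x)
  res <- run_ac_tests(tab, 2e5, 2e5)
  # x = y with equal libraries sits at the centre of the null
  expect_true(all(res$p_value > 0.05))
  expect_true(all(res$q_value > 0.001))
})
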