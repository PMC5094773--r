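test_that("Katz relative risk: identities and the suture worked example", {
  expect_equal(relative_risk(a = 10, b = 10, c = 10, d = 10)$rr, 1)

  rr <- relative_risk(a = 23, b = 15, c = 51, d = 9)
  # frozen from the closed-form Katz computation at z = 1.959964
  expect_equal(rr$rr, 0.7120743, tolerance = 1e-6)
  expect_equal(rr$ci_low, 0.5393066, tolerance = 1e-6)
  expect_equal(rr$ci_high, 0.9401884, tolerance = 1e-6)
  expect_equal(round(c(rr$ci_low, rr$ci_high), 2), c(0.54, 0.94))

  # row swap inverts the estimate; column swap gives the complementary outcome
  swap <- relative_risk(a = 51, b = 9, c = 23, d = 15)
  expect_equal(swap$rr, 1 / rr$rr)
  comp <- relative_risk(a = 15, b = 23, c = 9, d = 51)
  expect_equal(comp$rr, (15 / 38) / (9 / 60))

  ci <- relative_risk(a = 0, b = 10, c = 5, d = 5)
  expect_true(is.na(ci$ci_low))
  corr <- relative_risk(a = 0, b = 10, c = 5, d = 5, correct = TRUE)
  expect_true(corr$corrected && !is.na(corr$ci_low))
})

test_that("Katz interval covers near-nominally on simulated binomial pairs", {
  # cell counts large enough for the log-normal approximation to be in its
  # valid regime (small cells over-cover, a property of the method itself)
  set.seed(61)
  n1 <- 150; n2 <- 120; p1 <- 0.35; p2 <- 0.25
  x1 <- rbinom(10000, n1, p1)
  x2 <- rbinom(10000, n2, p2)
  keep <- x1 > 0 & x2 > 0
  lo <- hi <- numeric(sum(keep))
  i <- 0
  for (k in which(keep)) {
    i <- i + 1
    r <- relative_risk(a = x1[k], b = n1 - x1[k], c = x2[k], d = n2 - x2[k])
    lo[i] <- r$ci_low; hi[i] <- r$ci_high
  }
  cover <- mean(lo <= (p1 / p2) & (p1 / p2) <= hi)
  expect_lt(abs(cover - 0.95), 0.01)
})

test_that("two-sided exact test agrees with full enumeration across random tables", {
  expect_equal(fisher_exact(a = 1, b = 0, c = 0, d = 1), 1)
  expect_equal(fisher_exact(a = 3, b = 0, c = 4, d = 0), 1)   # zero margin
  expect_equal(fisher_exact(a = 9, b = 51, c = 15, d = 23), 0.008204729,
               tolerance = 1e-6)
  expect_error(fisher_exact(two_by_two(6000, 3000, 2000, 1000)), "10,000")

  set.seed(73)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    p <- fisher_exact(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p, ref, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney: exact enumeration for small samples, tie-corrected normal otherwise", {
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  sep <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$u, 0)
  expect_equal(sep$u_x + sep$u_y, 9)
  expect_equal(sep$p_value, 0.1)   # 2 of the C(6,3)=20 assignments are as extreme

  # exact branch equals a direct permutation count on random data with ties
  set.seed(83)
  for (i in 1:10) {
    x <- sample(1:6, 6, replace = TRUE)
    y <- sample(1:6, 6, replace = TRUE)
    res <- mann_whitney(x, y)
    r <- rank(c(x, y))
    dev_obs <- abs(sum(r[1:6]) - 21 - 18)
    dev <- apply(utils::combn(12, 6), 2,
                 function(idx) abs(sum(r[idx]) - 21 - 18))
    expect_equal(res$p_value, mean(dev >= dev_obs - 1e-9))
  }

  # approximate branch matches the standard implementation
  set.seed(89)
  x <- round(rnorm(30, 0, 2), 1)
  y <- round(rnorm(25, 0.8, 2), 1)
  res <- mann_whitney(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(max(res$u_x, res$u_y) + res$u, 30 * 25)
})

test_that("Kruskal-Wallis: degenerate inputs and two-group consistency with U", {
  expect_error(kruskal_wallis(list(1:3)), "two non-empty")
  allsame <- kruskal_wallis(list(rep(2, 5), rep(2, 6)))
  expect_equal(allsame$h, 0, tolerance = 1e-12)

  set.seed(97)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  kw <- kruskal_wallis(list(x, y))
  mw <- mann_whitney(x, y)
  z <- stats::qnorm(mw$p_value / 2)
  expect_equal(kw$h, z^2, tolerance = 1e-8)  # H = z^2 for two groups

  g <- list(rnorm(70), rnorm(70, 1), rnorm(60, 2))
  expect_lt(kruskal_wallis(g)$p_value, 0.001)
})

test_that("rates are exact quotients with display rounding kept separate", {
  expect_equal(rate_percent(70, 725), 100 * 70 / 725)
  expect_identical(format_rate(rate_percent(70, 725)), "9.7%")
  expect_identical(format_rate(rate_percent(24, 98)), "24.5%")
  expect_identical(format_rate(rate_percent(98, 725)), "13.5%")
  expect_equal(rate_percent(0, 10), 0)
  expect_error(rate_percent(1, 0), "positive")
})

test_that("the cohort suture comparison assembles the published direction", {
  co <- small_default_cohort(43)
  sc <- suture_comparison(co)
  expect_equal(sum(sc$rates$n), sum(!is.na(co$suture)))
  # the reported RR is term birth, braided vs monofilament
  tab <- sc$table
  expect_equal(sc$rr_term_braided_vs_mono$rr,
               (tab[2, 2] / sum(tab[2, ])) / (tab[1, 2] / sum(tab[1, ])))
  expect_lte(sc$fisher_p, 1)
})
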