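test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(signif(bonferroni_threshold(0.05, 9), 3), 0.00556)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("group comparisons run the right test and threshold", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_groups(x, x, "mean")
  expect_equal(r$p_value, 1)
  expect_false(r$significant)
  expect_error(compare_groups(rep(1, 5), rep(1, 5), "mean"), "variance")
  # Welch vs pooled are both available
  set.seed(1)
  a <- rnorm(40, 0, 1); b <- rnorm(40, 0, 4)
  rw <- compare_groups(a, b, "mean")
  rp <- compare_groups(a, b, "mean", var_equal = TRUE)
  expect_false(isTRUE(all.equal(rw$p_value, rp$p_value)))
})

test_that("Pearson chi-square matches the closed form with no correction", {
  r <- compare_groups(c(215, 94), c(160, 169), "proportion")
  expect_equal(r$statistic, hand_chisq_2x2(215, 94, 160, 169),
               tolerance = 1e-9)
  set.seed(12)
  for (rep in 1:20) {
    tab <- matrix(sample(5:200, 4), 2)
    r <- compare_groups(tab[1, ], tab[2, ], "proportion")
    expect_equal(r$statistic,
                 hand_chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
  # logical-vector form agrees with the count form
  a <- rep(c(TRUE, FALSE), c(30, 10)); b <- rep(c(TRUE, FALSE), c(15, 25))
  expect_equal(compare_groups(a, b, "proportion")$statistic,
               compare_groups(c(30, 10), c(15, 25), "proportion")$statistic)
})

test_that("a 17-point PDC difference at study scale is reliably detected", {
  set.seed(14)
  thr <- bonferroni_threshold(0.05, 9)
  hits <- 0L
  for (rep in 1:50) {
    a <- pmin(pmax(rnorm(309, 79, 32), 0), 100)
    b <- pmin(pmax(rnorm(329, 62, 38), 0), 100)
    if (compare_groups(a, b, "mean")$p_value < thr) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("univariate screen recovers a planted odds ratio", {
  set.seed(21)
  n <- 5000
  x <- rnorm(n)
  y <- runif(n) < plogis(-0.5 + log(1.6) * x)
  d <- data.frame(nonadherent = y, x = x, noise = rnorm(n))
  sc <- univariate_screen(d, "nonadherent")
  xr <- sc[sc$variable == "x", ]
  expect_gte(xr$odds_ratio, 1.45)
  expect_lte(xr$odds_ratio, 1.75)
  expect_true(xr$candidate)
  expect_true(xr$ci_low <= xr$odds_ratio && xr$odds_ratio <= xr$ci_high)
  nr <- sc[sc$variable == "noise", ]
  expect_true(nr$ci_low <= 1 && nr$ci_high >= 1)
})

test_that("degenerate covariates are excluded with a warning", {
  set.seed(22)
  d <- data.frame(nonadherent = rep(c(TRUE, FALSE), 50),
                  const = 1,
                  sep = rep(c(1, 0), 50))   # perfect separation
  expect_warning(
    expect_warning(sc <- univariate_screen(d, "nonadherent"), "constant"),
    "separation")
  expect_equal(nrow(sc), 0L)
  expect_error(univariate_screen(data.frame(nonadherent = rep(TRUE, 10),
                                            x = rnorm(10)), "nonadherent"),
               "both classes")
})

test_that("complete cases are taken per variable", {
  set.seed(23)
  d <- data.frame(nonadherent = rep(c(TRUE, FALSE), 100),
                  x = rnorm(200), partial = c(rnorm(120), rep(NA, 80)))
  sc <- univariate_screen(d, "nonadherent")
  expect_equal(sc$n[sc$variable == "x"], 200L)
  expect_equal(sc$n[sc$variable == "partial"], 120L)
})

test_that("stepwise selection keeps real effects and drops noise", {
  set.seed(24)
  keep1 <- keep2 <- drop3 <- 0L
  for (rep in 1:20) {
    n <- 800
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    y <- runif(n) < plogis(-0.3 + log(2) * x1 + log(1.6) * x2)
    d <- data.frame(y = y, x1 = x1, x2 = x2, x3 = x3)
    sw <- stepwise_multivariate(d, "y", c("x1", "x2", "x3"))
    keep1 <- keep1 + ("x1" %in% sw$terms)
    keep2 <- keep2 + ("x2" %in% sw$terms)
    drop3 <- drop3 + (!"x3" %in% sw$terms)
  }
  expect_equal(keep1, 20L)
  expect_equal(keep2, 20L)
  expect_gte(drop3 / 20, 0.9)
})

test_that("stepwise edge cases behave", {
  set.seed(25)
  n <- 400
  x1 <- rnorm(n)
  y <- runif(n) < plogis(log(2.5) * x1)
  # a collinear duplicate never joins alongside the original
  d <- data.frame(y = y, x1 = x1, dup = x1)
  sw <- stepwise_multivariate(d, "y", c("x1", "dup"))
  expect_length(sw$terms, 1L)
  # single candidate below the entry threshold is retained
  sw1 <- stepwise_multivariate(d, "y", "x1")
  expect_identical(sw1$terms, "x1")
  expect_equal(nrow(sw1$coefficients), 1L)
  or <- sw1$coefficients$odds_ratio
  expect_true(sw1$coefficients$ci_low <= or && or <= sw1$coefficients$ci_high)
  # nothing informative: empty model, not an error
  d2 <- data.frame(y = rep(c(TRUE, FALSE), 200), z = rnorm(400))
  set.seed(26)
  d2$y <- sample(d2$y)
  sw2 <- stepwise_multivariate(d2, "y", "z")
  expect_length(sw2$terms, 0L)
  expect_equal(nrow(sw2$coefficients), 0L)
})
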