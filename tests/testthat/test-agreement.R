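test_that("the normality gate routes to the paired t-test or Wilcoxon", {
  withr::with_seed(101, {
    rater <- 30 + rnorm(60, sd = 5)
    gauss <- paired_measurements(rater, rater - rnorm(60, sd = 2), "cax_deg")
    skew <- paired_measurements(rater, rater - rexp(60, rate = 0.5), "cax_deg")
  })
  g <- paired_compare(gauss)
  expect_gt(g$normality_p, 0.05)
  expect_identical(g$test_used, "paired_t")

  s <- paired_compare(skew)
  expect_lte(s$normality_p, 0.05)
  expect_identical(s$test_used, "wilcoxon")
})

test_that("identical rater and model measurements are handled as degenerate", {
  x <- c(30.2, 28.1, 35.7, 31.0, 29.9)
  pm <- paired_measurements(x, x, "cax_deg")
  res <- paired_compare(pm)
  expect_equal(res$test_p, 1)
  expect_true(length(res$warnings) > 0)
  ba <- bland_altman(pm)
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$loa, c(0, 0))
})

test_that("Bland-Altman matches an independent from-scratch evaluation", {
  pm <- paired_measurements(c(1, 2, 3, 4), c(-1, 0, 1, 2) + 0)
  expect_equal(bland_altman(pm)$bias, 2)
  expect_equal(bland_altman(pm)$sd_diff, 0)

  withr::with_seed(202, {
    rater <- 32 + rnorm(100, sd = 8)
    model <- rater - (1.2 + rnorm(100, sd = 4))
  })
  pm <- paired_measurements(rater, model, "cax_deg")
  ba <- bland_altman(pm)

  d <- rater - model
  n <- length(d)
  bias <- sum(d) / n
  sdd <- sqrt(sum((d - bias)^2) / (n - 1))
  expect_equal(ba$bias, bias, tolerance = 1e-10)
  expect_equal(ba$sd_diff, sdd, tolerance = 1e-10)
  expect_equal(ba$loa, c(bias - 1.96 * sdd, bias + 1.96 * sdd), tolerance = 1e-10)
  expect_equal(ba$bias_ci,
               bias + c(-1, 1) * qt(0.975, n - 1) * sdd / sqrt(n),
               tolerance = 1e-10)
  expect_true(ba$bias_ci[1] <= ba$bias && ba$bias <= ba$bias_ci[2])
})

test_that("Bland-Altman bias is antisymmetric under swapping rater and model", {
  withr::with_seed(203, {
    a <- rnorm(50); b <- a + rnorm(50, sd = 0.3)
  })
  f <- bland_altman(paired_measurements(a, b))
  r <- bland_altman(paired_measurements(b, a))
  expect_equal(f$bias, -r$bias)
  expect_equal(f$loa, -rev(r$loa))
})

test_that("ICC(2,1) matches a two-way ANOVA mean-squares oracle", {
  # fixed 6x2 table; oracle mean squares from aov()
  Y <- rbind(c(9, 2), c(6, 1), c(8, 4), c(7, 1), c(10, 5), c(6, 2))
  pm <- paired_measurements(Y[, 1], Y[, 2])
  got <- icc(pm)

  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 6; k <- 2
  oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  expect_equal(got$icc, oracle, tolerance = 1e-10)
  expect_true(got$icc_ci[1] <= got$icc && got$icc <= got$icc_ci[2])
})

test_that("ICC is 1 on identical columns and near 0 on independent noise", {
  x <- c(3, 7, 4, 9, 5, 6, 8)
  expect_equal(icc(paired_measurements(x, x))$icc, 1)

  withr::with_seed(204, {
    big <- paired_measurements(rnorm(10000), rnorm(10000))
  })
  expect_lt(abs(icc(big)$icc), 0.05)
})

test_that("ICC is invariant to common shifts/scales and tracks the variance ratio", {
  withr::with_seed(205, {
    subj <- rnorm(2000, sd = 3)
    rater <- subj + rnorm(2000, sd = 1)
    model <- subj + rnorm(2000, sd = 1)
  })
  base <- icc(paired_measurements(rater, model))$icc
  expect_equal(icc(paired_measurements(rater + 10, model + 10))$icc, base, tolerance = 1e-12)
  expect_equal(icc(paired_measurements(rater * 2.5, model * 2.5))$icc, base, tolerance = 1e-12)
  # expected ICC = var_subject / (var_subject + sigma^2) = 9 / 10
  expect_equal(base, 0.9, tolerance = 0.05)
})

test_that("agreement_report composes its parts and penalizes constant offsets", {
  x <- c(30, 28, 36, 31, 29, 34, 27, 33)
  perfect <- agreement_report(paired_measurements(x, x, "ctr"))
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$loa, c(0, 0))

  shifted <- agreement_report(paired_measurements(x + 2, x, "cax_deg"))
  expect_equal(shifted$bias, 2)
  expect_lt(shifted$icc, 1)

  withr::with_seed(206, {
    pm <- paired_measurements(rnorm(40, 30, 5), rnorm(40, 30, 5), "cax_deg")
  })
  rep <- agreement_report(pm)
  expect_equal(rep$bias, bland_altman(pm)$bias)
  expect_equal(rep$icc, icc(pm)$icc)
  expect_equal(rep$test_p, paired_compare(pm)$test_p)
  expect_equal(rep$loa, rep$bias + c(-1.96, 1.96) * rep$sd_diff, tolerance = 1e-9)
})

test_that("the Bland-Altman plot file is written", {
  withr::with_seed(207, {
    pm <- paired_measurements(rnorm(30, 30, 5), rnorm(30, 31, 5), "cax_deg")
  })
  f <- withr::local_tempfile(fileext = ".svg")
  agreement_report(pm, plot_file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
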