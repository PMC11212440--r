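test_that("spearman_rho matches rank arithmetic, handles ties and degenerate input", {
  expect_equal(spearman_rho(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_rho(1:5, rev(1:5))$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)

  # invariant under strictly increasing transforms of either input
  set.seed(5)
  x <- rnorm(40)
  y <- x + rnorm(40)
  base <- spearman_rho(x, y)$rho
  expect_equal(spearman_rho(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_rho(x, y^3)$rho, base, tolerance = 1e-12)

  # agrees with the standard t-approximation implementation, ties included
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 5, 9, 9)
  ref <- suppressWarnings(cor.test(xt, yt, method = "spearman", exact = FALSE))
  got <- spearman_rho(xt, yt)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)

  expect_warning(out <- spearman_rho(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(out$rho))
  expect_error(spearman_rho(1:4, 1:5), "same length")
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
})

test_that("Fisher-Z comparison is antisymmetric and reproduces its normal approximation", {
  a <- fisher_z_compare(0.3, 50, 0.6, 80)
  b <- fisher_z_compare(0.6, 80, 0.3, 50)
  expect_identical(a$z, -b$z)
  expect_equal(fisher_z_compare(0.5, 30, 0.5, 300)$z, 0)
  expect_equal(fisher_z_compare(0.5, 30, 0.5, 300)$p_one_sided, 0.5)
  # closed form recomputed in place
  z <- (atanh(0.37) - atanh(0.5)) / sqrt(1 / 46 + 1 / 55)
  expect_equal(fisher_z_compare(0.37, 49, 0.5, 58)$z, z, tolerance = 1e-12)
  expect_error(fisher_z_compare(1, 20, 0.5, 20), "strictly inside")
  expect_error(fisher_z_compare(0.2, 3, 0.5, 20), "sample sizes")
})

test_that("Bland-Altman statistics follow the differences' mean and SD", {
  perfect <- bland_altman(c(100, 200, 300), c(100, 200, 300))
  expect_equal(perfect$mean_bias, 0)
  expect_equal(perfect$sd_diff, 0)
  expect_equal(c(perfect$loa_lower, perfect$loa_upper), c(0, 0))
  expect_true(is.na(perfect$bias_p))

  ba <- bland_altman(c(100, 200, 300), c(110, 190, 310))
  # differences (-10, 10, -10): mean -10/3, sd sqrt(400/3)
  expect_equal(ba$mean_bias, -10 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_lower, -10 / 3 - 1.96 * sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_upper, -10 / 3 + 1.96 * sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(ba$bias_p, t.test(c(-10, 10, -10))$p.value)

  # swapping the vectors negates bias and swaps/negates the limits
  rev_ba <- bland_altman(c(110, 190, 310), c(100, 200, 300))
  expect_equal(rev_ba$mean_bias, -ba$mean_bias)
  expect_equal(rev_ba$loa_lower, -ba$loa_upper)
  expect_equal(rev_ba$loa_upper, -ba$loa_lower)

  td <- tidy(ba)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("mean_bias", "sd_diff", "loa_lower", "loa_upper", "bias_p", "n"))
  expect_equal(glance(ba), td)
  expect_s3_class(autoplot(ba), "ggplot")
  expect_error(bland_altman(1:3, 1:4), "same length")
})

test_that("P30 counts estimates within 30 percent, boundary inclusive", {
  expect_equal(p30_precision(c(50, 80, 120), c(50, 80, 120)), 100)
  expect_equal(p30_precision(c(100, 100), c(129, 131)), 50)
  expect_equal(p30_precision(100, 130), 100)
  expect_equal(p30_precision(100, 70), 100)
  expect_equal(p30_precision(100, 69.9), 0)
  expect_error(p30_precision(c(100, 0), c(90, 10)), "positive")
})

test_that("classification metrics come from the strict-threshold confusion table", {
  perfect <- classification_metrics(c(1, 3, 5), c(1, 3, 5), threshold = 2)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 100, specificity = 100, ppv = 100, npv = 100))

  out <- classification_metrics(
    c(3, 5, 1, 2.5, 4.5, 1.5), c(4.2, 4.8, 2.5, 1.8, 5, 1.2), threshold = 2
  )
  expect_equal(unlist(out[c("tp", "fp", "tn", "fn")]),
               c(tp = 3, fp = 1, tn = 1, fn = 1))
  expect_equal(out$sensitivity, 75)
  expect_equal(out$specificity, 50)
  expect_equal(out$ppv, 75)
  expect_equal(out$npv, 50)

  # empty-positive stratum: sensitivity and PPV undefined, not zero
  none <- classification_metrics(c(0.5, 1), c(0.6, 1.2), threshold = 2)
  expect_true(is.na(none$sensitivity))
  expect_true(is.na(none$ppv))
  expect_equal(none$specificity, 100)
  expect_equal(none$npv, 100)
  expect_error(classification_metrics(1, 1, threshold = 0), "positive")
})
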