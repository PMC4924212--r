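test_that("noiseless exponential series is recovered exactly", {
  t <- 1:5
  e <- 2.0e-4 * exp(-0.1 * t)
  fit <- fit_zero_time_enrichment(t, e)
  expect_equal(fit$e_zero, 2.0e-4, tolerance = 1e-12)
  expect_equal(fit$k, 0.1, tolerance = 1e-12)

  flat <- fit_zero_time_enrichment(t, rep(1.0e-4, 5))
  expect_equal(flat$e_zero, 1.0e-4, tolerance = 1e-12)
  expect_equal(flat$k, 0, tolerance = 1e-12)
})

test_that("disappearance-curve fit rejects bad input", {
  expect_error(fit_zero_time_enrichment(1, 2e-4), "at least 2")
  expect_error(fit_zero_time_enrichment(c(1, 2), c(2e-4, -1e-4)), "positive")
  expect_error(fit_zero_time_enrichment(c(2, 1), c(2e-4, 1e-4)), "increasing")
})

test_that("noisy series recovers the true curve within sampling error", {
  set.seed(201)
  e0 <- 2.0e-4; k <- 0.1; t <- c(1, 3, 5, 8, 11, 14)
  est <- t(vapply(1:500, function(i) {
    e <- e0 * exp(-k * t) * exp(rnorm(length(t), 0, 0.01))
    fit <- fit_zero_time_enrichment(t, e)
    c(fit$e_zero, fit$k)
  }, numeric(2)))
  # unbiased on the log scale: mean recovery well within 3 SE of the MC mean
  expect_lt(abs(mean(est[, 1]) - e0), 3 * sd(est[, 1]) / sqrt(500))
  expect_lt(abs(mean(est[, 2]) - k), 3 * sd(est[, 2]) / sqrt(500))
})

test_that("dilution space follows the plateau principle", {
  expect_equal(dilution_space(2.2884e-4, 0.15), 11.8058, tolerance = 1e-3)
  expect_equal(dilution_space(0.5, 1), 0.018015, tolerance = 1e-12)
  # strictly decreasing in e_zero; doubling in the small-enrichment limit
  n1 <- dilution_space(2e-4, 0.15)
  n2 <- dilution_space(1e-4, 0.15)
  expect_gt(n2, n1)
  expect_equal(n2 / n1, 2, tolerance = 1e-3)
  expect_error(dilution_space(1.5, 0.1), "mole fraction")
  expect_error(dilution_space(2e-4, -1), "dose_mol")
})

test_that("two-space average and ratio flagging match hand arithmetic", {
  res <- tbw_from_spaces(12.36, 11.90)
  expect_equal(res$tbw, (12.36 / 1.041 + 11.90 / 1.007) / 2, tolerance = 1e-12)
  expect_equal(res$tbw, 11.845, tolerance = 1e-3)
  expect_equal(res$ratio, 12.36 / 11.90, tolerance = 1e-12)
  expect_false(res$ratio_flag)

  # the exchange-correction constants cancel at nd = 1.041, no = 1.007
  expect_equal(tbw_from_spaces(1.041, 1.007)$tbw, 1.0, tolerance = 1e-12)

  flagged <- tbw_from_spaces(12.80, 11.90)
  expect_true(flagged$ratio_flag)
  expect_error(tbw_from_spaces(-1, 2), "positive")
})

test_that("two-space average is linear under common scaling", {
  set.seed(31)
  nd <- runif(20, 8, 15)
  no <- nd / runif(20, 1.02, 1.06)
  for (c_scale in c(0.5, 2, 7.3)) {
    expect_equal(tbw_from_spaces(c_scale * nd, c_scale * no)$tbw,
                 c_scale * tbw_from_spaces(nd, no)$tbw, tolerance = 1e-12)
  }
})

test_that("noiseless washout round trip recovers TBW to 1e-9 relative error", {
  set.seed(41)
  truth_tbw <- runif(10, 8, 14)
  ratio <- rnorm(10, 1.039, 0.008)
  no_true <- 2 * truth_tbw / (ratio / 1.041 + 1 / 1.007)
  nd_true <- ratio * no_true
  rows <- list()
  for (i in 1:10) {
    s2 <- simulate_enrichment_series(nd_true[i], dose_mol = 0.15, k = 0.10)
    s18 <- simulate_enrichment_series(no_true[i], dose_mol = 0.35, k = 0.13)
    rows[[i]] <- rbind(
      data.frame(subject_id = sprintf("S%02d", i), isotope = "2H",
                 time_days = s2$time_days, excess_mole_fraction = s2$excess,
                 dose_mol = 0.15),
      data.frame(subject_id = sprintf("S%02d", i), isotope = "18O",
                 time_days = s18$time_days, excess_mole_fraction = s18$excess,
                 dose_mol = 0.35)
    )
  }
  res <- tbw_from_enrichments(do.call(rbind, rows))
  res <- res[order(res$subject_id), ]
  expect_equal(res$tbw_kg / truth_tbw, rep(1, 10), tolerance = 1e-9)
  expect_equal(res$nd_kg / nd_true, rep(1, 10), tolerance = 1e-9)
  expect_equal(res$k_2h, rep(0.10, 10), tolerance = 1e-9)
  expect_equal(res$k_18o, rep(0.13, 10), tolerance = 1e-9)
})

test_that("long-format ingestion validates schema and sample counts", {
  bad <- data.frame(subject_id = "S1", isotope = "2H", time_days = 1,
                    excess_mole_fraction = 2e-4)
  expect_error(tbw_from_enrichments(bad), "dose_mol")
  one_pt <- data.frame(subject_id = "S1",
                       isotope = c("2H", "18O", "18O"),
                       time_days = c(1, 1, 5),
                       excess_mole_fraction = c(2e-4, 2e-4, 1.5e-4),
                       dose_mol = 0.15)
  expect_error(tbw_from_enrichments(one_pt), ">= 2")
  unknown <- transform(one_pt, isotope = "3H")
  expect_error(tbw_from_enrichments(unknown), "isotope")
})
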