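test_that("Bland-Altman block matches hand arithmetic on a 3-pair sample", {
  ba <- bland_altman(c(19, 20, 21), c(25, 24, 26))
  expect_equal(ba$mean_diff, -5, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 1, tolerance = 1e-12)
  expect_equal(ba$loa_lower, -7, tolerance = 1e-12)
  expect_equal(ba$loa_upper, -3, tolerance = 1e-12)
  expect_equal(ba$loa_half_width, 2 * ba$sd_diff, tolerance = 1e-15)
})

test_that("degenerate paired samples are reported as such, not forced", {
  x <- c(19, 20, 21)
  same <- bland_altman(x, x)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_lower, same$loa_upper), c(0, 0))

  shifted <- bland_altman(x + 2, x)
  expect_equal(shifted$mean_diff, 2)
  expect_equal(shifted$sd_diff, 0)
  expect_equal(shifted$trend_slope, 0)

  tt <- paired_t_test(x, x)
  expect_true(tt$degenerate)
  expect_true(is.na(tt$t) && is.na(tt$p))

  expect_true(is.na(pearson_cor(c(1, 2, 3, 4), rep(5, 4))$r))
  expect_error(bland_altman(c(1, 2), c(1, 2)), "insufficient")
})

test_that("paired t, Pearson and calibration match frozen hand values", {
  tt <- paired_t_test(c(19, 20, 21), c(25, 24, 26))
  expect_equal(tt$t, -5 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(tt$p, 0.013072, tolerance = 1e-4)

  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(2 * c(1, 5, 9) + 1, c(1, 5, 9))$r, 1,
               tolerance = 1e-12)
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 1, 3))$r, 0.5, tolerance = 1e-12)

  exact <- calibration_regression(c(1, 2, 4), 3 * c(1, 2, 4))
  expect_equal(exact$slope, 3, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  expect_equal(exact$see, 0, tolerance = 1e-10)

  cr <- calibration_regression(c(1, 2, 3), c(2, 1, 3))
  expect_equal(cr$slope, 0.5, tolerance = 1e-12)
  expect_equal(cr$intercept, 1.0, tolerance = 1e-12)
})

test_that("all agreement statistics agree with the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    test <- rnorm(n, 20, 4)
    ref <- 3 + 1.1 * test + rnorm(n, 0, 3)
    got <- agreement_summary(test, ref)
    want <- oracle_agreement(test, ref)
    for (field in names(want)) {
      expect_equal(got[[field]], want[[field]], tolerance = 1e-10,
                   info = sprintf("field %s, replicate %d", field, i))
    }
  }
})

test_that("swapping methods negates differences and preserves spread", {
  set.seed(103)
  for (i in 1:20) {
    test <- rnorm(15, 20, 4)
    ref <- 3 + 1.1 * test + rnorm(15, 0, 3)
    fwd <- agreement_summary(test, ref)
    rev <- agreement_summary(ref, test)
    expect_equal(rev$mean_diff, -fwd$mean_diff, tolerance = 1e-12)
    expect_equal(rev$loa_lower, -fwd$loa_upper, tolerance = 1e-12)
    expect_equal(rev$loa_upper, -fwd$loa_lower, tolerance = 1e-12)
    expect_equal(rev$sd_diff, fwd$sd_diff, tolerance = 1e-12)
    expect_equal(rev$pearson_r, fwd$pearson_r, tolerance = 1e-12)
  }
})

test_that("difference statistics are scale-equivariant, correlation invariant", {
  set.seed(107)
  test <- rnorm(25, 20, 4)
  ref <- 3 + 1.1 * test + rnorm(25, 0, 3)
  base <- agreement_summary(test, ref)
  for (c_scale in c(0.25, 3, 11.5)) {
    sc <- agreement_summary(c_scale * test, c_scale * ref)
    expect_equal(sc$mean_diff, c_scale * base$mean_diff, tolerance = 1e-10)
    expect_equal(sc$sd_diff, c_scale * base$sd_diff, tolerance = 1e-10)
    expect_equal(sc$loa_upper, c_scale * base$loa_upper, tolerance = 1e-10)
    expect_equal(sc$pearson_r, base$pearson_r, tolerance = 1e-12)
  }
})

test_that("FM and FFM agreement are mirror images on any cohort", {
  co <- small_cohort(n = 80, seed = 19)
  long <- compose_cohort(co$subjects)
  bia <- long[long$method == "BIA", ]
  c3 <- long[long$method == "3C", ]
  fm <- agreement_summary(bia$fm_kg, c3$fm_kg)
  ffm <- agreement_summary(bia$ffm_kg, c3$ffm_kg)
  # fm + ffm = weight under both methods forces exact antisymmetry
  expect_equal(ffm$mean_diff, -fm$mean_diff, tolerance = 1e-9)
  expect_equal(ffm$sd_diff, fm$sd_diff, tolerance = 1e-9)
  expect_equal(ffm$loa_lower, -fm$loa_upper, tolerance = 1e-9)
})
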