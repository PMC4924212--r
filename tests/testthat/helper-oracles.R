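# Brute-force reference implementations used as independent oracles: every
# statistic is evaluated directly from its textbook formula, without lm(),
# t.test() or cor.test().

oracle_agreement <- function(test, ref) {
  n <- length(test)
  d <- test - ref
  a <- (test + ref) / 2
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))

  r_of <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  p_from_r <- function(r, df) 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)

  r <- r_of(test, ref)
  t_paired <- md / (sdd / sqrt(n))

  slope_tr <- sum((a - mean(a)) * (d - mean(d))) / sum((a - mean(a))^2)
  r_tr <- r_of(a, d)

  slope_cal <- sum((test - mean(test)) * (ref - mean(ref))) /
    sum((test - mean(test))^2)
  int_cal <- mean(ref) - slope_cal * mean(test)
  res <- ref - (int_cal + slope_cal * test)

  list(
    mean_diff = md, sd_diff = sdd,
    loa_lower = md - 2 * sdd, loa_upper = md + 2 * sdd,
    trend_intercept = mean(d) - slope_tr * mean(a),
    trend_slope = slope_tr,
    trend_r = r_tr, trend_p = p_from_r(r_tr, n - 2),
    paired_t = t_paired, paired_p = 2 * stats::pt(-abs(t_paired), n - 1),
    pearson_r = r, pearson_p = p_from_r(r, n - 2),
    reg_intercept = int_cal, reg_slope = slope_cal,
    reg_r2 = 1 - sum(res^2) / sum((ref - mean(ref))^2),
    reg_see = sqrt(sum(res^2) / (n - 2))
  )
}

# small cohort used by several files
small_cohort <- function(n = 40, seed = 11) {
  generate_cohort(cohort_config(n = n, seed = seed))
}
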