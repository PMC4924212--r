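#' Bland-Altman agreement statistics for a paired sample
#'
#' Computes the difference block of a method-comparison analysis: per-subject
#' differences (test minus reference) against per-subject averages, the mean
#' difference, the SD of the differences (n - 1 denominator), limits of
#' agreement at exactly +/- 2 SD, and the trend regression of the differences
#' on the averages (a non-zero slope indicates proportional bias). The trend's
#' correlation p-value uses the t distribution with n - 2 df.
#'
#' Limits of agreement are mean +/- 2 x SD (not 1.96 x SD), the convention of
#' the validation literature this package mirrors.
#'
#' @param test,ref Numeric vectors of paired measurements (test method and
#'   criterion method), length >= 3, finite.
#' @return A list: `n`, `mean_test`, `mean_ref`, `mean_diff`, `sd_diff`,
#'   `loa_half_width`, `loa_lower`, `loa_upper`, `trend_intercept`,
#'   `trend_slope`, `trend_r`, `trend_p`. When the averages have zero
#'   variance the trend entries are `NA` (undefined).
#' @export
#' @examples
#' bland_altman(c(19, 20, 21), c(25, 24, 26))
bland_altman <- function(test, ref) {
  check_paired(test, ref, min_n = 3)
  n <- length(test)
  diffs <- test - ref
  avgs <- (test + ref) / 2
  mean_diff <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  out <- list(
    n = n,
    mean_test = mean(test), mean_ref = mean(ref),
    mean_diff = mean_diff, sd_diff = sd_diff,
    loa_half_width = 2 * sd_diff,
    loa_lower = mean_diff - 2 * sd_diff,
    loa_upper = mean_diff + 2 * sd_diff
  )
  if (stats::var(avgs) > 0 && stats::var(diffs) > 0) {
    fit <- stats::lm(diffs ~ avgs)
    ct <- stats::cor.test(avgs, diffs)
    out$trend_intercept <- unname(stats::coef(fit)[1])
    out$trend_slope <- unname(stats::coef(fit)[2])
    out$trend_r <- unname(ct$estimate)
    out$trend_p <- ct$p.value
  } else if (stats::var(avgs) > 0 && stats::var(diffs) == 0) {
    # constant offset: flat trend, correlation undefined
    out$trend_intercept <- mean_diff
    out$trend_slope <- 0
    out$trend_r <- NA_real_
    out$trend_p <- NA_real_
  } else {
    out$trend_intercept <- NA_real_
    out$trend_slope <- NA_real_
    out$trend_r <- NA_real_
    out$trend_p <- NA_real_
  }
  out
}

#' Paired t-test for the mean difference between two methods
#'
#' Two-sided paired Student t-test of test minus reference. When the
#' differences are constant (zero SD) the statistic is undefined and both
#' values are returned as `NA` rather than forcing a p-value.
#'
#' @inheritParams bland_altman
#' @return A list with `t` and `p` (Student t, n - 1 df).
#' @export
paired_t_test <- function(test, ref) {
  check_paired(test, ref, min_n = 2)
  diffs <- test - ref
  if (stats::sd(diffs) == 0) {
    return(list(t = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(test, ref, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Pearson correlation between two methods
#'
#' Product-moment correlation with a two-sided p-value from
#' t = r sqrt((n - 2)/(1 - r^2)). Zero variance in either series makes the
#' correlation undefined (`NA`).
#'
#' @inheritParams bland_altman
#' @return A list with `r` and `p`.
#' @export
pearson_cor <- function(test, ref) {
  check_paired(test, ref, min_n = 3)
  if (stats::var(test) == 0 || stats::var(ref) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(test, ref)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Calibration regression of the criterion on the test method
#'
#' Ordinary least squares of the reference (criterion) values on the test
#' values: `ref = intercept + slope x test`. This direction answers "what
#' criterion value does a given field reading imply", so the fitted line can
#' recalibrate field readings. The standard error of the estimate is
#' SEE = sqrt(SS_res / (n - 2)).
#'
#' @inheritParams bland_altman
#' @return A list: `intercept`, `slope`, `r2`, `see`.
#' @export
calibration_regression <- function(test, ref) {
  check_paired(test, ref, min_n = 3)
  if (stats::var(test) == 0) {
    return(list(intercept = NA_real_, slope = NA_real_,
                r2 = NA_real_, see = NA_real_))
  }
  fit <- stats::lm(ref ~ test)
  n <- length(test)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ref - mean(ref))^2)
  list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    see = sqrt(ss_res / (n - 2))
  )
}

#' Full agreement summary for one paired variable
#'
#' Runs the complete method-comparison battery for one variable measured by
#' two methods on the same subjects: Bland-Altman difference block with
#' trend, paired t-test, Pearson correlation, and the calibration regression
#' of the criterion on the test method.
#'
#' @inheritParams bland_altman
#' @param variable Label for the compared variable (e.g. `"bf_pct"`).
#' @param units Units label for reporting.
#' @return An object of class `agreement_summary`: a named list holding every
#'   statistic, printable as a compact report block.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(40, 19.4, 3.9)
#' y <- 2.974 + 1.142 * x + rnorm(40, 0, 3.29)
#' agreement_summary(x, y, variable = "bf_pct", units = "%")
agreement_summary <- function(test, ref, variable = "", units = "") {
  ba <- bland_altman(test, ref)
  tt <- paired_t_test(test, ref)
  pc <- pearson_cor(test, ref)
  cr <- calibration_regression(test, ref)
  out <- c(
    list(variable = variable, units = units),
    ba,
    list(paired_t = tt$t, paired_p = tt$p,
         pearson_r = pc$r, pearson_p = pc$p,
         reg_intercept = cr$intercept, reg_slope = cr$slope,
         reg_r2 = cr$r2, reg_see = cr$see)
  )
  class(out) <- "agreement_summary"
  out
}

#' @export
print.agreement_summary <- function(x, digits = 3, ...) {
  f <- function(v) ifelse(is.na(v), "NA",
                          trimws(formatC(v, digits = digits, format = "g")))
  cat(sprintf("Agreement summary%s (n = %d)\n",
              if (nzchar(x$variable)) paste0(": ", x$variable) else "", x$n))
  cat(sprintf("  means        : test %s, ref %s %s\n",
              f(x$mean_test), f(x$mean_ref), x$units))
  cat(sprintf("  mean diff    : %s (SD %s); limits of agreement [%s, %s]\n",
              f(x$mean_diff), f(x$sd_diff), f(x$loa_lower), f(x$loa_upper)))
  cat(sprintf("  trend        : slope %s (r = %s, p = %s)\n",
              f(x$trend_slope), f(x$trend_r), f(x$trend_p)))
  cat(sprintf("  paired t     : t = %s, p = %s\n", f(x$paired_t), f(x$paired_p)))
  cat(sprintf("  Pearson      : r = %s, p = %s\n", f(x$pearson_r), f(x$pearson_p)))
  cat(sprintf("  calibration  : ref = %s + %s x test (R2 = %s, SEE = %s)\n",
              f(x$reg_intercept), f(x$reg_slope), f(x$reg_r2), f(x$reg_see)))
  invisible(x)
}

#' @export
as.data.frame.agreement_summary <- function(x, ...) {
  as.data.frame(x[!vapply(x, is.null, logical(1))], stringsAsFactors = FALSE)
}

check_paired <- function(test, ref, min_n) {
  if (length(test) != length(ref)) {
    stop("test and ref must have equal length", call. = FALSE)
  }
  if (length(test) < min_n) {
    stop("insufficient data: at least ", min_n, " pairs required", call. = FALSE)
  }
  if (any(!is.finite(test)) || any(!is.finite(ref))) {
    stop("paired values must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
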