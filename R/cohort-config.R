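#' Configuration for the synthetic paired-method cohort generator
#'
#' Bundles and validates the parameters of the synthetic cohort model: the
#' marginal distribution of the field-method (BIA) body-fat percentage, the
#' linear calibration bias linking it to the criterion three-component (3C)
#' body-fat percentage, anthropometry, and the physiological quantities used
#' to manufacture self-consistent raw inputs (hydration of fat-free mass and
#' the deuterium/oxygen-18 dilution-space ratio).
#'
#' The defaults are calibrated to a published validation cohort of 40 healthy
#' 5.5-year-old children: BIA BF% 19.4 +/- 3.9, weight 20.5 +/- 4.2 kg, height
#' 114.0 +/- 4.0 cm, a criterion-on-field calibration line
#' `3C = 2.974 + 1.142 x BIA` with residual SD 3.29 BF%, and a dilution-space
#' ratio of 1.039 +/- 0.008. Under this linear bias model the implied 3C BF%
#' distribution has mean 2.974 + 1.142 x 19.4 = 25.13 and SD
#' sqrt(1.142^2 x 3.9^2 + 3.29^2) = 5.54, matching the cohort's printed
#' 25.1 +/- 5.5.
#'
#' @param n Number of subjects (>= 2).
#' @param bia_bf_mean,bia_bf_sd Mean and SD of BIA body-fat percentage.
#' @param bias_intercept,bias_slope Calibration line mapping BIA BF% to the
#'   criterion 3C BF% (intercept in BF% units, slope dimensionless).
#' @param bias_noise_sd Residual SD around the calibration line (BF% units).
#' @param weight_mean,weight_sd Body weight distribution, kg.
#' @param height_mean,height_sd Height distribution, cm.
#' @param wh_correlation Correlation between weight and height (children's
#'   weight and height track closely; default 0.7).
#' @param hydration_mean,hydration_sd Hydration fraction of fat-free mass.
#'   Used only to manufacture self-consistent total body water and body
#'   volume; the 3C model itself assumes no hydration constant.
#' @param nd_no_ratio_mean,nd_no_ratio_sd Deuterium/oxygen-18 dilution-space
#'   ratio N_D/N_O.
#' @param seed Integer seed for the single RNG stream.
#'
#' @return An object of class `cohort_config` (a validated named list).
#' @seealso [generate_cohort()]
#' @export
#' @examples
#' cfg <- cohort_config(n = 40, seed = 7)
#' cfg$bia_bf_mean
cohort_config <- function(n = 40,
                          bia_bf_mean = 19.4, bia_bf_sd = 3.9,
                          bias_intercept = 2.974, bias_slope = 1.142,
                          bias_noise_sd = 3.29,
                          weight_mean = 20.5, weight_sd = 4.2,
                          height_mean = 114.0, height_sd = 4.0,
                          wh_correlation = 0.7,
                          hydration_mean = 0.765, hydration_sd = 0.01,
                          nd_no_ratio_mean = 1.039, nd_no_ratio_sd = 0.008,
                          seed = 1L) {
  cfg <- list(
    n = n,
    bia_bf_mean = bia_bf_mean, bia_bf_sd = bia_bf_sd,
    bias_intercept = bias_intercept, bias_slope = bias_slope,
    bias_noise_sd = bias_noise_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    height_mean = height_mean, height_sd = height_sd,
    wh_correlation = wh_correlation,
    hydration_mean = hydration_mean, hydration_sd = hydration_sd,
    nd_no_ratio_mean = nd_no_ratio_mean, nd_no_ratio_sd = nd_no_ratio_sd,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  scalar_num <- vapply(cfg, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))
  if (!all(scalar_num)) {
    stop("cohort_config: all fields must be finite numeric scalars; offending: ",
         paste(names(cfg)[!scalar_num], collapse = ", "), call. = FALSE)
  }
  if (cfg$n < 2 || cfg$n != round(cfg$n)) {
    stop("cohort_config: `n` must be an integer >= 2", call. = FALSE)
  }
  sds <- c("bia_bf_sd", "bias_noise_sd", "weight_sd", "height_sd",
           "hydration_sd", "nd_no_ratio_sd")
  bad_sd <- sds[vapply(sds, function(s) cfg[[s]] < 0, logical(1))]
  if (length(bad_sd)) {
    stop("cohort_config: standard deviations must be >= 0; offending: ",
         paste(bad_sd, collapse = ", "), call. = FALSE)
  }
  if (cfg$hydration_mean <= 0 || cfg$hydration_mean >= 1) {
    stop("cohort_config: `hydration_mean` must lie in (0, 1)", call. = FALSE)
  }
  if (abs(cfg$wh_correlation) >= 1) {
    stop("cohort_config: `wh_correlation` must lie in (-1, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  BIA BF%%      : %.1f +/- %.1f\n", x$bia_bf_mean, x$bia_bf_sd))
  cat(sprintf("  bias model   : 3C = %.3f + %.3f x BIA, residual SD %.2f\n",
              x$bias_intercept, x$bias_slope, x$bias_noise_sd))
  cat(sprintf("  weight (kg)  : %.1f +/- %.1f;  height (cm): %.1f +/- %.1f (r = %.2f)\n",
              x$weight_mean, x$weight_sd, x$height_mean, x$height_sd,
              x$wh_correlation))
  cat(sprintf("  FFM hydration: %.3f +/- %.3f;  N_D/N_O: %.3f +/- %.3f\n",
              x$hydration_mean, x$hydration_sd,
              x$nd_no_ratio_mean, x$nd_no_ratio_sd))
  invisible(x)
}
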