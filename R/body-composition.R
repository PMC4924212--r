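#' Fat mass from the three-component model
#'
#' Evaluates the three-component (3C) equation for fat mass from body volume,
#' total body water and body weight:
#' FM (kg) = 2.220 x BV - 0.764 x TBW - 1.465 x BW.
#' The 3C model partitions the body into fat, water and dry fat-free mass,
#' removing the constant-hydration assumption of two-component models.
#'
#' Physiologically inconsistent inputs can yield negative fat mass; the value
#' is returned as computed (flagging happens in [composition_3c()]), never
#' clamped.
#'
#' @param bv Body volume, L (thoracic-gas-corrected, e.g. from air
#'   displacement plethysmography).
#' @param tbw Total body water, kg.
#' @param bw Body weight, kg.
#' @return Fat mass in kg; vectorised.
#' @export
#' @examples
#' fm_3c(bv = 19.5, tbw = 11.8, bw = 20.0) # 4.9748
fm_3c <- function(bv, tbw, bw) {
  if (any(!is.finite(bv)) || any(!is.finite(tbw)) || any(!is.finite(bw)) ||
      any(bv <= 0) || any(tbw <= 0) || any(bw <= 0)) {
    stop("bv, tbw and bw must all be positive and finite", call. = FALSE)
  }
  2.220 * bv - 0.764 * tbw - 1.465 * bw
}

#' Full composition result from a body-fat percentage
#'
#' Expands a body-fat percentage into fat mass, fat-free mass and the
#' height-normalised indices: FM = BF%/100 x weight, FFM = weight - FM,
#' BMI = weight/height^2, FMI = FM/height^2, FFMI = FFM/height^2 (heights
#' converted from cm to m internally). This is how a BIA device's BF% output
#' is turned into masses, and how the 3C model's fat mass is re-expressed.
#'
#' @param bf_pct Body-fat percentage in \[0, 100).
#' @param bw Body weight, kg.
#' @param height_cm Height, cm.
#' @param method Label recorded in the output (`"BIA"` or `"3C"`).
#' @return A tibble with columns `method`, `fm_kg`, `ffm_kg`, `bf_pct`,
#'   `fmi`, `ffmi`, `bmi`; vectorised over subjects.
#' @export
#' @examples
#' composition_from_bf(19.4, bw = 20.5, height_cm = 114.0)
composition_from_bf <- function(bf_pct, bw, height_cm, method = "BIA") {
  if (any(!is.finite(bf_pct)) || any(bf_pct < 0) || any(bf_pct >= 100)) {
    stop("bf_pct must lie in [0, 100)", call. = FALSE)
  }
  if (any(!is.finite(bw)) || any(bw <= 0) ||
      any(!is.finite(height_cm)) || any(height_cm <= 0)) {
    stop("bw and height_cm must be positive and finite", call. = FALSE)
  }
  h2 <- (height_cm / 100)^2
  fm <- bf_pct / 100 * bw
  ffm <- bw - fm
  tibble::tibble(
    method = method,
    fm_kg = fm, ffm_kg = ffm, bf_pct = bf_pct,
    fmi = fm / h2, ffmi = ffm / h2, bmi = bw / h2
  )
}

#' Criterion composition from raw three-component inputs
#'
#' Chains the isotope-dilution and 3C steps for one or more subjects: total
#' body water from the dilution spaces (unless supplied directly), fat mass
#' from the 3C equation, then fat-free mass, BF% and indices. Negative fat
#' mass or BF% > 60 raises a quality flag on the affected rows; values are
#' never clamped.
#'
#' @param bv Body volume, L.
#' @param bw Body weight, kg.
#' @param height_cm Height, cm.
#' @param nd,no Dilution spaces, kg (both required unless `tbw` is given).
#' @param tbw Total body water, kg; overrides `nd`/`no` when supplied.
#' @return A tibble as in [composition_from_bf()] with `method = "3C"` plus a
#'   logical `flag` column.
#' @export
#' @examples
#' composition_3c(bv = 19.5, bw = 20.0, height_cm = 114.0,
#'                nd = 12.36, no = 11.90)
composition_3c <- function(bv, bw, height_cm, nd = NULL, no = NULL, tbw = NULL) {
  if (missing(bv) || is.null(bv)) {
    stop("missing field: bv (body volume) is required for the 3C model",
         call. = FALSE)
  }
  if (is.null(tbw)) {
    if (is.null(nd) || is.null(no)) {
      stop("missing field: supply either tbw or both dilution spaces nd and no",
           call. = FALSE)
    }
    tbw <- tbw_from_spaces(nd, no)$tbw
  }
  fm <- fm_3c(bv, tbw, bw)
  bf <- 100 * fm / bw
  h2 <- (height_cm / 100)^2
  tibble::tibble(
    method = "3C",
    fm_kg = fm, ffm_kg = bw - fm, bf_pct = bf,
    fmi = fm / h2, ffmi = (bw - fm) / h2, bmi = bw / h2,
    flag = fm < 0 | bf > 60
  )
}

#' Per-subject composition under both methods for a cohort table
#'
#' Applies the BIA expansion and the 3C chain to every subject in a cohort
#' table and stacks the results in long format, one row per subject and
#' method.
#'
#' @param subjects A data frame with columns `id`, `weight_kg`, `height_cm`,
#'   `bia_bf_pct`, `bv_l`, and either `nd_kg`/`no_kg` or `tbw_kg`.
#' @param exclude_flagged Drop subjects whose 3C result is quality-flagged
#'   (negative FM or BF% > 60) from both methods' rows. Default `FALSE`:
#'   every subject is analysed.
#' @return A long tibble: `id`, `method`, `fm_kg`, `ffm_kg`, `bf_pct`,
#'   `fmi`, `ffmi`, `bmi`, `flag`.
#' @export
compose_cohort <- function(subjects, exclude_flagged = FALSE) {
  required <- c("id", "weight_kg", "height_cm", "bia_bf_pct", "bv_l")
  missing_cols <- setdiff(required, names(subjects))
  if (!("tbw_kg" %in% names(subjects)) &&
      !all(c("nd_kg", "no_kg") %in% names(subjects))) {
    missing_cols <- c(missing_cols, "nd_kg/no_kg (or tbw_kg)")
  }
  if (length(missing_cols)) {
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bia <- composition_from_bf(subjects$bia_bf_pct, subjects$weight_kg,
                             subjects$height_cm, method = "BIA")
  bia$flag <- FALSE
  if ("tbw_kg" %in% names(subjects)) {
    c3 <- composition_3c(subjects$bv_l, subjects$weight_kg,
                         subjects$height_cm, tbw = subjects$tbw_kg)
  } else {
    c3 <- composition_3c(subjects$bv_l, subjects$weight_kg,
                         subjects$height_cm,
                         nd = subjects$nd_kg, no = subjects$no_kg)
  }
  bia <- dplyr::bind_cols(tibble::tibble(id = subjects$id), bia)
  c3 <- dplyr::bind_cols(tibble::tibble(id = subjects$id), c3)
  if (exclude_flagged) {
    drop_ids <- c3$id[c3$flag]
    bia <- bia[!(bia$id %in% drop_ids), ]
    c3 <- c3[!(c3$id %in% drop_ids), ]
  }
  dplyr::bind_rows(bia, c3)
}
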