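#' Read and validate a cohort CSV
#'
#' Reads a per-subject cohort table and checks the schema needed by the
#' downstream stages, reporting every missing column and any rows with
#' non-positive weight or height by row number.
#'
#' @param path Path to a cohort CSV (columns `id`, `sex`, `age_y`,
#'   `weight_kg`, `height_cm`, `bia_bf_pct`, `bv_l`, and `nd_kg`/`no_kg` or
#'   `tbw_kg`).
#' @return A tibble of subjects.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  subjects <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("id", "weight_kg", "height_cm", "bia_bf_pct", "bv_l")
  missing_cols <- setdiff(required, names(subjects))
  if (!("tbw_kg" %in% names(subjects)) &&
      !all(c("nd_kg", "no_kg") %in% names(subjects))) {
    missing_cols <- c(missing_cols, "nd_kg/no_kg (or tbw_kg)")
  }
  if (length(missing_cols)) {
    stop("cohort file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(subjects$weight_kg) | subjects$weight_kg <= 0 |
               !is.finite(subjects$height_cm) | subjects$height_cm <= 0)
  if (length(bad)) {
    stop("cohort file ", path, ": non-positive weight or height at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  subjects
}

#' Read a pipeline run configuration from a YAML file
#'
#' The file may contain a `simulate:` block (fields of [cohort_config()]), or
#' a `cohort_csv:` path to measured data, plus optional `variables`,
#' `n_groups`, `report_digits` and `exclude_flagged` keys.
#'
#' @param path YAML file path.
#' @return A named list ready for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; restore it
  if (!is.null(cfg$simulate)) {
    names(cfg$simulate)[names(cfg$simulate) == "FALSE"] <- "n"
  }
  cfg
}

#' Run the full validation pipeline
#'
#' Orchestrates every stage end to end: obtain a cohort (simulate from a
#' [cohort_config()] or read a CSV), derive per-subject composition under
#' both methods, compute agreement statistics per variable, and run the
#' tertile classification-capacity procedure on BF%. Stage outputs are
#' written as CSVs when `out_dir` is given; the returned report holds a
#' Table-1-style cohort summary, one agreement block per variable, and the
#' classification block.
#'
#' @param config Either a `cohort_config` (simulate) or a list with
#'   `cohort_csv` (path to measured data) and optionally `simulate` (a list
#'   of [cohort_config()] fields), `variables`, `n_groups`,
#'   `exclude_flagged`.
#' @param variables Variables to compare between methods; subset of
#'   `c("bf_pct", "fm_kg", "ffm_kg", "fmi", "ffmi")`.
#' @param n_groups Ranked groups for the classification stage.
#' @param exclude_flagged Drop quality-flagged subjects before analysis
#'   (default `FALSE`: every subject is analysed).
#' @param out_dir Optional directory for stage CSVs (`cohort.csv`,
#'   `composition.csv`, `agreement.csv`, `classification.csv`).
#' @return An object of class `composition_report`.
#' @export
#' @examples
#' report <- run_pipeline(cohort_config(n = 40, seed = 1))
#' report
run_pipeline <- function(config,
                         variables = c("bf_pct", "fm_kg", "ffm_kg"),
                         n_groups = 3,
                         exclude_flagged = FALSE,
                         out_dir = NULL) {
  allowed <- c("bf_pct", "fm_kg", "ffm_kg", "fmi", "ffmi")
  bad_vars <- setdiff(variables, allowed)
  if (length(bad_vars)) {
    stop("unknown variable(s): ", paste(bad_vars, collapse = ", "),
         "; choose from ", paste(allowed, collapse = ", "), call. = FALSE)
  }

  if (inherits(config, "cohort_config")) {
    cohort <- generate_cohort(config)
    subjects <- cohort$subjects
  } else if (is.list(config) && !is.null(config$cohort_csv)) {
    subjects <- read_cohort(config$cohort_csv)
    variables <- config$variables %||% variables
    n_groups <- config$n_groups %||% n_groups
    exclude_flagged <- config$exclude_flagged %||% exclude_flagged
  } else if (is.list(config) && !is.null(config$simulate)) {
    cc <- do.call(cohort_config, config$simulate)
    cohort <- generate_cohort(cc)
    subjects <- cohort$subjects
    variables <- config$variables %||% variables
    n_groups <- config$n_groups %||% n_groups
    exclude_flagged <- config$exclude_flagged %||% exclude_flagged
  } else {
    stop("config must be a cohort_config or a list with cohort_csv or simulate",
         call. = FALSE)
  }

  composition <- compose_cohort(subjects, exclude_flagged = exclude_flagged)
  wide <- split(composition, composition$method)

  agreement <- lapply(variables, function(v) {
    agreement_summary(wide$BIA[[v]], wide$`3C`[[v]], variable = v,
                      units = if (v == "bf_pct") "%"
                              else if (v %in% c("fm_kg", "ffm_kg")) "kg"
                              else "kg/m2")
  })
  names(agreement) <- variables

  classification <- classification_capacity(wide$BIA$bf_pct, wide$`3C`$bf_pct,
                                            n_groups = n_groups)

  summary_tbl <- cohort_summary(subjects, composition)

  report <- structure(
    list(n = nrow(subjects), variables = variables, n_groups = n_groups,
         subjects = subjects, composition = composition,
         summary = summary_tbl, agreement = agreement,
         classification = classification),
    class = "composition_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(subjects, file.path(out_dir, "cohort.csv"))
    readr::write_csv(composition, file.path(out_dir, "composition.csv"))
    agree_df <- dplyr::bind_rows(lapply(agreement, as.data.frame))
    readr::write_csv(agree_df, file.path(out_dir, "agreement.csv"))
    readr::write_csv(classification$offsets,
                     file.path(out_dir, "classification.csv"))
  }
  report
}

# Table-1-style per-variable, per-method summary (mean, SD, range)
cohort_summary <- function(subjects, composition) {
  summarise_vec <- function(x, variable, method) {
    tibble::tibble(variable = variable, method = method,
                   mean = mean(x), sd = stats::sd(x),
                   min = min(x), max = max(x))
  }
  anthro <- dplyr::bind_rows(
    summarise_vec(subjects$age_y, "age_y", "-"),
    summarise_vec(subjects$weight_kg, "weight_kg", "-"),
    summarise_vec(subjects$height_cm, "height_cm", "-")
  )
  comp_vars <- c("bf_pct", "fm_kg", "ffm_kg", "fmi", "ffmi", "bmi")
  comp <- dplyr::bind_rows(lapply(split(composition, composition$method),
    function(df) {
      dplyr::bind_rows(lapply(comp_vars, function(v) {
        summarise_vec(df[[v]], v, df$method[1])
      }))
    }))
  dplyr::bind_rows(anthro, comp)
}

#' @export
print.composition_report <- function(x, digits = 1, ...) {
  cat(sprintf("Body-composition validation report: %d subjects\n\n", x$n))
  cat("Cohort summary (mean +/- SD [range]):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s %-4s %6.*f +/- %.*f  [%.*f, %.*f]\n",
                s$variable[i], s$method[i],
                digits, s$mean[i], digits, s$sd[i],
                digits, s$min[i], digits, s$max[i]))
  }
  cat("\n")
  for (v in x$variables) {
    print(x$agreement[[v]])
    cat("\n")
  }
  print(x$classification)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
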