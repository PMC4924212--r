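#' Rank subjects and partition them into ordered groups
#'
#' Sorts subjects by a variable into a sequence of gradually increasing
#' values and cuts the sequence into `n_groups` contiguous ranked groups
#' (tertiles by default). When n is not divisible by `n_groups`, the
#' remainder subjects are assigned one per group starting from the LOWEST
#' group, so n = 40 with 3 groups gives sizes 14, 13, 13. Ties are broken by
#' original position (stable sort), which matters only for exactly equal
#' measurements.
#'
#' @param values Numeric vector, one value per subject.
#' @param n_groups Number of ranked groups, >= 2.
#' @return A list: `group` (integer 1..n_groups per subject, 1 = lowest),
#'   `sizes` (per-group counts), `bounds` (tibble of per-group observed min
#'   and max of the variable).
#' @export
#' @examples
#' rank_and_partition(runif(40), 3)$sizes # 14 13 13
rank_and_partition <- function(values, n_groups = 3) {
  if (any(!is.finite(values))) {
    stop("values must be finite", call. = FALSE)
  }
  n <- length(values)
  if (n_groups < 2 || n_groups != round(n_groups)) {
    stop("n_groups must be an integer >= 2", call. = FALSE)
  }
  if (n < n_groups) {
    stop("insufficient data: need at least as many subjects as groups",
         call. = FALSE)
  }
  base <- n %/% n_groups
  rem <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, rem), rep(0L, n_groups - rem))
  ord <- order(values)               # stable: ties keep original order
  group_sorted <- rep.int(seq_len(n_groups), sizes)
  group <- integer(n)
  group[ord] <- group_sorted
  gmin <- vapply(seq_len(n_groups), function(g) min(values[group == g]), numeric(1))
  gmax <- vapply(seq_len(n_groups), function(g) max(values[group == g]), numeric(1))
  bounds <- tibble::tibble(
    group = seq_len(n_groups),
    size = as.integer(sizes),
    min = gmin,
    max = gmax
  )
  list(group = group, sizes = as.integer(sizes), bounds = bounds)
}

#' Cross-method classification table from two group assignments
#'
#' Tabulates, subject by subject, how far the test method's ranked-group
#' placement is from the criterion's: offset = test group - reference group,
#' ranging over -(g-1)..+(g-1). Offset 0 means the subject landed in the same
#' group under both methods.
#'
#' @param groups_test,groups_ref Integer group assignments (1..n_groups) of
#'   the same subjects under the two methods.
#' @param n_groups Number of groups used for both assignments.
#' @return An object of class `classification_table`: list with `n`,
#'   `n_groups`, `offsets` (tibble of offset, count, pct), `pct_correct`,
#'   `pct_within_one`.
#' @export
classification_table <- function(groups_test, groups_ref, n_groups = max(groups_test, groups_ref)) {
  if (length(groups_test) != length(groups_ref)) {
    stop("group assignments must have equal length", call. = FALSE)
  }
  n <- length(groups_test)
  if (any(groups_test < 1 | groups_test > n_groups) ||
      any(groups_ref < 1 | groups_ref > n_groups)) {
    stop("group labels must lie in 1..n_groups", call. = FALSE)
  }
  offset <- groups_test - groups_ref
  lev <- seq(-(n_groups - 1), n_groups - 1)
  counts <- as.integer(table(factor(offset, levels = lev)))
  offsets <- tibble::tibble(offset = lev, count = counts,
                            pct = 100 * counts / n)
  out <- list(
    n = n, n_groups = as.integer(n_groups),
    offsets = offsets,
    pct_correct = 100 * sum(offset == 0) / n,
    pct_within_one = 100 * sum(abs(offset) <= 1) / n
  )
  class(out) <- "classification_table"
  out
}

#' Classification capacity of a test method against a criterion
#'
#' Full rank-based concordance procedure for one variable: rank and partition
#' the subjects under each method independently, then cross-tabulate the
#' placement offsets. Because only ranks enter, any strictly increasing
#' recalibration of either method leaves the result unchanged — a pure
#' calibration bias costs nothing here; only rank scrambling does.
#'
#' @param test_values,ref_values Paired per-subject values under the test and
#'   criterion methods.
#' @param n_groups Number of ranked groups (default 3, tertiles).
#' @return A `classification_table` with per-method group bounds attached as
#'   `bounds_test` and `bounds_ref`.
#' @export
#' @examples
#' set.seed(1)
#' ref <- rnorm(40, 25.1, 5.5)
#' test <- 0.8 * ref + rnorm(40, 0, 2)
#' classification_capacity(test, ref, n_groups = 3)
classification_capacity <- function(test_values, ref_values, n_groups = 3) {
  check_paired(test_values, ref_values, min_n = n_groups)
  pt <- rank_and_partition(test_values, n_groups)
  pr <- rank_and_partition(ref_values, n_groups)
  out <- classification_table(pt$group, pr$group, n_groups)
  out$bounds_test <- pt$bounds
  out$bounds_ref <- pr$bounds
  out
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Classification capacity: %d subjects, %d ranked groups\n",
              x$n, x$n_groups))
  shown <- x$offsets[x$offsets$count > 0, ]
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("  offset %+d : %3d (%.0f%%)\n",
                shown$offset[i], shown$count[i], shown$pct[i]))
  }
  cat(sprintf("  correctly classified: %.0f%%; within one group: %.0f%%\n",
              x$pct_correct, x$pct_within_one))
  invisible(x)
}
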