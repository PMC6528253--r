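# Fixed-order transform chain (baseline -> normalise -> scale) and
# replicate aggregation.

# mean over usable (unmasked, non-missing) replicates of one test, per group
reference_means <- function(data, test_value, what) {
  if (!any(data$test == test_value)) {
    abort(sprintf(
      "%s test %g not present in the layout; available: %s", what, test_value,
      paste(sort(unique(data$test)), collapse = ", ")
    ))
  }
  data |>
    as_tibble() |>
    filter(.data$test == test_value, !.data$masked, !is.na(.data$value)) |>
    group_by(.data$group) |>
    summarise(ref_mean = mean(.data$value), n_ref = dplyr::n(), .groups = "drop")
}

#' Subtract a baseline reference from all values
#'
#' For each group independently, the mean of the unmasked, non-missing
#' replicates at `baseline_test` is subtracted from every observed value in
#' that group. Afterwards the baseline replicates of each group have mean 0.
#' Applied before normalisation.
#'
#' @param data A `plate_data` tibble.
#' @param baseline_test Test value whose replicates serve as the baseline.
#' @return The transformed data; the per-group reference means are attached
#'   as attribute `"reference"` (a tibble `group`, `ref_mean`, `n_ref`).
#' @export
subtract_baseline <- function(data, baseline_test) {
  ref <- reference_means(data, baseline_test, "baseline")
  missing_groups <- setdiff(unique(data$group), ref$group)
  if (length(missing_groups)) {
    abort(paste0(
      "baseline unavailable: all replicates of test ", baseline_test,
      " are masked or missing in group(s) ",
      paste(missing_groups, collapse = ", ")
    ))
  }
  out <- data |>
    left_join(ref, by = "group") |>
    mutate(value = .data$value - .data$ref_mean) |>
    select(-"ref_mean", -"n_ref")
  out <- restore_plate_data(out, data)
  attr(out, "reference") <- ref
  out
}

#' Normalise all values by a reference mean
#'
#' For each group independently, every observed value is divided by the mean
#' of the unmasked, non-missing replicates at `norm_test`. Afterwards the
#' normalisation replicates of each group have mean 1. Applied after baseline
#' subtraction and before scaling.
#'
#' @param data A `plate_data` tibble.
#' @param norm_test Test value whose replicate mean is the divisor.
#' @return The transformed data, with attribute `"reference"` as in
#'   [subtract_baseline()].
#' @export
normalise_values <- function(data, norm_test) {
  ref <- reference_means(data, norm_test, "normalisation")
  missing_groups <- setdiff(unique(data$group), ref$group)
  if (length(missing_groups)) {
    abort(paste0(
      "normalisation reference unavailable in group(s) ",
      paste(missing_groups, collapse = ", ")
    ))
  }
  degen <- ref$group[ref$ref_mean == 0 | !is.finite(ref$ref_mean)]
  if (length(degen)) {
    abort(paste0(
      "degenerate normalisation reference (mean is 0) in group(s) ",
      paste(degen, collapse = ", ")
    ))
  }
  out <- data |>
    left_join(ref, by = "group") |>
    mutate(value = .data$value / .data$ref_mean) |>
    select(-"ref_mean", -"n_ref")
  out <- restore_plate_data(out, data)
  attr(out, "reference") <- ref
  out
}

#' Scale all values by a constant factor
#'
#' Multiplies every observed value by `factor`. Applied after normalisation
#' and before aggregation and fitting.
#'
#' @param data A `plate_data` tibble.
#' @param factor Finite, non-zero multiplier.
#' @return The transformed data.
#' @export
scale_values <- function(data, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor)) {
    abort("scale factor must be a single finite number")
  }
  if (factor == 0) abort("scale factor must be non-zero")
  data$value <- data$value * factor
  data
}

restore_plate_data <- function(out, template) {
  if (inherits(template, "plate_data")) {
    new_plate_data(out, c(attr(template, "n_rows"), attr(template, "n_cols")))
  } else {
    out
  }
}

#' Aggregate replicates into per-test means and variations
#'
#' For each group x test value, computes the mean over usable (unmasked,
#' non-missing) replicates and a variation half-width: sample standard
#' deviation (`"sd"`, n-1 denominator), standard error of the mean (`"sem"`,
#' SD/sqrt(n)) or a 95% confidence half-width (`"ci95"`,
#' t(0.975, n-1) x SEM). Variation needs at least two usable replicates; a
#' test whose replicates are all masked or missing yields a `fully_masked`
#' point with no mean, which downstream fitting ignores.
#'
#' @param data A `plate_data` tibble.
#' @param variation One of `"sd"`, `"sem"`, `"ci95"`.
#' @return A `plate_summary` tibble: `group`, `test`, `mean`, `variation`,
#'   `n_used`, `fully_masked`, tests ascending within group. The variation
#'   kind is kept in attribute `"variation_kind"`.
#' @examples
#' lay <- parse_layout(rbind(c(0, 0, 0), c(10, 10, 10)))
#' g <- bind_group(lay, "a", rbind(c(2, 4, 6), c(1, 1, 1)))
#' aggregate_replicates(g, "sem")
#' @export
aggregate_replicates <- function(data, variation = c("sem", "sd", "ci95")) {
  variation <- match.arg(variation)
  out <- data |>
    as_tibble() |>
    arrange(.data$group, .data$test, .data$row, .data$col) |>
    group_by(.data$group, .data$test) |>
    summarise(
      mean = mean(.data$value[!.data$masked & !is.na(.data$value)]),
      .sd = sd(.data$value[!.data$masked & !is.na(.data$value)]),
      n_used = sum(!.data$masked & !is.na(.data$value)),
      .groups = "drop"
    ) |>
    mutate(
      mean = ifelse(.data$n_used >= 1L, .data$mean, NA_real_),
      variation = dplyr::case_when(
        .data$n_used < 2L ~ NA_real_,
        variation == "sd" ~ .data$.sd,
        variation == "sem" ~ .data$.sd / sqrt(.data$n_used),
        TRUE ~ qt(0.975, pmax(.data$n_used - 1L, 1L)) * .data$.sd / sqrt(.data$n_used)
      ),
      fully_masked = .data$n_used == 0L
    ) |>
    select("group", "test", "mean", "variation", "n_used", "fully_masked") |>
    arrange(.data$group, .data$test)
  structure(out,
    variation_kind = variation,
    class = c("plate_summary", class(out))
  )
}
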