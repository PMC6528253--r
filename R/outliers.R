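# Grubbs' test for a single outlier within a replicate set.

#' Grubbs' statistic of a sample
#'
#' G is the distance of the farthermost value from the sample mean, in units
#' of the sample standard deviation: `G = max_i |x_i - mean| / sd`. With zero
#' spread no value can be an outlier and G is 0. Ties in the deviation go to
#' the earliest value.
#'
#' @param values Numeric vector, length >= 3.
#' @return A list with `G` (the statistic) and `index` (position of the
#'   farthermost value).
#' @examples
#' grubbs_statistic(c(10, 11, 12, 13, 30))
#' @export
grubbs_statistic <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) abort("Grubbs' test not applicable: fewer than 3 values")
  if (anyNA(values)) abort("Grubbs' test requires complete values")
  s <- sd(values)
  if (!is.finite(s) || s == 0) {
    return(list(G = 0, index = NA_integer_))
  }
  dev <- abs(values - mean(values))
  i <- which.max(dev) # first max on ties
  list(G = dev[i] / s, index = i)
}

#' Two-sided Grubbs critical value
#'
#' The critical value of the two-sided single-outlier Grubbs test at
#' significance level `alpha`:
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` quantile of Student's t with `n - 2` degrees of
#' freedom.
#'
#' @param n Integer sample size(s), each >= 3.
#' @param alpha Significance level in (0, 1).
#' @return Numeric vector of critical values, same length as `n`.
#' @examples
#' grubbs_critical(5, 0.05) # ~ 1.715
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  n <- as.integer(n)
  if (any(n < 3L)) abort("Grubbs' critical value requires n >= 3")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)")
  }
  tq <- qt(alpha / (2 * n), df = n - 2L, lower.tail = FALSE)
  (n - 1L) / sqrt(n) * sqrt(tq^2 / (n - 2L + tq^2))
}

#' Screen replicate sets for outliers with Grubbs' test
#'
#' Runs the two-sided Grubbs test independently on every replicate set
#' (group x test value), using only unmasked, non-missing members. When
#' `G > G_crit` the farthermost member is masked and recorded; at most one
#' value is flagged per replicate set per run (single pass, non-iterative).
#' Sets with fewer than 3 usable members, or with zero spread, are skipped
#' and noted. Intended as the very first step of the pipeline, on raw
#' (pre-transform) values; the decision is invariant under affine transforms
#' of a set, so ordering relative to affine transforms cannot change it.
#'
#' @param data A `plate_data` tibble.
#' @param alpha Two-sided significance level (default 0.05).
#' @return The data with flagged wells added to `masked`. The report is
#'   attached as attribute `"outlier_report"` and retrievable with
#'   [outlier_report()]: a tibble `group`, `test`, `well`, `value`, `n`,
#'   `G`, `G_crit`. Skipped sets are in attribute `"outlier_skipped"`.
#' @export
screen_outliers <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort("alpha must be in (0, 1)")
  }
  sets <- replicate_sets(data)
  flags <- list()
  skipped <- list()
  for (k in seq_len(nrow(sets))) {
    mem <- sets$members[[k]]
    usable <- !mem$masked & !is.na(mem$value)
    nn <- sum(usable)
    if (nn < 3L) {
      skipped[[length(skipped) + 1L]] <- tibble(
        group = sets$group[k], test = sets$test[k], n = nn,
        reason = "n too small"
      )
      next
    }
    g <- grubbs_statistic(mem$value[usable])
    if (g$G == 0) {
      skipped[[length(skipped) + 1L]] <- tibble(
        group = sets$group[k], test = sets$test[k], n = nn,
        reason = "zero spread"
      )
      next
    }
    crit <- grubbs_critical(nn, alpha)
    if (g$G > crit) {
      hit <- mem[usable, ][g$index, ]
      flags[[length(flags) + 1L]] <- tibble(
        group = sets$group[k], test = sets$test[k], well = hit$well,
        value = hit$value, n = nn, G = g$G, G_crit = crit
      )
    }
  }
  report <- if (length(flags)) bind_rows(flags) else tibble(
    group = character(), test = double(), well = character(),
    value = double(), n = integer(), G = double(), G_crit = double()
  )
  if (nrow(report)) {
    key <- paste(data$group, data$well)
    data$masked <- data$masked | key %in% paste(report$group, report$well)
  }
  attr(data, "outlier_report") <- report
  attr(data, "outlier_skipped") <- if (length(skipped)) bind_rows(skipped) else tibble(
    group = character(), test = double(), n = integer(), reason = character()
  )
  attr(data, "alpha") <- alpha
  data
}

#' Retrieve the outlier report from screened data
#'
#' @param data The result of [screen_outliers()].
#' @return The report tibble (see [screen_outliers()]), or an empty tibble
#'   if the data were never screened.
#' @export
outlier_report <- function(data) {
  rep <- attr(data, "outlier_report")
  if (is.null(rep)) {
    rep <- tibble(
      group = character(), test = double(), well = character(),
      value = double(), n = integer(), G = double(), G_crit = double()
    )
  }
  rep
}
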