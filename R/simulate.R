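# Synthetic plate assays with known ground truth: the test harness for the
# whole pipeline. Replicate noise is Gaussian — the distributional
# assumption under which Grubbs' test is exact — and injected outliers are
# additive displacements with random sign, so both tails of the test are
# exercised.

#' Simulate a plate assay with known ground truth
#'
#' Builds a plate layout with each dose occupying one row (`n_replicates`
#' columns), generates responses from the true model plus i.i.d. Gaussian
#' noise, and optionally displaces a random subset of wells by
#' `outlier_magnitude` response-ranges to create gross outliers. The
#' response range is `|top - bottom|` for the 4PL and
#' `|slope| * (max(doses) - min(doses))` for the linear model.
#'
#' @param truth Named list of true parameters: `bottom`, `top`, `ec50`,
#'   `hill` for `model = "logistic4"`, or `intercept`, `slope` for
#'   `"linear"`.
#' @param doses Strictly increasing test values (a zero-dose control is
#'   allowed for the 4PL: its response is the asymptotic limit).
#' @param n_replicates Replicates per dose (>= 1), the plate's column count.
#' @param noise_sd Gaussian noise SD in response units (>= 0).
#' @param outlier_frac Fraction of wells (per group) to displace, in [0, 1).
#' @param outlier_magnitude Displacement size in response ranges (default 6).
#' @param n_groups Number of independent datasets sharing the layout.
#' @param model `"logistic4"` or `"linear"`.
#' @param seed Integer seed fixing all randomness of the simulation.
#' @return A list: `layout` (a `plate_layout`), `data` (a `plate_data` with
#'   all groups), and `truth` — the model, parameters, per-group injected
#'   outlier wells (`group`, `well`, `row`, `col`, `test`, `delta`), the
#'   clean (pre-noise) responses and the spec fingerprint used by
#'   [score_run()].
#' @examples
#' sim <- simulate_plate(
#'   truth = list(bottom = 0, top = 100, ec50 = 1, hill = 1.5),
#'   doses = c(0.01, 0.1, 0.3, 1, 3, 10, 30, 100),
#'   n_replicates = 4, noise_sd = 2, seed = 1
#' )
#' @export
simulate_plate <- function(truth, doses, n_replicates = 4L, noise_sd = 0,
                           outlier_frac = 0, outlier_magnitude = 6,
                           n_groups = 1L, model = c("logistic4", "linear"),
                           seed = 1L) {
  model <- match.arg(model)
  stopifnot(
    is.numeric(doses), length(doses) >= 2L, !is.unsorted(doses, strictly = TRUE),
    n_replicates >= 1L, noise_sd >= 0,
    outlier_frac >= 0, outlier_frac < 1, n_groups >= 1L
  )
  truth <- validate_start(unlist(truth), model)
  clean <- if (model == "logistic4") {
    logistic4(doses, truth[["bottom"]], truth[["top"]], truth[["ec50"]], truth[["hill"]])
  } else {
    linear_eval(doses, truth[["intercept"]], truth[["slope"]])
  }
  rng_range <- if (model == "logistic4") {
    abs(truth[["top"]] - truth[["bottom"]])
  } else {
    abs(truth[["slope"]]) * (max(doses) - min(doses))
  }
  lay_mat <- matrix(rep(doses, each = n_replicates),
    nrow = length(doses), ncol = n_replicates, byrow = TRUE
  )
  layout <- parse_layout(lay_mat)
  n_wells <- length(doses) * n_replicates
  n_out <- floor(outlier_frac * n_wells)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  groups <- vector("list", n_groups)
  out_rows <- list()
  for (gi in seq_len(n_groups)) {
    gname <- if (n_groups == 1L) "group1" else sprintf("group%d", gi)
    vals <- matrix(rep(clean, each = n_replicates),
      nrow = length(doses), ncol = n_replicates, byrow = TRUE
    )
    vals <- vals + rnorm(n_wells, 0, noise_sd)
    if (n_out > 0L) {
      idx <- sample.int(n_wells, n_out) # linear index, row-major over wells
      rr <- (idx - 1L) %/% n_replicates # 0-based plate row
      cc <- (idx - 1L) %% n_replicates  # 0-based plate col
      delta <- sample(c(-1, 1), n_out, replace = TRUE) * outlier_magnitude * rng_range
      vals[cbind(rr + 1L, cc + 1L)] <- vals[cbind(rr + 1L, cc + 1L)] + delta
      out_rows[[gi]] <- tibble(
        group = gname, well = well_label(rr, cc), row = rr, col = cc,
        test = doses[rr + 1L], delta = delta
      )
    }
    groups[[gi]] <- bind_group(layout, gname, vals)
  }
  outliers <- if (length(out_rows)) {
    arrange(bind_rows(out_rows), .data$group, .data$row, .data$col)
  } else {
    tibble(
      group = character(), well = character(), row = integer(),
      col = integer(), test = double(), delta = double()
    )
  }
  spec <- list(
    model = model, params = truth, doses = doses,
    n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
    outlier_frac = outlier_frac, outlier_magnitude = outlier_magnitude,
    n_groups = as.integer(n_groups), seed = as.integer(seed)
  )
  list(
    layout = layout,
    data = bind_groups(groups),
    truth = list(
      model = model, params = truth, outliers = outliers,
      clean_response = setNames(clean, doses), spec = spec,
      spec_hash = spec_fingerprint(spec)
    )
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

spec_fingerprint <- function(spec) {
  paste(deparse(spec[order(names(spec))], control = "all"), collapse = "")
}

#' Score a pipeline run against simulation ground truth
#'
#' Compares an outlier report and a fit against the injected outliers and
#' true parameters of [simulate_plate()].
#'
#' @param truth The `truth` element returned by [simulate_plate()].
#' @param report An outlier report tibble (see [outlier_report()]), or NULL.
#' @param fit A `platefit_fit`, or NULL.
#' @param expected_hash Optional spec fingerprint to assert the truth record
#'   matches the run's simulation spec.
#' @return A one-row tibble: `sensitivity` (flagged / injected; `NA` when
#'   nothing was injected), `false_positives`, `n_injected`, `n_flagged`,
#'   and one `rel_err_<param>` column per true parameter (`NA` without a
#'   fit). Relative error uses `|est - true| / |true|`, or `|est - true|`
#'   when the true value is 0.
#' @export
score_run <- function(truth, report = NULL, fit = NULL, expected_hash = NULL) {
  if (!is.null(expected_hash) && !identical(expected_hash, truth$spec_hash)) {
    abort("simulation spec mismatch: the truth record is from a different run")
  }
  inj <- paste(truth$outliers$group, truth$outliers$well)
  fl <- if (is.null(report) || nrow(report) == 0L) character() else paste(report$group, report$well)
  res <- tibble(
    sensitivity = if (length(inj)) sum(fl %in% inj) / length(inj) else NA_real_,
    false_positives = sum(!fl %in% inj),
    n_injected = length(inj),
    n_flagged = length(fl)
  )
  if (!is.null(fit)) {
    for (nm in names(truth$params)) {
      tv <- truth$params[[nm]]
      ev <- fit$params[[nm]]
      err <- if (tv == 0) abs(ev - tv) else abs(ev - tv) / abs(tv)
      res[[paste0("rel_err_", nm)]] <- err
    }
  }
  res
}
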