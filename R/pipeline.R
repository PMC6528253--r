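# The full analysis pipeline: outlier screen -> baseline -> normalise ->
# scale -> aggregate -> fit, per group, with per-stage logging.

#' Build and validate an analysis configuration
#'
#' Collects every setting of a run. The transform stages are optional and
#' always applied in the fixed order baseline subtraction, normalisation,
#' scaling; the outlier screen, when enabled, is the very first step and
#' operates on raw values.
#'
#' @param layout_source Path to the plate layout (or a `plate_layout`).
#' @param data_source Path(s) to the data groups (or a `plate_data`).
#' @param fit_model `"logistic4"` or `"linear"`.
#' @param baseline_test Optional test value whose replicate mean is
#'   subtracted from every value (per group).
#' @param norm_test Optional test value whose replicate mean divides every
#'   value (per group). Must differ from `baseline_test`: subtracting a
#'   baseline forces its own mean to 0, so the same test cannot then serve
#'   as a normalisation reference.
#' @param scale_factor Optional non-zero multiplier applied after
#'   normalisation.
#' @param variation `"sem"`, `"sd"` or `"ci95"` — the error-bar half-width.
#' @param outlier_check Run the Grubbs screen first? Default `TRUE`.
#' @param alpha Two-sided significance level of the screen (default 0.05).
#' @param x_title,y_title,plot_title Plot annotation strings.
#' @param out_dir Output directory for tables, log and plots.
#' @param image_format `"png"` or `"svg"`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(layout_source, data_source,
                            fit_model = c("logistic4", "linear"),
                            baseline_test = NULL, norm_test = NULL,
                            scale_factor = NULL,
                            variation = c("sem", "sd", "ci95"),
                            outlier_check = TRUE, alpha = 0.05,
                            x_title = "Test value", y_title = "Response",
                            plot_title = NULL,
                            out_dir = NULL,
                            image_format = c("png", "svg")) {
  fit_model <- match.arg(fit_model)
  variation <- match.arg(variation)
  image_format <- match.arg(image_format)
  if (!is.null(scale_factor)) {
    stopifnot(is.numeric(scale_factor), length(scale_factor) == 1L, is.finite(scale_factor))
    if (scale_factor == 0) abort("scale_factor must be non-zero")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!is.null(baseline_test) && !is.null(norm_test) &&
      baseline_test == norm_test) {
    abort("baseline_test and norm_test must differ (the baseline mean is 0 after subtraction)")
  }
  for (src in list(layout_source, data_source)) {
    if (is.character(src) && !all(file.exists(src))) {
      abort(paste0("input not found: ", paste(src[!file.exists(src)], collapse = ", ")))
    }
  }
  structure(
    list(
      layout_source = layout_source, data_source = data_source,
      fit_model = fit_model, baseline_test = baseline_test,
      norm_test = norm_test, scale_factor = scale_factor,
      variation = variation, outlier_check = isTRUE(outlier_check),
      alpha = alpha, x_title = x_title, y_title = y_title,
      plot_title = plot_title, out_dir = out_dir, image_format = image_format
    ),
    class = "analysis_config"
  )
}

#' Run the full plate-analysis pipeline
#'
#' Per group, in order: (1) Grubbs outlier screen on raw values (if
#' enabled), (2) baseline subtraction (if configured), (3) normalisation (if
#' configured), (4) scaling (if configured), (5) replicate aggregation,
#' (6) model fit. A stage failure is recorded for its group and the
#' remaining groups still run. When `write_outputs` is `TRUE` and
#' `config$out_dir` is set, the result tables, the per-stage log and one
#' plot per group are written there.
#'
#' For the 4PL model, zero-dose points that served as the baseline or
#' normalisation reference are excluded from the fit (they carry no
#' dose-response information once transformed out); any other zero dose is
#' included through the model's x = 0 limit.
#'
#' @param config An [analysis_config()].
#' @param write_outputs Write tables/log/plots to `config$out_dir`?
#'   Defaults to `TRUE` when `out_dir` is set.
#' @return A `platefit_run` list: `results` (one-row-per-group tibble),
#'   `aggregated`, `outlier_report`, `fits` (named list of `platefit_fit`),
#'   `log`, `config`, `status` (`0` all groups fitted, `2` partial failure),
#'   and `artifacts` (paths written).
#' @export
run_analysis <- function(config, write_outputs = !is.null(config$out_dir)) {
  stopifnot(inherits(config, "analysis_config"))
  inputs <- resolve_inputs(config)
  layout <- inputs$layout
  data <- inputs$data
  groups <- unique(data$group)
  log <- new.env(parent = emptyenv())
  log$rows <- list()
  note <- function(group, stage, detail) {
    log$rows[[length(log$rows) + 1L]] <- tibble(
      time = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3"),
      group = group, stage = stage, detail = detail
    )
  }

  rows <- list()
  aggs <- list()
  reports <- list()
  fits <- list()
  for (g in groups) {
    gd <- restore_plate_data(data[data$group == g, ], data)
    res <- tryCatch(
      run_group(gd, config, note),
      error = function(e) {
        note(g, "error", conditionMessage(e))
        list(error = conditionMessage(e))
      }
    )
    if (!is.null(res$error)) {
      rows[[g]] <- tibble(group = g, model = config$fit_model, status = "error",
                          error = res$error)
      next
    }
    rows[[g]] <- res$row
    aggs[[g]] <- res$agg
    reports[[g]] <- res$report
    fits[[g]] <- res$fit
  }

  results <- bind_rows(rows)
  # keep one column set across rows even when some groups failed
  if (!"error" %in% names(results)) results$error <- NA_character_
  report <- if (length(reports)) bind_rows(reports) else outlier_report(NULL)
  aggregated <- if (length(aggs)) bind_rows(lapply(aggs, as_tibble)) else tibble()
  status <- if (any(results$status != "ok")) 2L else 0L

  run <- structure(
    list(
      results = results, aggregated = aggregated, outlier_report = report,
      fits = fits, log = bind_rows(log$rows), config = unclass_config(config),
      status = status, artifacts = character()
    ),
    class = "platefit_run"
  )
  if (isTRUE(write_outputs)) {
    if (is.null(config$out_dir)) abort("config$out_dir must be set to write outputs")
    run$artifacts <- write_run_outputs(run, config)
  }
  run
}

resolve_inputs <- function(config) {
  if (inherits(config$layout_source, "plate_layout")) {
    layout <- config$layout_source
    data <- config$data_source
    stopifnot(is.data.frame(data))
    list(layout = layout, data = data)
  } else {
    read_inputs(config$layout_source, config$data_source)
  }
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$layout_source <- if (is.character(cfg$layout_source)) cfg$layout_source else "<in-memory>"
  cfg$data_source <- if (is.character(cfg$data_source)) cfg$data_source else "<in-memory>"
  cfg
}

run_group <- function(gd, config, note) {
  g <- gd$group[1]

  # (1) outlier screen — the very first step, on raw values
  if (config$outlier_check) {
    gd <- screen_outliers(gd, alpha = config$alpha)
    rep <- outlier_report(gd)
    note(g, "outliers", if (nrow(rep)) {
      paste0(
        "alpha=", config$alpha, "; flagged ", nrow(rep), " well(s): ",
        paste(sprintf("%s (test %g, value %g, G=%.4f > %.4f)",
                      rep$well, rep$test, rep$value, rep$G, rep$G_crit),
              collapse = "; ")
      )
    } else {
      paste0("alpha=", config$alpha, "; no outliers flagged")
    })
  } else {
    rep <- outlier_report(NULL)
    note(g, "outliers", "skipped")
  }

  # (2) baseline subtraction
  if (!is.null(config$baseline_test)) {
    gd <- subtract_baseline(gd, config$baseline_test)
    ref <- attr(gd, "reference")
    note(g, "baseline", sprintf(
      "subtracted mean %.10g of test %g (n=%d)",
      ref$ref_mean[1], config$baseline_test, ref$n_ref[1]
    ))
  } else {
    note(g, "baseline", "skipped")
  }

  # (3) normalisation
  if (!is.null(config$norm_test)) {
    gd <- normalise_values(gd, config$norm_test)
    ref <- attr(gd, "reference")
    note(g, "normalise", sprintf(
      "divided by mean %.10g of test %g (n=%d)",
      ref$ref_mean[1], config$norm_test, ref$n_ref[1]
    ))
  } else {
    note(g, "normalise", "skipped")
  }

  # (4) scaling
  if (!is.null(config$scale_factor)) {
    gd <- scale_values(gd, config$scale_factor)
    note(g, "scale", sprintf("multiplied all values by %.10g", config$scale_factor))
  } else {
    note(g, "scale", "skipped")
  }

  # (5) aggregation
  agg <- aggregate_replicates(gd, config$variation)
  note(g, "aggregate", sprintf(
    "%d test value(s), variation=%s, fully masked: %d",
    nrow(agg), config$variation, sum(agg$fully_masked)
  ))

  # (6) fit
  series <- agg
  if (config$fit_model == "logistic4") {
    drop0 <- c(config$baseline_test, config$norm_test)
    if (any(drop0 == 0)) series <- filter(series, .data$test != 0)
  }
  fit <- fit_series(series, config$fit_model)
  note(g, "fit", paste0(
    "model=", config$fit_model,
    "; start: ", fmt_params(fit$start_params),
    "; final: ", fmt_params(fit$params),
    sprintf("; ssr=%.8g r2=%.6f rmse=%s dof=%d; %s in %d iteration(s)",
            fit$ssr, fit$r2, ifelse(is.na(fit$rmse), "-", sprintf("%.6g", fit$rmse)),
            fit$dof, if (fit$converged) "converged" else "NOT converged", fit$n_iter)
  ))

  row <- tibble(group = g, model = config$fit_model, status = "ok",
                error = NA_character_)
  for (nm in names(fit$params)) row[[nm]] <- fit$params[[nm]]
  for (nm in names(fit$param_se)) row[[paste0("se_", nm)]] <- fit$param_se[[nm]]
  row$ssr <- fit$ssr
  row$r2 <- fit$r2
  row$rmse <- fit$rmse
  row$dof <- fit$dof
  row$converged <- fit$converged
  row$n_iter <- fit$n_iter
  row$n_points_used <- fit$n_points
  row$n_outliers_flagged <- nrow(rep)

  list(row = row, agg = agg, report = rep, fit = fit)
}

fmt_params <- function(p) {
  paste(sprintf("%s=%.8g", names(p), p), collapse = " ")
}

write_run_outputs <- function(run, config) {
  out_dir <- config$out_dir
  paths <- write_results(run, out_dir)
  log_path <- write_log(run, file.path(out_dir, "run.log"))
  plot_paths <- character()
  for (g in names(run$fits)) {
    series <- run$aggregated[run$aggregated$group == g, ]
    p <- tryCatch(
      render_plot(series, run$fits[[g]], config,
                  path = file.path(out_dir, paste0("plot_", sanitise(g), ".",
                                                   config$image_format))),
      error = function(e) {
        warning("plot failed for group ", g, ": ", conditionMessage(e), call. = FALSE)
        NA_character_
      }
    )
    if (!is.na(p)) plot_paths[g] <- p
  }
  c(paths, log = log_path, plot_paths)
}

sanitise <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' @export
print.platefit_run <- function(x, ...) {
  cat(sprintf(
    "<platefit_run> %d group(s), model %s, status %d\n",
    nrow(x$results), x$config$fit_model, x$status
  ))
  print(x$results)
  invisible(x)
}
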