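# Four-parameter logistic and linear models fitted to aggregated series.

#' Four-parameter logistic (4PL) dose-response function
#'
#' `y = bottom + (top - bottom) / (1 + (x / ec50)^hill)`.
#'
#' With this parameterisation the curve's inflection sits at `x = ec50`,
#' where the response is exactly midway between the asymptotes — so `ec50`
#' is the EC50/IC50 read off the fit directly. With `hill > 0` the curve
#' falls from `top` (at x = 0, taken as the limit) towards `bottom`; with
#' `hill < 0` it rises from `bottom` towards `top`.
#'
#' @param x Non-negative concentrations (test values).
#' @param bottom,top Lower and upper asymptotes (response units).
#' @param ec50 Midpoint concentration, > 0.
#' @param hill Slope factor, non-zero.
#' @return Numeric vector of responses.
#' @examples
#' logistic4(1, bottom = 0, top = 1, ec50 = 1, hill = 1) # 0.5 at the midpoint
#' @export
logistic4 <- function(x, bottom, top, ec50, hill) {
  if (any(x < 0, na.rm = TRUE)) abort("concentrations must be non-negative")
  stopifnot(ec50 > 0, is.finite(hill), hill != 0)
  l4_eval(x, bottom, top, ec50, hill)
}

# unvalidated evaluation; the optimiser may probe degenerate parameters,
# whose non-finite responses simply reject the step
l4_eval <- function(x, bottom, top, ec50, hill) {
  u <- ifelse(x == 0,
    if (hill > 0) 0 else Inf, # limit: top when hill > 0, bottom when hill < 0
    (x / ec50)^hill
  )
  bottom + (top - bottom) / (1 + u)
}

#' Straight-line model
#'
#' `y = intercept + slope * x`.
#'
#' @param x Numeric vector.
#' @param intercept,slope Finite reals.
#' @return Numeric vector of responses.
#' @export
linear_eval <- function(x, intercept, slope) {
  stopifnot(is.finite(intercept), is.finite(slope))
  intercept + slope * x
}

#' Start-value heuristic for the 4PL model
#'
#' `top` and `bottom` are the responses at the extreme ends of the dose
#' range (larger is `top`); `ec50` is the sampled x whose mean response is
#' nearest the midpoint `(top + bottom)/2`, clamped into the positive dose
#' range; `hill` starts at +1 for a decreasing series and -1 for an
#' increasing one.
#'
#' @param series A `plate_summary` for one group (or a tibble with `test`,
#'   `mean`, `fully_masked`).
#' @return Named numeric vector `c(bottom, top, ec50, hill)`. A flat series
#'   yields a degenerate guess with a "poorly determined" warning.
#' @export
guess_logistic4 <- function(series) {
  pts <- usable_points(series)
  if (nrow(pts) < 4L) {
    abort("under-determined: the 4PL model needs at least 4 usable points")
  }
  if (sum(pts$x > 0) < 2L) {
    abort("under-determined: need at least 2 distinct positive test values")
  }
  pts <- arrange(pts, .data$x)
  y_lo <- pts$y[1]           # response at smallest x
  y_hi <- pts$y[nrow(pts)]   # response at largest x
  top <- max(y_lo, y_hi)
  bottom <- min(y_lo, y_hi)
  xpos <- pts$x[pts$x > 0]
  if (top == bottom) {
    warn("flat series: 4PL start values are poorly determined")
    ec50 <- exp(mean(log(xpos)))
    return(c(bottom = bottom, top = top, ec50 = ec50, hill = 1))
  }
  mid <- (top + bottom) / 2
  ec50 <- pts$x[which.min(abs(pts$y - mid))]
  ec50 <- min(max(ec50, min(xpos)), max(xpos))
  hill <- if (y_hi < y_lo) 1 else -1
  c(bottom = bottom, top = top, ec50 = ec50, hill = hill)
}

usable_points <- function(series) {
  stopifnot(is.data.frame(series))
  df <- as_tibble(series)
  if (!all(c("test", "mean") %in% names(df))) {
    abort("series must have columns 'test' and 'mean' (see aggregate_replicates())")
  }
  if (!"fully_masked" %in% names(df)) df$fully_masked <- FALSE
  df |>
    filter(!.data$fully_masked, !is.na(.data$mean)) |>
    mutate(x = .data$test, y = .data$mean) |>
    select("x", "y")
}

# residual/Jacobian factories on the internal parameter scale.
# 4PL internal parameters: (bottom, top, log_ec50, hill) — log keeps ec50 > 0.
model_functions <- function(model, x, y) {
  if (model == "logistic4") {
    list(
      resid = function(p) {
        yhat <- l4_eval(x, p[1], p[2], exp(p[3]), p[4])
        yhat - y
      },
      jac = function(p) {
        ec50 <- exp(p[3])
        hill <- p[4]
        u <- ifelse(x == 0, if (hill > 0) 0 else Inf, (x / ec50)^hill)
        D <- 1 + u
        # limits at x = 0: derivative wrt everything but the reached asymptote is 0
        dbot <- ifelse(is.finite(u), u / D, 1)
        dtop <- ifelse(is.finite(u), 1 / D, 0)
        span <- p[2] - p[1]
        lr <- ifelse(x > 0, log(x / ec50), 0)
        core <- ifelse(is.finite(u), u / D^2, 0)
        core[!is.finite(core)] <- 0
        dlogec50 <- span * hill * core
        dhill <- ifelse(core == 0, 0, -span * lr * core)
        dhill[x == 0] <- 0
        dlogec50[x == 0] <- 0
        cbind(dbot, dtop, dlogec50, dhill)
      },
      to_internal = function(par) c(par[["bottom"]], par[["top"]], log(par[["ec50"]]), par[["hill"]]),
      from_internal = function(p) c(bottom = p[1], top = p[2], ec50 = exp(p[3]), hill = p[4]),
      # delta method: se(ec50) = ec50 * se(log ec50)
      se_from_internal = function(p, se) c(
        bottom = se[1], top = se[2], ec50 = exp(p[3]) * se[3], hill = se[4]
      ),
      n_par = 4L
    )
  } else {
    list(
      resid = function(p) p[1] + p[2] * x - y,
      jac = function(p) cbind(rep(1, length(x)), x),
      to_internal = function(par) c(par[["intercept"]], par[["slope"]]),
      from_internal = function(p) c(intercept = p[1], slope = p[2]),
      se_from_internal = function(p, se) c(intercept = se[1], slope = se[2]),
      n_par = 2L
    )
  }
}

#' Fit a model to an aggregated series
#'
#' Minimises the unweighted sum of squared residuals between the per-test
#' replicate means and the model curve, by Levenberg-Marquardt. Fully masked
#' points (all replicates masked or missing) are excluded. The 4PL midpoint
#' is fitted as log(ec50) internally so it stays positive; results are
#' reported on the natural scale. Convergence is declared when the relative
#' SSR decrease falls below `1e-10` or the gradient norm below `1e-10`,
#' within 1000 iterations.
#'
#' Parameter standard errors come from the residual-variance-scaled inverse
#' of the Gauss-Newton normal matrix when there is at least one residual
#' degree of freedom and the matrix is well-conditioned; otherwise they are
#' absent (`NA`).
#'
#' @param series A `plate_summary` for a single group, or any tibble with
#'   columns `test` and `mean` (optionally `fully_masked`).
#' @param model `"logistic4"` or `"linear"`.
#' @param start Optional named start parameters (`bottom`, `top`, `ec50`,
#'   `hill` or `intercept`, `slope`). Defaults to [guess_logistic4()] for the
#'   4PL and a closed-form-seeded guess for the linear model. Supplying your
#'   own `start` is the headless equivalent of manual re-fitting.
#' @param max_iter Iteration cap (default 1000).
#' @return A `platefit_fit` object; see [tidy.platefit_fit()],
#'   [glance.platefit_fit()], [predict.platefit_fit()],
#'   [autoplot.platefit_fit()].
#' @examples
#' x <- c(0.01, 0.1, 0.3, 1, 3, 10, 30, 100)
#' s <- tibble::tibble(test = x, mean = logistic4(x, 0, 100, 1, 1.5))
#' fit_series(s, "logistic4")
#' @export
fit_series <- function(series, model = c("logistic4", "linear"), start = NULL,
                       max_iter = 1000L) {
  model <- match.arg(model)
  pts <- usable_points(series)
  mf <- model_functions(model, pts$x, pts$y)
  if (nrow(pts) < mf$n_par) {
    abort(sprintf(
      "under-determined: %d usable points for a %d-parameter model",
      nrow(pts), mf$n_par
    ))
  }
  if (is.null(start)) {
    start <- if (model == "logistic4") {
      guess_logistic4(series)
    } else {
      # seed the linear search at the OLS solution
      b <- stats::coef(stats::lm(y ~ x, data = pts))
      c(intercept = unname(b[1]), slope = unname(b[2]))
    }
  }
  start <- validate_start(start, model)
  opt <- marquardt(mf$to_internal(start), mf$resid, mf$jac, max_iter = max_iter)
  params <- mf$from_internal(opt$par)
  se <- param_se(mf, opt$par, opt$ssr, nrow(pts))
  gof <- gof_from_ssr(opt$ssr, pts$y, mf$n_par)
  structure(
    list(
      model = model,
      params = params,
      param_se = se,
      ssr = opt$ssr,
      r2 = gof$r2,
      rmse = gof$rmse,
      dof = gof$dof,
      n_points = nrow(pts),
      converged = opt$converged,
      n_iter = opt$n_iter,
      message = opt$message,
      start_params = start,
      data = pts
    ),
    class = "platefit_fit"
  )
}

validate_start <- function(start, model) {
  want <- if (model == "logistic4") c("bottom", "top", "ec50", "hill") else c("intercept", "slope")
  if (is.null(names(start)) && length(start) == length(want)) names(start) <- want
  if (!all(want %in% names(start))) {
    abort(paste0("start parameters must be named: ", paste(want, collapse = ", ")))
  }
  start <- start[want]
  if (model == "logistic4") {
    if (!is.finite(start[["ec50"]]) || start[["ec50"]] <= 0) abort("start ec50 must be > 0")
    if (!is.finite(start[["hill"]]) || start[["hill"]] == 0) abort("start hill must be non-zero")
  }
  if (any(!is.finite(start))) abort("start parameters must be finite")
  start
}

param_se <- function(mf, p_internal, ssr, n_pts) {
  dof <- n_pts - mf$n_par
  blank <- setNames(rep(NA_real_, mf$n_par), names(mf$from_internal(p_internal)))
  if (dof < 1L) return(blank)
  J <- mf$jac(p_internal)
  A <- crossprod(J)
  if (!all(is.finite(A)) || rcond(A) < 1e-12) return(blank)
  covm <- tryCatch(solve(A) * ssr / dof, error = function(e) NULL)
  if (is.null(covm) || any(diag(covm) < 0)) return(blank)
  mf$se_from_internal(p_internal, unname(sqrt(diag(covm))))
}

gof_from_ssr <- function(ssr, y, n_par) {
  tss <- sum((y - mean(y))^2)
  dof <- length(y) - n_par
  list(
    r2 = if (tss > 0) 1 - ssr / tss else if (ssr == 0) 1 else NA_real_,
    rmse = if (dof >= 1L) sqrt(ssr / dof) else NA_real_,
    dof = dof
  )
}

#' Goodness-of-fit statistics for given parameters
#'
#' Evaluates SSR, R-squared, RMSE and residual degrees of freedom of a model
#' with fixed (e.g. manually entered) parameters against an aggregated
#' series, with the same definitions [fit_series()] reports for fitted
#' parameters.
#'
#' @inheritParams fit_series
#' @param params Named parameter vector for `model`.
#' @return A one-row tibble: `ssr`, `r2`, `rmse`, `dof`.
#' @export
gof_stats <- function(series, model = c("logistic4", "linear"), params) {
  model <- match.arg(model)
  pts <- usable_points(series)
  params <- validate_start(params, model)
  yhat <- if (model == "logistic4") {
    logistic4(pts$x, params[["bottom"]], params[["top"]], params[["ec50"]], params[["hill"]])
  } else {
    linear_eval(pts$x, params[["intercept"]], params[["slope"]])
  }
  ssr <- sum((pts$y - yhat)^2)
  g <- gof_from_ssr(ssr, pts$y, length(params))
  tibble(ssr = ssr, r2 = g$r2, rmse = g$rmse, dof = g$dof)
}

#' @export
print.platefit_fit <- function(x, ...) {
  cat(sprintf(
    "<platefit_fit> %s model, %d points, %s after %d iteration(s)\n",
    x$model, x$n_points,
    if (x$converged) "converged" else "NOT converged", x$n_iter
  ))
  est <- format(signif(x$params, 6))
  se <- ifelse(is.na(x$param_se), "-", format(signif(x$param_se, 3)))
  for (i in seq_along(x$params)) {
    cat(sprintf("  %-9s %12s  (se %s)\n", names(x$params)[i], est[i], se[i]))
  }
  cat(sprintf(
    "  ssr %.6g | r2 %.6g | rmse %s | dof %d\n",
    x$ssr, x$r2, if (is.na(x$rmse)) "-" else sprintf("%.6g", x$rmse), x$dof
  ))
  invisible(x)
}

#' Tidy a plate fit into one row per parameter
#'
#' @param x A `platefit_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
#' @export
tidy.platefit_fit <- function(x, ...) {
  tibble(
    term = names(x$params),
    estimate = unname(x$params),
    std.error = unname(x$param_se[names(x$params)])
  )
}

#' One-row summary of a plate fit
#'
#' @param x A `platefit_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `ssr`, `r2`, `rmse`, `dof`, `n_points`,
#'   `converged`, `n_iter`.
#' @exportS3Method generics::glance
#' @export
glance.platefit_fit <- function(x, ...) {
  tibble(
    model = x$model, ssr = x$ssr, r2 = x$r2, rmse = x$rmse, dof = x$dof,
    n_points = x$n_points, converged = x$converged, n_iter = x$n_iter
  )
}

#' Predict from a plate fit
#'
#' @param object A `platefit_fit`.
#' @param newdata Optional numeric vector of test values (or a data frame
#'   with a `test` column); defaults to the fitted points' x.
#' @param ... Unused.
#' @return Numeric vector of model responses.
#' @export
predict.platefit_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    object$data$x
  } else if (is.data.frame(newdata)) {
    newdata$test
  } else {
    as.numeric(newdata)
  }
  p <- object$params
  if (object$model == "logistic4") {
    logistic4(x, p[["bottom"]], p[["top"]], p[["ec50"]], p[["hill"]])
  } else {
    linear_eval(x, p[["intercept"]], p[["slope"]])
  }
}
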