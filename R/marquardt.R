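# Levenberg-Marquardt least squares, the fitting engine behind fit_series().
# Classic Marquardt scaling: (J'J + lambda diag(J'J)) delta = -J'r,
# lambda x10 on a rejected step, /10 on an accepted one.

marquardt <- function(start, resid_fn, jac_fn,
                      max_iter = 1000L, ftol = 1e-10, gtol = 1e-10,
                      lambda0 = 1e-3, lambda_max = 1e12) {
  p <- as.numeric(start)
  r <- resid_fn(p)
  if (any(!is.finite(r))) {
    return(list(
      par = p, ssr = Inf, converged = FALSE, n_iter = 0L,
      message = "non-finite residuals at start"
    ))
  }
  ssr <- sum(r^2)
  lambda <- lambda0
  converged <- FALSE
  msg <- "iteration limit reached"
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jac_fn(p)
    if (any(!is.finite(J))) {
      converged <- FALSE
      msg <- "non-finite Jacobian; best-so-far parameters reported"
      break
    }
    g <- 2 * drop(crossprod(J, r))
    if (sqrt(sum(g^2)) < gtol) {
      converged <- TRUE
      msg <- "gradient norm below tolerance"
      break
    }
    A <- crossprod(J)
    dA <- pmax(diag(A), 1e-12)
    accepted <- FALSE
    saw_nonfinite <- FALSE
    while (lambda <= lambda_max) {
      step <- tryCatch(
        solve(A + lambda * diag(dA, nrow(A)), -crossprod(J, r)),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        p_new <- p + drop(step)
        r_new <- resid_fn(p_new)
        if (any(!is.finite(r_new))) saw_nonfinite <- TRUE
        if (all(is.finite(r_new))) {
          ssr_new <- sum(r_new^2)
          if (ssr_new <= ssr) {
            rel <- (ssr - ssr_new) / max(ssr, .Machine$double.xmin)
            p <- p_new
            r <- r_new
            ssr <- ssr_new
            lambda <- max(lambda / 10, 1e-15)
            accepted <- TRUE
            if (rel < ftol) {
              converged <- TRUE
              msg <- "relative SSR change below tolerance"
            }
            break
          }
        }
      }
      lambda <- lambda * 10
    }
    if (!accepted) {
      if (saw_nonfinite) {
        converged <- FALSE
        msg <- "non-finite residuals during iteration; best-so-far parameters reported"
      } else {
        converged <- TRUE # stalled: no downhill step exists at any damping
        msg <- "no further improvement possible"
      }
      break
    }
    if (converged) break
  }
  list(par = unname(p), ssr = ssr, converged = converged, n_iter = iter, message = msg)
}
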