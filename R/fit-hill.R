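# shared least-squares machinery -------------------------------------------

r_squared <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  ssr <- sum((obs - fitted)^2)
  if (sst == 0) return(if (ssr == 0) 1 else 0)
  1 - ssr / sst
}

# minimise ssr_fn over theta: Nelder-Mead exploration, BFGS polish.
# Returns par, value, convergence and hessian-based standard errors
# (local quadratic approximation; cov = 2 sigma^2 H^-1 for an SSR surface).
ls_minimise <- function(ssr_fn, starts, n_obs) {
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch({
      nm <- stats::optim(th0, ssr_fn, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
      stats::optim(nm$par, ssr_fn, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12))
    }, error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("least-squares optimisation failed from every start", call. = FALSE)
  k <- length(best$par)
  se <- rep(NA_real_, k)
  sigma2 <- best$value / max(n_obs - k, 1)
  H <- tryCatch(stats::optimHess(best$par, ssr_fn), error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se <- ifelse(dg >= 0, sqrt(dg), NA_real_)
    }
  }
  list(par = best$par, value = best$value, se = se,
       converged = best$convergence == 0)
}

# Hill fit -------------------------------------------------------------------

#' Fit the Hill equation to a saturation curve
#'
#' Least-squares estimation of `(P50, nH)` on the saturation scale, in
#' log-parameter space for positivity.  Starting values come from the
#' linearised Hill plot (logit saturation against log pressure).  The
#' fit is flagged inadequate when R-squared does not exceed 0.97, the
#' conventional adequacy threshold for oxygenation curves; flagged fits
#' are still returned, never dropped.
#'
#' @param curve a [saturation_curve()] with at least 5 points spanning
#'   the half-saturation midpoint.
#' @return An object of class `"hill_fit"`: list with `P50`, `nH`, their
#'   standard errors, `r2`, `adequate`, `fitted`, `curve` and
#'   `converged`.
#' @examples
#' cv <- simulate_curve(mwc_params(0.7e5, 1.6, 128.8), noise_sd = 0, seed = 1)
#' fit_hill(cv)
#' @export
fit_hill <- function(curve) {
  check_fit_curve(curve)
  p <- curve$pressures
  y <- curve$saturations
  use <- p > 0
  yc <- pmin(pmax(y[use], 1e-3), 1 - 1e-3)
  lin <- stats::lm(stats::qlogis(yc) ~ log(p[use]))
  nH0 <- unname(max(abs(stats::coef(lin)[2]), 0.2))
  P500 <- unname(exp(-stats::coef(lin)[1] / stats::coef(lin)[2]))
  if (!is.finite(P500) || P500 <= 0) P500 <- approx_p50(curve)
  ssr_fn <- function(th)
    sum((y - hill_saturation(p, exp(th[1]), exp(th[2])))^2)
  opt <- ls_minimise(ssr_fn, list(c(log(P500), log(nH0))), length(y))
  if (!opt$converged)
    stop("Hill fit did not converge; best SSR = ",
         format(opt$value), call. = FALSE)
  P50 <- exp(opt$par[1]); nH <- exp(opt$par[2])
  fitted <- hill_saturation(p, P50, nH)
  r2 <- r_squared(y, fitted)
  structure(list(P50 = P50, nH = nH,
                 se = c(P50 = P50 * opt$se[1], nH = nH * opt$se[2]),
                 r2 = r2, adequate = r2 > 0.97, fitted = fitted,
                 curve = curve, converged = opt$converged),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit of '%s': P50 = %.4g mmHg, nH = %.4g, R2 = %.4f%s\n",
              x$curve$curve_id, x$P50, x$nH, x$r2,
              if (x$adequate) "" else " (inadequate, R2 <= 0.97)"))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) c(P50 = object$P50, nH = object$nH)

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$curve$pressures else newdata
  hill_saturation(p, object$P50, object$nH)
}
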