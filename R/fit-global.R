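#' Global MWC fit of an effector curve family
#'
#' Simultaneously fits every curve of a family to the traditional MWC
#' isotherm with a single shared `(K_R, K_T)` pair and one apparent
#' allosteric constant `L_app` per curve.  This is the appropriate model
#' when an allosteric effector acts only on the T/R conformational
#' equilibrium: affinities are common to all curves, only `L` varies.
#'
#' The pooled sum of squared saturation residuals is minimised over
#' `(log K_R, s, log L_1, ..., log L_J)` with `K_T = K_R * exp(s)`,
#' `s >= 0`, so `c <= 1` holds by construction (T is the low-affinity
#' state).  Points are unweighted by default.  Optimisation uses
#' `L-BFGS-B` from a data-driven start (affinities bracketing the
#' observed per-curve midpoints; `L_j` from inverting the half-saturation
#' identity) plus jittered restarts, so the result is deterministic given
#' data, configuration and seed.  Standard errors come from the local
#' quadratic approximation of the SSR surface at the optimum and are
#' reported on the log scale (`se_log`) and, via the delta method, on
#' the natural scale (`se`).
#'
#' @param curves list of at least two [saturation_curve()] objects, each
#'   with at least 5 points; all in the same ligand units.
#' @param weights optional list of per-point weight vectors matching
#'   `curves`.
#' @param n_starts number of starts (1 data-driven + `n_starts - 1`
#'   jittered; default 5).
#' @param seed integer seed for the jitter (default 1).
#' @return An object of class `"mwc_global_fit"`: list with `K_R`,
#'   `K_T`, `c`, named vector `L_app`, `se`, `se_log`, `r2_per_curve`,
#'   `r2_overall`, `converged`, `ssr`, `curves` and `config`.
#' @examples
#' m <- effector_model(230.3, 9.6, 140.5, 4)
#' fam <- simulate_effector_family(1.5, 140, m, c(0, 10, 40, 160),
#'                                 noise_sd = 0, seed = 1)
#' global_fit(fam)
#' @export
global_fit <- function(curves, weights = NULL, n_starts = 5, seed = 1) {
  if (inherits(curves, "saturation_curve")) curves <- list(curves)
  if (length(curves) < 2)
    stop("global fit requires at least 2 curves", call. = FALSE)
  lapply(curves, check_fit_curve)
  J <- length(curves)
  ids <- vapply(seq_len(J), function(j) {
    id <- curves[[j]]$curve_id
    if (is.null(id) || !nzchar(id)) sprintf("curve_%d", j) else id
  }, character(1))
  p_all <- lapply(curves, function(cv) cv$pressures)
  y_all <- lapply(curves, function(cv) cv$saturations)
  if (is.null(weights)) weights <- lapply(p_all, function(p) rep(1, length(p)))
  ranges <- vapply(p_all, function(p) diff(range(p)) / max(p), numeric(1))
  if (max(vapply(p_all, max, numeric(1))) / min(vapply(p_all, max, numeric(1))) > 50)
    warning("curves span very different pressure ranges; check units")

  ssr_fn <- function(th) {
    K_R <- exp(th[1]); K_T <- K_R * exp(th[2])
    sum(vapply(seq_len(J), function(j) {
      prm <- mwc_params(exp(th[2 + j]), K_R, K_T)
      sum(weights[[j]] * (y_all[[j]] - mwc_saturation(p_all[[j]], prm))^2)
    }, numeric(1)))
  }

  p50s <- vapply(curves, approx_p50, numeric(1))
  K_R0 <- unname(stats::quantile(p50s, 0.25)) / 15
  K_T0 <- unname(stats::quantile(p50s, 0.75)) * 4
  L0 <- vapply(p50s, function(p50) {
    a <- p50 / K_R0; b <- p50 / K_T0
    L <- (1 + a)^3 * (a - 1) / ((1 + b)^3 * (1 - b))
    if (!is.finite(L) || L <= 0) 1e3 else L
  }, numeric(1))
  th0 <- c(log(K_R0), log(K_T0 / K_R0), log(L0))
  jitters <- with_seed(seed, lapply(seq_len(max(n_starts - 1, 0)), function(i)
    th0 + stats::rnorm(length(th0), 0, 0.3)))
  starts <- c(list(th0), lapply(jitters, function(th) {
    th[2] <- max(th[2], 0); th
  }))

  lower <- c(-50, 0, rep(-50, J))
  upper <- rep(50, J + 2)
  best <- NULL
  for (th in starts) {
    fit <- tryCatch(
      stats::optim(th, ssr_fn, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("global fit failed to converge from any start", call. = FALSE)
  if (best$convergence != 0)
    warning("global fit: optimiser reported non-convergence (code ",
            best$convergence, ")")

  th <- unname(best$par)
  K_R <- exp(th[1]); K_T <- K_R * exp(th[2])
  L_app <- exp(th[3:(J + 2)])
  names(L_app) <- ids

  n_obs <- sum(lengths(p_all))
  k <- length(th)
  sigma2 <- best$value / max(n_obs - k, 1)
  se_log <- rep(NA_real_, k)
  H <- tryCatch(stats::optimHess(th, ssr_fn), error = function(e) NULL)
  if (!is.null(H)) {
    cov <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(cov)) {
      dg <- diag(cov)
      se_log <- ifelse(dg >= 0, sqrt(dg), NA_real_)
    }
  }
  names(se_log) <- c("log_K_R", "s", paste0("log_L_", ids))
  se <- c(K_R = K_R * se_log[[1]],
          K_T = K_T * sqrt(se_log[[1]]^2 + se_log[[2]]^2),
          stats::setNames(L_app * se_log[-(1:2)], paste0("L_", ids)))

  fitted <- lapply(seq_len(J), function(j)
    mwc_saturation(p_all[[j]], mwc_params(L_app[j], K_R, K_T)))
  r2_per_curve <- vapply(seq_len(J), function(j)
    r_squared(y_all[[j]], fitted[[j]]), numeric(1))
  names(r2_per_curve) <- ids
  r2_overall <- r_squared(unlist(y_all), unlist(fitted))

  structure(list(K_R = K_R, K_T = K_T, c = K_R / K_T, L_app = L_app,
                 se = se, se_log = se_log,
                 r2_per_curve = r2_per_curve, r2_overall = r2_overall,
                 converged = best$convergence == 0, ssr = best$value,
                 fitted = fitted, curves = curves,
                 config = list(n_starts = n_starts, seed = seed)),
            class = "mwc_global_fit")
}

#' @export
print.mwc_global_fit <- function(x, ...) {
  cat(sprintf("Global MWC fit: %d curves, shared K_R = %.4g, K_T = %.4g mmHg (c = %.4g)\n",
              length(x$L_app), x$K_R, x$K_T, x$c))
  cat(sprintf("  overall R2 = %.4f%s\n", x$r2_overall,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  L_app per curve:\n")
  print(signif(x$L_app, 4))
  invisible(x)
}

#' @export
summary.mwc_global_fit <- function(object, ...) {
  effc <- vapply(object$curves, function(cv) cv$effector_conc, numeric(1))
  tab <- data.frame(curve_id = names(object$L_app),
                    effector_conc = effc,
                    L_app = unname(object$L_app),
                    se_L_app = unname(object$se[-(1:2)]),
                    r2 = unname(object$r2_per_curve))
  structure(list(K_R = object$K_R, K_T = object$K_T, c = object$c,
                 se = object$se[1:2], table = tab,
                 r2_overall = object$r2_overall,
                 converged = object$converged),
            class = "summary.mwc_global_fit")
}

#' @export
print.summary.mwc_global_fit <- function(x, ...) {
  cat("Global MWC fit with shared affinities\n")
  cat(sprintf("  K_R = %.4g +/- %.2g mmHg\n  K_T = %.4g +/- %.2g mmHg\n  c   = %.4g\n",
              x$K_R, x$se[["K_R"]], x$K_T, x$se[["K_T"]], x$c))
  cat(sprintf("  overall R2 = %.4f, converged: %s\n", x$r2_overall,
              x$converged))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mwc_global_fit <- function(object, ...)
  c(K_R = object$K_R, K_T = object$K_T,
    stats::setNames(object$L_app, paste0("L_", names(object$L_app))))

#' @export
fitted.mwc_global_fit <- function(object, ...) object$fitted

#' @export
residuals.mwc_global_fit <- function(object, ...) {
  lapply(seq_along(object$curves), function(j)
    object$curves[[j]]$saturations - object$fitted[[j]])
}

#' Predict saturations from a global MWC fit
#'
#' @param object an `mwc_global_fit`.
#' @param newdata optional data frame with columns `curve_id` and
#'   `po2_mmHg`; defaults to the fitted pressures.
#' @param ... unused.
#' @return Numeric vector of predicted saturations.
#' @export
predict.mwc_global_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(unlist(object$fitted))
  stopifnot(all(c("curve_id", "po2_mmHg") %in% names(newdata)))
  vapply(seq_len(nrow(newdata)), function(i) {
    id <- newdata$curve_id[i]
    if (!id %in% names(object$L_app))
      stop("unknown curve_id: ", id, call. = FALSE)
    mwc_saturation(newdata$po2_mmHg[i],
                   mwc_params(object$L_app[[id]], object$K_R, object$K_T))
  }, numeric(1))
}

#' @export
plot.mwc_global_fit <- function(x, ...) {
  J <- length(x$curves)
  cols <- grDevices::hcl.colors(J, "Dark 2")
  all_p <- unlist(lapply(x$curves, function(cv) cv$pressures))
  graphics::plot(NA, xlim = range(all_p[all_p > 0]), ylim = c(0, 1),
                 log = "x", xlab = "pO2 (mmHg)",
                 ylab = "fractional saturation", ...)
  for (j in seq_len(J)) {
    cv <- x$curves[[j]]
    graphics::points(cv$pressures, cv$saturations, col = cols[j], pch = 16,
                     cex = 0.6)
    pg <- exp(seq(log(min(cv$pressures[cv$pressures > 0])),
                  log(max(cv$pressures)), length.out = 100))
    graphics::lines(pg, mwc_saturation(
      pg, mwc_params(x$L_app[j], x$K_R, x$K_T)), col = cols[j])
  }
  graphics::legend("topleft", legend = names(x$L_app), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}
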