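#' Fit the effector linkage relation to apparent allosteric constants
#'
#' Least-squares fit of the non-exclusive binding relation
#' `L_app = L0 * ((1 + I/KI_T) / (1 + I/KI_R))^n` to a set of
#' `(concentration, L_app)` pairs, typically the per-curve constants
#' from [global_fit()].  The fit runs on `log L_app` over
#' `(log L0, log KI_T, log KI_R)` with the site exponent held fixed
#' (4 for protons or CO2 on a tetramer; 1 for single-site
#' organophosphates such as 2,3-BPG).
#'
#' When all `L_app` values are (numerically) equal, there is no linkage
#' signal: the function returns `d = 1` with `L0` equal to that constant
#' and flags the affinities unidentifiable rather than fitting.
#'
#' @param l_apps positive apparent allosteric constants.
#' @param concs matching distinct nonnegative effector concentrations
#'   (at least 3).
#' @param n_sites fixed integer site exponent, default 4.
#' @param seed integer seed for jittered restarts (default 1).
#' @return An object of class `"effector_fit"`: list with `model` (an
#'   [effector_model()]), `se_log` standard errors, `r2` (on the log
#'   `L_app` scale), `unidentifiable` flag, the data, and `converged`.
#' @examples
#' m <- effector_model(230.3, 9.6, 140.5, 4)
#' I <- c(0, 2, 8, 32, 128, 512)
#' fit_lapp(lapp_effector(I, m), I)
#' @export
fit_lapp <- function(l_apps, concs, n_sites = 4, seed = 1) {
  stopifnot(is.numeric(l_apps), is.numeric(concs),
            length(l_apps) == length(concs))
  if (length(l_apps) < 3)
    stop("effector linkage fit requires at least 3 points", call. = FALSE)
  if (any(!is.finite(concs)) || any(concs < 0) || anyDuplicated(concs))
    stop("'concs' must be distinct, finite and >= 0", call. = FALSE)
  if (any(!is.finite(l_apps)) || any(l_apps <= 0))
    stop("'l_apps' must be finite and > 0", call. = FALSE)
  ll <- log(l_apps)
  if (stats::sd(ll) < 1e-10) {
    med <- stats::median(concs[concs > 0])
    return(structure(list(
      model = effector_model(exp(mean(ll)), med, med, n_sites),
      se_log = c(log_L0 = 0, log_KI_T = NA_real_, log_KI_R = NA_real_),
      r2 = 1, unidentifiable = TRUE, l_apps = l_apps, concs = concs,
      converged = TRUE), class = "effector_fit"))
  }
  ssr_fn <- function(th) {
    m <- effector_model(exp(th[1]), exp(th[2]), exp(th[3]), n_sites)
    sum((ll - log(lapp_effector(concs, m)))^2)
  }
  pos <- concs[concs > 0]
  L0g <- unname(l_apps[which.min(concs)])
  th0 <- c(log(L0g), log(stats::median(pos) / 10), log(stats::median(pos) * 10))
  jit <- with_seed(seed, lapply(1:4, function(i)
    th0 + stats::rnorm(3, 0, 0.5)))
  opt <- ls_minimise(ssr_fn, c(list(th0), jit), length(l_apps))
  model <- effector_model(exp(opt$par[1]), exp(opt$par[2]),
                          exp(opt$par[3]), n_sites)
  se_log <- opt$se
  names(se_log) <- c("log_L0", "log_KI_T", "log_KI_R")
  structure(list(model = model, se_log = se_log,
                 r2 = r_squared(ll, log(lapp_effector(concs, model))),
                 unidentifiable = FALSE, l_apps = l_apps, concs = concs,
                 converged = opt$converged),
            class = "effector_fit")
}

#' @export
print.effector_fit <- function(x, ...) {
  cat("Effector linkage fit (non-exclusive binding)\n")
  if (x$unidentifiable) {
    cat(sprintf("  L_app constant at %.4g: d = 1, affinities unidentifiable\n",
                x$model$L0))
    return(invisible(x))
  }
  cat(sprintf("  L0   = %.6g\n  KI_T = %.6g\n  KI_R = %.6g\n  d    = %.4g\n  sites = %d, R2(log L) = %.4f\n",
              x$model$L0, x$model$KI_T, x$model$KI_R, x$model$d,
              x$model$n_sites, x$r2))
  invisible(x)
}

#' @export
coef.effector_fit <- function(object, ...)
  c(L0 = object$model$L0, KI_T = object$model$KI_T,
    KI_R = object$model$KI_R, d = object$model$d)

#' @export
predict.effector_fit <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$concs else newdata
  lapp_effector(I, object$model)
}

#' @export
plot.effector_fit <- function(x, ...) {
  graphics::plot(x$concs, x$l_apps, log = "y", pch = 16,
                 xlab = "effector concentration", ylab = "L_app", ...)
  Ig <- seq(min(x$concs), max(x$concs), length.out = 200)
  graphics::lines(Ig, lapp_effector(Ig, x$model))
  invisible(x)
}
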