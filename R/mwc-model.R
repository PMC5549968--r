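#' Construct an MWC parameter set
#'
#' Bundles the three elementary parameters of the concerted two-state
#' (Monod-Wyman-Changeux) model for a tetrameric binding protein: the
#' conformational equilibrium constant `L` = \[T\]/\[R\] in the absence of
#' ligand, and the ligand affinities `K_R` and `K_T` of the relaxed and
#' tense quaternary conformations.  The relative affinity `c = K_R / K_T`
#' is always derived from the stored affinities, never stored itself.
#'
#' Pressures are in mmHg (identical to Torr); no unit conversion is
#' performed anywhere in the package.
#'
#' @param L conformational equilibrium constant, dimensionless, `>= 0`.
#'   `L = 0` is accepted as the pure-R limit.
#' @param K_R affinity of the R state, mmHg, `> 0`.
#' @param K_T affinity of the T state, mmHg, `> 0`.
#' @return An object of class `"mwc_params"`: a list with elements `L`,
#'   `K_R`, `K_T` and derived `c`.
#' @examples
#' hb <- mwc_params(L = 0.7e5, K_R = 1.6, K_T = 128.8)
#' hb$c
#' @export
mwc_params <- function(L, K_R, K_T) {
  stopifnot(is.numeric(L), is.numeric(K_R), is.numeric(K_T),
            length(L) == 1L, length(K_R) == 1L, length(K_T) == 1L)
  if (!is.finite(L) || L < 0)
    stop("'L' must be finite and >= 0", call. = FALSE)
  if (!is.finite(K_R) || K_R <= 0)
    stop("'K_R' must be finite and > 0", call. = FALSE)
  if (!is.finite(K_T) || K_T <= 0)
    stop("'K_T' must be finite and > 0", call. = FALSE)
  structure(list(L = unname(L), K_R = unname(K_R), K_T = unname(K_T),
                 c = unname(K_R / K_T)),
            class = "mwc_params")
}

#' @export
print.mwc_params <- function(x, ...) {
  cat("MWC parameter set\n")
  cat(sprintf("  L   = %.6g\n  K_R = %.6g mmHg\n  K_T = %.6g mmHg\n  c   = %.6g\n",
              x$L, x$K_R, x$K_T, x$c))
  invisible(x)
}

as_mwc_params <- function(x) {
  if (inherits(x, "mwc_params")) return(x)
  if (is.list(x) && all(c("L", "K_R", "K_T") %in% names(x)))
    return(mwc_params(x$L, x$K_R, x$K_T))
  stop("expected an 'mwc_params' object", call. = FALSE)
}

#' MWC fractional saturation
#'
#' Evaluates the traditional form of the MWC binding isotherm for a
#' tetramer,
#' \deqn{\bar{Y} = \frac{\alpha(1+\alpha)^3 + L\beta(1+\beta)^3}
#'                      {(1+\alpha)^4 + L(1+\beta)^4},}
#' with \eqn{\alpha = p/K_R} and \eqn{\beta = p/K_T}.  The function is
#' strictly increasing in `p`, equals 0 at `p = 0` and tends to 1 as
#' `p` grows.
#'
#' @param p ligand pressure(s), mmHg, `>= 0`.  Vectorised.
#' @param params an [mwc_params()] object.
#' @return Fractional saturation in `[0, 1]`, same length as `p`.
#' @examples
#' mwc_saturation(27.6, mwc_params(0.7e5, 1.6, 128.8))
#' @export
mwc_saturation <- function(p, params) {
  params <- as_mwc_params(params)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("'p' must be finite and >= 0", call. = FALSE)
  a <- p / params$K_R
  b <- p / params$K_T
  (a * (1 + a)^3 + params$L * b * (1 + b)^3) /
    ((1 + a)^4 + params$L * (1 + b)^4)
}

#' Hill fractional saturation
#'
#' The empirical all-or-none Hill isotherm
#' \eqn{Y = p^{n_H} / (p^{n_H} + P_{50}^{n_H})}.
#'
#' @param p ligand pressure(s), mmHg, `>= 0`.  Vectorised.
#' @param P50 pressure at half saturation, mmHg, `> 0`.
#' @param nH Hill coefficient, dimensionless, `> 0`.
#' @return Fractional saturation in `[0, 1]`.
#' @examples
#' hill_saturation(20, P50 = 10, nH = 2)  # 0.8
#' @export
hill_saturation <- function(p, P50, nH) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop("'p' must be finite and >= 0", call. = FALSE)
  if (!is.numeric(P50) || length(P50) != 1L || !is.finite(P50) || P50 <= 0)
    stop("'P50' must be a single finite value > 0", call. = FALSE)
  if (!is.numeric(nH) || length(nH) != 1L || !is.finite(nH) || nH <= 0)
    stop("'nH' must be a single finite value > 0", call. = FALSE)
  # work on the log scale to avoid overflow for large nH * log(p)
  r <- exp(nH * (log(p) - log(P50)))
  ifelse(p == 0, 0, r / (r + 1))
}

#' Half-saturation pressure of the MWC isotherm
#'
#' Locates the unique pressure at which [mwc_saturation()] equals 1/2 by
#' bracketed root search on the monotone saturation function, followed by
#' Newton polish so that `|Y(P50) - 1/2| <= 1e-10`.
#'
#' @param params an [mwc_params()] object.
#' @return The half-saturation pressure, mmHg.
#' @examples
#' p50_mwc(mwc_params(0.7e5, 1.6, 128.8))  # ~27.6 mmHg
#' @export
p50_mwc <- function(params) {
  params <- as_mwc_params(params)
  if (params$L == 0) return(params$K_R)
  lo <- min(params$K_R, params$K_T) * 1e-6
  hi <- max(params$K_R, params$K_T) * 1e6
  f <- function(p) mwc_saturation(p, params) - 0.5
  p50 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  # secant polish on the bisection result
  for (i in 1:8) {
    r <- f(p50)
    if (abs(r) <= 1e-12) break
    h <- p50 * 1e-7
    dr <- (f(p50 + h) - f(p50 - h)) / (2 * h)
    step <- r / dr
    if (!is.finite(step)) break
    p50 <- p50 - step
  }
  stopifnot(abs(mwc_saturation(p50, params) - 0.5) <= 1e-10)
  p50
}

#' Hill coefficient at half-saturation of the MWC isotherm
#'
#' Applies the Hill transformation to the MWC isotherm: the slope
#' \eqn{n_H = d\log(\bar{Y}/(1-\bar{Y})) / d\log p} evaluated at the
#' half-saturation pressure.  The derivative is taken by central finite
#' difference on `log p` with step `1e-4` (the base of the logarithm
#' cancels).  The result depends only on `(L, c)`, not on the pressure
#' scale, and lies in `[1, 4]` for a tetramer.
#'
#' @param params an [mwc_params()] object.
#' @return The Hill coefficient at half saturation, dimensionless.
#' @examples
#' hill_coefficient_mwc(mwc_params(0.7e5, 1.6, 128.8))  # ~2.73
#' @export
hill_coefficient_mwc <- function(params) {
  params <- as_mwc_params(params)
  if (params$L == 0) return(1)
  lp <- log(p50_mwc(params))
  h <- 1e-4
  y1 <- mwc_saturation(exp(lp + h), params)
  y0 <- mwc_saturation(exp(lp - h), params)
  (log(y1 / (1 - y1)) - log(y0 / (1 - y0))) / (2 * h)
}

#' Hill-coefficient profile over the allosteric constant
#'
#' Evaluates the half-saturation Hill coefficient along a grid of `L`
#' values at fixed relative affinity `c`.  The profile is bell-shaped in
#' `log L` with its maximum where `L * c^2 = 1`; at `c = 1` it is flat at
#' 1 (no cooperativity).  The computation is scale-free, so an arbitrary
#' `K_R = 1` mmHg is used internally.
#'
#' @param c relative affinity `K_R / K_T`, in `(0, 1]`.
#' @param L_grid positive numeric vector of allosteric constants.
#' @return A data frame with columns `L` and `nH`.
#' @examples
#' prof <- nh_profile_over_L(0.01, 10^seq(0, 8, by = 0.5))
#' prof$L[which.max(prof$nH)]  # ~1e4
#' @export
nh_profile_over_L <- function(c, L_grid) {
  stopifnot(is.numeric(c), length(c) == 1L, is.numeric(L_grid))
  if (!is.finite(c) || c <= 0 || c > 1)
    stop("'c' must be in (0, 1]", call. = FALSE)
  if (any(!is.finite(L_grid)) || any(L_grid <= 0))
    stop("'L_grid' must be positive", call. = FALSE)
  nH <- vapply(L_grid, function(L)
    hill_coefficient_mwc(mwc_params(L, 1, 1 / c)), numeric(1))
  data.frame(L = L_grid, nH = nH)
}

#' Construct an effector linkage model
#'
#' Parameters of the non-exclusive effector binding model, in which an
#' allosteric effector I binds both quaternary conformations (with
#' dissociation constants `KI_T` and `KI_R`) and shifts the apparent
#' conformational equilibrium
#' \deqn{L_{app} = L_0 \left(\frac{1 + [I]/K_I^T}{1 + [I]/K_I^R}\right)^{n},}
#' where `n` is the number of effector sites (4 for protons or CO2 on
#' tetrameric hemoglobin; 1 for single-site organophosphates such as
#' 2,3-BPG).  An inhibitor (`KI_T < KI_R`, i.e. tighter binding to T)
#' makes `L_app` increase with effector concentration.
#'
#' @param L0 allosteric constant at zero effector, dimensionless `>= 0`.
#' @param KI_T effector dissociation constant of the T state (effector
#'   concentration units; nM, mM or Torr depending on the effector).
#' @param KI_R effector dissociation constant of the R state, same units.
#' @param n_sites integer number of effector sites, one of 1, 2, 3, 4.
#' @return An object of class `"effector_model"` with derived
#'   `d = KI_R / KI_T`.
#' @examples
#' effector_model(L0 = 230.3, KI_T = 9.6, KI_R = 140.5, n_sites = 4)
#' @export
effector_model <- function(L0, KI_T, KI_R, n_sites = 4) {
  stopifnot(is.numeric(L0), is.numeric(KI_T), is.numeric(KI_R))
  if (!is.finite(L0) || L0 < 0)
    stop("'L0' must be finite and >= 0", call. = FALSE)
  if (!is.finite(KI_T) || KI_T <= 0 || !is.finite(KI_R) || KI_R <= 0)
    stop("'KI_T' and 'KI_R' must be finite and > 0", call. = FALSE)
  if (!n_sites %in% 1:4)
    stop("'n_sites' must be one of 1, 2, 3, 4", call. = FALSE)
  structure(list(L0 = unname(L0), KI_T = unname(KI_T), KI_R = unname(KI_R),
                 n_sites = as.integer(n_sites), d = unname(KI_R / KI_T)),
            class = "effector_model")
}

#' @export
print.effector_model <- function(x, ...) {
  cat("Effector linkage model (non-exclusive binding)\n")
  cat(sprintf("  L0    = %.6g\n  KI_T  = %.6g\n  KI_R  = %.6g\n  d     = %.6g\n  sites = %d\n",
              x$L0, x$KI_T, x$KI_R, x$d, x$n_sites))
  invisible(x)
}

#' Apparent allosteric constant at a given effector concentration
#'
#' Evaluates the non-exclusive binding linkage relation of
#' [effector_model()].
#'
#' @param I effector concentration(s), `>= 0`, in the model's units.
#'   Vectorised.
#' @param model an [effector_model()] object.
#' @return `L_app` value(s), dimensionless.
#' @examples
#' m <- effector_model(230.3, 9.6, 140.5, 4)
#' lapp_effector(c(0, 9.6), m)
#' @export
lapp_effector <- function(I, model) {
  stopifnot(inherits(model, "effector_model"))
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0))
    stop("'I' must be finite and >= 0", call. = FALSE)
  model$L0 * ((1 + I / model$KI_T) / (1 + I / model$KI_R))^model$n_sites
}
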