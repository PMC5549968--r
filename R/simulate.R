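# run expr with a reproducible RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# pressure at which the MWC isotherm reaches saturation y
pressure_at_saturation <- function(y, params) {
  params <- as_mwc_params(params)
  lo <- min(params$K_R, params$K_T) * 1e-8
  hi <- max(params$K_R, params$K_T) * 1e8
  stats::uniroot(function(p) mwc_saturation(p, params) - y,
                 c(lo, hi), tol = 1e-12)$root
}

# default simulation grid: n log-spaced pressures covering Y in [ylo, yhi]
default_pressure_grid <- function(params, n = 30, ylo = 0.02, yhi = 0.98) {
  p_lo <- pressure_at_saturation(ylo, params)
  p_hi <- pressure_at_saturation(yhi, params)
  exp(seq(log(p_lo), log(p_hi), length.out = n))
}

#' Simulate one MWC saturation curve
#'
#' Forward-simulates the MWC isotherm on a pressure grid and adds
#' homoscedastic Gaussian observational noise on the saturation scale.
#' Noisy values are deliberately not clipped to `[0, 1]`, so the noise
#' stays unbiased.  The generating parameters are attached as attribute
#' `"truth"` so recovery tests can compare against ground truth.
#'
#' @param params an [mwc_params()] object.
#' @param pressures optional pressure grid; by default `n` log-spaced
#'   points covering saturations 0.02 to 0.98.
#' @param n number of grid points when `pressures` is `NULL`.
#' @param noise_sd Gaussian noise standard deviation on the saturation
#'   scale (default 0.005, typical of high-quality oxygenation data).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param curve_id,effector_name,effector_conc,conc_unit,species curve
#'   metadata, see [saturation_curve()].
#' @return A [saturation_curve()] with attribute `"truth"` (list with
#'   `params` and `noise_sd`).
#' @examples
#' cv <- simulate_curve(mwc_params(0.7e5, 1.6, 128.8), seed = 1)
#' @export
simulate_curve <- function(params, pressures = NULL, n = 30,
                           noise_sd = 0.005, seed = NULL,
                           curve_id = "sim", effector_name = "",
                           effector_conc = NA_real_, conc_unit = "",
                           species = NA_character_) {
  params <- as_mwc_params(params)
  stopifnot(noise_sd >= 0)
  if (is.null(pressures)) pressures <- default_pressure_grid(params, n)
  y <- mwc_saturation(pressures, params)
  if (noise_sd > 0)
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  # keep the curve constructible under extreme noise draws
  y <- pmin(pmax(y, -0.05), 1.05)
  cv <- saturation_curve(curve_id, pressures, y,
                         effector_name = effector_name,
                         effector_conc = effector_conc,
                         conc_unit = conc_unit, species = species)
  attr(cv, "truth") <- list(params = params, noise_sd = noise_sd)
  cv
}

#' Simulate a family of effector-modulated curves
#'
#' Generates one curve per effector concentration, all sharing `K_R` and
#' `K_T`; the allosteric constant of curve `j` is
#' `lapp_effector(concs[j], model)`.  This emulates a physiological
#' dataset in which an allosteric effector acts only on the T/R
#' conformational equilibrium.
#'
#' @param K_R,K_T shared state affinities, mmHg.
#' @param model an [effector_model()] giving the L modulation.
#' @param concs distinct nonnegative effector concentrations.
#' @param noise_sd,seed see [simulate_curve()]; curve `j` uses seed
#'   `seed + j` so families are reproducible point-wise.
#' @param effector_name,conc_unit metadata applied to every curve.
#' @param n points per curve.
#' @return A named list of [saturation_curve()] objects, each with a
#'   `"truth"` attribute recording the concentration and true `L`.
#' @examples
#' m <- effector_model(230.3, 9.6, 140.5, 4)
#' fam <- simulate_effector_family(1.5, 140, m, c(0, 5, 20, 80), seed = 1)
#' @export
simulate_effector_family <- function(K_R, K_T, model, concs,
                                     noise_sd = 0.005, seed = NULL,
                                     effector_name = "effector",
                                     conc_unit = "", n = 30) {
  stopifnot(inherits(model, "effector_model"))
  if (any(!is.finite(concs)) || any(concs < 0))
    stop("'concs' must be finite and >= 0", call. = FALSE)
  if (anyDuplicated(concs))
    stop("'concs' must be distinct", call. = FALSE)
  curves <- lapply(seq_along(concs), function(j) {
    L <- lapp_effector(concs[j], model)
    params <- mwc_params(L, K_R, K_T)
    cv <- simulate_curve(params, n = n, noise_sd = noise_sd,
                         seed = if (is.null(seed)) NULL else seed + j,
                         curve_id = sprintf("%s_%g", effector_name, concs[j]),
                         effector_name = effector_name,
                         effector_conc = concs[j], conc_unit = conc_unit)
    attr(cv, "truth")$conc <- concs[j]
    attr(cv, "truth")$L <- L
    cv
  })
  names(curves) <- vapply(curves, function(cv) cv$curve_id, character(1))
  curves
}
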