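# Shared fixtures and independent oracles.

# human hemoglobin physiological triple (reference table row 14)
human_params <- function() mwc_params(L = 0.7e5, K_R = 1.6, K_T = 128.8)

# compound parameters forward-built from a triple
forward_compounds <- function(params) {
  compound_params(lkr4 = params$L * params$K_R^4,
                  lc4 = params$L * params$c^4,
                  p50 = p50_mwc(params))
}

# Independent brute-force TES oracle.  The first two equations are
# substituted exactly (L = lkr4 / K_R^4, K_T from the compound ratio);
# the half-saturation residual of the ORIGINAL MWC isotherm is then
# scanned on a dense log-K_R grid and sign changes are bisected.  The
# production quartic reduction is never touched.
bf_solve_tes <- function(cp, n_grid = 2000) {
  K_T <- (cp$lkr4 / cp$lc4)^0.25
  lkr <- exp(seq(log(cp$p50) - 12, log(cp$p50) + 12, length.out = n_grid))
  resid_at <- function(K_R) {
    L <- cp$lkr4 / K_R^4
    mwc_saturation(cp$p50, mwc_params(L, K_R, K_T)) - 0.5
  }
  r <- vapply(lkr, resid_at, numeric(1))
  flips <- which(r[-1] * r[-n_grid] < 0)
  roots <- vapply(flips, function(i)
    stats::uniroot(resid_at, c(lkr[i], lkr[i + 1]), tol = 1e-13)$root,
    numeric(1))
  sort(roots)
}

# random valid generating triple with c in [1e-3, 0.5], L in [1, 1e9]
random_triple <- function() {
  c_val <- exp(stats::runif(1, log(1e-3), log(0.5)))
  L <- exp(stats::runif(1, log(1), log(1e9)))
  K_R <- exp(stats::runif(1, log(0.1), log(50)))
  mwc_params(L, K_R, K_R / c_val)
}

# half-saturation slope by an independent route: analytic chain rule on
# dY/dp (central difference on p itself, not on log p as production does)
nh_slope_oracle <- function(params) {
  p50 <- p50_mwc(params)
  h <- p50 * 1e-6
  dYdp <- (mwc_saturation(p50 + h, params) -
             mwc_saturation(p50 - h, params)) / (2 * h)
  # d log(Y/(1-Y))/d log p = p / (Y (1-Y)) * dY/dp; Y = 1/2 at p50
  p50 / 0.25 * dYdp
}
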