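#' Construct a compound parameter set
#'
#' The identifiable compound parameters of a single tetramer saturation
#' curve: `lkr4` = L*K_R^4 (mmHg^4), `lc4` = L*c^4 (dimensionless) and
#' the half-saturation pressure `p50` (mmHg), with optional first-order
#' uncertainties.  These three quantities form the input of the
#' three-equation-system solver [solve_tes()].
#'
#' @param lkr4,lc4,p50 positive compound parameter values.
#' @param d_lkr4,d_lc4,d_p50 optional nonnegative uncertainties.
#' @return An object of class `"compound_params"`.
#' @examples
#' compound_params(lkr4 = 458752, lc4 = 1.667e-3, p50 = 27.58)
#' @export
compound_params <- function(lkr4, lc4, p50,
                            d_lkr4 = 0, d_lc4 = 0, d_p50 = 0) {
  vals <- c(lkr4 = lkr4, lc4 = lc4, p50 = p50)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("'lkr4', 'lc4' and 'p50' must be finite and > 0", call. = FALSE)
  dels <- c(d_lkr4 = d_lkr4, d_lc4 = d_lc4, d_p50 = d_p50)
  if (any(!is.finite(dels)) || any(dels < 0))
    stop("uncertainties must be finite and >= 0", call. = FALSE)
  structure(list(lkr4 = unname(lkr4), lc4 = unname(lc4), p50 = unname(p50),
                 d_lkr4 = unname(d_lkr4), d_lc4 = unname(d_lc4),
                 d_p50 = unname(d_p50)),
            class = "compound_params")
}

#' T-state affinity implied by the compound parameters
#'
#' `K_T = (lkr4 / lc4)^(1/4)` is an exact algebraic identity: because
#' `lkr4 / lc4 = K_T^4`, the T-state affinity is determined unequivocally
#' by the two compound parameters, independently of which root of the
#' three-equation system is later selected.
#'
#' @param lkr4 L*K_R^4, mmHg^4, `> 0`.
#' @param lc4 L*c^4, dimensionless, `> 0`.
#' @return `K_T` in mmHg.
#' @examples
#' kt_from_compounds(0.7e5 * 1.6^4, 0.7e5 * (1.6 / 128.8)^4)  # 128.8
#' @export
kt_from_compounds <- function(lkr4, lc4) {
  if (!is.numeric(lkr4) || !is.numeric(lc4) ||
      any(!is.finite(lkr4)) || any(!is.finite(lc4)) ||
      any(lkr4 <= 0) || any(lc4 <= 0))
    stop("'lkr4' and 'lc4' must be finite and > 0", call. = FALSE)
  (lkr4 / lc4)^0.25
}

#' Classify a three-equation-system root
#'
#' Labels a parameter triple as physiologically sound or not, following
#' the observation that for hemoglobin the sound solution sets have large
#' `L` (1e4-1e9) and small `c` (1e-2-1e-3), while the spurious mirror
#' roots cluster around `L ~ 1` with `c` in 0.1-0.3.  The default cut
#' points sit between those ranges with wide margin and are configurable.
#'
#' @param root an [mwc_params()] object.
#' @param L_min physiological label requires `L > L_min` (default 1e2).
#' @param c_max physiological label requires `c < c_max` (default 0.05).
#' @return One of `"physiological"`, `"non_physiological"`,
#'   `"degenerate"` (the latter when `c` is within 1e-6 of 1).
#' @examples
#' classify_root(mwc_params(0.7e5, 1.6, 128.8))
#' @export
classify_root <- function(root, L_min = 1e2, c_max = 0.05) {
  root <- as_mwc_params(root)
  if (abs(root$c - 1) < 1e-6) return("degenerate")
  if (root$L > L_min && root$c < c_max) "physiological" else "non_physiological"
}

#' First-order propagation of input uncertainties
#'
#' Propagates uncertainties through a scalar function by the linear
#' expansion \eqn{\Delta f = \sum_i |\partial f/\partial x_i| \Delta x_i},
#' with the partial derivatives obtained by central finite difference
#' (relative step 1e-5).  Absolute values are applied so that partials of
#' opposite sign do not cancel.  `method = "quadrature"` instead returns
#' the root-sum-square combination.
#'
#' @param fn function of a numeric vector returning one finite number.
#' @param x numeric vector of input values.
#' @param dx nonnegative uncertainties, same length as `x`.
#' @param method `"absolute"` (linear sum, default) or `"quadrature"`.
#' @return A single nonnegative uncertainty.
#' @examples
#' propagate_errors(function(v) v[1] + v[2], c(1, 2), c(0.1, 0.2))  # 0.3
#' @export
propagate_errors <- function(fn, x, dx, method = c("absolute", "quadrature")) {
  method <- match.arg(method)
  stopifnot(is.function(fn), is.numeric(x), is.numeric(dx),
            length(x) == length(dx))
  if (any(!is.finite(x)) || any(!is.finite(dx)) || any(dx < 0))
    stop("'x' must be finite and 'dx' finite and >= 0", call. = FALSE)
  partials <- vapply(seq_along(x), function(i) {
    h <- 1e-5 * max(abs(x[i]), 1e-12)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    d <- (fn(xp) - fn(xm)) / (2 * h)
    if (!is.finite(d))
      stop(sprintf("non-finite partial derivative in coordinate %d", i),
           call. = FALSE)
    d
  }, numeric(1))
  if (method == "absolute") sum(abs(partials) * dx)
  else sqrt(sum((partials * dx)^2))
}

#' Solve the three-equation system for the elementary MWC parameters
#'
#' Recovers the elementary parameter triples `(L, K_R, K_T)` compatible
#' with a curve's compound parameters.  The system is
#' `y1 = L*K_R^4`, `y2 = L*c^4`, and the half-saturation condition
#' `Y(P50) = 1/2` of the MWC isotherm.
#'
#' `K_T` follows exactly from [kt_from_compounds()].  Substituting
#' `L = lkr4 / K_R^4` into the half-saturation identity
#' `(1+a)^3 (a-1) = L (1+b)^3 (1-b)` (with `a = P50/K_R`,
#' `b = P50/K_T`) reduces the remaining problem to the quartic
#' \deqn{(1 - D)\,\alpha^4 + 2\alpha^3 - 2\alpha - 1 = 0, \qquad
#'       D = \frac{(1+\beta)^3 (1-\beta)\, y_1}{P_{50}^4},}
#' in `alpha = P50 / K_R`, solved numerically with [stats::polyroot()].
#' Real positive roots (imaginary part below `1e-8` relative, duplicates
#' merged at `1e-6` relative) give `K_R = P50 / alpha` and
#' `L = lkr4 / K_R^4`; each candidate is verified against all three
#' original equations (max relative residual `1e-8`) and classified with
#' [classify_root()].  Forward-generated systems typically yield two such
#' roots: the generating ("physiological") triple and a spurious mirror
#' with `L ~ 1`.  Both share the same `K_T`.
#'
#' When input uncertainties are present, each root's `(L, K_R, K_T)`
#' uncertainties are obtained by applying [propagate_errors()] to the
#' composed solver.
#'
#' @param cp a [compound_params()] object.
#' @param L_min,c_max classification thresholds, see [classify_root()].
#' @return An object of class `"tes_solution"`: a list with `roots` (a
#'   list of accepted roots, each carrying `params`, `label`,
#'   `residuals`, `nH` and optional `uncertainties`), `k_t`,
#'   `all_quartic_roots` (complex, diagnostic), `n_discarded` and the
#'   input `cp`.  Roots are sorted by ascending `K_R`.
#' @examples
#' cp <- compound_params(0.7e5 * 1.6^4, 0.7e5 * (1.6 / 128.8)^4, 27.577)
#' solve_tes(cp)
#' @export
solve_tes <- function(cp, L_min = 1e2, c_max = 0.05) {
  stopifnot(inherits(cp, "compound_params"))
  k_t <- kt_from_compounds(cp$lkr4, cp$lc4)
  beta <- cp$p50 / k_t
  D <- (1 + beta)^3 * (1 - beta) * cp$lkr4 / cp$p50^4
  # ascending coefficients of (1-D) a^4 + 2 a^3 + 0 a^2 - 2 a - 1
  coefs <- c(-1, -2, 0, 2, 1 - D)
  while (length(coefs) > 1 && coefs[length(coefs)] == 0)
    coefs <- coefs[-length(coefs)]
  qroots <- polyroot(coefs)
  real_pos <- Re(qroots[abs(Im(qroots)) <= 1e-8 * pmax(Mod(qroots), 1e-300) &
                          Re(qroots) > 0])
  real_pos <- sort(real_pos)
  if (length(real_pos) > 1) {   # merge near-duplicates (relative 1e-6)
    keep <- c(TRUE, diff(real_pos) / real_pos[-1] > 1e-6)
    real_pos <- real_pos[keep]
  }
  n_discarded <- 0L
  roots <- list()
  for (alpha in real_pos) {
    K_R <- cp$p50 / alpha
    L <- cp$lkr4 / K_R^4
    if (!is.finite(L) || L < 0 || !is.finite(K_R) || K_R <= 0) {
      n_discarded <- n_discarded + 1L
      next
    }
    params <- mwc_params(L, K_R, k_t)
    res <- c(
      lkr4 = abs(L * K_R^4 - cp$lkr4) / cp$lkr4,
      lc4  = abs(L * params$c^4 - cp$lc4) / cp$lc4,
      half = abs(mwc_saturation(cp$p50, params) - 0.5) / 0.5
    )
    if (max(res) > 1e-8) {
      n_discarded <- n_discarded + 1L
      next
    }
    roots <- c(roots, list(list(
      params = params,
      label = classify_root(params, L_min = L_min, c_max = c_max),
      residuals = res,
      nH = hill_coefficient_mwc(params)
    )))
  }
  ord <- order(vapply(roots, function(r) r$params$K_R, numeric(1)))
  roots <- roots[ord]
  if (any(c(cp$d_lkr4, cp$d_lc4, cp$d_p50) > 0) && length(roots) > 0) {
    roots <- lapply(seq_along(roots), function(i) {
      r <- roots[[i]]
      r$uncertainties <- tes_root_uncertainty(cp, i)
      r
    })
  }
  structure(list(roots = roots, k_t = k_t, all_quartic_roots = qroots,
                 n_discarded = n_discarded, cp = cp),
            class = "tes_solution")
}

# uncertainty of root i's (L, K_R, K_T) by propagating (lkr4, lc4, p50)
# through the composed solver; roots matched by sorted-K_R rank
tes_root_uncertainty <- function(cp, i) {
  x <- c(cp$lkr4, cp$lc4, cp$p50)
  dx <- c(cp$d_lkr4, cp$d_lc4, cp$d_p50)
  root_component <- function(which) {
    function(v) {
      sol <- solve_tes(compound_params(v[1], v[2], v[3]))
      if (length(sol$roots) < i) return(NA_real_)
      r <- sol$roots[[i]]$params
      switch(which, L = r$L, K_R = r$K_R, K_T = r$K_T)
    }
  }
  c(dL = propagate_errors(root_component("L"), x, dx),
    dK_R = propagate_errors(root_component("K_R"), x, dx),
    dK_T = propagate_errors(root_component("K_T"), x, dx))
}

#' @export
print.tes_solution <- function(x, ...) {
  cat("Three-equation-system solution\n")
  cat(sprintf("  inputs: LK_R^4 = %.6g  Lc^4 = %.6g  P50 = %.6g mmHg\n",
              x$cp$lkr4, x$cp$lc4, x$cp$p50))
  cat(sprintf("  shared K_T = %.6g mmHg; %d accepted root(s), %d discarded\n",
              x$k_t, length(x$roots), x$n_discarded))
  if (length(x$roots)) print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' @export
as.data.frame.tes_solution <- function(x, ...) {
  if (!length(x$roots))
    return(data.frame(root_index = integer(), label = character(),
                      L = numeric(), K_R = numeric(), K_T = numeric(),
                      c = numeric(), nH = numeric(), residual = numeric()))
  do.call(rbind, lapply(seq_along(x$roots), function(i) {
    r <- x$roots[[i]]
    out <- data.frame(root_index = i, label = r$label,
                      L = r$params$L, K_R = r$params$K_R,
                      K_T = r$params$K_T, c = r$params$c, nH = r$nH,
                      residual = max(r$residuals))
    if (!is.null(r$uncertainties)) {
      out$dL <- r$uncertainties[["dL"]]
      out$dK_R <- r$uncertainties[["dK_R"]]
      out$dK_T <- r$uncertainties[["dK_T"]]
    }
    out
  }))
}

#' Solve a table of compound parameter sets
#'
#' Applies [solve_tes()] to each row of a parameter table (as read from
#' CSV with columns `id`, `lkr4`, `lc4`, `p50` and optional `d_lkr4`,
#' `d_lc4`, `d_p50`) and returns one row per accepted root.
#'
#' @param tab data frame with the columns above.
#' @param ... passed to [solve_tes()].
#' @return Data frame with columns `id`, `root_index`, `label`, `L`,
#'   `K_R`, `K_T`, `c`, `nH`, `dL`, `dK_R`, `dK_T`, `residual`.
#' @export
solve_tes_table <- function(tab, ...) {
  need <- c("id", "lkr4", "lc4", "p50")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (d in c("d_lkr4", "d_lc4", "d_p50"))
    if (is.null(tab[[d]])) tab[[d]] <- 0
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    sol <- solve_tes(compound_params(row$lkr4, row$lc4, row$p50,
                                     row$d_lkr4, row$d_lc4, row$d_p50), ...)
    df <- as.data.frame(sol)
    if (!nrow(df)) return(NULL)
    for (d in c("dL", "dK_R", "dK_T")) if (is.null(df[[d]])) df[[d]] <- 0
    cbind(id = row$id, df[c("root_index", "label", "L", "K_R", "K_T",
                            "c", "nH", "dL", "dK_R", "dK_T", "residual")])
  })
  do.call(rbind, out)
}
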