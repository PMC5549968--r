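#' Correlate observed and model-calculated Hill coefficients
#'
#' Ordinary least squares of observed Hill coefficients on the values
#' calculated from the MWC parameters (observed as response, calculated
#' as predictor, with intercept).  Entries sharing a nonempty group
#' label — e.g. measurement triplicates of the same species — are
#' arithmetically averaged before the regression, so replicated systems
#' contribute one point each.
#'
#' A slope near one with high R-squared indicates that the extracted
#' `(L, K_R, K_T)` triples reproduce the independently measured
#' cooperativity, the validity check for a parameter-extraction
#' strategy.
#'
#' @param observed observed Hill coefficients.
#' @param calculated matching model-calculated Hill coefficients.
#' @param group_labels optional character vector; entries with the same
#'   nonempty label are averaged.  `NA`/empty labels stay individual.
#' @param transpose if `TRUE`, regress calculated on observed instead.
#' @return An object of class `"nh_correlation"`: list with `slope`,
#'   `intercept`, `r2`, `n_points` and a `grouping` description.
#' @examples
#' tab <- mammal_hb_table()
#' ok <- !is.na(tab$nh_calc_ph)
#' correlate_nh(tab$nh_obs[ok], tab$nh_calc_ph[ok], tab$replicate_group[ok])
#' @export
correlate_nh <- function(observed, calculated, group_labels = NULL,
                         transpose = FALSE) {
  stopifnot(is.numeric(observed), is.numeric(calculated),
            length(observed) == length(calculated))
  if (length(observed) < 3)
    stop("correlation requires at least 3 points", call. = FALSE)
  if (is.null(group_labels)) group_labels <- rep("", length(observed))
  if (length(group_labels) != length(observed))
    stop("'group_labels' length mismatch", call. = FALSE)
  g <- as.character(group_labels)
  own <- is.na(g) | !nzchar(g)
  g[own] <- paste0(".solo_", seq_len(sum(own)))
  obs <- as.numeric(tapply(observed, g, mean))
  calc <- as.numeric(tapply(calculated, g, mean))
  if (length(obs) < 3)
    stop("fewer than 3 points after group averaging", call. = FALSE)
  if (transpose) { tmp <- obs; obs <- calc; calc <- tmp }
  fit <- stats::lm(obs ~ calc)
  n_grouped <- sum(!own)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = summary(fit)$r.squared,
    n_points = length(obs),
    grouping = sprintf("%d entries averaged into %d points (%d grouped)",
                       length(observed), length(obs), n_grouped)),
    class = "nh_correlation")
}

#' @export
print.nh_correlation <- function(x, ...) {
  cat("Observed vs calculated Hill coefficient regression\n")
  cat(sprintf("  slope = %.4f, intercept = %.4f, R2 = %.4f (n = %d)\n",
              x$slope, x$intercept, x$r2, x$n_points))
  cat("  ", x$grouping, "\n", sep = "")
  invisible(x)
}

#' Monotone-scaling diagnostic for derived parameters
#'
#' Tests the mechanistic coherence criterion for effector series: any
#' parameter genuinely modulated by an allosteric effector must vary
#' monotonically with effector concentration.  The check uses the
#' Spearman rank correlation of the parameter values against
#' concentration; the verdict is `"monotone"` only for a perfect rank
#' correlation (`|rho| = 1`).  Rank correlation is used because the
#' criterion is monotonicity, not linearity.
#'
#' @param values derived parameter values (e.g. per-curve `L` or `c`).
#' @param concs matching effector concentrations, at least 4, no ties.
#' @return List with `rho` and `verdict` (`"monotone"` or
#'   `"non-monotone"`).
#' @examples
#' scaling_check(c(1, 2, 4, 9), c(0, 1, 2, 3))$verdict
#' @export
scaling_check <- function(values, concs) {
  stopifnot(is.numeric(values), is.numeric(concs),
            length(values) == length(concs))
  if (length(values) < 4)
    stop("scaling check requires at least 4 pairs", call. = FALSE)
  if (anyDuplicated(concs))
    stop("'concs' contains ties; concentrations must be distinct",
         call. = FALSE)
  rho <- stats::cor(values, concs, method = "spearman")
  list(rho = rho,
       verdict = if (abs(rho) >= 1 - 1e-12) "monotone" else "non-monotone")
}
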