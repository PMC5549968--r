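#' Construct a saturation curve
#'
#' One binding isotherm: ligand pressures with fractional saturations and
#' per-curve metadata.  Pressures must be strictly increasing; any fit in
#' the package requires at least 5 points.  Saturations are fractions;
#' small overshoot from observational noise is tolerated in
#' `[-0.05, 1.05]`.
#'
#' @param curve_id character identifier.
#' @param pressures strictly increasing pressures, mmHg, `>= 0`.
#' @param saturations fractional saturations, same length.
#' @param effector_name effector label, `""` when none.
#' @param effector_conc effector concentration (number), `NA` when none.
#' @param conc_unit unit string of `effector_conc`.
#' @param species optional species label.
#' @return An object of class `"saturation_curve"`.
#' @export
saturation_curve <- function(curve_id, pressures, saturations,
                             effector_name = "", effector_conc = NA_real_,
                             conc_unit = "", species = NA_character_) {
  stopifnot(is.numeric(pressures), is.numeric(saturations))
  if (length(pressures) != length(saturations))
    stop("'pressures' and 'saturations' must have equal length", call. = FALSE)
  if (any(!is.finite(pressures)) || any(pressures < 0))
    stop("'pressures' must be finite and >= 0", call. = FALSE)
  if (any(diff(pressures) <= 0))
    stop("'pressures' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(saturations)) ||
      any(saturations < -0.05) || any(saturations > 1.05))
    stop("'saturations' must lie in [-0.05, 1.05]", call. = FALSE)
  structure(list(curve_id = as.character(curve_id),
                 pressures = pressures, saturations = saturations,
                 effector_name = effector_name,
                 effector_conc = effector_conc, conc_unit = conc_unit,
                 species = species),
            class = "saturation_curve")
}

#' @export
print.saturation_curve <- function(x, ...) {
  cat(sprintf("Saturation curve '%s': %d points, %.3g-%.3g mmHg",
              x$curve_id, length(x$pressures),
              min(x$pressures), max(x$pressures)))
  if (nzchar(x$effector_name))
    cat(sprintf(", %s = %g %s", x$effector_name, x$effector_conc,
                x$conc_unit))
  cat("\n")
  invisible(x)
}

check_fit_curve <- function(curve, need_midpoint = TRUE) {
  stopifnot(inherits(curve, "saturation_curve"))
  if (length(curve$pressures) < 5)
    stop("a fit requires at least 5 points", call. = FALSE)
  if (need_midpoint &&
      !(min(curve$saturations) < 0.5 && max(curve$saturations) > 0.5))
    stop("curve does not span the half-saturation midpoint", call. = FALSE)
  invisible(curve)
}

#' Read saturation curves from a long-format CSV
#'
#' Expected columns: `curve_id`, `species`, `effector_name`,
#' `effector_conc`, `conc_unit`, `po2_mmHg`, `saturation`.  Rows sharing
#' a `curve_id` form one curve; rows are sorted by pressure within each
#' curve.
#'
#' @param path CSV file path.
#' @return A named list of [saturation_curve()] objects, in file order.
#' @export
read_curves <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "po2_mmHg", "saturation")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("curve CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("po2_mmHg", "saturation")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[col]]))))
    if (length(bad))
      stop(sprintf("curve CSV '%s': non-numeric value in column '%s', row %d",
                   path, col, bad[1]), call. = FALSE)
    tab[[col]] <- as.numeric(tab[[col]])
  }
  for (col in c("species", "effector_name", "conc_unit"))
    if (is.null(tab[[col]])) tab[[col]] <- ""
  if (is.null(tab$effector_conc)) tab$effector_conc <- NA_real_
  ids <- unique(tab$curve_id)
  curves <- lapply(ids, function(id) {
    sub <- tab[tab$curve_id == id, ]
    sub <- sub[order(sub$po2_mmHg), ]
    saturation_curve(id, sub$po2_mmHg, sub$saturation,
                     effector_name = sub$effector_name[1],
                     effector_conc = suppressWarnings(
                       as.numeric(sub$effector_conc[1])),
                     conc_unit = sub$conc_unit[1],
                     species = sub$species[1])
  })
  names(curves) <- ids
  curves
}

#' Write saturation curves to a long-format CSV
#'
#' Inverse of [read_curves()].
#'
#' @param curves a [saturation_curve()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "saturation_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(curve_id = cv$curve_id,
               species = if (is.na(cv$species)) "" else cv$species,
               effector_name = cv$effector_name,
               effector_conc = cv$effector_conc,
               conc_unit = cv$conc_unit,
               po2_mmHg = cv$pressures,
               saturation = cv$saturations)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# rough interpolated half-saturation pressure of observed data
approx_p50 <- function(curve) {
  p <- curve$pressures; y <- curve$saturations
  above <- which(y >= 0.5)
  below <- which(y < 0.5)
  if (!length(above) || !length(below))
    return(stats::median(p))
  i <- min(above)
  if (i == 1) return(p[1])
  # linear interpolation on log p across the 0.5 crossing
  w <- (0.5 - y[i - 1]) / (y[i] - y[i - 1])
  exp((1 - w) * log(max(p[i - 1], 1e-12)) + w * log(p[i]))
}
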