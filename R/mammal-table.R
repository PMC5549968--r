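.MAMMAL_TABLE_MD5 <- "1cfccdaeb2ee7d8adc46d3a5506dfa7a"

#' Reference table of TES-derived MWC parameters for mammalian hemoglobins
#'
#' Returns the packaged transcription of the published reference table of
#' three-equation-system-derived MWC parameters for 27 mammalian
#' hemoglobin oxygen saturation curves, measured under comparable
#' physiological conditions.  Each row carries the shared `K_T`, the
#' non-physiological solution set (`kr_np`, `c_np`, `l_np`,
#' `nh_calc_np`), the physiologically sound solution set (`kr_ph`,
#' `c_ph`, `l_ph_1e5` in units of 1e5, `nh_calc_ph`) and the observed
#' Hill coefficient `nh_obs`, all with `d_`-prefixed uncertainty
#' columns.  Ten rows whose equation systems had a single real root have
#' `NA` in the physiological columns.
#'
#' The `replicate_group` column labels the three human and the three
#' elephant entries as measurement triplicates; these groups are averaged
#' before correlation analyses (see [correlate_nh()]).
#'
#' Pressures are in mmHg.  The file's MD5 checksum is verified on read.
#'
#' @return A 27-row data frame.
#' @examples
#' tab <- mammal_hb_table()
#' sum(!is.na(tab$kr_ph))  # 17 rows with a physiological solution set
#' @export
mammal_hb_table <- function() {
  path <- system.file("extdata", "mammal_hb_tes_parameters.csv",
                      package = "mwcfit", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, .MAMMAL_TABLE_MD5))
    stop("checksum mismatch for packaged reference table", call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
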