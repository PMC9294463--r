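#' The packaged thiazolidine-2,4-dione compound set
#'
#' Loads the nineteen (Z)-5-arylidene-thiazolidine-2,4-diones (ids `1a`-`1s`)
#' with their measured activities at 100 uM: soybean lipoxygenase (LOX)
#' inhibition, lipid-peroxidation inhibition, and DPPH/ABTS radical
#' scavenging. The LOX endpoint is the one modelled; its decimal logarithm is
#' added as `log_lox`.
#'
#' @details Structures are encoded as SMILES built from the benzylidene-ring
#'   substitution pattern (compound `1s` carries an indol-3-yl-methylene group
#'   instead of a benzylidene). "NA" assay entries (no activity observed at
#'   100 uM) are stored as missing values, not zero.
#'
#' @return A tibble with 19 rows and columns `id`, `name`, `smiles`,
#'   `lp_inh_pct`, `lox_inh_pct`, `dpph_pct`, `abts_pct`, `log_lox`.
#' @export
#' @examples
#' tzd_compounds()
tzd_compounds <- function() {
  path <- system.file("extdata", "tzd_compounds.csv", package = "tzdqsar",
                      mustWork = TRUE)
  d <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  expected <- c("id", "name", "smiles", "lp_inh_pct", "lox_inh_pct",
                "dpph_pct", "abts_pct")
  if (!identical(names(d), expected) || nrow(d) != 19L ||
      anyDuplicated(d$id) || anyNA(d$lox_inh_pct)) {
    stop("packaged compound table is corrupted")
  }
  dplyr::mutate(d, log_lox = log_activity(.data$lox_inh_pct))
}

#' Decimal-log transform of a percent activity
#'
#' Converts percent inhibition values (in (0, 100]) to their decimal
#' logarithm, the response scale used for all modelling.
#'
#' @param percent numeric vector of percent values, all > 0.
#' @return `log10(percent)`.
#' @export
#' @examples
#' log_activity(c(7.3, 17.6, 100))
log_activity <- function(percent) {
  if (!is.numeric(percent)) stop("`percent` must be numeric")
  if (any(!is.na(percent) & percent <= 0)) {
    stop("percent activity must be > 0 to take its logarithm")
  }
  log10(percent)
}
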