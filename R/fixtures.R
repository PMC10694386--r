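#' Packaged Poyang Lake parameterization
#'
#' The stressor attributes, habitat suitability/sensitivity table, and the
#' two published decadal land-use transfer matrices for the Poyang Lake
#' watershed study, shipped as plain-CSV fixtures so a study-faithful
#' parameterization can be run on any co-registered land-use raster.
#'
#' Five land-cover classes act as threat sources: paddy field, dry land,
#' urban land, rural residential land, and industrial/traffic land. Distances
#' are kilometres. The legend uses codes 1 paddy, 2 dry land, 3 forestland,
#' 4 shrubland, 5 grassland, 6 water body, 7 urban, 8 bare land, 9 rural
#' residential, 10 industrial/traffic. The rural-residential and
#' industrial/traffic rows complete the legend with suitability 0 and
#' sensitivity 0, consistent with the urban (built-up) row; paddy and dry
#' land are simultaneously threats and (low-suitability) habitat.
#'
#' @return `poyang_threats()`: a [threat_table()]; `poyang_sensitivity()`: a
#'   [sensitivity_table()]; `poyang_transfer()`: a `transfer_matrix` for the
#'   requested decade.
#' @examples
#' poyang_threats()
#' transition_shares(poyang_transfer("2012-2022"))$classes
#' @export
poyang_threats <- function() {
  path <- system.file("extdata", "poyang_threats.csv", package = "habiq",
                      mustWork = TRUE)
  threat_table(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname poyang_threats
#' @export
poyang_sensitivity <- function() {
  path <- system.file("extdata", "poyang_sensitivity.csv", package = "habiq",
                      mustWork = TRUE)
  sensitivity_table(readr::read_csv(path, show_col_types = FALSE),
                    threats = poyang_threats())
}

#' @rdname poyang_threats
#' @param period `"2002-2012"` or `"2012-2022"`.
#' @export
poyang_transfer <- function(period = c("2002-2012", "2012-2022")) {
  period <- match.arg(period)
  file <- paste0("poyang_transfer_", gsub("-", "_", period), ".csv")
  path <- system.file("extdata", file, package = "habiq", mustWork = TRUE)
  read_transfer_csv(path, years = 10)
}

#' Read threat and sensitivity parameter CSVs
#'
#' Schemas: threats CSV with columns `threat,code,max_dist_km,weight,decay`;
#' sensitivity CSV with columns `lucode,name,habitat` plus one column per
#' threat name. Both are validated (ranges, completeness, cross-references).
#'
#' @param threats_csv,sensitivity_csv File paths.
#' @return A list with elements `threats` and `sensitivity`.
#' @export
read_params <- function(threats_csv, sensitivity_csv) {
  threats <- threat_table(readr::read_csv(threats_csv, show_col_types = FALSE))
  sens <- sensitivity_table(
    readr::read_csv(sensitivity_csv, show_col_types = FALSE),
    threats = threats
  )
  list(threats = threats, sensitivity = sens)
}
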