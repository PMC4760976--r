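#' Environmental observations from RV Polarstern cruise PS80 (ARK-XXVII)
#'
#' Station-level conditions at the chlorophyll a maximum for the 46 sites
#' sampled in Fram Strait, the Nansen Basin and the Amundsen Basin during
#' summer 2012: sea-ice concentration, water temperature, salinity and
#' NO3/Si/PO4 concentrations (some nutrient values missing). Regions are
#' labelled by water-mass setting: `fram_E` is the warm, largely ice-free
#' Atlantic inflow side of Fram Strait, `fram_W` the ice-covered Polar
#' Water side influenced by the East Greenland Current.
#'
#' This small published table doubles as the calibration source for the
#' synthetic station generator ([make_stations()] draws nutrients and ice
#' from its per-region statistics).
#'
#' @return a station data.frame (see [read_station_table()]).
#' @examples
#' st <- ps80_stations()
#' group_summary(st)
#' @export
ps80_stations <- function() {
  path <- system.file("extdata", "ps80_stations.csv", package = "arcticpico",
                      mustWork = TRUE)
  read_station_table(path)
}
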