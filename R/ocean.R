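# Water-mass physics (EOS-80, surface pressure) and environmental
# statistics over station tables.

#' Surface freezing point of seawater
#'
#' UNESCO (EOS-80) freezing temperature at atmospheric pressure,
#' `T_f = -0.0575 S + 1.710523e-3 S^1.5 - 2.154996e-4 S^2` (deg C).
#' Strictly decreasing in salinity over the valid range.
#'
#' @param S practical salinity, in \[0, 40\]; vectorized.
#' @return freezing temperature(s) in deg C.
#' @examples
#' freezing_temperature(35)  # -1.922
#' @export
freezing_temperature <- function(S) {
  if (any(is.na(S)) || any(S < 0 | S > 40))
    stop2("salinity must lie in [0, 40]")
  -0.0575 * S + 1.710523e-3 * S^1.5 - 2.154996e-4 * S^2
}

#' Surface density anomaly (EOS-80)
#'
#' Density of seawater at surface pressure minus 1000 kg/m^3 (sigma-0),
#' from the UNESCO 1983 one-atmosphere international equation of state.
#'
#' @param S practical salinity; `T` temperature in deg C. Vectorized.
#' @param T temperature (deg C).
#' @return sigma-0 in kg/m^3.
#' @export
density_sigma0 <- function(S, T) {
  rw <- 999.842594 + 6.793952e-2 * T - 9.095290e-3 * T^2 +
    1.001685e-4 * T^3 - 1.120083e-6 * T^4 + 6.536332e-9 * T^5
  A <- 8.24493e-1 - 4.0899e-3 * T + 7.6438e-5 * T^2 -
    8.2467e-7 * T^3 + 5.3875e-9 * T^4
  B <- -5.72466e-3 + 1.0227e-4 * T - 1.6546e-6 * T^2
  C <- 4.8314e-4
  rw + A * S + B * S^1.5 + C * S^2 - 1000
}

#' Classify a station's water mass from temperature and salinity
#'
#' Atlantic inflow water is warm and saline (`S >= atlantic_min_S` and
#' `T >= atlantic_min_T`; defaults 34.5 and 2 deg C). Failing that, water
#' within `freezing_band_degC` (default 0.7 deg C) of the surface freezing
#' line is Arctic halocline water; everything else is `other`. The
#' Atlantic rule is checked first.
#'
#' @param T,S temperature (deg C) and salinity; vectorized.
#' @param config a [pipeline_config()] supplying the thresholds.
#' @return character vector over
#'   `c("atlantic_inflow", "arctic_halocline", "other")`.
#' @export
classify_water_mass <- function(T, S, config = pipeline_config()) {
  oc <- config$ocean
  atlantic <- S >= oc$atlantic_min_S & T >= oc$atlantic_min_T
  halocline <- (T - freezing_temperature(S)) <= oc$freezing_band_degC
  ifelse(atlantic, "atlantic_inflow",
         ifelse(halocline, "arctic_halocline", "other"))
}

#' Density stratification between 10 m and 50 m
#'
#' `sigma0(S50, T50) - sigma0(S10, T10)`; positive values indicate static
#' stability. Arctic halocline stations typically show 0.5--3 kg/m^3,
#' Atlantic inflow stations 0.05--0.5 kg/m^3.
#'
#' @param S10,T10 salinity and temperature at 10 m.
#' @param S50,T50 salinity and temperature at 50 m.
#' @return density difference in kg/m^3.
#' @export
stratification_index <- function(S10, T10, S50, T50) {
  density_sigma0(S50, T50) - density_sigma0(S10, T10)
}

#' Pacific-water fraction from the nitrate:phosphate relationship
#'
#' Atlantic- and Pacific-origin waters follow distinct NO3-vs-PO4 source
#' lines; an observation's linear position between the two lines at its
#' PO4 value estimates its Pacific-water fraction (clipped to \[0, 1\]).
#'
#' @param NO3,PO4 nutrient concentrations (umol/L); vectorized. `PO4 > 0`.
#' @param config a [pipeline_config()]; `config$ocean$endmembers` holds the
#'   two `c(slope, intercept)` lines.
#' @return Pacific fraction(s) in \[0, 1\].
#' @export
pacific_fraction <- function(NO3, PO4, config = pipeline_config()) {
  if (any(PO4 <= 0, na.rm = TRUE)) stop2("PO4 must be positive")
  em <- config$ocean$endmembers
  atl <- em$atlantic[["slope"]] * PO4 + em$atlantic[["intercept"]]
  pac <- em$pacific[["slope"]] * PO4 + em$pacific[["intercept"]]
  gap <- atl - pac
  if (any(abs(gap) < 1e-12, na.rm = TRUE))
    stop2("endmember lines coincide at the observed PO4; fraction undefined")
  pmin(1, pmax(0, (atl - NO3) / gap))
}

#' Per-region means of station variables
#'
#' Arithmetic mean of each numeric column within each region, excluding
#' missing values column-wise (an `NA` nutrient drops that station from
#' that nutrient's mean only). The `n` column counts stations per region.
#'
#' @param stations station data.frame with a `region` column.
#' @param group_by grouping column name (default `"region"`).
#' @return data.frame, one row per group, columns
#'   `n, ice, temp, sal, no3, si, po4`.
#' @export
group_summary <- function(stations, group_by = "region") {
  if (is.null(stations[[group_by]])) stop2("no grouping column '", group_by, "'")
  groups <- split(stations, stations[[group_by]], drop = TRUE)
  if (any(vapply(groups, nrow, 0L) == 0)) stop2("empty group")
  vars <- intersect(c("ice", "temp", "sal", "no3", "si", "po4"),
                    names(stations))
  rows <- lapply(names(groups), function(g) {
    d <- groups[[g]]
    means <- vapply(vars, function(v) mean(d[[v]], na.rm = TRUE), 0)
    cbind(data.frame(group = g, n = nrow(d)), as.data.frame(as.list(means)))
  })
  do.call(rbind, rows)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance (Welch) two-sided t-test with Welch--Satterthwaite
#' degrees of freedom, used for the regional nutrient and chlorophyll
#' comparisons. Missing values are dropped.
#'
#' @param x,y numeric vectors (>= 2 non-missing values each).
#' @return a `welch_t` list: `t`, `df`, `p`, `means`, `n`.
#' @examples
#' st <- ps80_stations()
#' welch_t_test(st$po4[st$region == "nansen"], st$po4[st$region == "amundsen"])
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop2("need at least 2 non-missing values per group")
  if (sd(x) == 0 && sd(y) == 0)
    stop2("zero variance in both groups; t-test undefined")
  ht <- t.test(x, y, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, means = c(x = mean(x), y = mean(y)),
                 n = c(x = length(x), y = length(y))),
            class = "welch_t")
}

#' @export
print.welch_t <- function(x, ...) {
  cat(sprintf("Welch t-test: t = %.4f, df = %.2f, p = %.4g (n = %d, %d)\n",
              x$t, x$df, x$p, x$n[1], x$n[2]))
  invisible(x)
}
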