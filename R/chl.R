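# Size-fractionated chlorophyll a bookkeeping.

#' Total chlorophyll a from size fractions
#'
#' Total Chl a is the sum of the per-fraction concentrations (>10, 3--10
#' and 0.4--3 um). With `allow_partial = FALSE` (default) a missing
#' fraction makes the total missing rather than silently underestimating
#' it.
#'
#' @param chl chlorophyll data.frame (see [read_chl_table()]).
#' @param allow_partial sum over the available fractions when some are
#'   missing?
#' @return numeric vector of totals (ug/L), one per row.
#' @export
total_chl <- function(chl, allow_partial = FALSE) {
  fr <- as.matrix(chl[, c("chl_gt10", "chl_3_10", "chl_0p4_3")])
  if (any(fr < 0, na.rm = TRUE)) stop2("negative chlorophyll fraction")
  if (all(is.na(fr))) stop2("no chlorophyll fractions present")
  rowSums(fr, na.rm = allow_partial)
}

#' Pico-plankton share of total chlorophyll a
#'
#' Fraction of total Chl a contributed by the 0.4--3 um (pico) fraction.
#'
#' @inheritParams total_chl
#' @return numeric vector of shares in \[0, 1\].
#' @export
pico_share <- function(chl, allow_partial = FALSE) {
  tot <- total_chl(chl, allow_partial = allow_partial)
  if (any(tot <= 0, na.rm = TRUE))
    stop2("pico share undefined for zero total chlorophyll")
  chl$chl_0p4_3 / tot
}

#' Regional comparison of chlorophyll values
#'
#' Welch t-test of total Chl a (or pico share) between two groups of
#' stations, e.g. Fram Strait vs the Central Arctic Ocean.
#'
#' @param chl chlorophyll data.frame with a `station` column.
#' @param station_groups named character vector or data.frame mapping
#'   station id to a group label (exactly two distinct labels).
#' @param what `"total"` or `"pico_share"`.
#' @param allow_partial passed to [total_chl()].
#' @return a `welch_t` result (see [welch_t_test()]).
#' @export
region_compare <- function(chl, station_groups, what = c("total", "pico_share"),
                           allow_partial = FALSE) {
  what <- match.arg(what)
  if (is.data.frame(station_groups))
    station_groups <- setNames(station_groups$group, station_groups$station)
  g <- station_groups[chl$station]
  if (any(is.na(g))) stop2("stations without a group label: ",
                           paste(chl$station[is.na(g)], collapse = ", "))
  lev <- sort(unique(g))
  if (length(lev) != 2) stop2("region_compare needs exactly two groups")
  vals <- switch(what,
                 total = total_chl(chl, allow_partial),
                 pico_share = pico_share(chl, allow_partial))
  res <- welch_t_test(vals[g == lev[1]], vals[g == lev[2]])
  res$groups <- lev
  res
}
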