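# Tabular readers/writers. One CSV dialect throughout: comma-separated,
# UTF-8, "." decimal, literal "NA" for missing values.

REGIONS <- c("fram_E", "fram_W", "nansen", "amundsen", "other")

#' Read a station environment table
#'
#' One row per sampling site: ice concentration (%), water temperature
#' (deg C), practical salinity and nutrient concentrations (NO3, Si, PO4,
#' umol/L) at the chlorophyll maximum, plus a region label. Missing
#' nutrient values are encoded `NA` and stay missing (never coerced to 0).
#'
#' @param path CSV file with columns
#'   `station,date,region,ice,temp,sal,no3,si,po4`.
#' @return a validated data.frame of stations.
#' @export
read_station_table <- function(path) {
  if (!file.exists(path)) stop2("station table not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA",
                colClasses = c(station = "character"))
  validate_station_table(d)
}

validate_station_table <- function(d) {
  need <- c("station", "ice", "temp", "sal", "no3", "si", "po4")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop2("station table lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(d$station))
    stop2("duplicate station id(s): ",
          paste(unique(d$station[duplicated(d$station)]), collapse = ", "))
  for (v in c("ice", "temp", "sal", "no3", "si", "po4")) {
    if (!is.numeric(d[[v]]))
      stop2("non-numeric value in column '", v, "'")
  }
  if (any(d$ice < 0 | d$ice > 100, na.rm = TRUE))
    stop2("ice concentration must lie in [0, 100] %")
  if (any(d$sal <= 0 | d$sal >= 40, na.rm = TRUE))
    stop2("salinity out of plausible range (0, 40)")
  too_cold <- d$temp < freezing_temperature(d$sal) - 0.2
  if (any(too_cold, na.rm = TRUE))
    stop2("temperature below the freezing line beyond sensor tolerance at: ",
          paste(d$station[which(too_cold)], collapse = ", "))
  for (v in c("no3", "si", "po4"))
    if (any(d[[v]] < 0, na.rm = TRUE)) stop2("negative ", v, " concentration")
  if (!is.null(d$region) && !all(d$region %in% REGIONS))
    stop2("unknown region label(s): ",
          paste(setdiff(unique(d$region), REGIONS), collapse = ", "))
  d
}

#' @rdname read_station_table
#' @param stations a station data.frame.
#' @export
write_station_table <- function(stations, path) {
  write.csv(stations, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an ARISA peak table
#'
#' Rows of (sample, replicate, fragment size in bp, peak height in
#' relative fluorescence units).
#'
#' @param path CSV with columns `sample,replicate,size_bp,height`.
#' @return a validated peak table data.frame.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop2("peak table not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(sample = "character"))
  validate_peak_table(d)
}

validate_peak_table <- function(d) {
  need <- c("sample", "replicate", "size_bp", "height")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop2("peak table lacks column(s): ",
                          paste(miss, collapse = ", "))
  if (nrow(d) && any(d$size_bp <= 0)) stop2("fragment sizes must be positive")
  if (nrow(d) && any(d$height <= 0)) stop2("peak heights must be positive")
  d
}

#' @rdname read_peak_table
#' @param peaks a peak table data.frame.
#' @export
write_peak_table <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a size-fractionated chlorophyll table
#'
#' Columns are named by filter mesh: `chl_gt10` (>10 um), `chl_3_10`
#' (3--10 um) and `chl_0p4_3` (0.4--3 um, the pico-eukaryote fraction),
#' all in ug/L.
#'
#' @param path CSV with columns `station,chl_gt10,chl_3_10,chl_0p4_3`.
#' @return a validated data.frame.
#' @export
read_chl_table <- function(path) {
  if (!file.exists(path)) stop2("chlorophyll table not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(station = "character"))
  need <- c("station", "chl_gt10", "chl_3_10", "chl_0p4_3")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop2("chlorophyll table lacks column(s): ",
                          paste(miss, collapse = ", "))
  for (v in need[-1]) if (any(d[[v]] < 0, na.rm = TRUE))
    stop2("negative chlorophyll concentration in ", v)
  d
}

#' @rdname read_chl_table
#' @param chl a chlorophyll data.frame.
#' @export
write_chl_table <- function(chl, path) {
  write.csv(chl, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write an OTU table
#'
#' TSV with one row per OTU: `otu_id`, `consensus`, `taxonomy`
#' (semicolon-delimited lineage or empty) and one integer count column per
#' sample. Counts round-trip bit-exactly.
#'
#' @param path TSV file path.
#' @return a data.frame; count columns are every column after `taxonomy`.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop2("OTU table not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = c(otu_id = "character"))
  need <- c("otu_id", "consensus", "taxonomy")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop2("OTU table lacks column(s): ",
                          paste(miss, collapse = ", "))
  count_cols <- setdiff(names(d), need)
  for (v in count_cols) {
    if (any(d[[v]] != as.integer(d[[v]])))
      stop2("non-integer count in sample column '", v, "'")
    d[[v]] <- as.integer(d[[v]])
  }
  d$taxonomy[is.na(d$taxonomy)] <- ""
  d
}

#' @rdname read_otu_table
#' @param otu_table OTU table data.frame as returned by [build_otu_table()]
#'   (optionally with a `taxonomy` column filled in).
#' @export
write_otu_table <- function(otu_table, path) {
  write.table(otu_table, path, sep = "\t", row.names = FALSE,
              quote = FALSE, na = "")
  invisible(path)
}

#' Read a reference lineage table
#'
#' Maps reference sequence ids to ranked, semicolon-delimited lineages
#' (e.g. `Eukaryota;Haptophyta;Prymnesiophyceae;Phaeocystaceae;...`).
#'
#' @param path TSV with columns `id` and `lineage`.
#' @return a data.frame with columns `id`, `lineage`.
#' @export
read_lineage_table <- function(path) {
  if (!file.exists(path)) stop2("lineage table not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "lineage") %in% names(d)))
    stop2("lineage table needs columns 'id' and 'lineage'")
  d
}

#' Read / write a presence/absence community matrix
#'
#' Samples in rows, bins in columns; column names are the bin start
#' positions in bp. Values are 0/1 on disk and logical in memory.
#'
#' @param path CSV file path.
#' @return logical matrix with sample row names.
#' @export
read_pa_matrix <- function(path) {
  if (!file.exists(path)) stop2("presence/absence matrix not found: ", path)
  d <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d) > 0
  storage.mode(m) <- "logical"
  m
}

#' @rdname read_pa_matrix
#' @param m logical matrix (samples x bins).
#' @export
write_pa_matrix <- function(m, path) {
  out <- data.frame(sample = rownames(m), check.names = FALSE)
  out <- cbind(out, as.data.frame(m * 1L, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a square distance matrix
#'
#' @param path CSV with sample ids as both row names and header.
#' @return symmetric numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop2("distance matrix not found: ", path)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  check_square(m)
}

#' @rdname read_distance_matrix
#' @param D symmetric numeric matrix.
#' @export
write_distance_matrix <- function(D, path) {
  check_square(D)
  out <- data.frame(sample = rownames(D), check.names = FALSE)
  out <- cbind(out, as.data.frame(D, check.names = FALSE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
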