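#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated list.
#' Defaults carry the constants of the underlying protocols: a 50 bp
#' minimum ARISA fragment (primer/primer-dimer exclusion), 2 bp binning
#' with a shifted-frame search, 300--670 bp amplicon length window, at most
#' one ambiguous base, exact forward-primer prefix, 97% OTU identity,
#' a strict >1% abundant-biosphere rule, and an 85% taxonomy confidence
#' threshold.
#'
#' @param seed integer; default random seed recorded with every run.
#' @param arisa,amplicon,ocean,paths named lists overriding individual
#'   defaults of the corresponding section (partial lists are merged).
#' @return an object of class `pipeline_config` (a nested named list).
#' @examples
#' cfg <- pipeline_config(arisa = list(bin_width_bp = 3))
#' cfg$arisa$bin_width_bp
#' @export
pipeline_config <- function(seed = 1L, arisa = list(), amplicon = list(),
                            ocean = list(), paths = list()) {
  cfg <- list(
    seed = as.integer(seed),
    arisa = list(
      min_fragment_bp = 50,
      bin_width_bp = 2,
      shift_step_bp = 0.1,
      replicate_tol_bp = 1,
      replicate_min_count = 2L
    ),
    amplicon = list(
      min_len = 300L,
      max_len = 670L,
      max_n = 1L,
      forward_primer = "GCGGTAATTCCAGCTCCAA",
      primer_max_mismatch = 0L,
      identity_threshold = 0.97,
      abundance_threshold = 0.01,
      confidence_threshold = 0.85,
      min_split_gain = 0.02,
      align = list(match = 1, mismatch = 0, gap = -1),
      kmer = list(k = 8L, n_bootstrap = 100L)
    ),
    ocean = list(
      atlantic_min_S = 34.5,
      atlantic_min_T = 2.0,
      freezing_band_degC = 0.7,
      # NO3 = slope * PO4 + intercept endmember lines (Redfield-style
      # Atlantic vs Pacific source-water relationships); override to taste.
      endmembers = list(
        atlantic = c(slope = 17.499, intercept = -3.072),
        pacific = c(slope = 12.368, intercept = -10.549)
      )
    ),
    paths = list()
  )
  cfg$arisa <- utils::modifyList(cfg$arisa, arisa)
  cfg$amplicon <- utils::modifyList(cfg$amplicon, amplicon)
  cfg$ocean <- utils::modifyList(cfg$ocean, ocean)
  cfg$paths <- utils::modifyList(cfg$paths, paths)
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- function(x, nm) if (!is.numeric(x) || length(x) != 1 || x <= 0)
    stop2("config field '", nm, "' must be a positive number")
  pos(cfg$arisa$min_fragment_bp, "min_fragment_bp")
  pos(cfg$arisa$bin_width_bp, "bin_width_bp")
  pos(cfg$arisa$shift_step_bp, "shift_step_bp")
  pos(cfg$arisa$replicate_tol_bp, "replicate_tol_bp")
  pos(cfg$arisa$replicate_min_count, "replicate_min_count")
  pos(cfg$amplicon$min_len, "min_len")
  pos(cfg$amplicon$max_len, "max_len")
  if (cfg$amplicon$max_len < cfg$amplicon$min_len)
    stop2("max_len must be >= min_len")
  it <- cfg$amplicon$identity_threshold
  if (!is.numeric(it) || it <= 0 || it > 1)
    stop2("identity_threshold must be in (0, 1]")
  ab <- cfg$amplicon$abundance_threshold
  if (!is.numeric(ab) || ab <= 0 || ab >= 1)
    stop2("abundance_threshold must be in (0, 1)")
  ct <- cfg$amplicon$confidence_threshold
  if (!is.numeric(ct) || ct <= 0 || ct > 1)
    stop2("confidence_threshold must be in (0, 1]")
  pos(cfg$ocean$freezing_band_degC, "freezing_band_degC")
  for (nm in c("atlantic", "pacific")) {
    em <- cfg$ocean$endmembers[[nm]]
    if (!is.numeric(em) || length(em) != 2)
      stop2("endmember '", nm, "' must be c(slope, intercept)")
  }
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> seed =", x$seed, "\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip through YAML (or JSON, by file extension)
#' unchanged, so a run can always be reproduced from its logged config.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @param cfg a [pipeline_config()] object.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  em <- raw$ocean$endmembers
  if (!is.null(em)) {
    raw$ocean$endmembers <- lapply(em, function(v) {
      v <- unlist(v)
      c(slope = unname(v[["slope"]]), intercept = unname(v[["intercept"]]))
    })
  }
  pipeline_config(seed = raw$seed %||% 1L, arisa = raw$arisa %||% list(),
                  amplicon = raw$amplicon %||% list(),
                  ocean = raw$ocean %||% list(),
                  paths = raw$paths %||% list())
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- unclass(cfg)
  out$ocean$endmembers <- lapply(out$ocean$endmembers, as.list)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
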