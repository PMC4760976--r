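#' Read amplicon reads from FASTA
#'
#' Parses a FASTA file into a read table. The read id is the first
#' whitespace-delimited token of the header; a `sample=X` annotation
#' anywhere in the header is picked up as the sample id (the convention
#' used when pooled per-sample reads are written to a single file).
#' Sequences are upper-cased and validated against the \{A,C,G,T,N\}
#' alphabet. Record order is preserved.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return a data.frame with columns `id`, `sample` (NA when the header
#'   carries no `sample=` tag) and `seq`.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sample = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    stop2("malformed FASTA: sequence before header at line ", first)
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  sample <- rep(NA_character_, length(headers))
  has_tag <- grepl("sample=", headers)
  sample[has_tag] <- sub(".*sample=([^ ]+).*", "\\1", headers[has_tag])
  sq <- toupper(as.character(seqs))
  bad <- grepl("[^ACGTN]", sq)
  if (any(bad))
    stop2("non-ACGTN characters in record(s): ",
          paste(utils::head(ids[bad], 5), collapse = ", "))
  data.frame(id = unname(ids), sample = sample, seq = unname(sq),
             stringsAsFactors = FALSE)
}

#' Write reads to FASTA
#'
#' Inverse of [read_fasta()]: sample ids (when present) are encoded as
#' `sample=X` header annotations so that a write/read round trip is the
#' identity.
#'
#' @param reads data.frame with columns `id`, `seq` and optionally `sample`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  headers <- reads$id
  if (!is.null(reads$sample)) {
    tagged <- !is.na(reads$sample)
    headers[tagged] <- paste0(reads$id[tagged], " sample=", reads$sample[tagged])
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
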