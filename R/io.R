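#' Read protein sequences from FASTA
#'
#' Multi-record, wrapped-line FASTA via Biostrings. Identifiers are the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector, or list of [protein_record()]s.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  if (is.list(sequences) && length(sequences) > 0 &&
      inherits(sequences[[1]], "protein_record")) {
    sequences <- stats::setNames(
      vapply(sequences, `[[`, character(1), "sequence"),
      vapply(sequences, `[[`, character(1), "id"))
  }
  x <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a disordered-region file
#'
#' Tab-delimited file with columns `id`, `start`, `end` (1-based inclusive
#' coordinates; header optional, detected from the first line). Overlapping
#' or adjacent regions of one protein are merged with a warning.
#'
#' @param path TSV path.
#' @return Named list: per id a data frame with `start`, `end`.
#' @export
read_region_file <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^id\\t", first)
  d <- utils::read.delim(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (!has_header) names(d)[1:3] <- c("id", "start", "end")
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  if (any(d$start < 1L) || any(d$end < d$start))
    stop("region file: need 1 <= start <= end")
  out <- lapply(split(d, d$id), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    merged <- merge_intervals(as.matrix(g[c("start", "end")]))
    if (nrow(merged) < nrow(g))
      warning(sprintf("overlapping regions merged for %s", g$id[1L]))
    data.frame(start = as.integer(merged[, 1L]),
               end = as.integer(merged[, 2L]))
  })
  out[unique(d$id)]
}

#' Read a location-label file
#'
#' Tab-delimited `id`, `location` with location in central/periphery.
#'
#' @param path TSV path.
#' @return Named character vector id -> location.
#' @export
read_location_file <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^id\\t", first)
  d <- utils::read.delim(path, header = has_header,
                         stringsAsFactors = FALSE)
  if (!has_header) names(d)[1:2] <- c("id", "location")
  if (!all(d$location %in% c("central", "periphery")))
    stop("locations must be 'central' or 'periphery'")
  stats::setNames(d$location, d$id)
}

#' Assemble protein records from FASTA plus annotation files
#'
#' @param fasta Path to the FASTA file.
#' @param regions Optional path to a region TSV ([read_region_file()]);
#'   when absent every sequence is treated as fully disordered.
#' @param locations Optional path to a location TSV.
#' @return List of [protein_record()]s in FASTA order.
#' @export
read_protein_records <- function(fasta, regions = NULL, locations = NULL) {
  seqs <- read_fasta(fasta)
  reg <- if (!is.null(regions)) read_region_file(regions) else NULL
  loc <- if (!is.null(locations)) read_location_file(locations) else NULL
  lapply(names(seqs), function(id) {
    r <- if (!is.null(reg) && id %in% names(reg)) reg[[id]]
         else data.frame(start = 1L, end = nchar(seqs[[id]]))
    if (nrow(r) > 0 && max(r$end) > nchar(seqs[[id]]))
      stop(sprintf("region beyond sequence bounds for %s", id))
    l <- if (!is.null(loc) && id %in% names(loc)) loc[[id]] else "unknown"
    protein_record(id, seqs[[id]], disordered_regions = r, location = l)
  })
}

# deterministic TSV writer used by every pipeline stage
write_stage_tsv <- function(d, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
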