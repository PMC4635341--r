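#' Protein record
#'
#' Container for one protein: identifier, uppercase amino-acid sequence,
#' sorted non-overlapping disordered regions (1-based inclusive coordinates),
#' optional localization label and species. All downstream analyses of
#' FG nucleoporin cohorts operate on the disordered regions of each record
#' unless a function documents otherwise.
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid sequence (letters; X and other ambiguity codes
#'   are retained and classify as "other").
#' @param disordered_regions Data frame with integer columns `start`, `end`
#'   (1-based inclusive, within the sequence), or NULL for none. Overlapping
#'   or unsorted rows are rejected.
#' @param location One of `"central"`, `"periphery"`, `"unknown"`.
#' @param species Optional free-text species name.
#' @return An object of class `protein_record`.
#' @examples
#' p <- protein_record("P1", "MFGSFGKDEAAA",
#'                     disordered_regions = data.frame(start = 1, end = 8))
#' disorder_fraction(p)
#' @export
protein_record <- function(id, sequence, disordered_regions = NULL,
                           location = c("unknown", "central", "periphery"),
                           species = NA_character_) {
  location <- match.arg(location)
  sequence <- toupper(sequence)
  if (!grepl("^[A-Z]*$", sequence))
    stop("sequence must contain letters only")
  L <- nchar(sequence)
  if (is.null(disordered_regions)) {
    disordered_regions <- data.frame(start = integer(0), end = integer(0))
  } else {
    disordered_regions <- as.data.frame(disordered_regions)[c("start", "end")]
    disordered_regions$start <- as.integer(disordered_regions$start)
    disordered_regions$end <- as.integer(disordered_regions$end)
    r <- disordered_regions
    if (nrow(r) > 0) {
      if (any(r$start < 1L) || any(r$end > L) || any(r$end < r$start))
        stop("disordered regions must satisfy 1 <= start <= end <= length")
      if (is.unsorted(r$start, strictly = TRUE) && nrow(r) > 1)
        stop("disordered regions must be sorted by start")
      if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)]))
        stop("disordered regions must not overlap")
    }
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         disordered_regions = disordered_regions,
         location = location, species = species),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  L <- nchar(x$sequence)
  cat(sprintf("<protein_record> %s  (%d aa, %.1f%% disordered, location: %s)\n",
              x$id, L, 100 * disorder_fraction(x), x$location))
  invisible(x)
}

#' Fraction of residues annotated as disordered
#'
#' @param record A [protein_record()].
#' @return Value in \[0, 1\].
#' @export
disorder_fraction <- function(record) {
  L <- nchar(record$sequence)
  if (L == 0L) stop("empty sequence")
  r <- record$disordered_regions
  if (nrow(r) == 0L) return(0)
  sum(r$end - r$start + 1L) / L
}

#' Extract disordered subsequences
#'
#' Returns one entry per disordered region, in order, each with its interval
#' (whole-sequence 1-based coordinates) and substring.
#'
#' @param record A [protein_record()].
#' @return Data frame with columns `start`, `end`, `sequence`.
#' @export
disordered_subsequences <- function(record) {
  r <- record$disordered_regions
  if (nrow(r) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0)))
  data.frame(
    start = r$start, end = r$end,
    sequence = substring(record$sequence, r$start, r$end),
    stringsAsFactors = FALSE
  )
}

#' FG nucleoporin cohort filter
#'
#' A record passes when its disorder fraction exceeds `disorder_threshold`
#' and its FG-motif density (occurrences of the exact dimer FG, optionally
#' also GF, divided by full sequence length) exceeds `fg_density_threshold`.
#' Defaults 0.30 and 0.15 FG/AA are the cohort-construction thresholds for
#' FG nucleoporins.
#'
#' @param record A [protein_record()].
#' @param disorder_threshold Minimum disorder fraction (exclusive).
#' @param fg_density_threshold Minimum FG motifs per residue (exclusive).
#' @param include_gf Count GF dimers as motifs too (default FALSE: the
#'   cohort filter predates the clustering motif definition).
#' @return Logical.
#' @export
passes_fg_nup_filter <- function(record, disorder_threshold = 0.30,
                                 fg_density_threshold = 0.15,
                                 include_gf = FALSE) {
  stopifnot(disorder_threshold > 0, disorder_threshold < 1,
            fg_density_threshold > 0, fg_density_threshold < 1)
  L <- nchar(record$sequence)
  if (L == 0L) stop("empty sequence")
  n_fg <- nrow(find_fg_motifs(record$sequence, include_gf = include_gf))
  disorder_fraction(record) > disorder_threshold &&
    (n_fg / L) > fg_density_threshold
}
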