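#' Mean absolute net charge
#'
#' Absolute net charge of a sequence (number of positive minus number of
#' negative residues, in absolute value) divided by its length. All charged
#' residues carry unit charge.
#'
#' @param sequence Amino-acid sequence string.
#' @param scheme A [residue_scheme()].
#' @return Fraction in \[0, 1\].
#' @examples
#' mean_abs_net_charge("KKRDE")  # |3 - 2| / 5 = 0.2
#' @export
mean_abs_net_charge <- function(sequence, scheme = residue_scheme()) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence")
  abs(sum(chars %in% scheme$positive) - sum(chars %in% scheme$negative)) /
    length(chars)
}

#' Charged-residue number density
#'
#' Number of charged residues (both signs) divided by sequence length.
#'
#' @inheritParams mean_abs_net_charge
#' @return Fraction in \[0, 1\].
#' @export
charge_density <- function(sequence, scheme = residue_scheme()) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence")
  sum(chars %in% c(scheme$positive, scheme$negative)) / length(chars)
}

#' Normalized mean hydrophobicity
#'
#' Per-residue Kyte-Doolittle values are normalized to \[0, 1\] via
#' h' = (h + 4.5) / 9 and averaged over the sequence (no sliding window).
#' Nonstandard letters take the mid-scale value 0.5.
#'
#' @inheritParams mean_abs_net_charge
#' @return Value in \[0, 1\].
#' @export
mean_hydrophobicity <- function(sequence, scheme = residue_scheme()) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence")
  mean(normalized_hydro(chars, scheme))
}

# concatenated disordered residues of a record (error if none when required)
disordered_string <- function(record) {
  subs <- disordered_subsequences(record)
  paste(subs$sequence, collapse = "")
}

#' Charge-hydrophobicity plane coordinates
#'
#' Returns the (normalized mean hydrophobicity, mean absolute net charge)
#' pair used to place a protein in the charge-hydrophobicity plane that
#' separates intrinsically disordered from structured proteins. Computed on
#' the concatenated disordered regions by default.
#'
#' @param record A [protein_record()] or a plain sequence string.
#' @param scheme A [residue_scheme()].
#' @param use_disordered_only For records, restrict to disordered regions.
#' @return Named numeric vector `c(mean_hydrophobicity, mean_abs_net_charge)`.
#' @export
ch_plane_coordinates <- function(record, scheme = residue_scheme(),
                                 use_disordered_only = TRUE) {
  s <- if (inherits(record, "protein_record")) {
    if (use_disordered_only) disordered_string(record) else record$sequence
  } else {
    record
  }
  if (nchar(s) == 0L) stop("no residues in scope (empty disordered set?)")
  c(mean_hydrophobicity = mean_hydrophobicity(s, scheme),
    mean_abs_net_charge = mean_abs_net_charge(s, scheme))
}

#' Side of the charge-hydrophobicity boundary line
#'
#' Tests coordinates against a configurable straight line in the plane;
#' the default constants are the ones conventionally cited for separating
#' natively unfolded from structured proteins (external to this package's
#' own analyses, provided for convenience).
#'
#' @param coords Output of [ch_plane_coordinates()] (or a 2-vector).
#' @param slope,intercept Boundary line `charge = slope * hydro + intercept`.
#' @return `"disordered_side"` (above the line) or `"structured_side"`.
#' @export
ch_plane_side <- function(coords, slope = 2.785, intercept = -1.151) {
  if (coords[2] > slope * coords[1] + intercept) "disordered_side"
  else "structured_side"
}

#' Per-protein composition table
#'
#' Computes length, mean absolute net charge, charged-residue density and
#' normalized mean hydrophobicity for each record, on disordered regions by
#' default. Records with no residues in scope are dropped.
#'
#' @param records List of [protein_record()]s.
#' @param scheme A [residue_scheme()].
#' @param use_disordered_only Restrict to disordered regions.
#' @return Data frame, one row per retained record.
#' @export
composition_profile <- function(records, scheme = residue_scheme(),
                                use_disordered_only = TRUE) {
  rows <- lapply(records, function(rec) {
    s <- if (use_disordered_only) disordered_string(rec) else rec$sequence
    if (nchar(s) == 0L) return(NULL)
    data.frame(
      id = rec$id, n_residues = nchar(s),
      mean_abs_net_charge = mean_abs_net_charge(s, scheme),
      charge_density = charge_density(s, scheme),
      mean_hydrophobicity = mean_hydrophobicity(s, scheme),
      stringsAsFactors = FALSE
    )
  })
  rbind_rows(rows)
}

#' Database-level amino-acid abundance
#'
#' Fraction of each residue letter over all residues in scope across the
#' whole cohort, sorted by the disorder-propensity ranking (Trp most
#' order-promoting first, Pro most disorder-promoting last); letters outside
#' that ranking (ambiguity codes) follow alphabetically.
#'
#' @param records List of [protein_record()]s.
#' @param use_disordered_only Restrict to disordered regions.
#' @return Named numeric vector of fractions summing to 1.
#' @export
abundance_profile <- function(records, use_disordered_only = TRUE) {
  seqs <- vapply(records, function(rec) {
    if (use_disordered_only) disordered_string(rec) else rec$sequence
  }, character(1))
  chars <- seq_chars(paste(seqs, collapse = ""))
  if (length(chars) == 0L) stop("no residues in scope across the database")
  tab <- table(chars)
  frac <- as.numeric(tab) / length(chars)
  names(frac) <- names(tab)
  known <- intersect(disorder_propensity_order, names(frac))
  extra <- sort(setdiff(names(frac), known))
  frac[c(known, extra)]
}
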