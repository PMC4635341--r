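#' Kyte-Doolittle hydrophobicity scale
#'
#' Raw (unnormalized) per-residue hydropathy values for the 20 standard amino
#' acids, spanning \[-4.5, +4.5\] (Ile most hydrophobic, Arg least).
#'
#' @format Named numeric vector of length 20, one value per one-letter code.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Disorder-propensity ordering of the amino acids
#'
#' The conventional ranking from most order-promoting (Trp) to most
#' disorder-promoting (Pro), used to sort abundance profiles so that
#' composition differences between disordered cohorts read left-to-right
#' from structured to disordered character.
#'
#' @format Character vector of the 20 one-letter codes.
#' @export
disorder_propensity_order <- c(
  "W", "F", "Y", "I", "M", "L", "V", "N", "C", "T",
  "A", "G", "R", "D", "H", "Q", "K", "S", "E", "P"
)

#' Residue classification scheme
#'
#' Defines which residues count as positively charged, negatively charged,
#' polar, and hydrophobic, together with the hydrophobicity scale used for
#' averaging. Defaults: R/K positive, D/E negative, S/N/T/Q polar,
#' F/I/L/V/W/Y hydrophobic, Kyte-Doolittle hydropathy. All charged residues
#' carry unit charge magnitude; histidine is deliberately uncharged under
#' the default scheme. Everything else (including ambiguity codes such as X)
#' classifies as "other".
#'
#' @param positive Letters treated as positive charges.
#' @param negative Letters treated as negative charges.
#' @param polar Letters treated as polar.
#' @param hydrophobic Letters treated as hydrophobic.
#' @param hydrophobicity Named numeric vector of raw hydrophobicity values
#'   covering the 20 standard residues.
#' @param charge_magnitude Unit charge carried by every charged residue.
#' @return An object of class `residue_scheme`.
#' @examples
#' sch <- residue_scheme()
#' classify_residue(c("K", "S", "X"), sch)
#' @export
residue_scheme <- function(positive = c("R", "K"),
                           negative = c("D", "E"),
                           polar = c("S", "N", "T", "Q"),
                           hydrophobic = c("F", "I", "L", "V", "W", "Y"),
                           hydrophobicity = kyte_doolittle,
                           charge_magnitude = 1) {
  positive <- toupper(positive); negative <- toupper(negative)
  polar <- toupper(polar); hydrophobic <- toupper(hydrophobic)
  if (length(intersect(positive, negative)) > 0L)
    stop("positive and negative residue sets must be disjoint")
  sets <- list(positive, negative, polar, hydrophobic)
  for (i in seq_along(sets)) for (j in seq_along(sets))
    if (i < j && length(intersect(sets[[i]], sets[[j]])) > 0L)
      stop("residue classes must be pairwise disjoint")
  std20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (!all(std20 %in% names(hydrophobicity)))
    stop("hydrophobicity scale must cover all 20 standard residues")
  if (charge_magnitude != 1)
    stop("all charged residues carry unit charge under this scheme")
  structure(
    list(positive = positive, negative = negative, polar = polar,
         hydrophobic = hydrophobic, hydrophobicity = hydrophobicity,
         charge_magnitude = charge_magnitude),
    class = "residue_scheme"
  )
}

#' @export
print.residue_scheme <- function(x, ...) {
  cat("Residue classification scheme\n")
  cat("  positive:    ", paste(x$positive, collapse = " "), "\n")
  cat("  negative:    ", paste(x$negative, collapse = " "), "\n")
  cat("  polar:       ", paste(x$polar, collapse = " "), "\n")
  cat("  hydrophobic: ", paste(x$hydrophobic, collapse = " "), "\n")
  cat("  hydrophobicity scale on [",
      min(x$hydrophobicity), ", ", max(x$hydrophobicity), "]\n", sep = "")
  invisible(x)
}

#' Classify residues
#'
#' Maps each one-letter residue code to exactly one of `positive`,
#' `negative`, `polar`, `hydrophobic` or `other`. Unknown/ambiguity letters
#' (e.g. X) map to `other`.
#'
#' @param residue Character vector of single letters.
#' @param scheme A [residue_scheme()].
#' @return Character vector of class labels, same length as `residue`.
#' @export
classify_residue <- function(residue, scheme = residue_scheme()) {
  residue <- toupper(residue)
  if (any(nchar(residue) != 1L) || any(!grepl("^[A-Z]$", residue)))
    stop("residues must be single letters A-Z")
  out <- rep("other", length(residue))
  out[residue %in% scheme$positive] <- "positive"
  out[residue %in% scheme$negative] <- "negative"
  out[residue %in% scheme$polar] <- "polar"
  out[residue %in% scheme$hydrophobic] <- "hydrophobic"
  out
}

# split a sequence string into its residue letters
seq_chars <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string")
  strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
}

# per-residue normalized hydrophobicity h' = (h + 4.5) / 9 on [0, 1];
# nonstandard letters take mid-scale 0.5
normalized_hydro <- function(chars, scheme = residue_scheme()) {
  h <- unname(scheme$hydrophobicity[chars])
  h <- (h + 4.5) / 9
  h[is.na(h)] <- 0.5
  h
}
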