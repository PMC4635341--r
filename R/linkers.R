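#' Locate FG motif anchors
#'
#' Finds every occurrence of the dimer FG (and GF when `include_gf = TRUE`,
#' the motif set used for clustering) in a sequence. Overlapping occurrences
#' are all reported (e.g. "FGF" carries FG at 1 and GF at 2).
#'
#' @param sequence Amino-acid sequence string.
#' @param include_gf Also treat GF dimers as motifs.
#' @return Data frame with columns `start`, `end` (1-based inclusive) and
#'   `motif`, sorted by `start`.
#' @export
find_fg_motifs <- function(sequence, include_gf = TRUE) {
  sequence <- toupper(sequence)
  hits <- function(pat) {
    m <- gregexpr(pat, sequence, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  starts <- hits("FG")
  motifs <- rep("FG", length(starts))
  if (include_gf) {
    g <- hits("GF")
    starts <- c(starts, g)
    motifs <- c(motifs, rep("GF", length(g)))
  }
  o <- order(starts, motifs)
  data.frame(start = starts[o], end = starts[o] + 1L, motif = motifs[o],
             stringsAsFactors = FALSE)
}

#' Extract FG linkers
#'
#' An FG linker is the run of residues strictly between two consecutive
#' motif anchors, retained when its length lies in \[`min_len`, `max_len`\]
#' (10-30 residues by default). Gaps between overlapping anchors are never
#' linkers. Each linker is annotated with its signed net charge and its
#' charged, polar and hydrophobic number densities.
#'
#' @param sequence Sequence string (typically one disordered region).
#' @param min_len,max_len Inclusive length bounds.
#' @param include_gf Motif set: FG only, or FG and GF (default, the same set
#'   as clustering).
#' @param scheme A [residue_scheme()].
#' @return Data frame with columns `start`, `end` (1-based within
#'   `sequence`), `length`, `sequence`, `net_charge`, `charge_density`,
#'   `polar_density`, `hydrophobic_density`.
#' @export
extract_linkers <- function(sequence, min_len = 10L, max_len = 30L,
                            include_gf = TRUE, scheme = residue_scheme()) {
  anchors <- find_fg_motifs(sequence, include_gf = include_gf)
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sequence = character(0),
                      net_charge = integer(0), charge_density = numeric(0),
                      polar_density = numeric(0),
                      hydrophobic_density = numeric(0))
  if (nrow(anchors) < 2L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(anchors) - 1L)) {
    gap_start <- anchors$end[i] + 1L
    gap_end <- anchors$start[i + 1L] - 1L
    len <- gap_end - gap_start + 1L
    if (len < min_len || len > max_len) next
    s <- substring(sequence, gap_start, gap_end)
    # interior must be motif-free (guaranteed for consecutive anchors,
    # asserted cheaply anyway)
    if (nrow(find_fg_motifs(s, include_gf = include_gf)) > 0L) next
    chars <- seq_chars(s)
    n_pos <- sum(chars %in% scheme$positive)
    n_neg <- sum(chars %in% scheme$negative)
    rows[[length(rows) + 1L]] <- data.frame(
      start = gap_start, end = gap_end, length = len, sequence = s,
      net_charge = n_pos - n_neg,
      charge_density = (n_pos + n_neg) / len,
      polar_density = sum(chars %in% scheme$polar) / len,
      hydrophobic_density = sum(chars %in% scheme$hydrophobic) / len,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) return(empty)
  rbind_rows(rows)
}

#' Extract linkers from the disordered regions of a cohort
#'
#' @param records List of [protein_record()]s.
#' @param ... Passed to [extract_linkers()].
#' @return Data frame of linkers with a `parent_id` column; `start`/`end`
#'   are whole-sequence 1-based coordinates.
#' @export
cohort_linkers <- function(records, ...) {
  rows <- lapply(records, function(rec) {
    subs <- disordered_subsequences(rec)
    per_region <- lapply(seq_len(nrow(subs)), function(k) {
      lk <- extract_linkers(subs$sequence[k], ...)
      if (nrow(lk) == 0L) return(NULL)
      lk$start <- lk$start + subs$start[k] - 1L
      lk$end <- lk$end + subs$start[k] - 1L
      lk
    })
    out <- do.call(rbind, per_region)
    if (is.null(out) || nrow(out) == 0L) return(NULL)
    cbind(parent_id = rec$id, out, stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- cbind(parent_id = character(0),
                 extract_linkers("", min_len = 10L, max_len = 30L))
  out
}

#' Fraction of linkers with small net charge
#'
#' Proportion of linkers whose absolute net charge is 0 or 1. For FG
#' nucleoporin cohorts this fraction is characteristically high (about 93%
#' in the published cohort).
#'
#' @param linkers Data frame from [extract_linkers()]/[cohort_linkers()].
#' @return Fraction in \[0, 1\].
#' @export
linker_net_charge_summary <- function(linkers) {
  if (nrow(linkers) == 0L) stop("no linkers supplied")
  mean(abs(linkers$net_charge) <= 1L)
}

#' Mean polar density binned by charged density
#'
#' Bins linkers by their charged-residue number density and reports the
#' average polar density per bin. Linkers above `max_charge_density` are
#' excluded and only bins with at least `min_samples` linkers are reported.
#'
#' @param linkers Data frame of linkers.
#' @param bin_width Bin width on the charged-density axis, in (0, 0.7].
#' @param min_samples Minimum linkers per reported bin.
#' @param max_charge_density Exclude linkers denser than this.
#' @return Data frame with columns `bin_lo`, `bin_hi`, `bin_mid`,
#'   `mean_polar_density`, `n`. Zero rows (with a warning) when nothing
#'   survives the filters.
#' @export
polar_vs_charge_curve <- function(linkers, bin_width = 0.05,
                                  min_samples = 50L,
                                  max_charge_density = 0.7) {
  stopifnot(bin_width > 0, bin_width <= max_charge_density)
  keep <- linkers$charge_density <= max_charge_density
  d <- linkers[keep, , drop = FALSE]
  breaks <- seq(0, max_charge_density, by = bin_width)
  if (breaks[length(breaks)] < max_charge_density)
    breaks <- c(breaks, max_charge_density)
  empty <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      bin_mid = numeric(0), mean_polar_density = numeric(0),
                      n = integer(0))
  if (nrow(d) == 0L) {
    warning("no linkers survive the charge-density cap")
    return(empty)
  }
  idx <- findInterval(d$charge_density, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx == length(breaks)] <- length(breaks) - 1L
  rows <- lapply(seq_len(length(breaks) - 1L), function(b) {
    in_bin <- idx == b
    if (sum(in_bin) < min_samples) return(NULL)
    data.frame(bin_lo = breaks[b], bin_hi = breaks[b + 1L],
               bin_mid = (breaks[b] + breaks[b + 1L]) / 2,
               mean_polar_density = mean(d$polar_density[in_bin]),
               n = sum(in_bin))
  })
  out <- rbind_rows(rows)
  if (is.null(out)) {
    warning("no bin reaches the minimum sample count")
    return(empty)
  }
  out
}

#' Random control "linkers" from a cohort
#'
#' Samples random 10-30-residue windows uniformly from the disordered
#' regions of a control cohort (one window per draw, windows fully inside a
#' region), annotated like linkers. Used to contrast the polar-vs-charge
#' relationship of FG linkers against a disordered-protein control.
#'
#' @param records List of [protein_record()]s.
#' @param n Number of windows to draw.
#' @param min_len,max_len Window length bounds.
#' @param scheme A [residue_scheme()].
#' @return Data frame with the same columns as [cohort_linkers()].
#' @export
random_control_linkers <- function(records, n, min_len = 10L, max_len = 30L,
                                   scheme = residue_scheme()) {
  pool <- do.call(rbind, lapply(records, function(rec) {
    subs <- disordered_subsequences(rec)
    keep <- (subs$end - subs$start + 1L) >= min_len
    if (!any(keep)) return(NULL)
    cbind(id = rec$id, subs[keep, , drop = FALSE])
  }))
  if (is.null(pool) || nrow(pool) == 0L)
    stop("no disordered region long enough for a control window")
  rows <- lapply(seq_len(n), function(i) {
    k <- sample.int(nrow(pool), 1L)
    reg_len <- pool$end[k] - pool$start[k] + 1L
    len <- sample(seq.int(min_len, min(max_len, reg_len)), 1L)
    off <- sample.int(reg_len - len + 1L, 1L) - 1L
    a <- pool$start[k] + off
    s <- substring(pool$sequence[k], off + 1L, off + len)
    chars <- seq_chars(s)
    n_pos <- sum(chars %in% scheme$positive)
    n_neg <- sum(chars %in% scheme$negative)
    data.frame(parent_id = pool$id[k], start = a, end = a + len - 1L,
               length = len, sequence = s, net_charge = n_pos - n_neg,
               charge_density = (n_pos + n_neg) / len,
               polar_density = sum(chars %in% scheme$polar) / len,
               hydrophobic_density = sum(chars %in% scheme$hydrophobic) / len,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows)
}
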