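#' Scan a sequence for like-charge regions
#'
#' A like-charge region (LCR) is a maximal run of two or more charged
#' residues of the same sign that is not interrupted by a charged residue of
#' the opposite sign. Its span is counted inclusively from the first to the
#' last charged residue, and its charge content is the number of charges
#' divided by that span.
#'
#' @param sequence Amino-acid sequence string (typically one disordered
#'   region; LCRs never bridge region boundaries).
#' @param scheme A [residue_scheme()].
#' @return Data frame, one row per LCR sorted by `first_charge`, with
#'   columns `sign` ("positive"/"negative"), `charge_count`, `first_charge`,
#'   `last_charge` (1-based), `span_length`, `charge_content`.
#' @examples
#' scan_lcrs("SKTKSSKDDS")  # one positive LCR (3 charges) and one negative (2)
#' @export
scan_lcrs <- function(sequence, scheme = residue_scheme()) {
  chars <- seq_chars(sequence)
  if (length(chars) == 0L) stop("empty sequence")
  pos <- which(chars %in% c(scheme$positive, scheme$negative))
  empty <- data.frame(sign = character(0), charge_count = integer(0),
                      first_charge = integer(0), last_charge = integer(0),
                      span_length = integer(0), charge_content = numeric(0))
  if (length(pos) < 2L) return(empty)
  sign <- ifelse(chars[pos] %in% scheme$positive, "positive", "negative")
  run_id <- cumsum(c(1L, sign[-1L] != sign[-length(sign)]))
  rows <- lapply(split(seq_along(pos), run_id), function(ix) {
    if (length(ix) < 2L) return(NULL)
    first <- pos[ix[1L]]; last <- pos[ix[length(ix)]]
    span <- last - first + 1L
    data.frame(sign = sign[ix[1L]], charge_count = length(ix),
               first_charge = first, last_charge = last,
               span_length = span, charge_content = length(ix) / span,
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) return(empty)
  out[order(out$first_charge), , drop = FALSE]
}

#' Largest like-charge region
#'
#' Selects the LCR with the most charged residues; ties are broken by larger
#' span, then by smaller first-charge position.
#'
#' @param regions Data frame from [scan_lcrs()].
#' @return A one-row data frame, or NULL when `regions` is empty.
#' @export
largest_lcr <- function(regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(NULL)
  o <- order(-regions$charge_count, -regions$span_length,
             regions$first_charge)
  regions[o[1L], , drop = FALSE]
}

#' Classify pore localization from LCR charge count
#'
#' FG nucleoporins of the central channel carry largest LCRs of fewer than
#' eight charges, while peripheral ones carry seven or more; a count of
#' exactly seven satisfies both published conditions and is reported as
#' ambiguous.
#'
#' @param charge_count Charge count of the largest LCR (or a one-row LCR
#'   data frame).
#' @return One of `"central-like"`, `"periphery-like"`, `"ambiguous"`.
#' @export
classify_location_by_lcr <- function(charge_count) {
  if (is.data.frame(charge_count)) charge_count <- charge_count$charge_count
  vapply(charge_count, function(k) {
    if (k < 7L) "central-like"
    else if (k == 7L) "ambiguous"
    else "periphery-like"
  }, character(1))
}

# all LCRs of a record, scanned per disordered region, whole-sequence coords
record_lcrs <- function(record, scheme = residue_scheme()) {
  subs <- disordered_subsequences(record)
  rows <- lapply(seq_len(nrow(subs)), function(k) {
    r <- scan_lcrs(subs$sequence[k], scheme)
    if (nrow(r) == 0L) return(NULL)
    r$first_charge <- r$first_charge + subs$start[k] - 1L
    r$last_charge <- r$last_charge + subs$start[k] - 1L
    r
  })
  rbind_rows(rows)
}

#' Length-content table of largest LCRs
#'
#' For each protein with at least one LCR in its disordered regions, reports
#' the sign, inclusive span and charge content of its largest LCR. On FG
#' nucleoporin cohorts this table exhibits the published dichotomy: negative
#' LCRs short and dense, positive LCRs long and sparse.
#'
#' @param records List of [protein_record()]s.
#' @param scheme A [residue_scheme()].
#' @return Data frame with columns `id`, `sign`, `charge_count`,
#'   `span_length`, `charge_content` (no row for proteins without LCRs).
#' @export
lcr_length_content_table <- function(records, scheme = residue_scheme()) {
  rows <- lapply(records, function(rec) {
    best <- largest_lcr(record_lcrs(rec, scheme))
    if (is.null(best)) return(NULL)
    data.frame(id = rec$id, sign = best$sign,
               charge_count = best$charge_count,
               span_length = best$span_length,
               charge_content = best$charge_content,
               stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(id = character(0), sign = character(0),
                      charge_count = integer(0), span_length = integer(0),
                      charge_content = numeric(0))
  out
}
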