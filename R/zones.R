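#' Zone boundaries along a sequence
#'
#' Partitions a sequence of given length into `n_zones` contiguous zones of
#' (near-)equal length, zone 1 at the N-terminus; when the length is not a
#' multiple of `n_zones` the remainder residues go to the earliest zones.
#'
#' @param sequence_length Sequence length in residues (>= `n_zones`).
#' @param n_zones Number of zones (default 3: N-terminal tip, middle,
#'   C-terminal/scaffold-embedded end).
#' @return Data frame with columns `zone`, `start`, `end` (1-based
#'   inclusive).
#' @examples
#' zone_boundaries(10)  # sizes 4, 3, 3
#' @export
zone_boundaries <- function(sequence_length, n_zones = 3L) {
  sequence_length <- as.integer(sequence_length)
  n_zones <- as.integer(n_zones)
  if (sequence_length < n_zones)
    stop("sequence shorter than the number of zones")
  base <- sequence_length %/% n_zones
  rem <- sequence_length %% n_zones
  sizes <- base + as.integer(seq_len(n_zones) <= rem)
  ends <- cumsum(sizes)
  data.frame(zone = seq_len(n_zones),
             start = c(1L, ends[-n_zones] + 1L), end = ends)
}

#' Per-zone proportions of a cluster type
#'
#' For clusters of one feature type, the proportion of that type's total
#' cluster-footprint residues falling in each zone: a cluster straddling a
#' boundary contributes its residues to each zone separately, and the
#' proportions sum to one. E.g. 10 of 50 total cluster residues in zone 1
#' gives a zone-1 proportion of 10/50 = 0.2.
#'
#' @param clusters List of clusters (one feature type) from
#'   [density_cluster_1d()].
#' @param zones Data frame from [zone_boundaries()].
#' @return Named numeric vector, one proportion per zone; all-`NA` when no
#'   clusters are supplied (undefined; excluded from cohort aggregates).
#' @export
zone_proportions <- function(clusters, zones) {
  out <- setNames(rep(NA_real_, nrow(zones)),
                  paste0("zone", zones$zone))
  if (length(clusters) == 0L) return(out)
  counts <- numeric(nrow(zones))
  for (cl in clusters) {
    fp <- cl$footprint
    ov <- pmin(fp[2L], zones$end) - pmax(fp[1L], zones$start) + 1
    counts <- counts + pmax(0, ov)
  }
  out[] <- counts / sum(counts)
  out
}

#' Assign group A/B from the polar zone-1 proportion
#'
#' Proteins with strictly more than `cutoff` (default one half) of their
#' polar-cluster residues in zone 1 form group A; the rest form group B;
#' proteins without polar clusters are unassigned (`"none"`).
#'
#' @param polar_zone1 Zone-1 proportion of the polar clusters (`NA` when the
#'   protein has none).
#' @param cutoff Strict threshold (default 0.5).
#' @return `"A"`, `"B"` or `"none"` (vectorized).
#' @export
assign_group <- function(polar_zone1, cutoff = 0.5) {
  vapply(polar_zone1, function(p) {
    if (is.na(p)) "none" else if (p > cutoff) "A" else "B"
  }, character(1))
}

#' Zone profile of one protein
#'
#' Computes the three-zone proportions of every feature type's clusters on
#' whole-sequence coordinates and the group A/B label from the polar
#' clusters.
#'
#' @param record A [protein_record()].
#' @param clusters Named list from [cluster_record_features()].
#' @param n_zones Number of zones.
#' @param cutoff Group cutoff on the polar zone-1 proportion.
#' @return Object of class `zone_profile`: list with `protein_id`,
#'   `proportions` (feature-type x zone matrix), `group`.
#' @export
zone_profile <- function(record, clusters, n_zones = 3L, cutoff = 0.5) {
  zones <- zone_boundaries(nchar(record$sequence), n_zones)
  props <- t(vapply(clusters, zone_proportions, numeric(nrow(zones)),
                    zones = zones))
  structure(
    list(protein_id = record$id, proportions = props,
         group = assign_group(props["polar", 1L], cutoff)),
    class = "zone_profile"
  )
}

#' @export
print.zone_profile <- function(x, ...) {
  cat(sprintf("<zone_profile> %s  (group %s)\n", x$protein_id, x$group))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Compare FG-polar cluster overlap between groups A and B
#'
#' Summarizes the distribution of per-protein FG-polar cluster overlap
#' within each group (count, median, quartiles). In FG nucleoporin cohorts
#' group A (polar clusters concentrated at the N-terminal zone) shows the
#' higher overlap.
#'
#' @param overlap Numeric vector of per-protein `cluster_overlap(fg, polar)`
#'   values (`NA` allowed; dropped).
#' @param group Character vector of group labels, same length.
#' @return Data frame with one row per group present, columns `group`, `n`,
#'   `median`, `q1`, `q3`.
#' @export
group_overlap_comparison <- function(overlap, group) {
  stopifnot(length(overlap) == length(group))
  keep <- !is.na(overlap) & group %in% c("A", "B")
  overlap <- overlap[keep]; group <- group[keep]
  rows <- lapply(c("A", "B"), function(g) {
    v <- overlap[group == g]
    if (length(v) == 0L)
      return(data.frame(group = g, n = 0L, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v), median = q[2L], q1 = q[1L],
               q3 = q[3L])
  })
  rbind_rows(rows)
}
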