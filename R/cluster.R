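#' Clustering parameters
#'
#' Epsilon (residues) and minimum points for the one-dimensional
#' density-based clustering of a feature type. The defaults are the
#' Dunn-index-tuned values for FG nucleoporin cohorts: epsilon 35/8/2 for
#' FG motifs, charged residues and polar residues respectively, with two
#' minimum points except polar residues (four, reflecting their compact
#' distribution).
#'
#' @param epsilon Neighborhood radius in residues (> 0).
#' @param min_points Minimum points (including the point itself) for a core
#'   point (>= 2).
#' @return Object of class `clustering_params`.
#' @export
clustering_params <- function(epsilon, min_points = 2L) {
  stopifnot(epsilon > 0, min_points >= 2L)
  structure(list(epsilon = epsilon, min_points = as.integer(min_points)),
            class = "clustering_params")
}

#' Default per-feature clustering parameters for FG nucleoporins
#'
#' @return Named list of [clustering_params()] for `fg`, `charged`, `polar`.
#' @export
default_cluster_params <- function() {
  list(fg = clustering_params(35, 2L),
       charged = clustering_params(8, 2L),
       polar = clustering_params(2, 4L))
}

#' One-dimensional density-based clustering
#'
#' DBSCAN semantics on integer positions along a sequence: a position is a
#' core point when at least `min_points` positions (itself included) lie
#' within `epsilon`; clusters are maximal chains of core points pairwise
#' linked at distance <= epsilon, plus border points (non-core positions
#' with a core neighbor), each assigned deterministically to the cluster of
#' its leftmost core neighbor. Noise positions belong to no cluster.
#' (On one-dimensional data the subspace-preference generalization of
#' DBSCAN degenerates to exactly these semantics, since every point's
#' preference is the single available axis.)
#'
#' @param positions Integer positions, ascending, duplicate-free (unsorted
#'   input is sorted and deduplicated).
#' @param params A [clustering_params()].
#' @param feature_type Label stored on each cluster.
#' @param member_extent Residue footprint of one member: 1 for residues,
#'   2 for dimer motif anchors, so that a cluster's footprint runs from its
#'   first member to the last residue of its last member.
#' @return List of clusters; each is a list with `feature_type`, `members`
#'   (positions), `footprint` (c(start, end), 1-based inclusive), `size`
#'   (footprint length in residues).
#' @export
density_cluster_1d <- function(positions, params,
                               feature_type = "generic",
                               member_extent = 1L) {
  if (length(positions) == 0L) return(list())
  pos <- sort(unique(as.numeric(positions)))
  eps <- params$epsilon
  n <- length(pos)
  hi <- findInterval(pos + eps + 1e-9, pos)
  lo <- findInterval(pos - eps - 1e-9, pos)
  core <- (hi - lo) >= params$min_points
  if (!any(core)) return(list())
  corepos <- pos[core]
  corelab <- cumsum(c(TRUE, diff(corepos) > eps))
  lab <- rep(NA_integer_, n)
  lab[core] <- corelab
  # border points: leftmost core neighbor within eps
  for (i in which(!core)) {
    k <- findInterval(pos[i] - eps - 1e-9, corepos) + 1L
    if (k <= length(corepos) && corepos[k] <= pos[i] + eps + 1e-9)
      lab[i] <- corelab[k]
  }
  lapply(seq_len(max(corelab)), function(cl) {
    members <- pos[!is.na(lab) & lab == cl]
    fp <- c(min(members), max(members) + member_extent - 1L)
    list(feature_type = feature_type, members = members,
         footprint = fp, size = fp[2L] - fp[1L] + 1L)
  })
}

#' Dunn's cluster validity index
#'
#' Minimum inter-cluster point distance divided by the maximum intra-cluster
#' diameter (an intra-cluster diameter floor of one residue avoids division
#' by zero for singleton-member clusters). Higher means better separated.
#'
#' @param clusters List of clusters from [density_cluster_1d()].
#' @return Numeric index (> 0), or `NA_real_` when fewer than two clusters
#'   are supplied (the index is undefined there).
#' @export
dunn_index <- function(clusters) {
  if (length(clusters) < 2L) return(NA_real_)
  members <- lapply(clusters, `[[`, "members")
  diam <- vapply(members, function(m) max(1, diff(range(m))), numeric(1))
  min_inter <- Inf
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i >= j) next
      d <- min(abs(outer(members[[i]], members[[j]], "-")))
      if (d < min_inter) min_inter <- d
    }
  }
  min_inter / max(diam)
}

#' Tune epsilon by mean Dunn index
#'
#' Clusters every protein's feature positions at each candidate epsilon and
#' returns the grid value maximizing the average Dunn index across proteins
#' (proteins yielding fewer than two clusters are skipped at that epsilon;
#' an epsilon at which no protein yields two clusters is excluded). Ties go
#' to the smallest epsilon.
#'
#' @param positions_list List of per-protein position vectors.
#' @param epsilon_grid Candidate epsilon values.
#' @param min_points Minimum points, fixed across the grid.
#' @return The selected epsilon.
#' @export
tune_epsilon <- function(positions_list, epsilon_grid, min_points = 2L) {
  stopifnot(length(epsilon_grid) >= 1L)
  epsilon_grid <- sort(epsilon_grid)
  mean_dunn <- vapply(epsilon_grid, function(eps) {
    p <- clustering_params(eps, min_points)
    d <- vapply(positions_list, function(pos) {
      dunn_index(density_cluster_1d(pos, p))
    }, numeric(1))
    d <- d[!is.na(d)]
    if (length(d) == 0L) NA_real_ else mean(d)
  }, numeric(1))
  if (all(is.na(mean_dunn)))
    stop("no epsilon in the grid yields two clusters for any protein")
  epsilon_grid[which.max(mean_dunn)]
}

# merge 1-based inclusive intervals given as a 2-column matrix
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1L]) {
    last <- nrow(out)
    if (iv[i, 1L] <= out[last, 2L] + 0) {
      out[last, 2L] <- max(out[last, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Overlap of one cluster type with another
#'
#' Total number of residues shared between the footprints of clusters of
#' type X and the union of footprints of type Y, divided by the summed
#' footprint sizes of type X. The denominator makes the measure asymmetric:
#' `cluster_overlap(a, b)` is the fraction of type-X cluster residues also
#' covered by type-Y clusters.
#'
#' @param a Clusters of the type whose coverage is measured (X).
#' @param b Clusters of the covering type (Y).
#' @return Fraction in \[0, 1\], or `NA_real_` when `a` is empty (undefined;
#'   such proteins are excluded from cohort aggregates).
#' @export
cluster_overlap <- function(a, b) {
  if (length(a) == 0L) return(NA_real_)
  size_a <- sum(vapply(a, `[[`, numeric(1), "size"))
  if (length(b) == 0L) return(0)
  yb <- merge_intervals(do.call(rbind, lapply(b, `[[`, "footprint")))
  shared <- 0
  for (cl in a) {
    fp <- cl$footprint
    ov <- pmin(fp[2L], yb[, 2L]) - pmax(fp[1L], yb[, 1L]) + 1
    shared <- shared + sum(pmax(0, ov))
  }
  shared / size_a
}

#' Feature positions of a record
#'
#' Whole-sequence 1-based positions of a feature type within the disordered
#' regions of a record: anchor start positions of FG/GF dimers (`fg`),
#' positions of D/E/R/K (`charged`, both signs pooled), or of S/N/T/Q
#' (`polar`).
#'
#' @param record A [protein_record()].
#' @param feature_type `"fg"`, `"charged"` or `"polar"`.
#' @param scheme A [residue_scheme()].
#' @param include_gf Count GF anchors for `fg`.
#' @return Integer vector of positions (ascending).
#' @export
feature_positions <- function(record, feature_type = c("fg", "charged", "polar"),
                              scheme = residue_scheme(), include_gf = TRUE) {
  feature_type <- match.arg(feature_type)
  subs <- disordered_subsequences(record)
  if (nrow(subs) == 0L) return(integer(0))
  out <- lapply(seq_len(nrow(subs)), function(k) {
    if (feature_type == "fg") {
      a <- find_fg_motifs(subs$sequence[k], include_gf = include_gf)$start
      a + subs$start[k] - 1L
    } else {
      set <- if (feature_type == "charged")
        c(scheme$positive, scheme$negative) else scheme$polar
      which(seq_chars(subs$sequence[k]) %in% set) + subs$start[k] - 1L
    }
  })
  sort(unique(unlist(out)))
}

#' Cluster all three feature types of a record
#'
#' @param record A [protein_record()].
#' @param params Named list of [clustering_params()] (see
#'   [default_cluster_params()]).
#' @param scheme A [residue_scheme()].
#' @param include_gf Count GF anchors for the FG feature.
#' @return Named list `fg`, `charged`, `polar` of cluster lists.
#' @export
cluster_record_features <- function(record, params = default_cluster_params(),
                                    scheme = residue_scheme(),
                                    include_gf = TRUE) {
  out <- lapply(c(fg = "fg", charged = "charged", polar = "polar"),
                function(ft) {
    density_cluster_1d(
      feature_positions(record, ft, scheme, include_gf),
      params[[ft]], feature_type = ft,
      member_extent = if (ft == "fg") 2L else 1L
    )
  })
  out
}

#' Flatten cluster lists to a data frame
#'
#' @param clusters Cluster list (possibly from several types concatenated).
#' @return Data frame with `feature_type`, `start`, `end`, `n_members`,
#'   `size`.
#' @export
clusters_to_df <- function(clusters) {
  rows <- lapply(clusters, function(cl) {
    data.frame(feature_type = cl$feature_type, start = cl$footprint[1L],
               end = cl$footprint[2L], n_members = length(cl$members),
               size = cl$size, stringsAsFactors = FALSE)
  })
  out <- rbind_rows(rows)
  if (is.null(out))
    out <- data.frame(feature_type = character(0), start = numeric(0),
                      end = numeric(0), n_members = integer(0),
                      size = numeric(0))
  out
}
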