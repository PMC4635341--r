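# Independent brute-force oracles and fixture builders used across the suite.

# Brute-force density clustering: adjacency graph within eps, transitive
# closure over core points, border points to their leftmost core neighbor.
dbscan_oracle <- function(pos, eps, min_points) {
  pos <- sort(unique(as.numeric(pos)))
  n <- length(pos)
  if (n == 0L) return(list())
  adj <- abs(outer(pos, pos, "-")) <= eps + 1e-9
  core <- rowSums(adj) >= min_points
  lab <- rep(NA_integer_, n)
  ncl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(lab[i])) next
    ncl <- ncl + 1L
    frontier <- i
    lab[i] <- ncl
    while (length(frontier) > 0L) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0L)
      nb <- nb[core[nb] & is.na(lab[nb])]
      lab[nb] <- ncl
      frontier <- nb
    }
  }
  for (i in which(!core)) {
    nbcore <- which(adj[i, ] & core)
    if (length(nbcore) > 0L) lab[i] <- lab[nbcore[1L]]
  }
  keep <- !is.na(lab)
  if (!any(keep)) return(list())
  unname(split(pos[keep], lab[keep]))
}

# canonical form for comparing clusterings: member vectors sorted by first
canonical_members <- function(clusters) {
  m <- lapply(clusters, function(cl) if (is.list(cl)) cl$members else cl)
  m <- lapply(m, sort)
  m[order(vapply(m, function(x) x[1L], numeric(1)))]
}

# Brute-force like-charge-region scan: every candidate (first, last) pair of
# same-sign charges, interior purity and two-sided maximality checked
# explicitly.
lcr_oracle <- function(sequence, scheme = residue_scheme()) {
  chars <- strsplit(toupper(sequence), "")[[1L]]
  charged <- which(chars %in% c(scheme$positive, scheme$negative))
  sgn <- ifelse(chars[charged] %in% scheme$positive, "positive", "negative")
  out <- list()
  for (a in seq_along(charged)) {
    for (b in seq_along(charged)) {
      if (b <= a) next
      if (any(sgn[a:b] != sgn[a])) next
      prev_ok <- a == 1L || sgn[a - 1L] != sgn[a]
      next_ok <- b == length(charged) || sgn[b + 1L] != sgn[a]
      if (!prev_ok || !next_ok) next
      first <- charged[a]; last <- charged[b]
      out[[length(out) + 1L]] <- data.frame(
        sign = sgn[a], charge_count = b - a + 1L,
        first_charge = first, last_charge = last,
        span_length = last - first + 1L,
        charge_content = (b - a + 1L) / (last - first + 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(sign = character(0), charge_count = integer(0),
                      first_charge = integer(0), last_charge = integer(0),
                      span_length = integer(0), charge_content = numeric(0)))
  d <- do.call(rbind, out)
  d[order(d$first_charge), , drop = FALSE]
}

random_sequence <- function(n, letters = c("A", "G", "S", "K", "R", "D",
                                           "E", "T", "F", "L")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# fully disordered record from a plain sequence
full_record <- function(id, sequence) {
  protein_record(id, sequence,
                 disordered_regions = data.frame(start = 1L,
                                                 end = nchar(sequence)))
}

# 300-residue proteins with known zonal architecture.
# Group A: FG motifs interleaved with polar runs in zone 1.
# Group B: FG motifs in zone 1, a single polar block spanning zones 2-3.
make_group_a_protein <- function(id, n_units = 16L) {
  zone1 <- strrep("FGSNTQ", n_units)
  pad <- strrep("A", 300L - nchar(zone1))
  full_record(id, paste0(zone1, pad))
}

make_group_b_protein <- function(id, n_units = 16L) {
  zone1 <- strrep("FGAAAA", n_units)
  pad1 <- strrep("A", 149L - nchar(zone1))
  polar <- strrep("SNTQ", 25L)  # positions 150-249
  pad2 <- strrep("A", 300L - 149L - nchar(polar))
  full_record(id, paste0(zone1, pad1, polar, pad2))
}

# the worked zone-proportion fixture: polar residues form two clusters with
# footprints of 40 (positions 91-130) and 10 (151-160) residues, 10 of the
# 50 total falling in zone 1 of a 300-residue sequence
make_zone_example_protein <- function() {
  chars <- rep("A", 300L)
  chars[91:130] <- "S"
  chars[151:160] <- "T"
  full_record("ZONEX", paste(chars, collapse = ""))
}
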