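test_that("1-D density clustering matches hand-worked cases", {
  cl <- density_cluster_1d(c(10, 12, 14, 50), clustering_params(8, 2))
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$members, c(10, 12, 14))  # 50 is noise
  expect_equal(cl[[1L]]$footprint, c(10, 14))
  expect_equal(cl[[1L]]$size, 5)

  cl2 <- density_cluster_1d(c(0, 1, 2, 3), clustering_params(1, 2))
  expect_length(cl2, 1L)
  expect_equal(cl2[[1L]]$members, 0:3)

  expect_length(density_cluster_1d(7, clustering_params(5, 2)), 0L)
  expect_length(density_cluster_1d(integer(0), clustering_params(5, 2)), 0L)

  # dimer anchors extend the footprint by one residue
  clfg <- density_cluster_1d(c(1, 5, 9), clustering_params(8, 2),
                             feature_type = "fg", member_extent = 2L)
  expect_equal(clfg[[1L]]$footprint, c(1, 10))
  expect_equal(clfg[[1L]]$size, 10)
})

test_that("clustering equals the brute-force reachability oracle on random inputs", {
  set.seed(111)
  grid <- list(c(35, 2), c(8, 2), c(2, 4), c(5, 3))
  for (i in 1:150) {
    n <- sample(2:200, 1)
    pos <- sort(sample.int(600L, n))
    for (g in grid) {
      got <- canonical_members(
        density_cluster_1d(pos, clustering_params(g[1L], g[2L])))
      want <- canonical_members(dbscan_oracle(pos, g[1L], g[2L]))
      expect_identical(got, want,
                       info = sprintf("eps=%g minpts=%d n=%d", g[1L],
                                      g[2L], n))
    }
  }
})

test_that("clustering is translation-invariant and coarsens with epsilon", {
  set.seed(121)
  for (i in 1:20) {
    pos <- sort(sample.int(500L, 60L))
    shift <- sample(1:1000, 1)
    p <- clustering_params(sample(c(2, 5, 8, 20), 1), sample(2:4, 1))
    a <- density_cluster_1d(pos, p)
    b <- density_cluster_1d(pos + shift, p)
    expect_equal(lapply(a, function(cl) cl$members + shift),
                 lapply(b, `[[`, "members"))
    expect_equal(lapply(a, function(cl) cl$footprint + shift),
                 lapply(b, `[[`, "footprint"))

    # refinement: core members of any cluster at eps1 stay together at eps2
    eps2 <- p$epsilon * 3
    big <- density_cluster_1d(pos, clustering_params(eps2, p$min_points))
    is_core <- function(x, eps) {
      vapply(x, function(q) sum(abs(pos - q) <= eps), integer(1)) >=
        p$min_points
    }
    for (cl in a) {
      cores <- cl$members[is_core(cl$members, p$epsilon)]
      if (length(cores) == 0L) next
      host <- vapply(big, function(b2) all(cores %in% b2$members),
                     logical(1))
      expect_equal(sum(host), 1L)
    }
  }
})

test_that("Dunn index is inter-cluster separation over intra-cluster diameter", {
  mk <- function(...) lapply(list(...), function(m)
    list(feature_type = "x", members = m,
         footprint = range(m), size = diff(range(m)) + 1))
  expect_equal(dunn_index(mk(c(1, 2), c(10, 11))), 8)
  # singleton-member clusters fall back to the unit diameter floor
  expect_equal(dunn_index(mk(0, 100)), 100)
  expect_true(is.na(dunn_index(mk(c(1, 2)))))
})

test_that("epsilon tuning maximizes the mean Dunn index with smallest-value ties", {
  # two blocks, intra-gap 2, inter-gap 50: any eps in [2, 49] gives the
  # same two clusters, so the tuner returns the smallest such grid point
  blocks <- c(0, 2, 4, 6, 56, 58, 60, 62)
  expect_equal(tune_epsilon(list(blocks), c(1, 2, 8, 35, 49, 60)), 2)
  expect_equal(tune_epsilon(list(blocks), 35), 35)  # single-value grid

  # bimodal spacing: intra-gaps 2-3, inter-gap 60; fragmenting at eps=2
  # scores worse than clean separation from eps=3 up
  pos <- c(10, 12, 15, 17, 20, 22, 82, 84, 87, 89, 92, 94)
  expect_equal(tune_epsilon(list(pos), c(1, 2, 3, 5, 20, 59, 70)), 3)

  expect_error(tune_epsilon(list(c(1, 2)), c(5, 10)), "no epsilon")
})

test_that("cluster overlap is an asymmetric footprint-intersection fraction", {
  mk <- function(start, end) list(list(feature_type = "x",
                                       members = c(start, end),
                                       footprint = c(start, end),
                                       size = end - start + 1))
  x <- mk(1, 50)    # 50 residues
  y <- mk(41, 60)   # 20 residues, 10 shared
  expect_equal(cluster_overlap(x, y), 10 / 50)
  expect_equal(cluster_overlap(y, x), 10 / 20)  # asymmetric denominator
  expect_equal(cluster_overlap(x, x), 1)
  expect_equal(cluster_overlap(x, mk(100, 120)), 0)
  expect_true(is.na(cluster_overlap(list(), x)))
  expect_equal(cluster_overlap(x, list()), 0)
  # overlapping Y footprints are not double-counted
  y2 <- c(mk(10, 30), mk(20, 40))
  expect_equal(cluster_overlap(x, y2), 31 / 50)
})

test_that("feature positions and per-record clustering operate on whole-sequence coordinates", {
  seqs <- paste0(strrep("A", 10), "FGAFG", strrep("A", 5), "KDKSNTQ",
                 strrep("A", 10))
  rec <- protein_record("P", seqs,
                        disordered_regions = data.frame(start = 11,
                                                        end = 27))
  expect_equal(feature_positions(rec, "fg"), c(11L, 14L))
  expect_equal(feature_positions(rec, "charged"), c(21L, 22L, 23L))
  expect_equal(feature_positions(rec, "polar"), c(24L, 25L, 26L, 27L))
  cl <- cluster_record_features(rec)
  expect_equal(cl$fg[[1L]]$footprint, c(11, 15))  # anchor dimer extends
  expect_equal(cl$charged[[1L]]$footprint, c(21, 23))
  d <- clusters_to_df(c(cl$fg, cl$charged, cl$polar))
  expect_true(all(d$feature_type %in% c("fg", "charged", "polar")))
})
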