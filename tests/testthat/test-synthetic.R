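test_that("synthetic spec validates its parameters", {
  expect_error(synthetic_spec(fg_density = 0.5), "fg_density")
  expect_error(synthetic_spec(stalk_charge_density = 1.2), "fractions")
  expect_error(synthetic_spec(planted_lcr = list(sign = "positive",
                                                 charge_count = 5,
                                                 span = 3)))
  expect_s3_class(synthetic_spec(), "synthetic_spec")
})

test_that("cohort generation is fully deterministic under a fixed seed", {
  spec <- synthetic_spec(n_proteins = 5L, seed = 97L)
  a <- synth_fg_cohort(spec)
  b <- synth_fg_cohort(spec)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(a$records, f1); write_fasta(b$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  set.seed(3)
  d1 <- synth_disprot(3, seed = 5L)
  d2 <- synth_disprot(3, seed = 5L)
  expect_identical(d1, d2)
  expect_length(synth_disprot(0), 0L)
})

test_that("planted motif anchors are exactly the motifs in the sequence", {
  spec <- synthetic_spec(n_proteins = 8L, seed = 131L)
  co <- synth_fg_cohort(spec)
  for (i in seq_along(co$records)) {
    found <- find_fg_motifs(co$records[[i]]$sequence, include_gf = TRUE)
    expect_equal(found$start, co$truths[[i]]$fg_anchors)
    expect_true(all(found$motif == "FG"))
  }
})

test_that("motif count follows the binomial target and segments carry planted densities", {
  spec <- synthetic_spec(n_proteins = 1L, length_range = c(500L, 500L),
                         fg_density = 0.2, stalk_fraction = 0.2,
                         polar_fraction_fg_segment = 0.25, seed = 141L)
  set.seed(141)
  counts <- replicate(40, synth_fg_nup(spec)$truth$n_motifs)
  ci <- qbinom(c(0.0005, 0.9995), 500L, 0.2)  # joint band over 40 draws
  expect_gte(min(counts), ci[1L])
  expect_lte(max(counts), ci[2L])
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(500 * 0.2 * 0.8 / 40))

  # segment-wise charge and polar content match the spec within rounding
  spec2 <- synthetic_spec(n_proteins = 20L, seed = 151L)
  co <- synth_fg_cohort(spec2)
  seg_density <- function(rec, tr, span, set) {
    chars <- strsplit(substr(rec$sequence, span[1L], span[2L]), "")[[1L]]
    mean(chars %in% set)
  }
  charged <- c("K", "R", "D", "E"); polar <- c("S", "N", "T", "Q")
  stalk_cd <- mapply(function(r, t) seg_density(r, t, t$stalk, charged),
                     co$records, co$truths)
  fg_cd <- mapply(function(r, t) seg_density(r, t, t$fg_segment, charged),
                  co$records, co$truths)
  fg_pd <- mapply(function(r, t) seg_density(r, t, t$fg_segment, polar),
                  co$records, co$truths)
  expect_lt(abs(mean(stalk_cd) - 0.30), 0.01)
  expect_lt(abs(mean(fg_cd) - 0.02), 0.01)
  expect_lt(abs(mean(fg_pd) - 0.35), 0.01)
  # bimodal layout: charged clusters concentrate toward the C-terminal
  # stalk when it is disordered
  spec3 <- synthetic_spec(n_proteins = 6L, disorder_fraction = 1,
                          seed = 161L)
  co3 <- synth_fg_cohort(spec3)
  for (rec in co3$records) {
    cl <- cluster_record_features(rec)
    pr <- zone_proportions(cl$charged,
                           zone_boundaries(nchar(rec$sequence)))
    expect_gt(pr[3L], pr[1L])
  }
})

test_that("planted like-charge regions are recovered exactly in a charge-free background", {
  spec <- synthetic_spec(
    n_proteins = 1L, fg_segment_charge_density = 0,
    disorder_fraction = 0.65, stalk_fraction = 0.35,
    planted_lcr = list(sign = "negative", charge_count = 6L, span = 40L),
    seed = 171L
  )
  set.seed(171)
  for (i in 1:25) {
    out <- synth_fg_nup(spec)
    subs <- disordered_subsequences(out$record)
    found <- scan_lcrs(subs$sequence[1L])
    expect_equal(nrow(found), 1L)
    expect_equal(found$sign, out$truth$lcr$sign)
    expect_equal(found$charge_count, out$truth$lcr$charge_count)
    expect_equal(found$span_length, out$truth$lcr$span)
    expect_equal(found$first_charge, out$truth$lcr$first_charge)
  }
})

test_that("control cohort reproduces its sampled charge density without FG enrichment", {
  recs <- synth_disprot(40, charge_density_range = c(0.25, 0.25),
                        seed = 181L)
  d <- composition_profile(recs)
  expect_equal(mean(d$charge_density), 0.25, tolerance = 0.005)
  fgd <- vapply(recs, function(r)
    nrow(find_fg_motifs(r$sequence, include_gf = FALSE)) /
      nchar(r$sequence), numeric(1))
  expect_lt(mean(fgd), 0.05)  # no FG enrichment
  expect_false(any(vapply(recs, passes_fg_nup_filter, logical(1))))
})
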