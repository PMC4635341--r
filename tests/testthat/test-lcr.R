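test_that("like-charge-region scan matches hand-worked examples", {
  r <- scan_lcrs("SKTKSSKDDS")
  expect_equal(nrow(r), 2L)
  expect_equal(r$sign, c("positive", "negative"))
  expect_equal(r$charge_count, c(3L, 2L))
  expect_equal(r$first_charge, c(2L, 8L))
  expect_equal(r$span_length, c(6L, 2L))
  expect_equal(r$charge_content, c(0.5, 1))

  expect_equal(nrow(scan_lcrs("KDKDKD")), 0L)  # alternating signs

  r3 <- scan_lcrs("KKKK")
  expect_equal(r3$charge_count, 4L)
  expect_equal(r3$span_length, 4L)
  expect_equal(r3$charge_content, 1)

  expect_equal(nrow(scan_lcrs("SSSSS")), 0L)   # no charges at all
  expect_error(scan_lcrs(""), "empty")
})

test_that("scan agrees with the brute-force maximal-run oracle on random short strings", {
  set.seed(81)
  for (i in 1:300) {
    s <- random_sequence(sample(2:30, 1),
                         letters = c("K", "R", "D", "E", "S", "G", "A"))
    got <- scan_lcrs(s)
    want <- lcr_oracle(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = s)
  }
})

test_that("scan is invariant to the identity of non-charged residues", {
  set.seed(91)
  for (i in 1:20) {
    s <- random_sequence(60L)
    chars <- strsplit(s, "")[[1L]]
    neutral <- !(chars %in% c("K", "R", "D", "E"))
    chars2 <- chars
    chars2[neutral] <- sample(c("S", "T", "G", "A", "P"), sum(neutral),
                              replace = TRUE)
    expect_equal(scan_lcrs(s), scan_lcrs(paste(chars2, collapse = "")))
  }
})

test_that("an opposite-sign charge inserted inside a run splits it", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    span <- sample((n + 2):40, 1)
    chars <- rep("S", span)
    inside <- sort(sample(2:(span - 1L), n - 2L))
    kpos <- c(1L, inside, span)
    chars[kpos] <- "K"
    base <- scan_lcrs(paste(chars, collapse = ""))
    expect_equal(nrow(base), 1L)
    expect_equal(base$charge_count, n)
    # insert a D at a neutral position strictly inside
    at <- sample(setdiff(2:(span - 1L), kpos), 1)
    chars[at] <- "D"
    split <- scan_lcrs(paste(chars, collapse = ""))
    expect_true(all(split$charge_count[split$sign == "positive"] < n))
    expect_false(any(split$charge_count < 2L))  # singletons never reported
    expect_lte(sum(split$charge_count[split$sign == "positive"]), n)
  }
})

test_that("largest LCR selection uses count, then span, then position", {
  r <- data.frame(sign = c("positive", "negative"),
                  charge_count = c(3L, 2L), first_charge = c(1L, 20L),
                  last_charge = c(10L, 21L), span_length = c(10L, 2L),
                  charge_content = c(0.3, 1))
  expect_equal(largest_lcr(r)$charge_count, 3L)
  r2 <- data.frame(sign = c("positive", "negative"),
                   charge_count = c(3L, 3L), first_charge = c(30L, 1L),
                   last_charge = c(39L, 6L), span_length = c(10L, 6L),
                   charge_content = c(0.3, 0.5))
  expect_equal(largest_lcr(r2)$span_length, 10L)
  r3 <- r2; r3$span_length <- c(10L, 10L)
  expect_equal(largest_lcr(r3)$first_charge, 1L)  # smaller position wins tie
  expect_null(largest_lcr(r[0, ]))
})

test_that("LCR charge count separates central-like from periphery-like, 7 ambiguous", {
  expect_identical(classify_location_by_lcr(3L), "central-like")
  expect_identical(classify_location_by_lcr(12L), "periphery-like")
  expect_identical(classify_location_by_lcr(7L), "ambiguous")
  expect_identical(classify_location_by_lcr(c(2L, 8L)),
                   c("central-like", "periphery-like"))
})

test_that("length-content table reports the largest LCR per protein", {
  # planted positive LCR: 5 charges over 60 residues -> sparse
  pos_chars <- rep("G", 80L)
  pos_chars[c(10L, 25L, 40L, 55L, 69L)] <- "K"
  # planted negative LCR: 5 charges over 6 residues -> dense
  neg_chars <- rep("G", 80L)
  neg_chars[c(10L, 11L, 12L, 14L, 15L)] <- "D"
  recs <- list(full_record("pos", paste(pos_chars, collapse = "")),
               full_record("neg", paste(neg_chars, collapse = "")),
               full_record("none", strrep("G", 40L)))
  tab <- lcr_length_content_table(recs)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$sign, c("positive", "negative"))
  expect_equal(tab$span_length, c(60L, 6L))
  expect_equal(tab$charge_content, c(5 / 60, 5 / 6))
})
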