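test_that("canonicalization orders ends by chromosome then position and is idempotent", {
  p <- make_pairs(c("chr2", "chr1", "chr1"), c(100, 900, 100),
                  c("chr1", "chr1", "chr1"), c(500, 100, 900),
                  strand1 = c("+", "+", "-"), strand2 = c("-", "-", "+"))
  cp <- canonicalize_pairs(p)
  expect_equal(cp$chrom1, c("chr1", "chr1", "chr1"))
  expect_equal(cp$pos1, c(500, 100, 100))
  expect_equal(cp$pos2, c(100, 900, 900))
  # strands travel with their end
  expect_equal(cp$strand1[1], "-")
  expect_equal(cp$strand2[1], "+")
  expect_identical(canonicalize_pairs(cp), cp)
})

test_that("deduplication keys on coordinates and strands, not read ids", {
  p <- make_pairs(rep("chr1", 4), c(100, 100, 100, 200),
                  rep("chr1", 4), c(900, 900, 900, 800),
                  strand1 = c("+", "+", "-", "+"),
                  read_id = c("A", "B", "C", "D"))
  dd <- deduplicate_pairs(canonicalize_pairs(p))
  # A==B (same coords+strands, different id), C differs by strand
  expect_equal(dd$read_id, c("A", "C", "D"))
  distinct <- make_pairs(rep("chr1", 3), c(1, 2, 3), rep("chr1", 3), c(10, 20, 30))
  expect_equal(nrow(deduplicate_pairs(distinct)), 3L)
})

test_that("the pre-filter removes trans and sub-1kb cis pairs, keeping the boundary", {
  p <- canonicalize_pairs(make_pairs(
    c("chr1", "chr1", "chr1", "chr1"), c(1000, 1000, 1000, 1000),
    c("chr1", "chr2", "chr1", "chr1"), c(1500, 5000, 2000, 1999)
  ))
  kept <- filter_pairs(p, analysis_params())
  # distance 500 removed, trans removed, distance 1000 retained, 999 removed
  expect_equal(kept$pos2, c(2000))
})

test_that("interaction calling applies the window and the peak-anchor rule per pair", {
  params <- analysis_params()
  peaks <- make_peaks("chr1", 900, 1200)
  p <- canonicalize_pairs(make_pairs(
    rep("chr1", 4), c(1000, 1000, 5e6, 1000),
    rep("chr1", 4), c(51000, 11000, 5e6 + 5e4, 51000)
  ))
  ints <- call_interactions(p, peaks, params)
  # pair at 50 kb with anchor1 in peak called; 10 kb dropped; far pair has no
  # peak anchor; identical surviving coordinates from different reads both kept
  expect_equal(nrow(ints), 2L)
  expect_equal(ints$anchor1, c(1000, 1000))
  expect_equal(ints$distance, c(50000, 50000))
  expect_equal(ints$source_id, c("R001", "R004"))

  expect_error(call_interactions(p, peaks[0, ], params), "empty")
  no_peaks <- call_interactions(p, peaks[0, ], params, require_peaks = FALSE)
  expect_equal(nrow(no_peaks), 3L)  # distance-only call
})

test_that("interaction calls match the brute-force oracle and are order invariant", {
  set.seed(101)
  params <- analysis_params(long_min = 20000, long_max = 200000)
  pairs <- canonicalize_pairs(random_pairs(1000))
  pairs <- deduplicate_pairs(pairs)
  peaks <- random_peaks(30)
  filt <- filter_pairs(pairs, params)
  ints <- call_interactions(filt, peaks, params)
  expect_equal(nrow(ints), length(oracle_call_interactions(filt, peaks, params)))
  expect_equal(paste(ints$chrom, ints$anchor1, ints$anchor2),
               paste(filt$chrom1, filt$pos1, filt$pos2)[oracle_call_interactions(filt, peaks, params)])

  # permutation of the input permutes but does not change the called set
  perm <- filt[sample.int(nrow(filt)), ]
  ints2 <- call_interactions(perm, peaks, params)
  expect_setequal(paste(ints2$chrom, ints2$anchor1, ints2$anchor2, ints2$source_id),
                  paste(ints$chrom, ints$anchor1, ints$anchor2, ints$source_id))
})

test_that("called sets are nested under nested distance windows", {
  set.seed(7)
  pairs <- deduplicate_pairs(canonicalize_pairs(random_pairs(800)))
  peaks <- random_peaks(20)
  key <- function(x) paste(x$chrom, x$anchor1, x$anchor2, x$source_id)
  narrow <- call_interactions(pairs, peaks, analysis_params(long_min = 50000, long_max = 200000))
  wide <- call_interactions(pairs, peaks, analysis_params(long_min = 20000, long_max = 500000))
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("QC metrics count the constructed fixture correctly", {
  # 10 distinct pairs: 6 cis of which 4 are >= 20 kb, 4 trans
  p <- make_pairs(
    rep("chr1", 10), rep(1000, 10),
    c(rep("chr1", 6), rep("chr2", 4)),
    c(1000 + c(5e3, 1e4, 2e4, 3e4, 5e4, 9e4), c(500, 600, 700, 800))
  )
  qc <- qc_metrics(p)
  expect_equal(qc$total_pairs, 10L)
  expect_equal(qc$unique_pairs, 10L)
  expect_equal(qc$cis_pairs, 6L)
  expect_equal(qc$trans_pairs, 4L)
  expect_equal(qc$cis_trans_ratio, 1.5)
  expect_equal(qc$long_range_pairs, 4L)

  all_cis <- qc_metrics(p[1:6, ])
  expect_identical(all_cis$trans_pairs, 0L)
  expect_identical(all_cis$cis_trans_ratio, Inf)

  zero <- qc_metrics(p[0, ])
  expect_equal(zero$total_pairs, 0L)
  expect_true(is.na(zero$cis_trans_ratio))
})

test_that("every raw pair lands in exactly one classification category", {
  set.seed(55)
  pairs <- random_pairs(500)
  pairs <- rbind(pairs, pairs[sample.int(500, 50), ])  # inject duplicates
  peaks <- random_peaks(15)
  cls <- classify_pairs(pairs, peaks, analysis_params(long_min = 20000, long_max = 300000))
  expect_equal(length(cls), nrow(pairs))
  expect_false(anyNA(cls))
  expect_equal(sum(table(cls)), nrow(pairs))
  expect_equal(sum(cls == "called"),
               nrow(call_interactions(
                 filter_pairs(deduplicate_pairs(canonicalize_pairs(pairs)),
                              analysis_params(long_min = 20000, long_max = 300000)),
                 peaks, analysis_params(long_min = 20000, long_max = 300000))))
})
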