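test_that("contact binning places pairs and conserves mass", {
  p <- make_pairs("chr1", 1, "chr1", 5001)
  cm <- bin_pairs(p, 5000)[["chr1"]]
  expect_equal(as.numeric(cm$mat[1, 2]), 1)
  expect_equal(as.numeric(cm$mat[2, 1]), 1)  # symmetric storage

  diag_pair <- make_pairs("chr1", 15001, "chr1", 16000)
  cmd <- bin_pairs(diag_pair, 5000)[["chr1"]]
  expect_equal(as.numeric(cmd$mat[4, 4]), 1)

  set.seed(12)
  many <- canonicalize_pairs(random_pairs(1000, trans_frac = 0.2))
  mats <- bin_pairs(many, 5000, chrom_sizes = c(chr1 = 1e6, chr2 = 1e6))
  total <- sum(vapply(mats, contact_mass, 0))
  expect_equal(total, sum(many$chrom1 == many$chrom2))  # trans pairs excluded

  expect_error(bin_pairs(p, 0), "positive")
})

test_that("KR balancing hits closed forms and equalizes row sums", {
  # closed form: [[0,2],[2,0]] balances with weights 1/sqrt(2)
  m <- matrix(c(0, 2, 2, 0), 2)
  w <- kr_balance(m)
  expect_equal(w, rep(1 / sqrt(2), 2), tolerance = 1e-6)

  # doubly stochastic input is a fixed point
  ds <- matrix(c(0.5, 0.5, 0.5, 0.5), 2)
  expect_equal(kr_balance(ds), c(1, 1), tolerance = 1e-6)

  # random symmetric positive 20x20: post-balance row sums within 1e-6 of 1
  set.seed(8)
  A <- matrix(runif(400, 0.1, 2), 20)
  A <- A + t(A)
  w <- kr_balance(A)
  B <- diag(w) %*% A %*% diag(w)
  expect_lt(max(abs(rowSums(B) - 1)), 1e-6)

  # zero rows are excluded and get NA weights
  Az <- A
  Az[3, ] <- 0
  Az[, 3] <- 0
  wz <- kr_balance(Az)
  expect_true(is.na(wz[3]))
  Bz <- diag(ifelse(is.na(wz), 0, wz)) %*% Az %*% diag(ifelse(is.na(wz), 0, wz))
  expect_lt(max(abs(rowSums(Bz)[-3] - 1)), 1e-6)

  expect_error(kr_balance(matrix(0, 3, 3)), "no nonzero rows")
  expect_error(kr_balance(matrix(-1, 2, 2)), "nonnegative")
})

test_that("KR weights commute with symmetric permutations of the bins", {
  set.seed(21)
  A <- matrix(runif(225, 0.1, 1), 15)
  A <- A + t(A)
  perm <- sample.int(15)
  w <- kr_balance(A)
  w_perm <- kr_balance(A[perm, perm])
  expect_equal(w_perm, w[perm], tolerance = 1e-4)
})

test_that("loci enumeration applies separation bounds on peak midpoints", {
  params <- analysis_params()
  near <- make_peaks("chr1", c(9500, 13500), c(10500, 14500))  # midpoints 10001, 14001
  expect_equal(nrow(enumerate_loci(near, 5000, params)), 0L)   # 4 kb < 5 kb

  far <- make_peaks("chr1", c(9500, 1009500), c(10500, 1010500))  # sep exactly 1 Mb
  expect_equal(nrow(enumerate_loci(far, 5000, params)), 0L)       # < 1 Mb is strict

  ok <- make_peaks("chr1", c(9500, 29500), c(10500, 30500))  # sep 20 kb
  expect_equal(nrow(enumerate_loci(ok, 5000, params)), 1L)

  # five mutually admissible peaks -> C(5,2) = 10 pairs
  five <- make_peaks("chr1", seq(100000, by = 50000, length.out = 5),
                     seq(100000, by = 50000, length.out = 5) + 1000)
  expect_equal(nrow(enumerate_loci(five, 5000, params)), 10L)
})

test_that("loci sampling clamps, is seed-deterministic, and varies across seeds", {
  loci <- data.frame(chrom = "chr1", bin_i = 1:50, bin_j = 101:150)
  expect_equal(nrow(sample_loci(loci, 200000, seed = 1)), 50L)

  big <- data.frame(chrom = "chr1", bin_i = 1:10000, bin_j = 20001:30000)
  s1 <- sample_loci(big, 100, seed = 4)
  s2 <- sample_loci(big, 100, seed = 4)
  s3 <- sample_loci(big, 100, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
})

test_that("aggregation equals the naive slice-and-average oracle", {
  set.seed(17)
  n_bins <- 120
  # sparse random symmetric counts
  idx <- data.frame(i = sample.int(n_bins, 600, TRUE), j = sample.int(n_bins, 600, TRUE))
  p <- make_pairs("chr1", (pmin(idx$i, idx$j) - 1) * 5000 + sample.int(5000, 600, TRUE),
                  "chr1", (pmax(idx$i, idx$j) - 1) * 5000 + sample.int(5000, 600, TRUE))
  p <- canonicalize_pairs(p)
  mats <- lapply(bin_pairs(p, 5000, c(chr1 = n_bins * 5000)), kr_balance)
  loci <- data.frame(chrom = "chr1",
                     bin_i = sample.int(40, 30, TRUE) + 10,
                     bin_j = sample.int(40, 30, TRUE) + 70)
  res <- aggregate_apa(mats, loci, window_bins = 5, corner = 3)
  dense <- list(chr1 = as.matrix(balanced_matrix(mats[["chr1"]])))
  ora <- oracle_aggregate(dense, loci, w = 5, corner = 3)
  expect_equal(res$matrix, ora$matrix, ignore_attr = TRUE)
  expect_equal(res$score, ora$score)
  expect_equal(res$n_pairs_used, ora$n)
})

test_that("aggregation handles lone-center and constant matrices as expected", {
  # single locus, one contact exactly at the center
  p <- make_pairs("chr1", 50 * 5000 + 100, "chr1", 80 * 5000 + 100)  # bins 50, 80
  mats <- bin_pairs(p, 5000, c(chr1 = 150 * 5000))
  res <- aggregate_apa(mats, data.frame(chrom = "chr1", bin_i = 50, bin_j = 80),
                       window_bins = 5, corner = 3, balanced = FALSE)
  expect_equal(res$matrix[6, 6], 1)
  expect_equal(sum(res$matrix), 1)

  # translation-invariant constant matrix: score is exactly 1
  const <- mats
  const[["chr1"]]$mat <- Matrix::forceSymmetric(
    Matrix::Matrix(1, 150, 150, sparse = TRUE))
  res_c <- aggregate_apa(const, data.frame(chrom = "chr1", bin_i = 50, bin_j = 80),
                         window_bins = 5, corner = 3, balanced = FALSE)
  expect_equal(res_c$score, 1.0)

  # zero usable loci is an error
  expect_error(
    aggregate_apa(mats, data.frame(chrom = "chr1", bin_i = 2, bin_j = 5),
                  window_bins = 5, balanced = FALSE),
    "no usable loci"
  )
})

test_that("the apa() wrapper runs the full pipeline on simulated input", {
  # library depth per bp matches the default study conditions (4 pairs/kb),
  # below which 5-kb matrices are too sparse to balance
  cfg <- simulation_config(chrom_sizes = c(chr1 = 5e6), n_peaks = 40L,
                           n_loops = 8L, loop_distance_range = c(120000, 900000),
                           n_background_pairs = 20000L, trans_fraction = 0,
                           n_snps = 5L, n_genes = 10L, seed = 3L)
  b <- simulate_dataset(cfg)
  pairs <- filter_pairs(deduplicate_pairs(canonicalize_pairs(b$pairs)))
  res <- apa(pairs, b$peaks, analysis_params(seed = 3), chrom_sizes = cfg$chrom_sizes)
  expect_s3_class(res, "apa_result")
  expect_equal(dim(res$matrix), c(21, 21))
  expect_gt(res$n_pairs_used, 0)
  expect_true(is.finite(res$score))
})

test_that("APA score concentrates near 1 on i.i.d.-noise matrices", {
  set.seed(33)
  n_bins <- 200
  A <- matrix(rpois(n_bins^2, 5), n_bins)
  A <- A + t(A)
  cm <- structure(list(chrom = "chr1", resolution = 5000, n_bins = n_bins,
                       mat = Matrix::forceSymmetric(Matrix::Matrix(A, sparse = TRUE)),
                       weights = NULL), class = "contact_matrix")
  loci <- data.frame(chrom = "chr1",
                     bin_i = sample.int(60, 400, TRUE) + 15,
                     bin_j = sample.int(80, 400, TRUE) + 105)
  res <- aggregate_apa(list(chr1 = cm), loci, balanced = FALSE)
  expect_lt(abs(res$score - 1), 0.1)
})
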