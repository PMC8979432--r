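test_that("promoter intervals are strand-aware, flank-symmetric and clipped", {
  genes <- data.frame(
    name = c("P", "M", "EDGE"),
    chrom = "chr1",
    tx_start = c(10000, 2000, 99),
    tx_end = c(20000, 10000, 4000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
  prom <- promoters(genes, flank = 2500)
  # + strand: TSS is tx_start+1 = 10001 -> [7500, 12501)
  expect_equal(prom$start[1], 7500)
  expect_equal(prom$end[1], 12501)
  # - strand: TSS is tx_end = 10000 (1-based) -> centered on 10000
  expect_equal(prom$start[2], 10000 - 1 - 2500)
  expect_equal(prom$end[2], 10000 + 2500)
  # TSS at 100 clips to 0
  expect_equal(prom$start[3], 0)

  # strand-ignorant mode uses tx_start for every gene (clipped at 0 here)
  flat <- promoters(genes, flank = 2500, strand_aware = FALSE)
  expect_equal(flat$start[2], 0)
  expect_equal(flat$end[2], 2001 + 2500)
})

test_that("SNP linking applies the inclusive 5-kb window per anchor", {
  params <- analysis_params()
  snps <- data.frame(chrom = "chr1", pos = 100000, rsid = "rs1",
                     trait = "t", stringsAsFactors = FALSE)
  near <- make_interactions("chr1", 97000, 400000)
  li <- link_snps(near, snps, params)
  expect_equal(nrow(li), 1L)
  expect_equal(li$matched_anchor, "1")

  off <- make_interactions("chr1", 94999, 400000)
  expect_equal(nrow(link_snps(off, snps, params)), 0L)  # 5,001 bp misses

  # one interaction near two SNPs: two linkage rows, one unique interaction
  two <- rbind(snps, data.frame(chrom = "chr1", pos = 398000, rsid = "rs2", trait = "t"))
  li2 <- link_snps(near, two, params)
  expect_equal(nrow(li2), 2L)
  expect_equal(attr(li2, "n_unique_interactions"), 1L)

  # both anchors near one SNP
  straddle <- make_interactions("chr1", 98000, 103000)
  expect_equal(link_snps(straddle, snps, params)$matched_anchor, "both")
})

test_that("SNP linking agrees with the brute-force oracle over random instances", {
  set.seed(202)
  params <- analysis_params()
  for (k in 1:15) {
    ints <- make_interactions(sample(c("chr1", "chr2"), 40, TRUE),
                              sample.int(5e5, 40), sample.int(5e5, 40) + 6e5)
    snps <- data.frame(chrom = sample(c("chr1", "chr2"), 25, TRUE),
                       pos = sample.int(1.2e6, 25),
                       rsid = sprintf("rs%d", 1:25), trait = "t",
                       stringsAsFactors = FALSE)
    got <- link_snps(ints, snps, params)
    ora <- oracle_link_snps(ints, snps, params$snp_window)
    expect_equal(nrow(got), nrow(ora))
    expect_setequal(paste(got$interaction_id, got$rsid),
                    paste(ora$ia, snps$rsid[ora$snp]))
  }
})

test_that("a zero window reduces linking to exact position equality", {
  params0 <- analysis_params(snp_window = 0)
  ints <- make_interactions("chr1", c(100, 200), c(7e5, 8e5))
  snps <- data.frame(chrom = "chr1", pos = c(100, 201), rsid = c("rs1", "rs2"),
                     trait = "t", stringsAsFactors = FALSE)
  li <- link_snps(ints, snps, params0)
  expect_equal(li$rsid, "rs1")
  expect_equal(li$anchor1, 100)
})

test_that("promoter mapping collects genes containing either anchor", {
  genes <- data.frame(name = c("G1", "G2"), chrom = "chr1",
                      tx_start = c(50000, 400000), tx_end = c(60000, 410000),
                      strand = c("+", "+"), stringsAsFactors = FALSE)
  prom <- promoters(genes, 2500)
  snps <- data.frame(chrom = "chr1", pos = 52000, rsid = "rs1", trait = "t",
                     stringsAsFactors = FALSE)
  # anchor1 in G1's promoter, anchor2 in G2's promoter
  ints <- make_interactions("chr1", 50500, 400500)
  li <- map_to_promoters(link_snps(ints, snps, analysis_params()), prom)
  expect_equal(li$promoter_genes[[1]], c("G1", "G2"))
  expect_true(li$has_promoter[1])
  expect_equal(attr(li, "unique_genes"), c("G1", "G2"))

  # anchor in no promoter
  far <- make_interactions("chr1", 52000, 900000)
  li2 <- map_to_promoters(link_snps(far, snps, analysis_params()),
                          promoters(genes[2, , drop = FALSE], 2500))
  expect_false(li2$has_promoter[1])
  expect_equal(attr(li2, "n_promoter_linkages"), 0L)
})

test_that("a planted promoter fixture reports the constructed counts exactly", {
  # 725 SNP-linked interactions; 343 have anchor2 in a distinct gene promoter
  n_link <- 725
  n_prom <- 343
  a1 <- seq(100000, by = 20000, length.out = n_link)
  # anchor2 offset chosen off the SNP grid so each interaction links its own
  # SNP only (via anchor1)
  ints <- make_interactions("chr1", a1, a1 + 510000)
  snps <- data.frame(chrom = "chr1", pos = a1 + 1000,
                     rsid = sprintf("rs%04d", seq_len(n_link)), trait = "t",
                     stringsAsFactors = FALSE)
  genes <- data.frame(
    name = sprintf("G%03d", seq_len(n_prom)),
    chrom = "chr1",
    tx_start = a1[seq_len(n_prom)] + 510000 - 1,  # + strand TSS at anchor2
    tx_end = a1[seq_len(n_prom)] + 510000 + 9999,
    strand = "+",
    stringsAsFactors = FALSE
  )
  li <- map_to_promoters(link_snps(ints, snps, analysis_params()),
                         promoters(genes, 2500))
  expect_equal(attr(li, "n_unique_interactions"), n_link)
  expect_equal(attr(li, "n_promoter_linkages"), n_prom)
  expect_equal(length(attr(li, "unique_genes")), n_prom)
})

test_that("motif anchors exclude promoter-proximal points and extend by 100 bp", {
  params <- analysis_params()
  genes <- data.frame(name = "G", chrom = "chr1", tx_start = 49999, tx_end = 60000,
                      strand = "+", stringsAsFactors = FALSE)  # TSS at 50,000
  # anchor 2,400 bp from the TSS is dropped; 2,501 bp away survives
  ints <- make_interactions("chr1", c(52400, 52501, 52501), c(9e5, 9.5e5, 9.9e5))
  out <- prepare_motif_anchors(ints, genes, params)
  expect_false(52400 %in% (out$start + 101))
  expect_true(52501 %in% (out$start + 101))
  # surviving anchor p becomes [p-101, p+100), width 201
  expect_true(all(out$end - out$start == 201))
  row <- out[out$start + 101 == 52501, ]
  expect_equal(row$start, 52400)
  expect_equal(row$end, 52601)
  # duplicate anchors collapse
  expect_equal(sum(out$start + 101 == 52501), 1L)

  # output is disjoint from the promoter windows by construction
  prom <- promoters(genes, params$promoter_flank)
  centers <- out$start + 101
  expect_false(any(centers > prom$start & centers <= prom$end))
})
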