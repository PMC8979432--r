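# Small in-code fixtures shared across test files.

make_pairs <- function(chrom1, pos1, chrom2, pos2,
                       strand1 = "+", strand2 = "-",
                       read_id = sprintf("R%03d", seq_along(pos1))) {
  data.frame(
    read_id = read_id,
    chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
    chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
    stringsAsFactors = FALSE
  )
}

make_peaks <- function(chrom, start, end, name = NULL) {
  df <- data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- name
  df
}

make_interactions <- function(chrom, anchor1, anchor2) {
  data.frame(
    chrom = chrom, anchor1 = anchor1, anchor2 = anchor2,
    distance = anchor2 - anchor1,
    source_id = sprintf("I%03d", seq_along(anchor1)),
    stringsAsFactors = FALSE
  )
}

make_loops <- function(chrom, startA, endA, startB, endB) {
  data.frame(
    chromA = chrom, startA = startA, endA = endA,
    chromB = chrom, startB = startB, endB = endB,
    score = NA_real_, trans = FALSE, stringsAsFactors = FALSE
  )
}

# Random cis/trans pair table on a 2-chromosome toy genome.
random_pairs <- function(n, chrom_len = 1e6, trans_frac = 0.1) {
  chrom1 <- sample(c("chr1", "chr2"), n, replace = TRUE)
  chrom2 <- ifelse(stats::runif(n) < trans_frac,
                   ifelse(chrom1 == "chr1", "chr2", "chr1"), chrom1)
  make_pairs(chrom1, sample.int(chrom_len, n, replace = TRUE),
             chrom2, sample.int(chrom_len, n, replace = TRUE),
             strand1 = sample(c("+", "-"), n, TRUE),
             strand2 = sample(c("+", "-"), n, TRUE))
}

random_peaks <- function(n, chrom_len = 1e6, width = 2000) {
  start <- sample.int(chrom_len - width, n, replace = TRUE)
  make_peaks(sample(c("chr1", "chr2"), n, replace = TRUE), start, start + width)
}
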