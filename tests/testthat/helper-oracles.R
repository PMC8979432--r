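# Brute-force reference implementations, kept deliberately naive (plain
# double loops, no interval machinery) so they are independent of the code
# paths they check.

oracle_point_in_peak <- function(chrom, pos, peaks, slack = 0) {
  for (k in seq_len(nrow(peaks))) {
    if (peaks$chrom[k] == chrom &&
        pos >= peaks$start[k] + 1 - slack && pos <= peaks$end[k] + slack) {
      return(TRUE)
    }
  }
  FALSE
}

oracle_call_interactions <- function(pairs, peaks, params, slack = 0) {
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    if (pairs$chrom1[i] != pairs$chrom2[i]) next
    d <- pairs$pos2[i] - pairs$pos1[i]
    if (d < params$long_min || d > params$long_max) next
    hit <- oracle_point_in_peak(pairs$chrom1[i], pairs$pos1[i], peaks, slack) ||
      oracle_point_in_peak(pairs$chrom2[i], pairs$pos2[i], peaks, slack)
    keep[i] <- hit
  }
  which(keep)
}

oracle_match_loops <- function(reference, query, slack = 0) {
  matched <- logical(nrow(reference))
  for (i in seq_len(nrow(reference))) {
    if (reference$trans[i]) next
    for (j in seq_len(nrow(query))) {
      if (query$chrom[j] != reference$chromA[i]) next
      inA <- query$anchor1[j] >= reference$startA[i] + 1 - slack &&
        query$anchor1[j] <= reference$endA[i] + slack
      inB <- query$anchor2[j] >= reference$startB[i] + 1 - slack &&
        query$anchor2[j] <= reference$endB[i] + slack
      if (inA && inB) {
        matched[i] <- TRUE
        break
      }
    }
  }
  matched
}

oracle_colocalization <- function(interactions, peaks, mode) {
  hits <- vapply(seq_len(nrow(interactions)), function(i) {
    h1 <- oracle_point_in_peak(interactions$chrom[i], interactions$anchor1[i], peaks)
    h2 <- oracle_point_in_peak(interactions$chrom[i], interactions$anchor2[i], peaks)
    if (mode == "any_anchor") h1 || h2 else h1 && h2
  }, TRUE)
  mean(hits)
}

oracle_link_snps <- function(interactions, snps, window) {
  rows <- list()
  for (i in seq_len(nrow(interactions))) {
    for (s in seq_len(nrow(snps))) {
      if (interactions$chrom[i] != snps$chrom[s]) next
      d1 <- abs(snps$pos[s] - interactions$anchor1[i])
      d2 <- abs(snps$pos[s] - interactions$anchor2[i])
      if (min(d1, d2) <= window) {
        rows[[length(rows) + 1L]] <- data.frame(ia = i, snp = s)
      }
    }
  }
  if (length(rows) == 0L) data.frame(ia = integer(), snp = integer()) else do.call(rbind, rows)
}

# Direct per-locus slice-and-average on dense matrices.
oracle_aggregate <- function(dense_mats, loci, w, corner) {
  size <- 2 * w + 1
  acc <- matrix(0, size, size)
  used <- 0
  for (r in seq_len(nrow(loci))) {
    M <- dense_mats[[loci$chrom[r]]]
    i <- loci$bin_i[r]
    j <- loci$bin_j[r]
    if (is.null(M)) next
    n <- nrow(M)
    if (i - w < 0 || j + w > n - 1 || (j - i) <= 2 * w) next
    acc <- acc + M[(i - w):(i + w) + 1, (j - w):(j + w) + 1]
    used <- used + 1
  }
  if (used == 0) return(NULL)
  avg <- acc / used
  corner_block <- avg[(size - corner + 1):size, 1:corner]
  list(matrix = avg, score = avg[w + 1, w + 1] / mean(corner_block), n = used)
}
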