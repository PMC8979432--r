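# Benchmarking called interactions against reference loop sets, and
# replicate reproducibility via binned anchor coverage.
#
# Matching is "both anchors": a reference loop is recovered only if a single
# query record spans both of its anchors (two independent single-anchor hits
# do not count).

#' Match reference loops against called interactions
#'
#' A reference loop is matched iff at least one query interaction has
#' `anchor1` inside the loop's first anchor interval (+/- `slack` bp) and
#' `anchor2` inside the second (+/- `slack`), on the same chromosome, after
#' canonical ordering on both sides. Trans reference loops cannot be matched
#' by cis interactions and count as unmatched.
#'
#' @param reference Loop data.frame from [read_bedpe()].
#' @param query Interaction data.frame from [call_interactions()].
#' @param slack Symmetric slack in bp applied to each reference anchor.
#' @return An `overlap_report` list: `n_reference`, `n_matched`,
#'   `fraction_matched`, `n_query`, `matcher_slack`, and `matched`, a logical
#'   vector over reference rows.
#' @export
match_loops <- function(reference, query, slack = 0) {
  stopifnot(slack >= 0)
  if (nrow(reference) == 0L) stop("empty reference loop set: fraction undefined")
  matched <- rep(FALSE, nrow(reference))
  if (nrow(query) > 0L) {
    cis <- !reference$trans
    if (any(cis)) {
      ref <- reference[cis, , drop = FALSE]
      hitsA <- anchor_hits(ref$chromA, ref$startA, ref$endA, query$chrom, query$anchor1, slack)
      hitsB <- anchor_hits(ref$chromB, ref$startB, ref$endB, query$chrom, query$anchor2, slack)
      both <- merge(hitsA, hitsB, by = c("ref", "qry"))
      matched[which(cis)[unique(both$ref)]] <- TRUE
    }
  }
  overlap_report(matched, nrow(query), slack)
}

# (ref interval +/- slack) x (query point) containment hits as a data.frame.
anchor_hits <- function(ref_chrom, ref_start, ref_end, q_chrom, q_pos, slack) {
  ref_gr <- GenomicRanges::GRanges(
    ref_chrom,
    IRanges::IRanges(start = ref_start + 1L - slack, end = ref_end + slack)
  )
  q_gr <- points_to_gr(q_chrom, q_pos)
  hits_df(find_overlaps(ref_gr, q_gr), c("ref", "qry"))
}

#' Match reference loops against a query loop set
#'
#' A reference loop is matched iff some query loop's first anchor overlaps
#' its first anchor by at least 1 bp and the second anchors likewise
#' overlap, after canonical ordering.
#'
#' @param reference,query Loop data.frames from [read_bedpe()].
#' @return An `overlap_report`; see [match_loops()].
#' @export
match_loops_to_loops <- function(reference, query) {
  if (nrow(reference) == 0L) stop("empty reference loop set: fraction undefined")
  matched <- rep(FALSE, nrow(reference))
  if (nrow(query) > 0L) {
    refA <- GenomicRanges::GRanges(reference$chromA,
      IRanges::IRanges(reference$startA + 1L, reference$endA))
    refB <- GenomicRanges::GRanges(reference$chromB,
      IRanges::IRanges(reference$startB + 1L, reference$endB))
    qryA <- GenomicRanges::GRanges(query$chromA,
      IRanges::IRanges(query$startA + 1L, query$endA))
    qryB <- GenomicRanges::GRanges(query$chromB,
      IRanges::IRanges(query$startB + 1L, query$endB))
    both <- merge(
      hits_df(find_overlaps(refA, qryA), c("ref", "qry")),
      hits_df(find_overlaps(refB, qryB), c("ref", "qry")),
      by = c("ref", "qry")
    )
    matched[unique(both$ref)] <- TRUE
  }
  overlap_report(matched, nrow(query), slack = 0)
}

overlap_report <- function(matched, n_query, slack) {
  structure(list(
    n_reference = length(matched),
    n_matched = sum(matched),
    fraction_matched = sum(matched) / length(matched),
    n_query = n_query,
    matcher_slack = slack,
    matched = matched
  ), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %d / %d reference loops matched (%.1f%%) by %s query records (slack %d bp)\n",
              x$n_matched, x$n_reference, 100 * x$fraction_matched,
              format(x$n_query, big.mark = ","), x$matcher_slack))
  invisible(x)
}

#' Fraction of interactions colocalizing with peaks
#'
#' @param interactions Interaction data.frame.
#' @param peaks Peak interval data.frame.
#' @param mode `"any_anchor"` (default): at least one anchor inside a peak;
#'   `"both_anchors"`: both anchors inside peaks.
#' @return A proportion in `[0, 1]`.
#' @export
colocalization <- function(interactions, peaks, mode = c("any_anchor", "both_anchors")) {
  mode <- match.arg(mode)
  if (nrow(interactions) == 0L) stop("empty interaction set: colocalization undefined")
  h1 <- point_in_intervals(interactions$chrom, interactions$anchor1, peaks)
  h2 <- point_in_intervals(interactions$chrom, interactions$anchor2, peaks)
  mean(if (mode == "any_anchor") h1 | h2 else h1 & h2)
}

#' Binned anchor coverage of cis pairs
#'
#' Counts, per chromosome, how many cis-pair anchor points fall in each
#' fixed-size bin; 1-based position `p` maps to bin `floor((p-1)/bin_size)`.
#' Both anchors of every cis pair are counted; trans pairs are ignored.
#' Bins run from 0 to the last bin of the chromosome (when `chrom_sizes` is
#' given) or to the last occupied bin, so interior zero bins are retained.
#'
#' @param pairs Valid-pairs data.frame (canonical or not).
#' @param bin_size Bin width in bp.
#' @param chrom_sizes Optional named vector of chromosome lengths in bp,
#'   fixing the bin universe.
#' @return A `coverage_vector`: list with `bin_size` and `bins`, a
#'   data.frame of (`chrom`, `bin`, `count`) dense within each chromosome.
#' @export
coverage_vector <- function(pairs, bin_size, chrom_sizes = NULL) {
  stopifnot(bin_size > 0)
  cis <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  chrom <- c(cis$chrom1, cis$chrom2)
  bin <- floor((c(cis$pos1, cis$pos2) - 1) / bin_size)
  chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes) else sort(unique(chrom))
  out <- lapply(chroms, function(cc) {
    sel <- chrom == cc
    n_bins <- if (!is.null(chrom_sizes)) {
      max(1L, ceiling(chrom_sizes[[cc]] / bin_size))
    } else if (any(sel)) max(bin[sel]) + 1L else 0L
    if (n_bins == 0L) return(NULL)
    counts <- tabulate(bin[sel] + 1L, nbins = n_bins)
    data.frame(chrom = cc, bin = seq_len(n_bins) - 1L, count = counts)
  })
  structure(list(bin_size = bin_size, bins = do.call(rbind, out) %||%
                   data.frame(chrom = character(), bin = integer(), count = integer())),
            class = "coverage_vector")
}

#' Spearman correlation between two coverage vectors
#'
#' Aligns the two vectors on the union of their (chromosome, bin) keys,
#' filling absent bins with zero, concatenates genome-wide, and computes the
#' Spearman rank correlation (average ranks for ties). Bins that are zero in
#' both vectors are retained by default; dropping them materially changes
#' the coefficient, so a flag is provided.
#'
#' @param a,b `coverage_vector` objects with identical `bin_size`.
#' @param drop_zeros If `TRUE`, bins zero in both vectors are removed first.
#' @return Spearman's rho, or `NA` when either aligned vector is constant.
#' @export
spearman_correlation <- function(a, b, drop_zeros = FALSE) {
  stopifnot(inherits(a, "coverage_vector"), inherits(b, "coverage_vector"))
  if (a$bin_size != b$bin_size) stop("coverage vectors have different bin sizes")
  m <- merge(a$bins, b$bins, by = c("chrom", "bin"), all = TRUE, suffixes = c("_a", "_b"))
  m$count_a[is.na(m$count_a)] <- 0
  m$count_b[is.na(m$count_b)] <- 0
  if (drop_zeros) m <- m[m$count_a > 0 | m$count_b > 0, , drop = FALSE]
  if (nrow(m) < 2L) return(NA_real_)
  if (stats::sd(m$count_a) == 0 || stats::sd(m$count_b) == 0) return(NA_real_)
  stats::cor(m$count_a, m$count_b, method = "spearman")
}
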