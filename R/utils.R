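# Internal helpers shared across modules.

#' Normalize chromosome names to a single style
#'
#' Maps between bare ("1", "X") and UCSC-prefixed ("chr1", "chrX") naming.
#' "MT" is rewritten to "M" under the UCSC style. Idempotent.
#'
#' @param x Character vector of chromosome names.
#' @param style Either "ucsc" ("chr"-prefixed, the default, matching hg19
#'   UCSC-style annotation) or "plain".
#' @return Character vector of the same length.
#' @examples
#' normalize_chroms(c("1", "chr2", "MT"))
#' @export
normalize_chroms <- function(x, style = c("ucsc", "plain")) {
  style <- match.arg(style)
  x <- as.character(x)
  bare <- sub("^chr", "", x)
  if (style == "ucsc") {
    bare[bare == "MT"] <- "M"
    paste0("chr", bare)
  } else {
    bare[bare == "M"] <- "MT"
    bare
  }
}

# Deterministic chromosome ordering: numeric chromosomes by value, then
# X, Y, M, then anything else alphabetically. Used to canonicalize pair ends.
chrom_rank <- function(x) {
  bare <- sub("^chr", "", as.character(x))
  num <- suppressWarnings(as.numeric(bare))
  rank <- ifelse(!is.na(num), num,
    ifelse(bare == "X", 1e6,
      ifelse(bare == "Y", 1e6 + 1,
        ifelse(bare %in% c("M", "MT"), 1e6 + 2, NA_real_))))
  if (anyNA(rank)) {
    other <- sort(unique(bare[is.na(rank)]))
    rank[is.na(rank)] <- 2e6 + match(bare[is.na(rank)], other)
  }
  rank
}

# Run `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# BED-convention intervals (0-based half-open data.frame) -> GRanges (1-based
# closed). All interval arithmetic in the package goes through GRanges; the
# two genomic coordinate conventions meet only here and in write_* functions.
bed_to_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# 1-based genomic points -> width-1 GRanges.
points_to_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(seqnames = chrom, ranges = IRanges::IRanges(pos, pos))
}

# findOverlaps across objects built from different chromosome sets emits a
# routine seqlevel-union warning; silence it once here.
find_overlaps <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(a, b))
}

# TRUE for each point falling inside (or within `slack` bp of) any interval.
point_in_intervals <- function(chrom, pos, intervals, slack = 0) {
  if (length(pos) == 0L) return(logical(0))
  if (nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  gr <- bed_to_gr(intervals)
  if (slack > 0) gr <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2 * slack, fix = "center")
  suppressWarnings(IRanges::overlapsAny(points_to_gr(chrom, pos), gr))
}

# Hits object -> data.frame of (query, subject) index pairs.
hits_df <- function(h, names = c("q", "s")) {
  out <- data.frame(S4Vectors::queryHits(h), S4Vectors::subjectHits(h))
  names(out) <- names
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
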