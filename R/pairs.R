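# Valid-pair processing: canonical ordering, duplicate removal, the distance
# pre-filter, peak-anchored interaction calling, and library QC.
#
# The pipeline order mirrors the upstream procedure: dedup -> drop trans and
# sub-1 kb cis pairs -> keep 20 kb--2 Mb pairs with >= 1 anchor in a ChIP
# peak. Each surviving valid pair is reported as one interaction; coincident
# pairs from different reads stay separate interactions.

#' Canonicalize valid pairs
#'
#' Orders the two ends of every pair by (chromosome rank, position), with
#' strands travelling with their end, so downstream keys and distances are
#' well defined. Idempotent.
#'
#' @param pairs Valid-pairs data.frame (see [read_valid_pairs()]).
#' @return The same data.frame with ends ordered.
#' @export
canonicalize_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  swap <- (chrom_rank(pairs$chrom1) > chrom_rank(pairs$chrom2)) |
    (pairs$chrom1 == pairs$chrom2 & pairs$pos1 > pairs$pos2)
  if (any(swap)) {
    tmp <- pairs[swap, c("chrom1", "pos1", "strand1")]
    pairs[swap, c("chrom1", "pos1", "strand1")] <- pairs[swap, c("chrom2", "pos2", "strand2")]
    pairs[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  pairs
}

#' Remove duplicate pairs
#'
#' Collapses exact duplicates on (chrom1, pos1, strand1, chrom2, pos2,
#' strand2) — the read id is deliberately not part of the key, so PCR
#' duplicates with fresh ids are removed. Keeps the first occurrence;
#' otherwise preserves order.
#'
#' @param pairs Canonicalized valid-pairs data.frame.
#' @return Deduplicated data.frame.
#' @export
deduplicate_pairs <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  key <- paste(pairs$chrom1, pairs$pos1, pairs$strand1,
               pairs$chrom2, pairs$pos2, pairs$strand2, sep = "\r")
  out <- pairs[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Separation of a canonical cis pair; NA for trans.
pair_distance <- function(pairs) {
  ifelse(pairs$chrom1 == pairs$chrom2, pairs$pos2 - pairs$pos1, NA_real_)
}

#' Filter trans and short-range pairs
#'
#' Removes trans pairs and cis pairs separated by less than
#' `params$min_pair_dist` (default 1 kb; a pair at exactly the threshold is
#' retained). Input must be canonicalized and deduplicated.
#'
#' @param pairs Canonical, deduplicated valid-pairs data.frame.
#' @param params [analysis_params()].
#' @return Filtered data.frame.
#' @export
filter_pairs <- function(pairs, params = analysis_params()) {
  params <- as_params(params)
  if (nrow(pairs) == 0L) return(pairs)
  d <- pair_distance(pairs)
  out <- pairs[!is.na(d) & d >= params$min_pair_dist, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call peak-anchored long-range interactions
#'
#' Keeps cis pairs whose separation lies in the inclusive window
#' `[params$long_min, params$long_max]` (20 kb--2 Mb by default) and that
#' have at least one 1-bp anchor falling inside a ChIP peak interval. Every
#' surviving valid pair becomes exactly one interaction; pairs with identical
#' coordinates from different reads yield separate interactions.
#'
#' @param pairs Filtered valid-pairs data.frame (see [filter_pairs()]).
#' @param peaks Peak interval data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open), e.g. from [read_bed()].
#' @param params [analysis_params()].
#' @param slack Optional symmetric slack in bp added to each peak when
#'   testing anchor containment (default 0).
#' @param require_peaks If `TRUE` (default) an empty peak set is an error;
#'   set `FALSE` to call on distance alone.
#' @return Interaction data.frame with columns `chrom`, `anchor1`, `anchor2`,
#'   `distance`, `source_id`.
#' @export
call_interactions <- function(pairs, peaks, params = analysis_params(),
                              slack = 0, require_peaks = TRUE) {
  params <- as_params(params)
  no_peaks <- is.null(peaks) || nrow(peaks) == 0L
  if (no_peaks && require_peaks) {
    stop("peak set is empty; peak-anchored interaction calling needs peaks ",
         "(use require_peaks = FALSE for a distance-only call)")
  }
  d <- pair_distance(pairs)
  in_window <- !is.na(d) & d >= params$long_min & d <= params$long_max
  sub <- pairs[in_window, , drop = FALSE]
  if (nrow(sub) > 0L && !no_peaks) {
    hit <- point_in_intervals(sub$chrom1, sub$pos1, peaks, slack) |
      point_in_intervals(sub$chrom2, sub$pos2, peaks, slack)
    sub <- sub[hit, , drop = FALSE]
  }
  data.frame(
    chrom = sub$chrom1,
    anchor1 = sub$pos1,
    anchor2 = sub$pos2,
    distance = sub$pos2 - sub$pos1,
    source_id = sub$read_id,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Classify every raw pair into exactly one pipeline category
#'
#' Categories, applied in pipeline order: `duplicate`, `trans`, `short`
#' (cis below `min_pair_dist`), `out_of_window` (cis outside
#' `[long_min, long_max]`), `no_peak_anchor`, `called`. Counts sum to the
#' number of input pairs.
#'
#' @inheritParams call_interactions
#' @param pairs Raw valid-pairs data.frame (any order, duplicates allowed).
#' @return A factor of length `nrow(pairs)` with the above levels, in input
#'   order.
#' @export
classify_pairs <- function(pairs, peaks, params = analysis_params(), slack = 0) {
  params <- as_params(params)
  lev <- c("duplicate", "trans", "short", "out_of_window", "no_peak_anchor", "called")
  if (nrow(pairs) == 0L) return(factor(character(), levels = lev))
  canon <- canonicalize_pairs(pairs)
  key <- paste(canon$chrom1, canon$pos1, canon$strand1,
               canon$chrom2, canon$pos2, canon$strand2, sep = "\r")
  cat <- rep(NA_character_, nrow(canon))
  cat[duplicated(key)] <- "duplicate"
  d <- pair_distance(canon)
  open <- is.na(cat)
  cat[open & is.na(d)] <- "trans"
  open <- is.na(cat)
  cat[open & d < params$min_pair_dist] <- "short"
  open <- is.na(cat)
  cat[open & (d < params$long_min | d > params$long_max)] <- "out_of_window"
  open <- is.na(cat)
  if (any(open)) {
    hit <- point_in_intervals(canon$chrom1[open], canon$pos1[open], peaks, slack) |
      point_in_intervals(canon$chrom2[open], canon$pos2[open], peaks, slack)
    cat[open] <- ifelse(hit, "called", "no_peak_anchor")
  }
  factor(cat, levels = lev)
}

#' Library QC metrics
#'
#' Computes the standard per-library metrics: total and unique pair counts,
#' cis/trans split and ratio, long-range (cis separation >=
#' `params$long_min`) counts and fraction, and — when peaks are supplied —
#' the fraction of long-range pairs with at least one anchor inside a ChIP
#' peak. The peak-anchored fraction is computed on the pre-filter long-range
#' set (after the call filter it is 1 by construction).
#'
#' @param raw_pairs Raw valid-pairs data.frame.
#' @param params [analysis_params()].
#' @param peaks Optional peak intervals; when `NULL` the peak-anchored
#'   fraction is `NA`.
#' @return An object of class `qc_metrics` (a named list): `total_pairs`,
#'   `unique_pairs`, `cis_pairs`, `trans_pairs`, `cis_trans_ratio`
#'   (`Inf` when there are cis pairs but no trans; `NA` on empty input),
#'   `long_range_pairs`, `long_range_fraction`, `peak_anchored_fraction`.
#' @export
qc_metrics <- function(raw_pairs, params = analysis_params(), peaks = NULL) {
  params <- as_params(params)
  uniq <- deduplicate_pairs(canonicalize_pairs(raw_pairs))
  d <- pair_distance(uniq)
  cis <- sum(!is.na(d))
  trans <- sum(is.na(d))
  long_idx <- !is.na(d) & d >= params$long_min
  n_long <- sum(long_idx)
  peak_frac <- NA_real_
  if (!is.null(peaks) && n_long > 0L) {
    sub <- uniq[long_idx, , drop = FALSE]
    hit <- point_in_intervals(sub$chrom1, sub$pos1, peaks) |
      point_in_intervals(sub$chrom2, sub$pos2, peaks)
    peak_frac <- mean(hit)
  }
  structure(list(
    total_pairs = nrow(raw_pairs),
    unique_pairs = nrow(uniq),
    cis_pairs = cis,
    trans_pairs = trans,
    cis_trans_ratio = if (nrow(uniq) == 0L) NA_real_ else if (trans == 0L) Inf else cis / trans,
    long_range_pairs = n_long,
    long_range_fraction = if (nrow(uniq) == 0L) 0 else n_long / nrow(uniq),
    peak_anchored_fraction = peak_frac
  ), class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat("Library QC\n")
  cat(sprintf("  total pairs            %s\n", format(x$total_pairs, big.mark = ",")))
  cat(sprintf("  unique pairs           %s\n", format(x$unique_pairs, big.mark = ",")))
  cat(sprintf("  cis / trans            %s / %s (ratio %.3g)\n",
              format(x$cis_pairs, big.mark = ","), format(x$trans_pairs, big.mark = ","),
              x$cis_trans_ratio))
  cat(sprintf("  long-range (cis)       %s (%.1f%% of unique)\n",
              format(x$long_range_pairs, big.mark = ","), 100 * x$long_range_fraction))
  if (!is.na(x$peak_anchored_fraction)) {
    cat(sprintf("  peak-anchored fraction %.1f%% of long-range\n",
                100 * x$peak_anchored_fraction))
  }
  invisible(x)
}

#' Write QC metrics as a two-column TSV report
#'
#' @param qc A `qc_metrics` object.
#' @param path Output path.
#' @export
write_qc_report <- function(qc, path) {
  df <- data.frame(metric = names(unclass(qc)),
                   value = vapply(unclass(qc), as.numeric, 0))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
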