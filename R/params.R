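#' Analysis parameters
#'
#' Collects every threshold of the interaction-calling and annotation
#' procedure in one validated object, so that each stage receives the same
#' conventions. Defaults are the values used throughout the workflow:
#' a 1 kb minimum pair separation, a 20 kb--2 Mb long-range window (inclusive
#' on both ends), a 5 kb SNP window, promoters defined as TSS +/- 2,500 bp,
#' motif anchors extended 100 bp on each side, and APA over peak pairs
#' separated by at least 5 kb but less than 1 Mb, 200,000 sampled loci pairs,
#' at 5 kb matrix resolution.
#'
#' @param min_pair_dist Minimum cis pair separation in bp; pairs closer than
#'   this are treated as self-ligation/religation artifacts and removed.
#' @param long_min,long_max Long-range window in bp, inclusive at both ends.
#' @param snp_window Maximum anchor-to-SNP distance in bp (inclusive).
#' @param promoter_flank Half-width of the promoter interval around the TSS, bp.
#' @param anchor_extension Extension applied to each side of a 1-bp anchor
#'   when writing motif-ready intervals, bp.
#' @param apa_min_sep,apa_max_sep Peak-midpoint separation bounds for APA loci,
#'   bp; the lower bound is inclusive, the upper exclusive.
#' @param apa_sample_n Number of loci pairs sampled per APA plot.
#' @param apa_resolution Contact-matrix bin size for APA, bp.
#' @param corr_bin Bin size for replicate coverage correlation, bp.
#' @param seed Integer seed forwarded to any randomized step.
#' @return An object of class `analysis_params` (a named list).
#' @examples
#' p <- analysis_params()
#' p$long_min
#' @export
analysis_params <- function(min_pair_dist = 1000L,
                            long_min = 20000L,
                            long_max = 2000000L,
                            snp_window = 5000L,
                            promoter_flank = 2500L,
                            anchor_extension = 100L,
                            apa_min_sep = 5000L,
                            apa_max_sep = 1000000L,
                            apa_sample_n = 200000L,
                            apa_resolution = 5000L,
                            corr_bin = 10000L,
                            seed = 1L) {
  p <- list(
    min_pair_dist = as.numeric(min_pair_dist),
    long_min = as.numeric(long_min),
    long_max = as.numeric(long_max),
    snp_window = as.numeric(snp_window),
    promoter_flank = as.numeric(promoter_flank),
    anchor_extension = as.numeric(anchor_extension),
    apa_min_sep = as.numeric(apa_min_sep),
    apa_max_sep = as.numeric(apa_max_sep),
    apa_sample_n = as.numeric(apa_sample_n),
    apa_resolution = as.numeric(apa_resolution),
    corr_bin = as.numeric(corr_bin),
    seed = as.integer(seed)
  )
  stopifnot(
    p$min_pair_dist > 0,
    p$min_pair_dist < p$long_min,
    p$long_min < p$long_max,
    p$apa_min_sep < p$apa_max_sep,
    p$snp_window >= 0,
    p$promoter_flank > 0,
    p$anchor_extension > 0,
    p$apa_sample_n > 0,
    p$apa_resolution > 0,
    p$corr_bin > 0
  )
  structure(p, class = "analysis_params")
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("analysis_params:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]], big.mark = ",")))
  invisible(x)
}

as_params <- function(params) {
  if (is.null(params)) return(analysis_params())
  stopifnot(inherits(params, "analysis_params"))
  params
}
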