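# Linking called interactions to GWAS SNPs and gene promoters, and
# preparing non-promoter anchor sets for external motif discovery.

#' Promoter intervals from a gene table
#'
#' One interval per gene, centered on the strand-aware TSS (the 1-based
#' position `tx_start + 1` for `+` genes, `tx_end` for `-` genes), spanning
#' TSS +/- `flank` bp and clipped at the chromosome start. With
#' `strand_aware = FALSE` the `tx_start` end is used for every gene,
#' matching strand-ignorant replication of window-tool pipelines.
#'
#' @param genes Gene data.frame from [read_gene_table()].
#' @param flank Half-width in bp (default 2,500).
#' @param strand_aware Use the strand to pick the TSS end (default `TRUE`).
#' @return Interval data.frame (`chrom`, `start`, `end`, `name`), 0-based
#'   half-open, each of width `2*flank + 1` unless clipped.
#' @export
promoters <- function(genes, flank = 2500L, strand_aware = TRUE) {
  stopifnot(flank > 0)
  tss <- if (strand_aware) {
    ifelse(genes$strand == "+", genes$tx_start + 1, genes$tx_end)
  } else {
    genes$tx_start + 1
  }
  data.frame(
    chrom = genes$chrom,
    start = pmax(0, tss - 1 - flank),
    end = tss + flank,
    name = genes$name,
    stringsAsFactors = FALSE
  )
}

#' Link interactions to GWAS SNPs
#'
#' An interaction links to a SNP iff they share a chromosome and the SNP
#' lies within `params$snp_window` bp (inclusive) of either anchor point.
#' Every qualifying (interaction, SNP) combination is emitted as one row;
#' the number of distinct linked interactions is attached as an attribute
#' (reported alongside the row count, since one interaction near several
#' SNPs yields several rows).
#'
#' @param interactions Interaction data.frame from [call_interactions()].
#' @param snps SNP data.frame from [read_gwas_catalog()].
#' @param params [analysis_params()].
#' @return A data.frame of linkages with the interaction columns, `rsid`,
#'   `snp_pos`, `trait`, `matched_anchor` (`"1"`, `"2"` or `"both"`) and
#'   `interaction_id` (row index into `interactions`); attribute
#'   `n_unique_interactions` carries the distinct-interaction count.
#' @export
link_snps <- function(interactions, snps, params = analysis_params()) {
  params <- as_params(params)
  empty <- data.frame(
    interaction_id = integer(), chrom = character(), anchor1 = numeric(),
    anchor2 = numeric(), distance = numeric(), source_id = character(),
    rsid = character(), snp_pos = numeric(), trait = character(),
    matched_anchor = character(), stringsAsFactors = FALSE
  )
  if (nrow(interactions) == 0L || nrow(snps) == 0L) {
    attr(empty, "n_unique_interactions") <- 0L
    return(empty)
  }
  win <- GenomicRanges::GRanges(
    snps$chrom,
    IRanges::IRanges(pmax(1, snps$pos - params$snp_window), snps$pos + params$snp_window)
  )
  h1 <- hits_df(find_overlaps(points_to_gr(interactions$chrom, interactions$anchor1), win),
                c("ia", "snp"))
  h2 <- hits_df(find_overlaps(points_to_gr(interactions$chrom, interactions$anchor2), win),
                c("ia", "snp"))
  h1$anchor <- rep(1L, nrow(h1))
  h2$anchor <- rep(2L, nrow(h2))
  hits <- rbind(h1, h2)
  if (nrow(hits) == 0L) {
    attr(empty, "n_unique_interactions") <- 0L
    return(empty)
  }
  agg <- stats::aggregate(anchor ~ ia + snp, data = hits,
                          FUN = function(a) paste(sort(unique(a)), collapse = ","))
  agg$matched_anchor <- ifelse(agg$anchor == "1,2", "both", agg$anchor)
  out <- data.frame(
    interaction_id = agg$ia,
    interactions[agg$ia, c("chrom", "anchor1", "anchor2", "distance", "source_id")],
    rsid = snps$rsid[agg$snp],
    snp_pos = snps$pos[agg$snp],
    trait = snps$trait[agg$snp],
    matched_anchor = agg$matched_anchor,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out <- out[order(out$interaction_id, out$snp_pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unique_interactions") <- length(unique(out$interaction_id))
  out
}

#' Map SNP-linked interactions to gene promoters
#'
#' For each linkage row, records the genes whose promoter interval contains
#' either anchor point (containment, not a further window). Adds a
#' `promoter_genes` list-column and a `has_promoter` flag; the distinct gene
#' names across promoter-positive linkages are attached as attribute
#' `unique_genes`.
#'
#' @param linkages Linkage data.frame from [link_snps()].
#' @param promoter_intervals Promoter intervals from [promoters()] (must
#'   carry a `name` column).
#' @return `linkages` with `promoter_genes` (list of character vectors) and
#'   `has_promoter` columns; attributes `unique_genes` and
#'   `n_promoter_linkages`.
#' @export
map_to_promoters <- function(linkages, promoter_intervals) {
  stopifnot(!is.null(promoter_intervals$name))
  n <- nrow(linkages)
  genes_per_row <- rep(list(character()), n)
  if (n > 0L && nrow(promoter_intervals) > 0L) {
    prom <- bed_to_gr(promoter_intervals)
    for (anchor in c("anchor1", "anchor2")) {
      h <- find_overlaps(points_to_gr(linkages$chrom, linkages[[anchor]]), prom)
      for (k in seq_along(h)) {
        i <- S4Vectors::queryHits(h)[k]
        genes_per_row[[i]] <- c(genes_per_row[[i]], promoter_intervals$name[S4Vectors::subjectHits(h)[k]])
      }
    }
    genes_per_row <- lapply(genes_per_row, function(g) sort(unique(g)))
  }
  linkages$promoter_genes <- genes_per_row
  linkages$has_promoter <- lengths(genes_per_row) > 0L
  attr(linkages, "unique_genes") <- sort(unique(unlist(genes_per_row)))
  attr(linkages, "n_promoter_linkages") <- sum(linkages$has_promoter)
  linkages
}

#' Prepare non-promoter anchors for motif discovery
#'
#' Collects all interaction anchor points, drops those falling within
#' TSS +/- `params$promoter_flank` of any gene (promoter containment, same
#' rule as [promoters()]), and extends each surviving 1-bp anchor by
#' `params$anchor_extension` bp on each side, yielding BED-writable
#' intervals of width `2*extension + 1` (201 bp at the defaults). Output is
#' sorted and deduplicated.
#'
#' @param interactions Interaction data.frame.
#' @param genes Gene data.frame from [read_gene_table()].
#' @param params [analysis_params()].
#' @param strand_aware Passed to [promoters()].
#' @return Interval data.frame (`chrom`, `start`, `end`), 0-based half-open.
#' @export
prepare_motif_anchors <- function(interactions, genes, params = analysis_params(),
                                  strand_aware = TRUE) {
  params <- as_params(params)
  anchors <- data.frame(
    chrom = c(interactions$chrom, interactions$chrom),
    pos = c(interactions$anchor1, interactions$anchor2),
    stringsAsFactors = FALSE
  )
  anchors <- unique(anchors)
  prom <- promoters(genes, flank = params$promoter_flank, strand_aware = strand_aware)
  drop <- point_in_intervals(anchors$chrom, anchors$pos, prom)
  keep <- anchors[!drop, , drop = FALSE]
  out <- data.frame(
    chrom = keep$chrom,
    start = pmax(0, keep$pos - 1 - params$anchor_extension),
    end = keep$pos + params$anchor_extension,
    stringsAsFactors = FALSE
  )
  out <- unique(out)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
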