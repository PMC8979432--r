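#!/usr/bin/env Rscript
# Link called interactions to GWAS-style SNPs (5 kb window on 1-bp anchors),
# map SNP-linked interactions to gene promoters (TSS +/- 2,500 bp), and
# prepare the non-promoter anchor set for external motif discovery
# (anchors extended 100 bp on each side).
#
# Reads  results/synthetic/, results/interactions.bedpe;
# writes results/snp_links.tsv, results/linked_genes.txt,
#        results/motif_anchors.bed.

suppressMessages(library(proxloop))

params <- analysis_params(seed = 7)
interactions <- read_interactions_bedpe("results/interactions.bedpe")
snps <- read_gwas_catalog("results/synthetic/snps.tsv")
genes <- read_gene_table("results/synthetic/genes.tsv")

links <- link_snps(interactions, snps, params)
cat(sprintf("%d linkage rows over %d distinct SNP-linked interactions (of %s called)\n",
            nrow(links), attr(links, "n_unique_interactions"),
            format(nrow(interactions), big.mark = ",")))

prom <- promoters(genes, params$promoter_flank)
links <- map_to_promoters(links, prom)
genes_hit <- attr(links, "unique_genes")
cat(sprintf("%d linkages touch a promoter; %d unique candidate genes\n",
            attr(links, "n_promoter_linkages"), length(genes_hit)))

flat <- links
flat$promoter_genes <- vapply(links$promoter_genes, paste, "", collapse = ",")
write.table(flat, "results/snp_links.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(genes_hit, "results/linked_genes.txt")

anchors <- prepare_motif_anchors(interactions, genes, params)
write_bed(anchors, "results/motif_anchors.bed")
cat(sprintf("%s motif-ready anchor intervals (201 bp, promoter-excluded) -> results/motif_anchors.bed\n",
            format(nrow(anchors), big.mark = ",")))
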