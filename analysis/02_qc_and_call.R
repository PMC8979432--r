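#!/usr/bin/env Rscript
# Library QC and interaction calling on the simulated dataset, through the
# same file formats a real run would use: read the valid-pairs file and peak
# BED back in, deduplicate, drop trans and sub-1 kb pairs, then keep
# 20 kb - 2 Mb pairs with at least one anchor in a ChIP peak. Each surviving
# valid pair is one interaction.
#
# Reads  results/synthetic/; writes qc.tsv, pair_classes.tsv, interactions.bedpe.

suppressMessages(library(proxloop))

params <- analysis_params(seed = 7)
pairs <- read_valid_pairs("results/synthetic/pairs.allValidPairs")
peaks <- read_bed("results/synthetic/peaks.bed")

qc <- qc_metrics(pairs, params, peaks)
print(qc)
write_qc_report(qc, "results/qc.tsv")

cls <- classify_pairs(pairs, peaks, params)
cls_tab <- as.data.frame(table(class = cls))
write.table(cls_tab, "results/pair_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nPipeline classification (sums to the input):\n")
print(cls_tab)
stopifnot(sum(cls_tab$Freq) == nrow(pairs))

interactions <- call_interactions(
  filter_pairs(deduplicate_pairs(canonicalize_pairs(pairs)), params),
  peaks, params
)
write_interactions_bedpe(interactions, "results/interactions.bedpe")
cat(sprintf("\nCalled %s long-range peak-anchored interactions -> results/interactions.bedpe\n",
            format(nrow(interactions), big.mark = ",")))
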