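#!/usr/bin/env Rscript
# Aggregate peak analysis on the simulated dataset: bin the filtered cis
# pairs into 5 kb contact matrices, Knight-Ruiz balance them, and average
# 21x21 balanced submatrices over (a) the planted loop anchor pairs,
# (b) random peak-pair loci, and (c) the same loci on a loop-free,
# decay-only control simulation.
#
# Reads  results/synthetic/; writes results/apa_scores.tsv and
# results/apa_matrix_planted.tsv.

suppressMessages(library(proxloop))

params <- analysis_params(seed = 7)
cfg <- simulation_config(seed = 7L)

pairs <- read_valid_pairs("results/synthetic/pairs.allValidPairs")
peaks <- read_bed("results/synthetic/peaks.bed")
truth <- read_bedpe("results/synthetic/loops_truth.bedpe")

canon <- filter_pairs(deduplicate_pairs(canonicalize_pairs(pairs)), params)
mats <- lapply(bin_pairs(canon, params$apa_resolution, cfg$chrom_sizes), kr_balance)

planted <- data.frame(
  chrom = truth$chromA,
  bin_i = floor(truth$endA / params$apa_resolution),
  bin_j = floor(truth$endB / params$apa_resolution)
)
apa_planted <- aggregate_apa(mats, planted)
cat("APA at planted loop anchors: ")
print(apa_planted)

random_loci <- sample_loci(enumerate_loci(peaks, params$apa_resolution, params),
                           2000L, seed = params$seed)
apa_random <- aggregate_apa(mats, random_loci)
cat("APA at random peak pairs:    ")
print(apa_random)

cfg0 <- simulation_config(n_loops = 0L, peak_anchor_fraction = 0,
                          trans_fraction = 0, duplicate_fraction = 0, seed = 7L)
b0 <- simulate_dataset(cfg0)
canon0 <- filter_pairs(deduplicate_pairs(canonicalize_pairs(b0$pairs)), params)
mats0 <- lapply(bin_pairs(canon0, params$apa_resolution, cfg0$chrom_sizes), kr_balance)
loci0 <- sample_loci(enumerate_loci(b0$peaks, params$apa_resolution, params),
                     2000L, seed = params$seed)
apa_null <- aggregate_apa(mats0, loci0)
cat("APA on decay-only control:   ")
print(apa_null)
cat("(the lower-left corner sits nearer the diagonal than the center, so a\n")
cat(" pure distance-decay background pushes this score below 1; see the\n")
cat(" methods vignette for the analysis)\n")

scores <- data.frame(
  set = c("planted_loops", "random_peak_pairs", "decay_only_control"),
  score = c(apa_planted$score, apa_random$score, apa_null$score),
  loci_used = c(apa_planted$n_pairs_used, apa_random$n_pairs_used, apa_null$n_pairs_used)
)
write.table(scores, "results/apa_scores.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(round(apa_planted$matrix, 6), "results/apa_matrix_planted.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
cat("Wrote results/apa_scores.tsv, results/apa_matrix_planted.tsv\n")
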