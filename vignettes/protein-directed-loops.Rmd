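---
title: "Calling protein-directed chromatin interactions from valid pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling protein-directed chromatin interactions from valid pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxloop)
```

## The analysis model

Low-input, tagmentation-assisted proximity-ligation assays read out chromatin
contacts that are directed by a specific DNA-binding protein (a transcription
factor such as CTCF, RNA polymerase II, or a histone mark such as H3K27ac).
Because the transposase cuts only at antibody-marked chromatin, the libraries
carry very little nonspecific background, and the contact signal can be
interpreted without a loop-calling model: the pipeline implemented here is a
deterministic sequence of filters over the aligned *valid pairs* (uniquely
mapped, artifact-free ligation read pairs, one per line of a HiC-Pro-style
`allValidPairs` file).

The calling rule is:

1. **Canonicalize** each pair so its ends are ordered by chromosome, then
   position (strands travel with their end), and **deduplicate** on the exact
   coordinate-and-strand key — read identifiers are not part of the key, so
   PCR duplicates collapse.
2. **Pre-filter**: remove trans pairs and cis pairs separated by less than
   1 kb (self-ligation and re-ligation artifacts). A pair at exactly 1 kb is
   retained.
3. **Call**: keep cis pairs whose separation $d = p_2 - p_1$ satisfies
   $20\,\mathrm{kb} \le d \le 2\,\mathrm{Mb}$ (inclusive at both ends) *and*
   that have at least one anchor point inside a ChIP/CUT&RUN peak interval.
   Every surviving valid pair is reported as one interaction with two 1-bp
   anchors; coincident pairs from different reads stay separate interactions
   — no merging, clustering or significance model is applied.

Everything downstream (benchmarking, APA, SNP annotation) consumes this
interaction set.

### Coordinate conventions

Positions of pairs, interaction anchors and SNPs are 1-based points. All
interval tables (peaks, loop anchors, promoters, motif anchors) use the BED
convention: 0-based, half-open. The two conventions meet only inside the I/O
module; a 1-bp anchor at 1-based position $p$ is written as the interval
$[p-1, p)$. Chromosome names are normalized once, to UCSC style (`chr1`),
and chromosomes order numerically, then X, Y, M, then others alphabetically.

## Parameters

All thresholds live in one object, `analysis_params()`:

| parameter | default | unit | role |
|---|---|---|---|
| `min_pair_dist` | 1,000 | bp | cis pre-filter; `< 1 kb` removed, boundary kept |
| `long_min`, `long_max` | 20,000 / 2,000,000 | bp | calling window, inclusive both ends |
| `snp_window` | 5,000 | bp | max anchor-to-SNP distance, inclusive |
| `promoter_flank` | 2,500 | bp | promoter = TSS ± flank |
| `anchor_extension` | 100 | bp | motif anchors become 201-bp intervals |
| `apa_min_sep`, `apa_max_sep` | 5,000 / 1,000,000 | bp | peak-pair loci: `min ≤ s < max` |
| `apa_sample_n` | 200,000 | count | loci sampled per APA |
| `apa_resolution` | 5,000 | bp | contact-matrix bin size |
| `corr_bin` | 10,000 | bp | replicate-coverage bin size |

Boundary semantics were chosen once and are asserted by tests: the calling
window is inclusive at both ends (the conventional reading of "between 20 kb
and 2 Mb"), the SNP window is inclusive (`5,000` links, `5,001` does not),
the APA separation range is inclusive below and exclusive above ("at least
5 kb but less than 1 Mb"), and a point exactly `promoter_flank` from a TSS is
inside the promoter.

## Benchmarking

`match_loops()` asks, for each reference loop (a BEDPE record with two anchor
intervals), whether **a single** query interaction spans both anchors —
anchor 1 inside the first interval, anchor 2 inside the second, after
canonical ordering on both sides. Two independent single-anchor hits do not
match a loop: a loop is evidence of one paired contact, so it must be
recovered by one paired-end observation. An optional symmetric `slack`
widens the reference anchors; recovered fractions are monotone in slack, and
published overlaps whose tolerance is unknown can be reproduced by sweeping
it (`analysis/03_benchmark.R` does). Loop-against-loop comparison
(`match_loops_to_loops()`) instead requires at least 1 bp of interval
overlap on both anchors.

Replicate reproducibility follows the genome-browser convention: both
anchors of every cis pair are counted into fixed-size bins
(`floor((pos-1)/bin)`), the two genome-wide vectors are aligned on the union
of their bins, and Spearman's rank correlation is computed with average
ranks for ties. Bins that are zero in both replicates are *retained* by
default — dropping them changes the coefficient materially, so
`spearman_correlation(..., drop_zeros = TRUE)` makes the choice explicit
rather than silent.

## Aggregate peak analysis

APA is implemented from scratch:

* `bin_pairs()` builds per-chromosome sparse symmetric contact matrices;
  total upper-triangle mass equals the number of cis pairs binned.
* `kr_balance()` computes Knight–Ruiz weights $w$ such that
  $w_i c_{ij} w_j$ has unit row sums, by the inner–outer Newton iteration
  with a conjugate-gradient inner solve; all-zero rows are excluded and get
  `NA` weights. Tolerance is $10^{-6}$ on the maximum row-sum deviation with
  a 3,000-iteration budget; if the Newton iteration stalls, a symmetric
  Sinkhorn–Knopp fixed point ($x \leftarrow \sqrt{x / (Ax)}$) is tried
  before the function errors with the residual.
* `enumerate_loci()` reduces each peak to a point — the interval midpoint,
  or the narrowPeak summit column when requested — and keeps all
  within-chromosome pairs with point separation in
  $[\texttt{apa\_min\_sep}, \texttt{apa\_max\_sep})$, measured in bp before
  binning, deduplicated at bin level. `sample_loci()` draws up to 200,000 of
  them uniformly without replacement under an explicit seed.
* `aggregate_apa()` averages the $(2w+1)\times(2w+1)$ balanced submatrix
  centered on each locus ($w = 10$ bins by default). Loci whose window runs
  off the matrix **or touches/crosses the diagonal** ($\mathrm{bin}_j -
  \mathrm{bin}_i \le 2w$) are dropped and counted: a window crossing the
  diagonal would read reflected upper-triangle counts. The score is the
  central pixel over the mean of the $6\times6$ lower-left corner block —
  the corner nearest the diagonal.

### Why the null score of the corner convention sits below 1

The lower-left corner lies 10–20 bins closer to the diagonal than the
center, i.e. at systematically *shorter* genomic separation. Under a pure
distance-decay background $c(d) \propto d^{-1}$ the corner therefore has a
higher expected balanced count than the center, and the aggregate score over
random loci concentrates near
$\mathbb{E}[1/d]\,/\,\mathbb{E}[1/(d - 12.5\ \mathrm{bins})] \approx
0.7\text{–}0.8$ for loci separated by 0.1–1 Mb at 5 kb bins — not at 1.
`analysis/04_apa.R` measures exactly this on a loop-free control simulation
(score 0.70) against planted loops (score ≫ 1.5). This is a property of the
corner-normalized convention itself, which is why tools using it
distance-filter their loop lists; the score is still a sharp discriminator
between looping and non-looping loci at matched loci distributions. A
`balanced = FALSE` mode aggregates raw counts; distance-normalized
("expected model") APA is deliberately out of scope.

## The synthetic-data generator

`simulation_config()` / `simulate_dataset()` generate a valid-pairs library
with complete ground truth. It emulates the statistical structure the
pipeline's decisions rest on:

* **distance decay**: background cis separations follow a truncated power
  law $P(d) \propto d^{-\alpha}$ on $[1\ \mathrm{kb}, L)$, with
  $\alpha = 1$, the canonical sub-Mb contact-probability slope, by inverse-CDF
  sampling (the law is exact, which the Kolmogorov–Smirnov test relies on);
* **protein-directed capture**: 70% of background pairs have one end inside
  a planted peak, peaks carrying log-normal strengths, matching the
  60–80% peak-anchored fraction such libraries report; half of those pairs
  have their distal end at another occupied site, chosen with probability
  proportional to strength times the decay kernel;
* **coverage heterogeneity**: a planted accessibility field (log-normal
  weights on 20 kb tiles, shared between replicates) modulates where
  background pairs originate. Without it, bins of equal expected count have
  random relative ranks and replicate Spearman correlations plateau around
  0.6 regardless of structure; with it the default conditions reproduce the
  ρ > 0.7 reported for real biological replicates (measured ≈ 0.85);
* **planted loops**: loop anchors are midpoints of planted peaks, so the
  peak-anchor filter can never exclude a planted loop; loop pairs jitter
  uniformly within the anchor peak, keeping them recoverable at
  slack ≤ peak width;
* **artifacts**: uniform trans pairs and exact-replay PCR duplicates (fresh
  read ids, same coordinates and strands — exercising the deduplication
  key).

The default conditions are two 10-Mb chromosomes, 200 peaks of 1 kb, 50
loops × 40 pairs, and 80,000 background pairs — the library depth matched
per-bp to a 12-million-pair library on a 3-Gb genome. Replicates share the
planted structure and redraw pairs under per-replicate seed offsets.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: TAD/compartment structure, restriction-fragment
geometry, mappability holes, chromosome-specific decay, LD structure among
GWAS SNPs, and realistic gene density. The generator validates the
*operations* (filters, matching, balancing, aggregation, annotation), not
biological effect sizes.

## Annotation

`promoters()` centers the promoter on the strand-aware TSS (`tx_start` for
`+` genes, `tx_end` for `-` genes, both as 1-based points), spanning
TSS ± 2,500 bp clipped at zero. Promoters are biologically strand-anchored,
so strand-awareness is the default; `strand_aware = FALSE` reproduces
strand-ignorant window pipelines exactly. `link_snps()` joins interactions
to SNPs within 5 kb of either 1-bp anchor and reports *both* counts — every
qualifying (interaction, SNP) row, and the number of distinct linked
interactions — because one interaction near several SNPs is one candidate
locus but several associations. `map_to_promoters()` requires the anchor
point to lie *inside* the promoter interval (containment, not a second
window). `prepare_motif_anchors()` drops promoter-proximal anchors and
extends the survivors by 100 bp per side into 201-bp intervals, sorted and
deduplicated, disjoint from the promoter set by construction.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the generator at the default
20-Mb genome (seconds per stage on one core); oracle-equivalence checks use
50 randomized instances of 20–60 pairs against plain double-loop
reimplementations; KR accuracy is checked on 200×200 dense and
~2,000-bin sparse matrices. Every randomized step takes an explicit seed,
and a bundle is a byte-identical function of its configuration.

## Known limitations

* The each-pair-is-an-interaction rule means interaction counts scale with
  depth; comparisons across libraries should use fractions, not counts.
* KR weights are defined only for bins with nonzero marginals; fully zero
  rows propagate zeros (not `NA`s) into balanced submatrices.
* The corner-normalized APA score is distance-biased under decay (above);
  compare scores only between loci sets with matched separation
  distributions.
* Loop matching treats reference loops independently; a single interaction
  may match several overlapping reference loops.
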