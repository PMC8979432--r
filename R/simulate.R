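# Synthetic valid-pairs datasets with known ground truth: planted ChIP
# peaks, planted loops anchored at peaks, a distance-decay cis background,
# trans noise, PCR duplicates, GWAS-style SNPs and a gene table. Every
# pipeline stage can be exercised against the emitted truth report.
#
# The generator emulates a protein-directed assay: a configurable fraction
# of background pairs has one end inside a ChIP peak, and peaks carry
# log-normal strengths, reproducing the two properties of the real data the
# benchmarks rely on -- a majority of long-range pairs anchored in peaks,
# and replicate coverage that rank-correlates strongly because peak
# strengths (not Poisson noise) dominate bin ranks.

#' Simulation configuration
#'
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @param n_peaks Number of planted peaks (allocated across chromosomes by
#'   length).
#' @param peak_width Peak width in bp.
#' @param n_loops Number of planted loops; each loop joins the midpoints of
#'   two planted peaks on one chromosome.
#' @param loop_distance_range Numeric length-2: admissible anchor-midpoint
#'   separation for planted loops, bp (inclusive).
#' @param n_background_pairs Number of background cis pairs.
#' @param n_loop_pairs_per_loop Pairs emitted per planted loop.
#' @param decay_exponent Power-law slope of the background contact-distance
#'   density (`P(d) ~ d^-decay_exponent`), truncated to
#'   `[1 kb, chromosome span)`. 1.0 is the canonical sub-Mb Hi-C slope.
#' @param trans_fraction Trans pairs added, as a fraction of cis pairs.
#' @param duplicate_fraction PCR duplicates added, as a fraction of emitted
#'   pairs; duplicates replay exact coordinates and strands under fresh read
#'   ids.
#' @param n_snps Number of SNPs placed uniformly.
#' @param n_genes Number of genes with uniform TSS, lengths 5--50 kb.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @param peak_anchor_fraction Fraction of background pairs with one end
#'   inside a peak (protein-directed capture).
#' @param peak_pair_fraction Of the peak-anchored background pairs, the
#'   fraction whose distal end also lies in a peak, the partner chosen with
#'   probability proportional to its strength times the decay kernel of the
#'   separation (contacts between occupied sites dominate protein-directed
#'   libraries).
#' @param peak_weight_sdlog Log-normal sd of per-peak anchoring strength.
#' @param accessibility_sdlog Log-normal sd of the planted chromatin
#'   accessibility field (20 kb tiles) that modulates where background pairs
#'   originate; shared between replicates, it reproduces the genome-wide
#'   coverage heterogeneity (accessibility, mappability) that real replicate
#'   correlations rest on. Set to 0 for a spatially flat background.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(chrom_sizes = c(chr1 = 10e6, chr2 = 10e6),
                              n_peaks = 200L,
                              peak_width = 1000L,
                              n_loops = 50L,
                              loop_distance_range = c(30000, 1000000),
                              n_background_pairs = 80000L,
                              n_loop_pairs_per_loop = 40L,
                              decay_exponent = 1.0,
                              trans_fraction = 0.05,
                              duplicate_fraction = 0.05,
                              n_snps = 100L,
                              n_genes = 200L,
                              seed = 7L,
                              peak_anchor_fraction = 0.7,
                              peak_pair_fraction = 0.5,
                              peak_weight_sdlog = 1.0,
                              accessibility_sdlog = 1.0) {
  cfg <- list(
    chrom_sizes = chrom_sizes, n_peaks = as.integer(n_peaks),
    peak_width = as.numeric(peak_width), n_loops = as.integer(n_loops),
    loop_distance_range = as.numeric(loop_distance_range),
    n_background_pairs = as.integer(n_background_pairs),
    n_loop_pairs_per_loop = as.integer(n_loop_pairs_per_loop),
    decay_exponent = as.numeric(decay_exponent),
    trans_fraction = as.numeric(trans_fraction),
    duplicate_fraction = as.numeric(duplicate_fraction),
    n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
    seed = as.integer(seed),
    peak_anchor_fraction = as.numeric(peak_anchor_fraction),
    peak_pair_fraction = as.numeric(peak_pair_fraction),
    peak_weight_sdlog = as.numeric(peak_weight_sdlog),
    accessibility_sdlog = as.numeric(accessibility_sdlog)
  )
  stopifnot(
    length(cfg$chrom_sizes) >= 1L, all(cfg$chrom_sizes > 0),
    !is.null(names(cfg$chrom_sizes)),
    cfg$n_peaks >= 0L, cfg$peak_width > 0, cfg$n_loops >= 0L,
    length(cfg$loop_distance_range) == 2L,
    cfg$loop_distance_range[1] > 0,
    cfg$loop_distance_range[2] < min(cfg$chrom_sizes),
    cfg$loop_distance_range[1] <= cfg$loop_distance_range[2],
    cfg$n_background_pairs >= 0L, cfg$n_loop_pairs_per_loop >= 0L,
    cfg$trans_fraction >= 0, cfg$trans_fraction <= 1,
    cfg$duplicate_fraction >= 0, cfg$duplicate_fraction <= 1,
    cfg$peak_anchor_fraction >= 0, cfg$peak_anchor_fraction <= 1,
    cfg$peak_pair_fraction >= 0, cfg$peak_pair_fraction <= 1,
    cfg$n_snps >= 0L, cfg$n_genes >= 0L
  )
  structure(cfg, class = "simulation_config")
}

# Inverse-CDF sample from a power law d^-alpha truncated to [lo, hi].
rpowerlaw <- function(n, alpha, lo, hi) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    (lo^(1 - alpha) + u * (hi^(1 - alpha) - lo^(1 - alpha)))^(1 / (1 - alpha))
  }
}

# Allocate a count across chromosomes proportionally to length, exactly.
allocate_by_length <- function(n, chrom_sizes) {
  frac <- chrom_sizes / sum(chrom_sizes)
  base <- floor(n * frac)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(chrom_sizes))
}

# Plant the shared structure: peaks (with strengths), loops, SNPs, genes.
plant_structure <- function(config) {
  with_seed(config$seed, {
    margin <- 20000
    w <- config$peak_width
    per_chrom <- allocate_by_length(config$n_peaks, config$chrom_sizes)
    peaks <- do.call(rbind, lapply(names(config$chrom_sizes), function(cc) {
      k <- per_chrom[[cc]]
      if (k == 0L) return(NULL)
      L <- config$chrom_sizes[[cc]]
      span <- L - 2 * margin - k * w
      if (span <= 0) stop("peaks do not fit on ", cc, " without overlap")
      u <- sort(floor(stats::runif(k, 0, span)))
      starts <- margin + u + (seq_len(k) - 1) * w
      data.frame(chrom = cc, start = starts, end = starts + w,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(peaks)) peaks <- data.frame(chrom = character(), start = numeric(), end = numeric())
    peaks$name <- sprintf("peak%04d", seq_len(nrow(peaks)))
    peaks$weight <- stats::rlnorm(nrow(peaks), meanlog = 0, sdlog = config$peak_weight_sdlog)
    peaks$mid <- floor((peaks$start + peaks$end) / 2) + 1  # 1-based midpoint

    # loops: ordered peak pairs whose midpoint separation is in range
    loops <- NULL
    if (config$n_loops > 0L) {
      cand <- do.call(rbind, lapply(split(seq_len(nrow(peaks)), peaks$chrom), function(idx) {
        if (length(idx) < 2L) return(NULL)
        cj <- expand.grid(a = idx, b = idx)
        cj <- cj[cj$a < cj$b, , drop = FALSE]
        s <- peaks$mid[cj$b] - peaks$mid[cj$a]
        cj[s >= config$loop_distance_range[1] & s <= config$loop_distance_range[2], , drop = FALSE]
      }))
      if (is.null(cand) || nrow(cand) < config$n_loops) {
        stop("not enough admissible peak pairs for ", config$n_loops, " loops")
      }
      pick <- cand[sample.int(nrow(cand), config$n_loops), , drop = FALSE]
      loops <- data.frame(
        chrom = peaks$chrom[pick$a],
        peakA = pick$a, peakB = pick$b,
        midA = peaks$mid[pick$a], midB = peaks$mid[pick$b],
        stringsAsFactors = FALSE, row.names = NULL
      )
      loops <- loops[order(chrom_rank(loops$chrom), loops$midA, loops$midB), , drop = FALSE]
      rownames(loops) <- NULL
      loops$name <- sprintf("loop%03d", seq_len(nrow(loops)))
    } else {
      loops <- data.frame(chrom = character(), peakA = integer(), peakB = integer(),
                          midA = numeric(), midB = numeric(), name = character())
    }

    snps <- NULL
    if (config$n_snps > 0L) {
      per <- allocate_by_length(config$n_snps, config$chrom_sizes)
      snps <- do.call(rbind, lapply(names(config$chrom_sizes), function(cc) {
        k <- per[[cc]]
        if (k == 0L) return(NULL)
        data.frame(chrom = cc,
                   pos = sort(floor(stats::runif(k, 1, config$chrom_sizes[[cc]]))),
                   stringsAsFactors = FALSE)
      }))
      snps$rsid <- sprintf("rs%06d", seq_len(nrow(snps)))
      snps$trait <- "synthetic trait"
    } else {
      snps <- data.frame(chrom = character(), pos = numeric(), rsid = character(),
                         trait = character())
    }

    genes <- NULL
    if (config$n_genes > 0L) {
      per <- allocate_by_length(config$n_genes, config$chrom_sizes)
      genes <- do.call(rbind, lapply(names(config$chrom_sizes), function(cc) {
        k <- per[[cc]]
        if (k == 0L) return(NULL)
        L <- config$chrom_sizes[[cc]]
        len <- floor(stats::runif(k, 5000, 50000))
        tss <- sort(floor(stats::runif(k, margin, L - margin)))
        strand <- sample(c("+", "-"), k, replace = TRUE)
        tx_start <- ifelse(strand == "+", tss - 1, pmax(0, tss - len))
        tx_end <- ifelse(strand == "+", pmin(L, tss - 1 + len), tss)
        data.frame(chrom = cc, tx_start = tx_start, tx_end = tx_end,
                   strand = strand, stringsAsFactors = FALSE)
      }))
      genes$name <- sprintf("G%04d", seq_len(nrow(genes)))
      genes <- genes[, c("name", "chrom", "tx_start", "tx_end", "strand")]
    } else {
      genes <- data.frame(name = character(), chrom = character(), tx_start = numeric(),
                          tx_end = numeric(), strand = character())
    }

    # shared accessibility field: per-tile log-normal origin propensities
    tile <- 20000
    access <- lapply(names(config$chrom_sizes), function(cc) {
      k <- ceiling(config$chrom_sizes[[cc]] / tile)
      stats::rlnorm(k, meanlog = 0, sdlog = config$accessibility_sdlog)
    })
    names(access) <- names(config$chrom_sizes)

    list(peaks = peaks, loops = loops, snps = snps, genes = genes,
         access = access, access_tile = tile)
  })
}

# Draw one replicate's pairs given the planted structure.
draw_pairs <- function(structure, config, seed) {
  with_seed(seed, {
    peaks <- structure$peaks
    loops <- structure$loops
    sizes <- config$chrom_sizes
    min_d <- 1000

    bg <- NULL
    if (config$n_background_pairs > 0L) {
      n <- config$n_background_pairs
      anchored <- stats::runif(n) < config$peak_anchor_fraction & nrow(peaks) > 0L
      chrom <- character(n)
      p1 <- numeric(n)
      p2 <- numeric(n)

      na <- sum(anchored)
      if (na > 0L) {
        pk <- sample.int(nrow(peaks), na, replace = TRUE, prob = peaks$weight)
        chrom[anchored] <- peaks$chrom[pk]
        a <- floor(stats::runif(na, peaks$start[pk] + 1, peaks$end[pk] + 1))
        b <- numeric(na)

        # distal end at another occupied site, partner weighted by
        # strength x decay kernel of the separation
        snap <- stats::runif(na) < config$peak_pair_fraction
        if (any(snap)) {
          for (p in unique(pk[snap])) {
            rows <- which(snap & pk == p)
            same <- which(peaks$chrom == peaks$chrom[p])
            sep <- abs(peaks$mid[same] - peaks$mid[p])
            ok <- sep >= min_d
            if (!any(ok)) { snap[rows] <- FALSE; next }
            wgt <- peaks$weight[same][ok] * sep[ok]^(-config$decay_exponent)
            q <- same[ok][sample.int(sum(ok), length(rows), replace = TRUE, prob = wgt)]
            b[rows] <- floor(stats::runif(length(rows), peaks$start[q] + 1, peaks$end[q] + 1))
          }
        }

        free <- anchored
        free[anchored] <- !snap   # anchored pairs with a decay-placed distal end
        nf <- sum(!snap)
        if (nf > 0L) {
          rows <- which(!snap)
          L <- sizes[chrom[anchored][rows]]
          aa <- a[rows]
          # anchor is fixed at the peak: truncate the decay law to the
          # feasible separation for that anchor
          d <- floor(rpowerlaw(nf, config$decay_exponent, min_d,
                               pmax(aa - 1, L - aa)))
          right_ok <- aa + d <= L
          left_ok <- aa - d >= 1
          dir_right <- ifelse(right_ok & left_ok, stats::runif(nf) < 0.5, right_ok)
          b[rows] <- ifelse(dir_right, aa + d, aa - d)
        }
        p1[anchored] <- a
        p2[anchored] <- b
      }

      nu <- sum(!anchored)
      if (nu > 0L) {
        cc <- sample(names(sizes), nu, replace = TRUE, prob = sizes)
        L <- sizes[cc]
        d <- floor(rpowerlaw(nu, config$decay_exponent, min_d, L - 1))
        # origin drawn from the planted accessibility field; keep the drawn
        # separation and redraw infeasible origins so the decay law is exact
        tile <- structure$access_tile
        draw_origin <- function(ch, k) {
          wts <- structure$access[[ch]]
          t_idx <- sample.int(length(wts), k, replace = TRUE, prob = wts)
          t_lo <- (t_idx - 1) * tile + 1
          t_hi <- pmin(t_idx * tile, sizes[[ch]])
          floor(stats::runif(k, t_lo, t_hi + 1))
        }
        a <- numeric(nu)
        for (ch in unique(cc)) {
          rows <- which(cc == ch)
          a[rows] <- draw_origin(ch, length(rows))
        }
        for (iter in 1:100) {
          bad <- which(a + d > L & a - d < 1)
          if (length(bad) == 0L) break
          for (ch in unique(cc[bad])) {
            rows <- bad[cc[bad] == ch]
            a[rows] <- draw_origin(ch, length(rows))
          }
        }
        bad <- which(a + d > L & a - d < 1)
        if (length(bad) > 0L) {  # pathological weights: uniform feasible fallback
          a[bad] <- floor(stats::runif(length(bad), 1, L[bad] - d[bad] + 1))
        }
        right_ok <- a + d <= L
        left_ok <- a - d >= 1
        dir_right <- ifelse(right_ok & left_ok, stats::runif(nu) < 0.5, right_ok)
        b <- ifelse(dir_right, a + d, a - d)
        chrom[!anchored] <- cc
        p1[!anchored] <- a
        p2[!anchored] <- b
      }
      bg <- data.frame(chrom1 = chrom, pos1 = p1, chrom2 = chrom, pos2 = p2,
                       class = "background", stringsAsFactors = FALSE)
    }

    lp <- NULL
    if (nrow(loops) > 0L && config$n_loop_pairs_per_loop > 0L) {
      k <- config$n_loop_pairs_per_loop
      jit <- floor(config$peak_width / 2)
      idx <- rep(seq_len(nrow(loops)), each = k)
      a <- loops$midA[idx] + floor(stats::runif(length(idx), -jit, jit + 1))
      b <- loops$midB[idx] + floor(stats::runif(length(idx), -jit, jit + 1))
      lp <- data.frame(chrom1 = loops$chrom[idx], pos1 = a,
                       chrom2 = loops$chrom[idx], pos2 = b,
                       class = "loop", stringsAsFactors = FALSE)
    }

    cis <- rbind(bg, lp)
    n_cis <- if (is.null(cis)) 0L else nrow(cis)

    tr <- NULL
    n_trans <- round(config$trans_fraction * n_cis)
    if (n_trans > 0L && length(sizes) >= 2L) {
      c1 <- sample(names(sizes), n_trans, replace = TRUE, prob = sizes)
      c2 <- vapply(c1, function(x) sample(setdiff(names(sizes), x), 1L), "")
      tr <- data.frame(
        chrom1 = c1, pos1 = floor(stats::runif(n_trans, 1, sizes[c1] + 1)),
        chrom2 = c2, pos2 = floor(stats::runif(n_trans, 1, sizes[c2] + 1)),
        class = "trans", stringsAsFactors = FALSE
      )
    }

    pairs <- rbind(cis, tr)
    if (is.null(pairs)) {
      pairs <- data.frame(chrom1 = character(), pos1 = numeric(),
                          chrom2 = character(), pos2 = numeric(),
                          class = character(), stringsAsFactors = FALSE)
    }
    pairs$strand1 <- sample(c("+", "-"), nrow(pairs), replace = TRUE)
    pairs$strand2 <- sample(c("+", "-"), nrow(pairs), replace = TRUE)
    pairs$read_id <- sprintf("R%07d", seq_len(nrow(pairs)))

    n_dup <- round(config$duplicate_fraction * nrow(pairs))
    if (n_dup > 0L) {
      src <- sample.int(nrow(pairs), n_dup, replace = FALSE)
      dup <- pairs[src, , drop = FALSE]
      dup$read_id <- sprintf("D%07d", seq_len(n_dup))
      dup$class <- "duplicate"
      pairs <- rbind(pairs, dup)
    }

    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    rownames(pairs) <- NULL
    counts <- list(
      n_background = if (is.null(bg)) 0L else nrow(bg),
      n_loop_pairs = if (is.null(lp)) 0L else nrow(lp),
      n_trans = if (is.null(tr)) 0L else nrow(tr),
      n_duplicates = n_dup,
      n_total = nrow(pairs)
    )
    list(pairs = pairs[, c("read_id", "chrom1", "pos1", "strand1",
                           "chrom2", "pos2", "strand2", "class")],
         counts = counts)
  })
}

#' Simulate a valid-pairs dataset with planted ground truth
#'
#' Places non-overlapping peaks, picks loops joining admissible peak pairs,
#' draws background cis pairs with a truncated power-law separation density,
#' loop pairs jittered within their anchor peaks (so the peak-anchor filter
#' cannot exclude a planted loop), trans noise, and PCR duplicates. The
#' bundle is a deterministic function of the configuration.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, the bundle is written as
#'   `pairs.allValidPairs`, `peaks.bed` (name + weight columns),
#'   `loops_truth.bedpe` (1-bp midpoint anchors), `snps.tsv` (GWAS-catalog
#'   style columns), `genes.tsv` (UCSC table style) and `truth_counts.tsv`.
#' @param pair_seed Seed for the pair draw; defaults to `config$seed` (the
#'   planted structure always uses `config$seed`).
#' @return A list: `pairs` (valid-pairs data.frame with an extra truth
#'   `class` column), `peaks`, `loops` (BEDPE-style with 1-bp midpoint
#'   anchors plus `midA`/`midB`), `snps`, `genes`, `truth` (config, planted
#'   objects, per-class counts).
#' @export
simulate_dataset <- function(config = simulation_config(), out_dir = NULL,
                             pair_seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  structure_ <- plant_structure(config)
  drawn <- draw_pairs(structure_, config, pair_seed)
  if (nrow(structure_$loops) == 0L) {
    loops_bedpe <- data.frame(
      chromA = character(), startA = numeric(), endA = numeric(),
      chromB = character(), startB = numeric(), endB = numeric(),
      score = numeric(), trans = logical(), midA = numeric(), midB = numeric(),
      name = character(), stringsAsFactors = FALSE
    )
  } else loops_bedpe <- data.frame(
    chromA = structure_$loops$chrom,
    startA = structure_$loops$midA - 1,
    endA = structure_$loops$midA,
    chromB = structure_$loops$chrom,
    startB = structure_$loops$midB - 1,
    endB = structure_$loops$midB,
    score = NA_real_,
    trans = FALSE,
    midA = structure_$loops$midA,
    midB = structure_$loops$midB,
    name = structure_$loops$name,
    stringsAsFactors = FALSE
  )
  bundle <- list(
    pairs = drawn$pairs,
    peaks = structure_$peaks,
    loops = loops_bedpe,
    snps = structure_$snps,
    genes = structure_$genes,
    truth = list(config = config, counts = drawn$counts,
                 loops = structure_$loops, peaks = structure_$peaks)
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Write a simulated bundle to disk in the pipeline's input dialects
#'
#' @param bundle A bundle from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_valid_pairs(bundle$pairs, file.path(out_dir, "pairs.allValidPairs"))
  pk <- bundle$peaks
  data.table::fwrite(
    data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
               name = pk$name, score = round(pk$weight, 4)),
    file.path(out_dir, "peaks.bed"), sep = "\t", col.names = FALSE, quote = FALSE
  )
  write_bedpe(bundle$loops, file.path(out_dir, "loops_truth.bedpe"))
  data.table::fwrite(
    data.frame(`CHR_ID` = sub("^chr", "", bundle$snps$chrom),
               `CHR_POS` = bundle$snps$pos,
               `SNPS` = bundle$snps$rsid,
               `DISEASE/TRAIT` = bundle$snps$trait,
               check.names = FALSE),
    file.path(out_dir, "snps.tsv"), sep = "\t", quote = FALSE
  )
  data.table::fwrite(
    data.frame(name2 = bundle$genes$name, chrom = bundle$genes$chrom,
               txStart = bundle$genes$tx_start, txEnd = bundle$genes$tx_end,
               strand = bundle$genes$strand),
    file.path(out_dir, "genes.tsv"), sep = "\t", quote = FALSE
  )
  counts <- bundle$truth$counts
  data.table::fwrite(
    data.frame(metric = names(counts), value = unlist(counts)),
    file.path(out_dir, "truth_counts.tsv"), sep = "\t", quote = FALSE
  )
  invisible(out_dir)
}

#' Simulate replicate datasets sharing one planted structure
#'
#' Replicates share peaks, loops, SNPs and genes (planted from
#' `config$seed`) but draw pairs independently, using seed offsets
#' `config$seed + 1000 * replicate`.
#'
#' @param config A [simulation_config()].
#' @param n_replicates Number of replicates (>= 2).
#' @return A list of bundles (see [simulate_dataset()]) sharing `truth`.
#' @export
simulate_replicates <- function(config = simulation_config(), n_replicates = 2L) {
  if (n_replicates < 2L) stop("n_replicates must be at least 2")
  lapply(seq_len(n_replicates), function(r) {
    simulate_dataset(config, pair_seed = config$seed + 1000L * r)
  })
}
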