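# File formats. Conventions used throughout the package:
#   * pair / SNP / interaction-anchor positions are 1-based points;
#   * all interval tables (peaks, loop anchors, promoters, motif anchors) are
#     BED-style 0-based half-open data.frames with columns chrom,start,end.
# Conversions between the two live here and in utils.R, nowhere else.

#' Read a HiC-Pro style valid-pairs file
#'
#' Expects a tab-separated file whose first seven columns are
#' read_id, chrom1, pos1, strand1, chrom2, pos2, strand2 (the
#' allValidPairs layout); any trailing columns (fragment ids, sizes) are
#' ignored. Lines that are empty or start with `#` are skipped.
#'
#' @param path Path to the file.
#' @param strict If `TRUE` (default), any malformed line (fewer than 7
#'   columns, non-integer position) is an error naming the line number.
#'   If `FALSE`, malformed lines are skipped with a message reporting how
#'   many were dropped and which lines.
#' @param chrom_style Chromosome-name style to normalize to; see
#'   [normalize_chroms()].
#' @return A data.frame with columns `read_id`, `chrom1`, `pos1`, `strand1`,
#'   `chrom2`, `pos2`, `strand2`.
#' @export
read_valid_pairs <- function(path, strict = TRUE, chrom_style = "ucsc") {
  if (!file.exists(path)) stop("valid-pairs file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(
    read_id = character(), chrom1 = character(), pos1 = numeric(),
    strand1 = character(), chrom2 = character(), pos2 = numeric(),
    strand2 = character(), stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) return(empty)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  pos1 <- suppressWarnings(as.numeric(vapply(fields, function(f) f[3] %||% NA_character_, "")))
  pos2 <- suppressWarnings(as.numeric(vapply(fields, function(f) f[6] %||% NA_character_, "")))
  bad <- nfield < 7L | is.na(pos1) | is.na(pos2) | pos1 < 1 | pos2 < 1 |
    pos1 != floor(pos1) | pos2 != floor(pos2)
  if (any(bad)) {
    msg <- sprintf(
      "%d malformed valid-pair line(s) at line(s) %s",
      sum(bad), paste(utils::head(lineno[bad], 10L), collapse = ", ")
    )
    if (strict) stop(msg) else message(msg, " -- skipped")
    fields <- fields[!bad]
    pos1 <- pos1[!bad]
    pos2 <- pos2[!bad]
  }
  if (length(fields) == 0L) return(empty)
  data.frame(
    read_id = vapply(fields, `[`, "", 1L),
    chrom1 = normalize_chroms(vapply(fields, `[`, "", 2L), chrom_style),
    pos1 = pos1,
    strand1 = vapply(fields, `[`, "", 4L),
    chrom2 = normalize_chroms(vapply(fields, `[`, "", 5L), chrom_style),
    pos2 = pos2,
    strand2 = vapply(fields, `[`, "", 7L),
    stringsAsFactors = FALSE
  )
}

#' Write a valid-pairs file
#'
#' Inverse of [read_valid_pairs()]: tab-separated, seven columns, no header.
#'
#' @param pairs Valid-pairs data.frame.
#' @param path Output path.
#' @export
write_valid_pairs <- function(pairs, path) {
  data.table::fwrite(
    pairs[, c("read_id", "chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2")],
    path, sep = "\t", col.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read a BED / narrowPeak interval file
#'
#' Uses the first three columns (chrom, start, end; 0-based half-open) and,
#' when present, column 4 as `name` and column 5 as `score`. ENCODE
#' narrowPeak files (10 columns) are read the same way, with column 10
#' (summit offset) kept as `summit` when present.
#'
#' @param path Path to the file.
#' @param chrom_style See [normalize_chroms()].
#' @return A data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `summit`, in file order.
#' @export
read_bed <- function(path, chrom_style = "ucsc") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          blank.lines.skip = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  }
  # tolerate track/browser/header lines
  drop <- grepl("^(#|track|browser)", dt[[1]]) | dt[[1]] %in% c("chrom", "chr")
  dt <- dt[!drop, , drop = FALSE]
  out <- data.frame(
    chrom = normalize_chroms(dt[[1]], chrom_style),
    start = as.numeric(dt[[2]]),
    end = as.numeric(dt[[3]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$start) || anyNA(out$end)) stop("non-numeric BED coordinates in ", path)
  if (any(out$start < 0)) stop("negative BED start in ", path)
  if (any(out$start >= out$end)) stop("BED interval with start >= end in ", path)
  if (ncol(dt) >= 4L) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5L) out$score <- suppressWarnings(as.numeric(dt[[5]]))
  if (ncol(dt) >= 10L) out$summit <- suppressWarnings(as.numeric(dt[[10]]))
  out
}

#' Read a BEDPE loop file
#'
#' First six columns are chromA, startA, endA, chromB, startB, endB (0-based
#' half-open); column 8 is kept as `score` when numeric. Header lines
#' beginning with `#` or with a literal `chrom`/`chr` token are skipped.
#' Anchors are returned canonically ordered (A before B by chromosome rank,
#' then start); records whose anchors lie on different chromosomes are kept
#' and flagged `trans = TRUE`.
#'
#' @param path Path to the file.
#' @param chrom_style See [normalize_chroms()].
#' @return A data.frame with columns `chromA`, `startA`, `endA`, `chromB`,
#'   `startB`, `endB`, `score`, `trans`.
#' @export
read_bedpe <- function(path, chrom_style = "ucsc") {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  empty <- data.frame(
    chromA = character(), startA = numeric(), endA = numeric(),
    chromB = character(), startB = numeric(), endB = numeric(),
    score = numeric(), trans = logical(), stringsAsFactors = FALSE
  )
  if (file.size(path) == 0L) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          blank.lines.skip = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) return(empty)
  drop <- grepl("^(#|track|browser|chrom|chr1\\b|chr\\t)", dt[[1]]) & is.na(suppressWarnings(as.numeric(dt[[2]])))
  dt <- dt[!drop, , drop = FALSE]
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 6L) stop("BEDPE needs at least 6 columns: ", path)
  loops <- data.frame(
    chromA = normalize_chroms(dt[[1]], chrom_style),
    startA = as.numeric(dt[[2]]),
    endA = as.numeric(dt[[3]]),
    chromB = normalize_chroms(dt[[4]], chrom_style),
    startB = as.numeric(dt[[5]]),
    endB = as.numeric(dt[[6]]),
    score = if (ncol(dt) >= 8L) suppressWarnings(as.numeric(dt[[8]])) else NA_real_,
    stringsAsFactors = FALSE
  )
  bad <- is.na(loops$startA) | is.na(loops$endA) | is.na(loops$startB) | is.na(loops$endB)
  if (any(bad)) stop("non-numeric BEDPE coordinates in ", path)
  if (any(loops$startA < 0 | loops$startB < 0)) stop("negative BEDPE start in ", path)
  if (any(loops$startA >= loops$endA | loops$startB >= loops$endB)) {
    stop("BEDPE anchor with start >= end in ", path)
  }
  canonicalize_loops(loops)
}

# Order each record's anchors by (chromosome rank, start); flag trans records.
canonicalize_loops <- function(loops) {
  swap <- (chrom_rank(loops$chromA) > chrom_rank(loops$chromB)) |
    (loops$chromA == loops$chromB & loops$startA > loops$startB)
  if (any(swap)) {
    tmp <- loops[swap, c("chromA", "startA", "endA")]
    loops[swap, c("chromA", "startA", "endA")] <- loops[swap, c("chromB", "startB", "endB")]
    loops[swap, c("chromB", "startB", "endB")] <- tmp
  }
  loops$trans <- loops$chromA != loops$chromB
  loops
}

#' Read an NHGRI-EBI GWAS catalog export
#'
#' Expects the catalog's tab-separated association export with at least the
#' columns `CHR_ID`, `CHR_POS` and `SNPS`; the trait is taken from
#' `DISEASE/TRAIT` (or `MAPPED_TRAIT`) when present. Rows with a missing or
#' non-numeric `CHR_POS` (haplotypes, interaction entries) are skipped with a
#' message reporting the count.
#'
#' @param path Path to the TSV export.
#' @param trait_filter Optional substring; only rows whose trait contains it
#'   (case-insensitively) are kept.
#' @param chrom_style See [normalize_chroms()].
#' @return A data.frame with columns `chrom`, `pos` (1-based), `rsid`, `trait`.
#' @export
read_gwas_catalog <- function(path, trait_filter = NULL, chrom_style = "ucsc") {
  if (!file.exists(path)) stop("GWAS catalog file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", quote = "",
                          data.table = FALSE, check.names = FALSE)
  need <- c("CHR_ID", "CHR_POS", "SNPS")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("GWAS export lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  trait_col <- intersect(c("DISEASE/TRAIT", "MAPPED_TRAIT", "TRAIT"), names(dt))[1]
  trait <- if (!is.na(trait_col)) as.character(dt[[trait_col]]) else rep(NA_character_, nrow(dt))
  pos <- suppressWarnings(as.numeric(dt$CHR_POS))
  ok <- !is.na(pos) & pos >= 1 & !is.na(dt$CHR_ID) & dt$CHR_ID != ""
  if (any(!ok)) message(sum(!ok), " GWAS row(s) without usable coordinates skipped")
  out <- data.frame(
    chrom = normalize_chroms(dt$CHR_ID[ok], chrom_style),
    pos = pos[ok],
    rsid = as.character(dt$SNPS[ok]),
    trait = trait[ok],
    stringsAsFactors = FALSE
  )
  if (!is.null(trait_filter)) {
    out <- out[grepl(trait_filter, out$trait, ignore.case = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a RefSeq/UCSC style gene table
#'
#' Tab-separated with a header; requires columns `chrom`, `txStart`, `txEnd`,
#' `strand` and a gene-name column (`name2` preferred over `name`).
#' Coordinates follow the UCSC table-browser convention: `txStart` 0-based,
#' `txEnd` exclusive.
#'
#' @param path Path to the table.
#' @param chrom_style See [normalize_chroms()].
#' @return A data.frame with columns `name`, `chrom`, `tx_start`, `tx_end`,
#'   `strand`.
#' @export
read_gene_table <- function(path, chrom_style = "ucsc") {
  if (!file.exists(path)) stop("gene table not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  need <- c("chrom", "txStart", "txEnd", "strand")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("gene table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  name_col <- intersect(c("name2", "name"), names(dt))[1]
  if (is.na(name_col)) stop("gene table lacks a name/name2 column")
  out <- data.frame(
    name = as.character(dt[[name_col]]),
    chrom = normalize_chroms(dt$chrom, chrom_style),
    tx_start = as.numeric(dt$txStart),
    tx_end = as.numeric(dt$txEnd),
    strand = as.character(dt$strand),
    stringsAsFactors = FALSE
  )
  if (any(out$tx_start >= out$tx_end)) stop("gene with txStart >= txEnd in ", path)
  if (!all(out$strand %in% c("+", "-"))) stop("gene strand must be + or - in ", path)
  out
}

#' Write called interactions as BEDPE
#'
#' Each 1-bp anchor at 1-based position `p` is encoded as the 0-based
#' half-open interval `[p-1, p)`, so the file round-trips through
#' [read_bedpe()] without loss. Columns 7 and 8 carry the source read id and
#' the separation distance.
#'
#' @param interactions Interaction data.frame from [call_interactions()].
#' @param path Output path.
#' @export
write_interactions_bedpe <- function(interactions, path) {
  df <- data.frame(
    chromA = interactions$chrom,
    startA = interactions$anchor1 - 1,
    endA = interactions$anchor1,
    chromB = interactions$chrom,
    startB = interactions$anchor2 - 1,
    endB = interactions$anchor2,
    name = interactions$source_id,
    score = interactions$distance
  )
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read interactions written by [write_interactions_bedpe()]
#'
#' @param path BEDPE path with 1-bp anchors.
#' @return An interaction data.frame (`chrom`, `anchor1`, `anchor2`,
#'   `distance`, `source_id`).
#' @export
read_interactions_bedpe <- function(path) {
  loops <- read_bedpe(path)
  if (any(loops$trans)) stop("interaction BEDPE contains trans records: ", path)
  if (nrow(loops) == 0L) {
    return(data.frame(chrom = character(), anchor1 = numeric(), anchor2 = numeric(),
                      distance = numeric(), source_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(loops$endA - loops$startA != 1 | loops$endB - loops$startB != 1)) {
    stop("interaction BEDPE must have 1-bp anchors: ", path)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE, data.table = FALSE)
  source_id <- if (ncol(dt) >= 7L && nrow(loops)) as.character(dt[[7]]) else rep(NA_character_, nrow(loops))
  data.frame(
    chrom = loops$chromA,
    anchor1 = loops$endA,
    anchor2 = loops$endB,
    distance = loops$endB - loops$endA,
    source_id = source_id,
    stringsAsFactors = FALSE
  )
}

#' Write a BED file
#'
#' @param intervals Interval data.frame (`chrom`, `start`, `end`, optional
#'   `name`, `score`).
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  # BED columns are positional: emit the longest present prefix
  std <- c("chrom", "start", "end", "name", "score")
  first_absent <- match(FALSE, std %in% names(intervals))
  take <- std[seq_len(if (is.na(first_absent)) length(std) else first_absent - 1L)]
  stopifnot(length(take) >= 3L)
  data.table::fwrite(intervals[, take, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write loops as BEDPE
#'
#' @param loops Loop data.frame as returned by [read_bedpe()].
#' @param path Output path.
#' @export
write_bedpe <- function(loops, path) {
  cols <- c("chromA", "startA", "endA", "chromB", "startB", "endB")
  df <- loops[, cols, drop = FALSE]
  if ("score" %in% names(loops) && any(!is.na(loops$score))) {
    df$name <- "."
    df$score <- loops$score
  }
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
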