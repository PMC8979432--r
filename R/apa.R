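# Aggregate peak analysis from scratch: bin cis pairs into per-chromosome
# sparse symmetric contact matrices, Knight-Ruiz balance them, enumerate and
# sample peak-pair loci, and average centered submatrices.
#
# Score convention: central pixel over the mean of the 6x6 lower-left corner
# of the (2w+1)x(2w+1) aggregate (w = 10 bins by default) -- the corner
# nearest the diagonal, which reflects contacts at shorter separations than
# the putative loop. This is a convention, not a law; both the window and
# the corner size are arguments.

#' Bin cis pairs into per-chromosome contact matrices
#'
#' Each cis pair increments the symmetric entry
#' (`floor((pos1-1)/res)`, `floor((pos2-1)/res)`); total upper-triangle mass
#' (diagonal included) equals the number of pairs binned.
#'
#' @param pairs Canonical valid-pairs data.frame; trans pairs are ignored.
#' @param resolution Bin size in bp.
#' @param chrom_sizes Optional named chromosome lengths fixing matrix
#'   dimensions; otherwise each matrix extends to the last occupied bin.
#' @return A named list of `contact_matrix` objects (one per chromosome),
#'   each a list with `chrom`, `resolution`, `n_bins`, `mat` (a sparse
#'   symmetric `Matrix`), and `weights` (`NULL` until balanced).
#' @export
bin_pairs <- function(pairs, resolution, chrom_sizes = NULL) {
  if (resolution <= 0) stop("resolution must be positive")
  cis <- pairs[pairs$chrom1 == pairs$chrom2, , drop = FALSE]
  chroms <- if (!is.null(chrom_sizes)) names(chrom_sizes) else sort(unique(cis$chrom1))
  out <- lapply(chroms, function(cc) {
    sel <- cis$chrom1 == cc
    i <- floor((cis$pos1[sel] - 1) / resolution)
    j <- floor((cis$pos2[sel] - 1) / resolution)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    n_bins <- if (!is.null(chrom_sizes)) {
      as.integer(ceiling(chrom_sizes[[cc]] / resolution))
    } else if (any(sel)) as.integer(max(hi) + 1L) else 0L
    if (n_bins == 0L) return(NULL)
    agg <- data.table::data.table(i = lo, j = hi)[, .N, by = c("i", "j")]
    mat <- Matrix::sparseMatrix(
      i = agg$i + 1L, j = agg$j + 1L, x = agg$N,
      dims = c(n_bins, n_bins), symmetric = TRUE
    )
    structure(list(chrom = cc, resolution = resolution, n_bins = n_bins,
                   mat = mat, weights = NULL),
              class = "contact_matrix")
  })
  names(out) <- chroms
  out[!vapply(out, is.null, TRUE)]
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s: %d bins @ %s bp, %s contacts%s\n",
              x$chrom, x$n_bins, format(x$resolution, big.mark = ","),
              format(contact_mass(x), big.mark = ","),
              if (is.null(x$weights)) "" else ", KR-balanced"))
  invisible(x)
}

#' Total contact mass (upper triangle plus diagonal) of a contact matrix
#'
#' @param cm A `contact_matrix`.
#' @return Number of pairs binned into the matrix.
#' @export
contact_mass <- function(cm) {
  (sum(cm$mat) + sum(Matrix::diag(cm$mat))) / 2
}

#' Knight-Ruiz matrix balancing
#'
#' Computes positive per-bin weights `w` such that the rescaled matrix with
#' entries `w_i * a_ij * w_j` has all row sums equal to 1 within `tol`
#' (maximum absolute deviation), using the Knight-Ruiz inner-outer Newton
#' iteration with a conjugate-gradient inner solve. Rows that are entirely
#' zero are excluded from balancing and get `NA` weights. If the Newton
#' iteration fails to reach `tol`, a Sinkhorn-Knopp fixed-point iteration is
#' run as a fallback; if that also fails (sparse matrices without total
#' support are not balanceable), the lowest-coverage rows are dropped in
#' increasing percentile steps and balancing is retried — the usual
#' sparsity handling for contact matrices. Dropped rows get `NA` weights.
#'
#' @param m A square symmetric nonnegative matrix (base or `Matrix`), or a
#'   `contact_matrix`.
#' @param tol Convergence tolerance on the maximum row-sum deviation.
#' @param max_iter Iteration budget (outer Newton steps; also the cap on
#'   Sinkhorn sweeps).
#' @return For a plain matrix: a numeric weight vector (`NA` at zero rows).
#'   For a `contact_matrix`: the same object with `weights` filled in.
#' @export
kr_balance <- function(m, tol = 1e-6, max_iter = 3000L) {
  if (inherits(m, "contact_matrix")) {
    m$weights <- kr_balance(m$mat, tol = tol, max_iter = max_iter)
    return(m)
  }
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (min(m) < 0) stop("matrix must be nonnegative")
  rs <- as.numeric(Matrix::rowSums(m))
  if (!any(rs > 0)) stop("matrix has no nonzero rows; nothing to balance")
  x <- NULL
  for (drop_frac in c(0, 0.02, 0.05, 0.1, 0.2, 0.3)) {
    cut <- stats::quantile(rs[rs > 0], drop_frac)
    keep <- rs > 0 & rs >= cut
    if (sum(keep) < 2L) next
    A <- m[keep, keep, drop = FALSE]
    # dropping columns can empty further rows; require positivity
    if (min(Matrix::rowSums(A)) <= 0) next
    x <- kr_core(A, tol = tol, max_iter = max_iter)
    if (is.null(x)) x <- sinkhorn_core(A, tol = tol, max_iter = max_iter)
    if (!is.null(x)) break
  }
  if (is.null(x)) {
    stop(sprintf("KR balancing failed to converge within %d iterations (tol %g)",
                 max_iter, tol))
  }
  w <- rep(NA_real_, nrow(m))
  w[keep] <- x
  w
}

# Knight-Ruiz inner-outer Newton iteration (bnewt). Returns the weight
# vector, or NULL if the tolerance was not reached within the budget.
kr_core <- function(A, tol, max_iter, delta = 0.1, Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  # outer residual measured in the infinity norm against row sums of 1
  v <- x * as.numeric(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  rt <- tol^2  # 2-norm^2 target; implies inf-norm <= tol
  outer <- 0L
  while (max(abs(1 - v)) > tol) {
    outer <- outer + 1L
    if (outer > max_iter) return(NULL)
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      if (k > 10L * n + 50L) break
      w <- x * as.numeric(A %*% (x * p)) + v * p
      denom <- sum(p * w)
      if (!is.finite(denom) || denom <= 0) break
      alpha <- rho_km1 / denom
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * as.numeric(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    # Inexact-Newton forcing term update
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / max(res_norm, .Machine$double.eps))
  }
  x
}

# Symmetric Sinkhorn-Knopp fixed point: x <- sqrt(x / (A x)).
sinkhorn_core <- function(A, tol, max_iter) {
  n <- nrow(A)
  x <- rep(1, n)
  for (i in seq_len(max_iter)) {
    v <- as.numeric(A %*% x)
    if (any(v <= 0) || any(!is.finite(v))) return(NULL)
    dev <- max(abs(x * v - 1))
    if (dev <= tol) return(x)
    x <- sqrt(x / v)
    if (any(!is.finite(x))) return(NULL)
  }
  v <- as.numeric(A %*% x)
  if (max(abs(x * v - 1)) <= tol) x else NULL
}

#' Balanced contact values of a contact matrix
#'
#' @param cm A KR-balanced `contact_matrix`.
#' @return A sparse symmetric matrix of `w_i * c_ij * w_j` values; bins
#'   excluded from balancing contribute zeros (their raw rows are zero).
#' @export
balanced_matrix <- function(cm) {
  if (is.null(cm$weights)) stop("contact matrix has no balance weights; run kr_balance()")
  w <- cm$weights
  w[is.na(w)] <- 0
  D <- Matrix::Diagonal(x = w)
  Matrix::forceSymmetric(D %*% cm$mat %*% D)
}

#' Enumerate candidate loci pairs from peaks
#'
#' Reduces each peak to a point (interval midpoint by default, or the
#' narrowPeak summit when `use_summit = TRUE` and a `summit` column is
#' present), keeps all unordered within-chromosome pairs whose point
#' separation `s` satisfies `apa_min_sep <= s < apa_max_sep`, converts
#' points to bins at `resolution`, and deduplicates at the bin level.
#'
#' @param peaks Peak interval data.frame.
#' @param resolution Contact-matrix bin size in bp.
#' @param params [analysis_params()] supplying `apa_min_sep` / `apa_max_sep`.
#' @param use_summit Use the summit offset column when available.
#' @return A data.frame of loci (`chrom`, `bin_i`, `bin_j`) with
#'   `bin_i < bin_j`.
#' @export
enumerate_loci <- function(peaks, resolution, params = analysis_params(),
                           use_summit = FALSE) {
  params <- as_params(params)
  if (use_summit && !is.null(peaks$summit) && all(!is.na(peaks$summit))) {
    pos <- peaks$start + peaks$summit + 1   # 1-based summit point
  } else {
    pos <- floor((peaks$start + peaks$end) / 2) + 1  # 1-based midpoint
  }
  dt <- data.table::data.table(chrom = peaks$chrom, pos = pos)
  out <- dt[, {
    p <- sort(pos)
    n <- length(p)
    if (n < 2L) {
      data.table::data.table(bin_i = integer(), bin_j = integer())
    } else {
      idx <- data.table::CJ(a = seq_len(n), b = seq_len(n))[a < b]
      s <- p[idx$b] - p[idx$a]
      ok <- s >= params$apa_min_sep & s < params$apa_max_sep
      data.table::data.table(
        bin_i = floor((p[idx$a[ok]] - 1) / resolution),
        bin_j = floor((p[idx$b[ok]] - 1) / resolution)
      )
    }
  }, by = "chrom"]
  out <- unique(out[bin_i != bin_j])
  swap <- out$bin_i > out$bin_j
  if (any(swap)) {
    tmp <- out$bin_i[swap]
    out$bin_i[swap] <- out$bin_j[swap]
    out$bin_j[swap] <- tmp
    out <- unique(out)
  }
  as.data.frame(out)
}

#' Sample loci pairs without replacement
#'
#' Draws `min(n, nrow(loci))` loci uniformly without replacement,
#' reproducibly for a given seed; the caller's RNG state is untouched.
#'
#' @param loci Loci data.frame from [enumerate_loci()].
#' @param n Number of loci to draw.
#' @param seed Integer seed.
#' @return A subset of `loci` rows.
#' @export
sample_loci <- function(loci, n, seed) {
  stopifnot(n > 0)
  if (nrow(loci) <= n) return(loci)
  idx <- with_seed(seed, sample.int(nrow(loci), n))
  out <- loci[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate peak analysis
#'
#' Element-wise mean, over loci, of the (2w+1)x(2w+1) submatrix of balanced
#' (or raw) contacts centered on each locus (`bin_i`, `bin_j`). Loci whose
#' window would run off a chromosome edge, or would touch or cross the
#' diagonal (`bin_j - bin_i <= 2w`, where the window would read reflected
#' upper-triangle counts), are dropped and counted. The score is the central
#' pixel divided by the mean of the `corner x corner` lower-left block (last
#' `corner` rows, first `corner` columns — the corner nearest the diagonal).
#'
#' @param matrices Named list of `contact_matrix` objects from
#'   [bin_pairs()], KR-balanced unless `balanced = FALSE`.
#' @param loci Loci data.frame (`chrom`, `bin_i`, `bin_j`).
#' @param window_bins Half-width `w` of the aggregate window in bins.
#' @param corner Corner block size in bins (6 when `w` is 10, following the
#'   usual convention).
#' @param balanced Use KR-balanced values (default) or raw counts.
#' @return An `apa_result`: `matrix` ((2w+1) square), `score`,
#'   `n_pairs_used`, `n_dropped`, `window_bins`, `corner`.
#' @export
aggregate_apa <- function(matrices, loci, window_bins = 10L, corner = 6L,
                          balanced = TRUE) {
  w <- as.integer(window_bins)
  stopifnot(w >= 1L, corner >= 1L, corner <= 2L * w + 1L)
  size <- 2L * w + 1L
  acc <- matrix(0, size, size)
  used <- 0L
  dropped <- 0L
  for (cc in unique(loci$chrom)) {
    cm <- matrices[[cc]]
    sub <- loci[loci$chrom == cc, , drop = FALSE]
    if (is.null(cm)) {
      dropped <- dropped + nrow(sub)
      next
    }
    B <- if (balanced) balanced_matrix(cm) else cm$mat
    ok <- sub$bin_i - w >= 0L & sub$bin_j + w <= cm$n_bins - 1L &
      (sub$bin_j - sub$bin_i) > 2L * w
    dropped <- dropped + sum(!ok)
    sub <- sub[ok, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      ri <- (sub$bin_i[r] - w):(sub$bin_i[r] + w) + 1L
      ci <- (sub$bin_j[r] - w):(sub$bin_j[r] + w) + 1L
      acc <- acc + as.matrix(B[ri, ci, drop = FALSE])
      used <- used + 1L
    }
  }
  if (used == 0L) stop("no usable loci (all dropped at edges/diagonal or off-matrix)")
  avg <- acc / used
  corner_block <- avg[(size - corner + 1L):size, 1:corner, drop = FALSE]
  corner_mean <- mean(corner_block)
  score <- if (corner_mean > 0) avg[w + 1L, w + 1L] / corner_mean else NA_real_
  structure(list(matrix = avg, score = score, n_pairs_used = used,
                 n_dropped = dropped, window_bins = w, corner = as.integer(corner)),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("apa_result: %d loci aggregated (%d dropped), window +/-%d bins, score %.3f\n",
              x$n_pairs_used, x$n_dropped, x$window_bins, x$score))
  invisible(x)
}

#' Run the full APA pipeline on valid pairs and peaks
#'
#' Convenience wrapper: bin pairs, KR-balance per chromosome, enumerate and
#' sample loci, aggregate.
#'
#' @param pairs Canonical cis valid-pairs data.frame.
#' @param peaks Peak interval data.frame.
#' @param params [analysis_params()]; supplies resolution, separation range,
#'   sample size and seed.
#' @param chrom_sizes Optional named chromosome lengths.
#' @param window_bins,corner,balanced See [aggregate_apa()].
#' @return An `apa_result`.
#' @export
apa <- function(pairs, peaks, params = analysis_params(), chrom_sizes = NULL,
                window_bins = 10L, corner = 6L, balanced = TRUE) {
  params <- as_params(params)
  mats <- bin_pairs(pairs, params$apa_resolution, chrom_sizes)
  if (balanced) mats <- lapply(mats, kr_balance)
  loci <- enumerate_loci(peaks, params$apa_resolution, params)
  loci <- sample_loci(loci, params$apa_sample_n, params$seed)
  aggregate_apa(mats, loci, window_bins = window_bins, corner = corner,
                balanced = balanced)
}
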