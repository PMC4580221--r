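#' Bin di-tags into a symmetric contact matrix
#'
#' Each classified unique di-tag increments exactly one (i, j) cell with
#' i <= j over a genome-wide bin table; the stored matrix is symmetrized
#' (M\[j,i\] = M\[i,j\]; diagonal counted once), so the upper triangle
#' including the diagonal conserves the di-tag count.
#'
#' @param table A classified `ditag_table` (records with a non-NA `locality`
#'   are binned) or any di-tag table if `use_all = TRUE`.
#' @param binsize Fixed bin size in bp (> 0); ignored when `bins` given.
#' @param chrom_lengths Named vector of chromosome lengths; defaults to the
#'   table's `chromosome_lengths` attribute.
#' @param bins Optional explicit bin table (chrom, start, end) with
#'   non-overlapping sorted intervals per chromosome, e.g. TADs as
#'   variable-sized bins. Di-tags outside any bin are dropped.
#' @param use_all Bin every record regardless of classification.
#' @return Object of class `hic_matrix`: list with `bins` (data.table
#'   chrom/start/end), `counts` (dense symmetric matrix), `binsize` (NA for
#'   variable bins), and empty slots `mask`, `bias`, `corrected`, `oe`
#'   filled by [mask_bins()], [ice_correct()], [distance_correct()].
#' @export
bin_contacts <- function(table, binsize = NULL, chrom_lengths = NULL,
                         bins = NULL, use_all = FALSE) {
  if (is.null(bins)) {
    if (is.null(binsize) || binsize <= 0) stop("binsize must be > 0")
    if (is.null(chrom_lengths)) chrom_lengths <- attr(table, "chromosome_lengths")
    if (is.null(chrom_lengths)) stop("chromosome lengths unavailable")
    bins <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
      st <- seq(0, chrom_lengths[[ch]] - 1, by = binsize)
      data.table::data.table(chrom = ch, start = st,
                             end = pmin(st + binsize, chrom_lengths[[ch]]))
    }))
  } else {
    bins <- data.table::as.data.table(bins)[, .(chrom, start, end)]
    binsize <- NA_real_
  }
  bins[, bin_id := seq_len(.N)]
  tab <- data.table::as.data.table(table)
  if (!use_all && "locality" %in% names(tab)) tab <- tab[!is.na(locality)]
  assign_bin <- function(chrom, pos) {
    out <- rep(NA_integer_, length(chrom))
    for (cc in unique(chrom)) {
      bsub <- bins[chrom == cc]
      if (!nrow(bsub)) next
      sel <- which(chrom == cc)
      k <- findInterval(pos[sel], bsub$start)
      ok <- k >= 1L & pos[sel] < bsub$end[pmax(k, 1L)]
      out[sel[ok]] <- bsub$bin_id[k[ok]]
    }
    out
  }
  b1 <- assign_bin(tab$chrom1, tab$pos1)
  b2 <- assign_bin(tab$chrom2, tab$pos2)
  ok <- !is.na(b1) & !is.na(b2)
  i <- pmin(b1[ok], b2[ok]); j <- pmax(b1[ok], b2[ok])
  n <- nrow(bins)
  M <- matrix(0, n, n)
  if (length(i)) {
    cnt <- data.table::data.table(i, j)[, .N, by = .(i, j)]
    M[cbind(cnt$i, cnt$j)] <- cnt$N
    M[cbind(cnt$j, cnt$i)] <- cnt$N
  }
  structure(list(bins = bins[], counts = M, binsize = binsize,
                 mask = NULL, bias = NULL, corrected = NULL, oe = NULL),
            class = "hic_matrix")
}

#' Mask low- and extreme-coverage bins
#'
#' Excludes bins whose raw coverage (row sum) is below `low_fraction` of the
#' mean bin coverage or more than `sd_cut` standard deviations away from it;
#' mean and SD are computed over nonzero-coverage bins. Zero-coverage bins
#' are always excluded.
#'
#' @param m A `hic_matrix`.
#' @param low_fraction Minimum coverage as a fraction of the mean
#'   (default 0.20; the directionality-index pipeline uses 0.15).
#' @param sd_cut z-score cutoff (default 4).
#' @return The matrix with its logical `mask` slot filled (TRUE = included).
#' @export
mask_bins <- function(m, low_fraction = 0.20, sd_cut = 4) {
  cov <- rowSums(m$counts)
  nz <- cov > 0
  if (!any(nz)) stop("all bins have zero coverage")
  mu <- mean(cov[nz]); s <- stats::sd(cov[nz])
  inc <- nz & cov >= low_fraction * mu
  if (is.finite(s) && s > 0) inc <- inc & abs(cov - mu) <= sd_cut * s
  if (!any(inc)) stop("all bins masked")
  m$mask <- inc
  m
}

#' Iterative coverage correction (matrix balancing)
#'
#' Factorizes the observed counts over included bins as
#' `O_ij = mu * b_i * b_j * T_ij` with equal corrected coverage for every
#' included bin, by iterative proportional scaling: each iteration divides
#' the working matrix by the outer product of its relative coverages and
#' accumulates the per-bin bias `b`, until the coefficient of variation of
#' included-bin coverage falls below `tol`. The bias vector is normalized
#' to mean 1 over included bins, and the corrected matrix `T` is rescaled
#' so its included-cell total matches the raw total (the scalar `mu`
#' carries the residual scale). Masked rows/columns are zero in the output.
#'
#' @param m A masked `hic_matrix` ([mask_bins()] is applied with defaults if
#'   the mask is missing).
#' @param tol Convergence tolerance on the coverage CV (default 1e-6).
#' @param max_iter Maximum iterations (default 200).
#' @return The matrix with `bias` (per-bin, NA at masked bins), `corrected`
#'   (dense matrix, masked rows/cols zero) and attributes `ice_cv`,
#'   `ice_iterations` filled. Errors on non-convergence, carrying the last
#'   CV in the message.
#' @export
ice_correct <- function(m, tol = 1e-6, max_iter = 200L) {
  if (is.null(m$mask)) m <- mask_bins(m)
  inc <- m$mask
  O <- m$counts[inc, inc, drop = FALSE]
  nb <- nrow(O)
  b <- rep(1, nb)
  W <- O
  cv <- Inf
  for (it in seq_len(max_iter)) {
    s <- rowSums(W)
    if (any(s == 0)) stop("included bin with zero coverage during balancing")
    cv <- stats::sd(s) / mean(s)
    if (cv < tol) break
    d <- s / mean(s)
    b <- b * d
    W <- W / (d %o% d)
  }
  if (cv >= tol)
    stop(sprintf("ICE did not converge in %d iterations (last CV %.3g)",
                 max_iter, cv))
  b <- b / mean(b)
  Tm <- O / (b %o% b)
  Tm <- Tm * sum(O) / sum(Tm)
  bias <- rep(NA_real_, length(inc)); bias[inc] <- b
  Corr <- matrix(0, length(inc), length(inc))
  Corr[inc, inc] <- Tm
  m$bias <- bias
  m$corrected <- Corr
  attr(m, "ice_cv") <- cv
  attr(m, "ice_iterations") <- it
  m
}

#' Distance correction (observed / expected matrix)
#'
#' Divides each cis cell of the coverage-corrected matrix by the mean
#' corrected value at its bin distance, pooled over all chromosomes
#' (included bins only), giving an observed/expected matrix with mean 1 at
#' each distance. Diagonal (distance-0) cells are set to NA, as are cells at
#' distances with no included pairs. Trans cells are divided by the mean
#' included trans value.
#'
#' @param m A coverage-corrected `hic_matrix` (fixed binsize).
#' @return The matrix with its `oe` slot and an `expected` (per-distance
#'   mean) vector filled.
#' @export
distance_correct <- function(m) {
  if (is.null(m$corrected)) stop("run ice_correct() first")
  if (is.na(m$binsize)) stop("distance correction needs fixed-size bins")
  n <- nrow(m$bins)
  inc <- m$mask
  chroms <- unique(m$bins$chrom)
  idx_by <- lapply(chroms, function(ch) which(m$bins$chrom == ch))
  dmax <- max(vapply(idx_by, length, integer(1))) - 1L
  sums <- numeric(dmax + 1L); cnts <- numeric(dmax + 1L)
  cis_sum <- 0; cis_cnt <- 0
  # pass 1: pooled per-distance means over included cis cells
  for (idx in idx_by) {
    sub <- m$corrected[idx, idx, drop = FALSE]
    isub <- inc[idx]
    if (sum(isub) < 1L) next
    nd <- length(idx)
    D <- abs(outer(seq_len(nd), seq_len(nd), "-"))
    sel <- outer(isub, isub, "&")
    dv <- D[sel]; vv <- sub[sel]
    ag_s <- rowsum(vv, dv); ag_c <- rowsum(rep(1, length(dv)), dv)
    dd <- as.integer(rownames(ag_s)) + 1L
    sums[dd] <- sums[dd] + ag_s[, 1]
    cnts[dd] <- cnts[dd] + ag_c[, 1]
    cis_sum <- cis_sum + sum(vv); cis_cnt <- cis_cnt + length(vv)
  }
  expected <- ifelse(cnts > 0, sums / cnts, NA_real_)
  # trans mean over included cells
  incv <- which(inc)
  tot_sum <- sum(m$corrected[incv, incv]); tot_cnt <- length(incv)^2
  trans_cnt <- tot_cnt - cis_cnt
  trans_mean <- if (trans_cnt > 0) (tot_sum - cis_sum) / trans_cnt else NA_real_
  # pass 2: fill observed/expected
  OE <- matrix(NA_real_, n, n)
  if (!is.na(trans_mean) && trans_mean > 0)
    OE[incv, incv] <- m$corrected[incv, incv] / trans_mean
  for (idx in idx_by) {
    isub <- which(inc[idx])
    gi <- idx[isub]
    if (!length(gi)) next
    D <- abs(outer(isub, isub, "-"))
    ed <- matrix(expected[D + 1L], nrow(D), ncol(D))
    block <- m$corrected[gi, gi, drop = FALSE] / ed
    block[D == 0 | is.na(ed) | ed <= 0] <- NA_real_
    OE[gi, gi] <- block
  }
  m$oe <- OE
  m$expected <- expected
  m
}
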