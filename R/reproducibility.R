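#' Spearman correlation between two contact matrices
#'
#' Rank correlation over the union of upper-triangle (including diagonal)
#' cells included in both matrices' masks; cells masked in either matrix
#' are excluded. Works on any shared bin table, including variable-sized
#' bins such as TADs.
#'
#' @param mx,my `hic_matrix` objects on identical bin tables.
#' @param use Which matrix slot to correlate: "counts" (default) or
#'   "corrected".
#' @return Spearman's rank correlation coefficient.
#' @export
matrix_spearman <- function(mx, my, use = c("counts", "corrected")) {
  use <- match.arg(use)
  if (nrow(mx$bins) != nrow(my$bins)) stop("matrices on different bin tables")
  n <- nrow(mx$bins)
  incx <- if (is.null(mx$mask)) rep(TRUE, n) else mx$mask
  incy <- if (is.null(my$mask)) rep(TRUE, n) else my$mask
  inc <- incx & incy
  ut <- upper.tri(mx[[use]], diag = TRUE) & (inc %o% inc)
  x <- mx[[use]][ut]; y <- my[[use]][ut]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 10L) stop("fewer than 10 shared included cells")
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Deviation from expected slope (DES) between two contact matrices
#'
#' Reproducibility statistic for a pair of Hi-C libraries: cells of the two
#' count matrices are stratified by genomic distance (log10 bins, plus one
#' trans stratum), an ordinary least-squares line y = a x + b is fitted per
#' stratum, the slope is corrected for the library-size difference,
#' `a_corr = a * C_x / C_y` (C = total counts), and
#' \deqn{DES = \mathrm{atan}(a_{corr}) - \mathrm{atan}(1)}
#' in radians. DES = 0 for perfectly reproducible libraries in that
#' stratum; negative DES indicates slope attenuation, the signature of
#' uncorrelated (random-ligation) counts. Unlike rank correlation, DES is
#' sensitive to noise that preserves ranks, so the two statistics are
#' complementary.
#'
#' @param mx,my `hic_matrix` objects on identical fixed-binsize bin tables
#'   (x and y axes of the fit respectively).
#' @param strata_edges Distance stratum edges in bp (default: log10-equal
#'   bins spanning the observed cis distances, `n_strata` of them).
#' @param n_strata Number of default distance strata (default 12).
#' @param use Matrix slot to fit: "counts" (default) or "corrected".
#' @param log_counts Fit on log2(x + 1) instead of raw counts.
#' @param drop_zeros Drop cells that are zero in both matrices.
#' @param min_points Minimum cells per stratum; smaller strata are skipped
#'   and flagged.
#' @return Object of class `des_result`: `strata` data.table (stratum
#'   bounds, n, slope a, intercept b, a_corr, des, spearman, skipped flag),
#'   `overall_des` (count-weighted mean over fitted strata), `overall_spearman`,
#'   `C_x`, `C_y`.
#' @export
des <- function(mx, my, strata_edges = NULL, n_strata = 12L,
                use = c("counts", "corrected"), log_counts = FALSE,
                drop_zeros = FALSE, min_points = 3L) {
  use <- match.arg(use)
  if (nrow(mx$bins) != nrow(my$bins)) stop("matrices on different bin tables")
  n <- nrow(mx$bins)
  incx <- if (is.null(mx$mask)) rep(TRUE, n) else mx$mask
  incy <- if (is.null(my$mask)) rep(TRUE, n) else my$mask
  inc <- incx & incy
  ut <- which(upper.tri(mx[[use]], diag = TRUE) & (inc %o% inc))
  x <- mx[[use]][ut]; y <- my[[use]][ut]
  Cx <- sum(mx$counts[upper.tri(mx$counts, diag = TRUE)])
  Cy <- sum(my$counts[upper.tri(my$counts, diag = TRUE)])
  if (Cx <= 0 || Cy <= 0) stop("library totals must be positive")
  # distance per cell (NA = trans)
  row_i <- (ut - 1L) %% n + 1L
  col_j <- (ut - 1L) %/% n + 1L
  same <- mx$bins$chrom[row_i] == mx$bins$chrom[col_j]
  dist <- rep(NA_real_, length(ut))
  dist[same] <- abs(mx$bins$start[row_i[same]] - mx$bins$start[col_j[same]])
  if (drop_zeros) {
    keep <- !(x == 0 & y == 0)
    x <- x[keep]; y <- y[keep]; dist <- dist[keep]; same <- same[keep]
  }
  if (log_counts) { x <- log2(x + 1); y <- log2(y + 1) }
  if (is.null(strata_edges)) {
    dpos <- dist[!is.na(dist) & dist > 0]
    strata_edges <- if (length(dpos))
      10^seq(log10(min(dpos)), log10(max(dpos) + 1), length.out = n_strata + 1)
    else numeric(0)
  }
  ns <- max(length(strata_edges) - 1L, 0L)
  stratum <- rep(NA_integer_, length(x))
  if (ns > 0) {
    s <- findInterval(dist, strata_edges, rightmost.closed = TRUE)
    s[is.na(dist) | s < 1L | s > ns] <- NA_integer_
    stratum <- s
  }
  stratum[is.na(dist)] <- ns + 1L   # trans stratum
  rows <- lapply(seq_len(ns + 1L), function(k) {
    sel <- which(stratum == k)
    lo <- if (k <= ns) strata_edges[k] else NA_real_
    hi <- if (k <= ns) strata_edges[k + 1L] else NA_real_
    lab <- if (k <= ns) sprintf("cis_%d", k) else "trans"
    if (length(sel) < min_points || stats::var(x[sel]) == 0) {
      return(data.table::data.table(stratum = lab, lo = lo, hi = hi,
        n = length(sel), a = NA_real_, b = NA_real_, a_corr = NA_real_,
        des = NA_real_, spearman = NA_real_, total = NA_real_, skipped = TRUE))
    }
    a <- stats::cov(x[sel], y[sel]) / stats::var(x[sel])
    b <- mean(y[sel]) - a * mean(x[sel])
    a_corr <- a * Cx / Cy
    sp <- suppressWarnings(stats::cor(x[sel], y[sel], method = "spearman"))
    data.table::data.table(stratum = lab, lo = lo, hi = hi, n = length(sel),
      a = a, b = b, a_corr = a_corr, des = atan(a_corr) - atan(1),
      spearman = sp, total = sum(x[sel]) + sum(y[sel]), skipped = FALSE)
  })
  st <- data.table::rbindlist(rows)
  fitted <- st[skipped == FALSE & is.finite(des)]
  overall <- if (nrow(fitted))
    sum(fitted$des * fitted$total) / sum(fitted$total) else NA_real_
  osp <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  structure(list(strata = st[], overall_des = overall,
                 overall_spearman = osp, C_x = Cx, C_y = Cy),
            class = "des_result")
}
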