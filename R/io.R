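#' Contact matrix I/O as COO triplets plus a bin BED
#'
#' Writes the raw counts of a `hic_matrix` as a tab-separated triplet file
#' (bin_i, bin_j, count; upper triangle including diagonal, 1-based bin
#' ids) and the bin table as BED (`<path>.bins.bed`: chrom, start, end,
#' bin_id). `read_matrix_coo` rebuilds the dense symmetric matrix.
#'
#' @param m A `hic_matrix`.
#' @param path Triplet file path.
#' @return `read_matrix_coo` returns a `hic_matrix` (mask and corrections
#'   unset).
#' @export
write_matrix_coo <- function(m, path) {
  ut <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0)
  n <- nrow(m$counts)
  coo <- data.table::data.table(bin_i = (ut - 1L) %% n + 1L,
                                bin_j = (ut - 1L) %/% n + 1L,
                                count = m$counts[ut])
  data.table::fwrite(coo, path, sep = "\t")
  data.table::fwrite(m$bins[, .(chrom, start, end, bin_id)],
                     paste0(path, ".bins.bed"), sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_coo
#' @export
read_matrix_coo <- function(path) {
  coo <- data.table::fread(path)
  bins <- data.table::fread(paste0(path, ".bins.bed"), header = FALSE,
                            col.names = c("chrom", "start", "end", "bin_id"))
  n <- nrow(bins)
  M <- matrix(0, n, n)
  M[cbind(coo$bin_i, coo$bin_j)] <- coo$count
  M[cbind(coo$bin_j, coo$bin_i)] <- coo$count
  binsize <- stats::median(bins$end - bins$start)
  if (length(unique(bins$end - bins$start)) > 2L) binsize <- NA_real_
  structure(list(bins = bins, counts = M, binsize = binsize,
                 mask = NULL, bias = NULL, corrected = NULL, oe = NULL),
            class = "hic_matrix")
}

#' Export a per-bin track as bedGraph
#'
#' @param track A data.table with chrom, start, end and a value column
#'   (e.g. an `eigen_track`'s `value` or a `bin_track`'s `signal`).
#' @param path Output path.
#' @param column Name of the value column.
#' @export
write_bedgraph <- function(track, path, column = "value") {
  tr <- data.table::as.data.table(track)
  out <- tr[, .(chrom, start, end)]
  out[, value := tr[[column]]]
  data.table::fwrite(out[!is.na(value)], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Export a boundary set as BED
#'
#' Boundaries are written as 1-bp intervals at their lattice position.
#'
#' @param b A `boundary_set`.
#' @param path Output path.
#' @export
write_boundaries_bed <- function(b, path) {
  out <- data.table::data.table(chrom = b$chrom, start = b$pos,
                                end = b$pos + 1)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
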