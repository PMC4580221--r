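#' Call A/B compartments from interaction-profile correlation eigenvectors
#'
#' Per chromosome, forms the Pearson correlation matrix of bin interaction
#' profiles (columns of the coverage-and-distance-corrected matrix,
#' included bins only), eigen-decomposes it, and assigns compartment labels
#' by eigenvector sign: positive = A, negative = B. When an activity track
#' (e.g. an active-histone-mark signal) is supplied, the selected
#' eigenvector is multiplied by -1 if its Pearson correlation with the
#' track is negative, so A is the active compartment; among the first
#' `n_eigs` eigenvectors the one with the largest absolute correlation
#' with the track is selected (the compartmental rather than the
#' chromosome-arm pattern). A chromosome is excluded when its two leading
#' eigenvalues are separated by less than `eigengap_tol` (no clear
#' compartment signal), or when it has fewer than `min_bins` included bins.
#'
#' @param m A `hic_matrix` with its `oe` slot filled ([distance_correct()]).
#' @param activity Optional `bin_track` on the same bins (matched on
#'   chrom/start) with a `signal` column.
#' @param n_eigs Number of leading eigenvectors considered (default 2).
#' @param eigengap_tol Minimum relative separation of the two leading
#'   eigenvalues (default 0.05); chromosomes below it are excluded.
#' @param min_bins Minimum included bins per chromosome (default 10).
#' @return An `eigen_track`: data.table(chrom, start, end, value, label)
#'   with label in A/B/excluded, plus attribute `chrom_info`
#'   (per-chromosome eigenvector index, activity correlation, eigenvalues).
#' @export
call_compartments <- function(m, activity = NULL, n_eigs = 2L,
                              eigengap_tol = 0.05, min_bins = 10L) {
  if (is.null(m$oe)) stop("run distance_correct() first")
  bins <- data.table::copy(m$bins)
  bins[, `:=`(value = NA_real_, label = "excluded")]
  act <- NULL
  if (!is.null(activity)) {
    act <- data.table::as.data.table(activity)[, .(chrom, start, signal)]
  }
  info <- list()
  for (ch in unique(bins$chrom)) {
    idx <- which(bins$chrom == ch)
    isub <- idx[m$mask[idx]]
    if (length(isub) < min_bins) {
      warning(sprintf("chromosome %s: fewer than %d included bins, excluded",
                      ch, min_bins))
      next
    }
    prof <- m$oe[isub, isub, drop = FALSE]
    C <- suppressWarnings(stats::cor(prof, use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    diag(C) <- 1
    eg <- eigen(C, symmetric = TRUE)
    k_avail <- min(n_eigs, ncol(eg$vectors))
    if (k_avail >= 2L) {
      l1 <- abs(eg$values[1]); l2 <- abs(eg$values[2])
      if (l1 > 0 && (l1 - l2) / l1 < eigengap_tol) {
        warning(sprintf(
          "chromosome %s: no clear separation between the first %d eigenvectors, excluded",
          ch, k_avail))
        info[[ch]] <- list(excluded = TRUE, eigenvalues = eg$values[1:k_avail])
        next
      }
    }
    asig <- NULL
    if (!is.null(act)) {
      am <- act[bins[isub], on = c("chrom", "start")]
      asig <- am$signal
    }
    pick <- 1L; rr <- NA_real_
    if (!is.null(asig) && !all(is.na(asig))) {
      cors <- vapply(seq_len(k_avail), function(k)
        suppressWarnings(stats::cor(eg$vectors[, k], asig,
                                    use = "complete.obs")), numeric(1))
      pick <- which.max(abs(cors))
      rr <- cors[pick]
    }
    v <- eg$vectors[, pick]
    if (!is.na(rr) && rr < 0) { v <- -v; rr <- -rr }
    data.table::set(bins, isub, "value", v)
    data.table::set(bins, isub, "label",
                    ifelse(v > 0, "A", ifelse(v < 0, "B", "excluded")))
    info[[ch]] <- list(excluded = FALSE, eigenvector = pick,
                       activity_cor = rr,
                       eigenvalues = eg$values[seq_len(k_avail)])
  }
  data.table::setattr(bins, "chrom_info", info)
  data.table::setattr(bins, "class", c("eigen_track", "data.table", "data.frame"))
  bins[]
}

#' Test hybrid di-tags for compartment interaction bias
#'
#' In a species-mixing experiment, counts hybrid di-tags whose two ends both
#' fall in labeled (A or B) compartment bins of their respective genomes,
#' forms the 2x2 table (species-1 compartment x species-2 compartment), and
#' applies a two-sided Fisher's exact test (hypergeometric enumeration) for
#' a preference of like-compartment interactions. Under fully random
#' cross-complex ligation, no association is expected.
#'
#' @param hybrids A `ditag_table`; records with `locality == "hybrid"` are
#'   used (all records if no `locality` column).
#' @param trackX,trackY `eigen_track`s for the two genomes (their chromosome
#'   names identify which end belongs to which).
#' @return List of class `hybrid_compartment_table`: `table` (2x2 matrix,
#'   rows = species-X label A/B, cols = species-Y), `odds_ratio`, `p_value`,
#'   `n_used`, and `degenerate` (TRUE when a margin is zero; then p = 1).
#' @export
hybrid_compartment_test <- function(hybrids, trackX, trackY) {
  tab <- data.table::as.data.table(hybrids)
  if ("locality" %in% names(tab)) tab <- tab[locality == "hybrid"]
  label_at <- function(track, chrom, pos) {
    out <- rep(NA_character_, length(chrom))
    trk <- data.table::as.data.table(track)
    for (cc in intersect(unique(chrom), unique(trk$chrom))) {
      sel <- which(chrom == cc)
      tsub <- trk[chrom == cc]
      k <- findInterval(pos[sel], tsub$start)
      ok <- k >= 1L & pos[sel] < tsub$end[pmax(k, 1L)]
      out[sel[ok]] <- tsub$label[k[ok]]
    }
    out
  }
  chrX <- unique(trackX$chrom)
  e1_in_X <- tab$chrom1 %in% chrX
  cx <- ifelse(e1_in_X, tab$chrom1, tab$chrom2)
  px <- ifelse(e1_in_X, tab$pos1, tab$pos2)
  cy <- ifelse(e1_in_X, tab$chrom2, tab$chrom1)
  py <- ifelse(e1_in_X, tab$pos2, tab$pos1)
  lx <- label_at(trackX, cx, px)
  ly <- label_at(trackY, cy, py)
  use <- lx %in% c("A", "B") & ly %in% c("A", "B")
  tt <- matrix(0L, 2, 2, dimnames = list(X = c("A", "B"), Y = c("A", "B")))
  if (any(use)) {
    cnt <- table(factor(lx[use], c("A", "B")), factor(ly[use], c("A", "B")))
    tt[] <- as.integer(cnt)
  }
  degenerate <- any(rowSums(tt) == 0) || any(colSums(tt) == 0)
  if (degenerate) {
    res <- list(table = tt, odds_ratio = NA_real_, p_value = 1,
                n_used = sum(use), degenerate = TRUE)
  } else {
    ft <- stats::fisher.test(tt, alternative = "two.sided")
    res <- list(table = tt, odds_ratio = unname(ft$estimate),
                p_value = ft$p.value, n_used = sum(use), degenerate = FALSE)
  }
  structure(res, class = "hybrid_compartment_table")
}
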