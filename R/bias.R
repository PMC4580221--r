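#' Filter di-tags by total segment length
#'
#' Removes di-tags whose summed read-to-ligated-fragment-end distances
#' exceed a threshold (default 500 bp). The ligated fragment end of a read
#' is inferred from its strand: a "+" read ligates at its fragment's right
#' end, a "-" read at the left end; the segment length of one end is the
#' distance from the 5' read position to that fend.
#'
#' @param table A `ditag_table` with fragment ids.
#' @param maps Fragment map(s) resolving `frag1`/`frag2`.
#' @param threshold Maximum summed segment length in bp (default 500).
#' @return The filtered `ditag_table`, with `seglen1`/`seglen2` columns.
#' @export
segment_length_filter <- function(table, maps, threshold = 500) {
  map <- if (inherits(maps, "fragment_map")) maps else pool_fragment_maps(maps)
  if (nrow(table) && !any(table$chrom1 %in% unique(map$chrom)) &&
      inherits(maps, "fragment_map"))
    map <- pool_fragment_maps(maps)
  tab <- data.table::copy(data.table::as.data.table(table))
  seg <- function(frag, pos, strand) {
    st <- map$start[frag]; en <- map$end[frag]
    ifelse(strand == "+", en - pos, pos - st)
  }
  tab[, seglen1 := seg(frag1, pos1, strand1)]
  tab[, seglen2 := seg(frag2, pos2, strand2)]
  out <- tab[seglen1 + seglen2 <= threshold]
  data.table::setattr(out, "chromosome_lengths",
                      attr(table, "chromosome_lengths"))
  data.table::setattr(out, "class", c("ditag_table", "data.table", "data.frame"))
  out[]
}

#' Estimate 20x20 fragment-length and GC bias matrices from trans di-tags
#'
#' Fits the factorized fragment-end bias model of Hi-C coverage correction:
#' the probability of observing a trans-chromosomal contact between fragment
#' ends i and j is proportional to
#' `F_len[b_len(i), b_len(j)] * F_gc[b_gc(i), b_gc(j)]`,
#' where `b_len`/`b_gc` assign each fend to one of 20 equal-occupancy
#' quantile bins of fragment length and of terminal-200-bp GC content.
#' Trans data are used because, absent bias, every fend pair on different
#' chromosomes is equally likely a priori.
#'
#' Estimation aggregates fend pairs by feature-bin pair: observed contact
#' counts are Poisson events against the number of possible trans fend
#' pairs per feature-bin cell as exposure. The likelihood is maximized by
#' coordinate ascent alternating closed-form updates of the two matrices
#' (each update is the conditional MLE, so the log-likelihood never
#' decreases), with symmetrization and geometric-mean normalization to 1
#' each sweep, until the log-likelihood gain drops below `tol`.
#'
#' @param trans_table A `ditag_table`; only records with ends on different
#'   chromosomes are used.
#' @param features Fend features from [fend_features()] on the same map.
#' @param resolutions Optional numeric vector of genomic bin resolutions
#'   (bp), recorded for provenance; the aggregated likelihood itself is
#'   resolution-free.
#' @param tol Convergence tolerance on the log-likelihood gain per sweep.
#' @param max_iter Maximum sweeps.
#' @param block_order Order of the two coordinate blocks, `c("length","gc")`
#'   by default.
#' @return Object of class `bias_matrices`: list with `length` and `gc`
#'   (20x20 symmetric positive matrices, geometric mean 1; rows/columns of
#'   empty feature bins fixed at 1), `edges`, `loglik` (per-sweep trace),
#'   `converged`, `n_trans`, and `wide_uncertainty` (TRUE with a warning
#'   when fewer than 1000 trans di-tags are available).
#' @export
estimate_bias <- function(trans_table, features, resolutions = NULL,
                          tol = 1e-6, max_iter = 200L,
                          block_order = c("length", "gc")) {
  stopifnot(all(block_order %in% c("length", "gc")))
  nb <- features$n_bins
  fe <- features$fends[mappable == TRUE]
  tab <- trans_table[trans_table$chrom1 != trans_table$chrom2]
  wide <- nrow(tab) < 1000L
  if (wide) warning("fewer than 1000 trans di-tags: bias estimates have wide uncertainty")

  side_of <- function(strand) ifelse(strand == "+", "R", "L")
  fkey <- paste(fe$frag_id, fe$side)
  i1 <- match(paste(tab$frag1, side_of(tab$strand1)), fkey)
  i2 <- match(paste(tab$frag2, side_of(tab$strand2)), fkey)
  keep <- !is.na(i1) & !is.na(i2)
  i1 <- i1[keep]; i2 <- i2[keep]

  # joint feature index a = (len_bin - 1) * nb + gc_bin, in 1..nb^2
  joint <- (fe$len_bin - 1L) * nb + fe$gc_bin
  a1 <- joint[i1]; a2 <- joint[i2]
  nj <- nb * nb
  # symmetric count matrix over joint bins (each di-tag in both orders)
  K <- matrix(0, nj, nj)
  tk <- data.table::data.table(a = c(a1, a2), b = c(a2, a1))[, .N, by = .(a, b)]
  K[cbind(tk$a, tk$b)] <- tk$N

  # exposure: ordered trans fend pairs per joint-bin pair
  ctab <- data.table::data.table(chrom = fe$chrom, a = joint)[, .N, by = .(chrom, a)]
  Nvec <- numeric(nj)
  tot <- ctab[, .(N = sum(N)), by = a]
  Nvec[tot$a] <- tot$N
  E <- Nvec %o% Nvec
  for (cc in unique(ctab$chrom)) {
    v <- numeric(nj)
    sub <- ctab[chrom == cc]
    v[sub$a] <- sub$N
    E <- E - v %o% v
  }
  sup <- E > 0

  lidx <- rep(seq_len(nb), each = nb)  # l(a) for joint index a
  expand <- function(F20) F20[lidx, lidx]
  expand_gc <- function(F20) {
    gidx <- rep(seq_len(nb), times = nb)
    F20[gidx, gidx]
  }
  gidx <- rep(seq_len(nb), times = nb)

  Flen <- matrix(1, nb, nb); Fgc <- matrix(1, nb, nb)
  big <- function() expand(Flen) * expand_gc(Fgc)
  loglik <- function(mu) {
    lam <- mu * E * big()
    sum(K[sup] * log(pmax(lam[sup], 1e-300))) - sum(lam[sup])
  }
  agg <- function(M, idx) {
    # sum M over groups of rows and columns given by idx
    r <- rowsum(M, idx)
    t(rowsum(t(r), idx))
  }

  ll_trace <- numeric(0)
  mu <- sum(K) / max(sum(E * big()), 1e-300)
  ll_old <- loglik(mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    for (blk in block_order) {
      if (blk == "length") {
        den <- mu * agg(E * expand_gc(Fgc), lidx)
        num <- agg(K, lidx)
        Fnew <- matrix(1, nb, nb)
        ok <- den > 0
        Fnew[ok] <- pmax(num[ok] / den[ok], 1e-8)
        Fnew <- (Fnew + t(Fnew)) / 2
        gm <- exp(mean(log(Fnew[ok])))
        Fnew[ok] <- Fnew[ok] / gm
        Flen <- Fnew
      } else {
        den <- mu * agg(E * expand(Flen), gidx)
        num <- agg(K, gidx)
        Fnew <- matrix(1, nb, nb)
        ok <- den > 0
        Fnew[ok] <- pmax(num[ok] / den[ok], 1e-8)
        Fnew <- (Fnew + t(Fnew)) / 2
        gm <- exp(mean(log(Fnew[ok])))
        Fnew[ok] <- Fnew[ok] / gm
        Fgc <- Fnew
      }
      mu <- sum(K) / max(sum(E * big()), 1e-300)
    }
    ll <- loglik(mu)
    ll_trace <- c(ll_trace, ll)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(length = Flen, gc = Fgc, edges = features$edges,
                 loglik = ll_trace, converged = converged,
                 n_trans = length(i1), mu = mu,
                 resolutions = resolutions, wide_uncertainty = wide),
            class = "bias_matrices")
}
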