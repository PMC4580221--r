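#' Directionality index profile
#'
#' For each 25-kb window (5 consecutive 5-kb elementary bins, stepped by one
#' bin) the upstream and downstream coverage-corrected contact sums within
#' `max_dist` are contrasted by the signed chi-square-like directionality
#' index:
#' \deqn{DI = \mathrm{sign}(B - A)\left(\frac{(A-E)^2}{E} + \frac{(B-E)^2}{E}\right),
#'   \quad E = (A+B)/2}
#' where A is the contact sum from the window to bins strictly upstream
#' within `max_dist` and B the downstream analogue; DI = 0 when A = B.
#' Strongly positive DI marks the start of a domain (downstream-biased
#' contacts), strongly negative DI its end. Elementary bins with raw
#' coverage below `low_fraction` of the nonzero-bin mean or more than
#' `sd_cut` SD above it are excluded (DI = NA at those window centers).
#'
#' @param m A `hic_matrix` at the elementary (step) resolution, ideally
#'   coverage-corrected; `corrected` is used when present, else raw counts.
#' @param max_dist Interaction distance in bp (default 1 Mb).
#' @param window Window width in bp (default 25 kb).
#' @param low_fraction,sd_cut Elementary-bin coverage mask (defaults 0.15
#'   and 4).
#' @return A `di_profile`: data.table(chrom, pos, di, included) with `pos`
#'   the window center on the step lattice; plus attribute `step`.
#' @export
directionality_index <- function(m, max_dist = 1e6, window = 25000,
                                 low_fraction = 0.15, sd_cut = 4) {
  step <- m$binsize
  if (is.na(step)) stop("directionality index needs fixed-size bins")
  wbins <- round(window / step)
  half <- wbins %/% 2L
  dbins <- round(max_dist / step)
  V <- if (!is.null(m$corrected)) m$corrected else m$counts
  cov <- rowSums(m$counts)
  nz <- cov > 0
  mu <- mean(cov[nz]); s <- stats::sd(cov[nz])
  inc <- nz & cov >= low_fraction * mu
  if (is.finite(s) && s > 0) inc <- inc & (cov - mu) <= sd_cut * s
  out <- list()
  for (ch in unique(m$bins$chrom)) {
    idx <- which(m$bins$chrom == ch)
    nd <- length(idx)
    if (nd < wbins) next
    Tm <- V[idx, idx, drop = FALSE]
    isub <- inc[idx]
    Tm[!isub, ] <- 0; Tm[, !isub] <- 0
    CR <- apply(Tm, 2, cumsum)                 # CR[i, j] = sum_{k<=i} T[k, j]
    zeros <- rep(0, nd)
    di <- rep(NA_real_, nd)
    for (c0 in seq.int(half + 1L, nd - half)) {
      if (!isub[c0]) next
      ws <- c0 - half; we <- c0 + half
      v <- CR[we, ] - (if (ws > 1L) CR[ws - 1L, ] else zeros)  # window row sums
      cv <- cumsum(v)
      up_hi <- ws - 1L
      up_lo <- max(ws - dbins, 1L)
      A <- if (up_hi >= up_lo) cv[up_hi] - (if (up_lo > 1L) cv[up_lo - 1L] else 0) else 0
      dn_lo <- we + 1L
      dn_hi <- min(we + dbins, nd)
      B <- if (dn_hi >= dn_lo) cv[dn_hi] - cv[dn_lo - 1L] else 0
      E <- (A + B) / 2
      di[c0] <- if (E <= 0 || A == B) 0 else
        sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    }
    out[[ch]] <- data.table::data.table(
      chrom = ch, pos = (seq_len(nd) - 1) * step + step / 2,
      di = di, included = isub)
  }
  prof <- data.table::rbindlist(out)
  data.table::setattr(prof, "step", step)
  data.table::setattr(prof, "class", c("di_profile", "data.table", "data.frame"))
  prof[]
}

#' Smooth a DI profile with a running average
#'
#' Centered moving mean over all available (non-NA) DI values within
#' `half_window` bp of each position; windows are truncated at chromosome
#' ends.
#'
#' @param p A `di_profile`.
#' @param half_window Half window in bp (default 25 kb).
#' @return The profile with a `di_smooth` column added.
#' @export
smooth_di <- function(p, half_window = 25000) {
  step <- attr(p, "step")
  k <- round(half_window / step)
  prof <- data.table::copy(data.table::as.data.table(p))
  sm <- function(x) {
    n <- length(x)
    v <- ifelse(is.na(x), 0, x)
    cnt <- as.numeric(!is.na(x))
    cv <- c(0, cumsum(v)); cc <- c(0, cumsum(cnt))
    lo <- pmax(seq_len(n) - k, 1L); hi <- pmin(seq_len(n) + k, n)
    s <- cv[hi + 1L] - cv[lo]
    m <- cc[hi + 1L] - cc[lo]
    ifelse(m > 0, s / m, NA_real_)
  }
  prof[, di_smooth := sm(di), by = chrom]
  data.table::setattr(prof, "step", step)
  data.table::setattr(prof, "class", c("di_profile", "data.table", "data.frame"))
  prof[]
}

#' Call TAD boundaries from a smoothed DI profile
#'
#' Qualifying extrema are local minima of the smoothed DI at least
#' `z_threshold` standard deviations below the profile mean, and local
#' maxima at least `z_threshold` SD above it (mean/SD over all included
#' positions genome-wide). One boundary is placed per domain junction: at
#' the DI sign transition between a qualifying minimum (end of one domain)
#' and the next qualifying maximum (start of the next), rounded to the
#' `lattice` (25 kb) grid.
#'
#' @param p A smoothed `di_profile` (see [smooth_di()]).
#' @param z_threshold Extremum threshold in SD units (default 0.5).
#' @param lattice Rounding lattice in bp (default 25 kb).
#' @return A `boundary_set`: data.table(chrom, pos), sorted and unique.
#' @export
call_boundaries <- function(p, z_threshold = 0.5, lattice = 25000) {
  prof <- data.table::as.data.table(p)
  if (!"di_smooth" %in% names(prof)) prof <- smooth_di(prof)
  vals <- prof$di_smooth[prof$included & !is.na(prof$di_smooth)]
  if (!length(vals)) return(empty_boundary_set())
  mu <- mean(vals); s <- stats::sd(vals)
  if (!is.finite(s) || s == 0) return(empty_boundary_set())
  res <- list()
  for (ch in unique(prof$chrom)) {
    sub <- prof[chrom == ch & !is.na(di_smooth)]
    x <- sub$di_smooth
    n <- length(x)
    if (n < 3L) next
    lmin <- c(FALSE, x[2:(n - 1)] <= x[1:(n - 2)] & x[2:(n - 1)] <= x[3:n] &
                (x[2:(n - 1)] < x[1:(n - 2)] | x[2:(n - 1)] < x[3:n]), FALSE)
    lmax <- c(FALSE, x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                (x[2:(n - 1)] > x[1:(n - 2)] | x[2:(n - 1)] > x[3:n]), FALSE)
    qmin <- which(lmin & x < mu - z_threshold * s)
    qmax <- which(lmax & x > mu + z_threshold * s)
    if (!length(qmin) || !length(qmax)) next
    pos <- numeric(0)
    for (i in qmin) {
      nxt <- qmax[qmax > i]
      if (!length(nxt)) next
      j <- nxt[1]
      if (any(qmin > i & qmin < j)) next  # pair each max with its nearest min
      cross <- which(x[i:j] >= 0)
      kk <- if (length(cross)) i + cross[1] - 1L else round((i + j) / 2)
      pos <- c(pos, sub$pos[kk])
    }
    if (length(pos))
      res[[ch]] <- data.table::data.table(
        chrom = ch, pos = round(pos / lattice) * lattice)
  }
  if (!length(res)) return(empty_boundary_set())
  out <- unique(data.table::rbindlist(res))
  data.table::setorder(out, chrom, pos)
  data.table::setattr(out, "class", c("boundary_set", "data.table", "data.frame"))
  out[]
}

empty_boundary_set <- function() {
  out <- data.table::data.table(chrom = character(), pos = numeric())
  data.table::setattr(out, "class", c("boundary_set", "data.table", "data.frame"))
  out[]
}

#' Consensus TAD boundaries between two sets
#'
#' Keeps boundaries present in both sets after rounding to the 25-kb
#' lattice. `slop = 1` additionally accepts matches one lattice step apart.
#'
#' @param a,b `boundary_set`s on the same genome.
#' @param lattice Lattice in bp (default 25 kb).
#' @param slop Allowed lattice-step difference (default 0 = exact match).
#' @return A `boundary_set` of consensus positions (from `a`'s rounding).
#' @export
consensus_boundaries <- function(a, b, lattice = 25000, slop = 0L) {
  ra <- unique(data.table::data.table(
    chrom = a$chrom, pos = round(a$pos / lattice) * lattice))
  rb <- unique(data.table::data.table(
    chrom = b$chrom, pos = round(b$pos / lattice) * lattice))
  keep <- vapply(seq_len(nrow(ra)), function(i) {
    cand <- rb[chrom == ra$chrom[i]]
    any(abs(cand$pos - ra$pos[i]) <= slop * lattice)
  }, logical(1))
  out <- ra[keep]
  data.table::setorder(out, chrom, pos)
  data.table::setattr(out, "class", c("boundary_set", "data.table", "data.frame"))
  out[]
}

#' Fraction of boundaries reproduced within a window
#'
#' @param a,b `boundary_set`s; the fraction of `a`'s boundaries with a
#'   boundary of `b` on the same chromosome within `window` bp.
#' @param window Matching window in bp (default 100 kb).
#' @return A fraction in \[0, 1\]; NA with a warning when `a` is empty.
#' @export
boundary_overlap <- function(a, b, window = 1e5) {
  if (!nrow(a)) { warning("empty boundary set"); return(NA_real_) }
  hit <- vapply(seq_len(nrow(a)), function(i) {
    cand <- b[b$chrom == a$chrom[i], ]
    nrow(cand) > 0 && any(abs(cand$pos - a$pos[i]) <= window)
  }, logical(1))
  mean(hit)
}

#' Aggregate DI and contact profiles around TAD boundaries
#'
#' Averages the standard score of the un-smoothed DI at each offset in
#' `[-flank, +flank]` across boundaries (boundaries with an incomplete
#' flank are dropped), together with the same aggregate over `n_random`
#' uniformly drawn control positions, and optionally the mean
#' coverage-and-distance-corrected contact sub-matrix centered on the
#' boundaries.
#'
#' @param boundaries A `boundary_set`.
#' @param p A `di_profile` (raw DI used; z-scored over included positions).
#' @param m Optional `hic_matrix` with `oe` filled, for the contact pileup.
#' @param n_random Number of random control positions (default 9686).
#' @param flank Flank in bp (default 500 kb).
#' @param seed Seed for the control positions.
#' @return List with `offsets` (bp), `mean_zdi`, `n_boundaries`,
#'   `control_zdi`, `n_control`, and (with `m`) `pileup` / `control_pileup`
#'   matrices.
#' @export
aggregate_boundary_profile <- function(boundaries, p, m = NULL,
                                       n_random = 9686L, flank = 5e5,
                                       seed = 1L) {
  step <- attr(p, "step")
  prof <- data.table::as.data.table(p)
  zvals <- prof$di[prof$included]
  mu <- mean(zvals, na.rm = TRUE); s <- stats::sd(zvals, na.rm = TRUE)
  prof[, zdi := (di - mu) / s]
  offsets <- seq(-flank, flank, by = step)
  chrom_extent <- prof[, .(lo = min(pos), hi = max(pos)), by = chrom]
  collect <- function(bs) {
    rows <- list()
    for (i in seq_len(nrow(bs))) {
      ch <- bs$chrom[i]; b0 <- bs$pos[i]
      ext <- chrom_extent[chrom == ch]
      if (!nrow(ext)) next
      # snap to the profile lattice (window centers sit at step/2 offsets)
      b_lat <- (round((b0 - step / 2) / step)) * step + step / 2
      if (b_lat - flank < ext$lo || b_lat + flank > ext$hi) next
      sub <- prof[chrom == ch]
      k <- match(b_lat + offsets, sub$pos)
      rows[[length(rows) + 1L]] <- sub$zdi[k]
    }
    rows
  }
  brows <- collect(boundaries)
  mean_zdi <- if (length(brows))
    colMeans(do.call(rbind, brows), na.rm = TRUE) else rep(NA_real_, length(offsets))
  set.seed(derive_seed(seed, 4))
  rnd <- chrom_extent[sample.int(nrow(chrom_extent), n_random, replace = TRUE,
                                 prob = chrom_extent$hi - chrom_extent$lo)]
  rnd[, pos := stats::runif(.N, lo, hi)]
  crows <- collect(rnd[, .(chrom, pos)])
  control_zdi <- if (length(crows))
    colMeans(do.call(rbind, crows), na.rm = TRUE) else rep(NA_real_, length(offsets))
  out <- list(offsets = offsets, mean_zdi = mean_zdi,
              n_boundaries = length(brows), control_zdi = control_zdi,
              n_control = length(crows))
  if (!is.null(m) && !is.null(m$oe)) {
    fb <- round(flank / m$binsize)
    pile <- function(bs) {
      acc <- matrix(0, 2 * fb + 1, 2 * fb + 1); cnt <- 0
      for (i in seq_len(nrow(bs))) {
        idx <- which(m$bins$chrom == bs$chrom[i])
        c0 <- idx[findInterval(bs$pos[i], m$bins$start[idx])]
        lo <- c0 - fb; hi <- c0 + fb
        if (length(c0) != 1L || is.na(c0) || lo < min(idx) || hi > max(idx)) next
        blk <- m$oe[lo:hi, lo:hi]
        blk[is.na(blk)] <- 1
        acc <- acc + blk; cnt <- cnt + 1
      }
      if (cnt > 0) acc / cnt else acc * NA
    }
    out$pileup <- pile(boundaries)
    out$control_pileup <- pile(rnd[seq_len(min(nrow(rnd), 500L)), .(chrom, pos)])
  }
  out
}
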