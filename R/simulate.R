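#' Simulate Hi-C di-tags with known ground truth
#'
#' Generates a di-tag library from a mixture of cells of one or more
#' species-like genomes under an explicit noise model. Each di-tag is either
#'
#' * **intra-complex** (probability `1 - f_random`): both ends from one
#'   cell. Cis pairs are drawn with a `s^(-decay_exponent)` distance decay,
#'   boosted `tad_enrichment`-fold within one planted TAD and
#'   `checkerboard_enrichment`-fold for same-compartment pairs; a fraction
#'   `trans_background_weight` of intra-complex contacts is trans.
#' * **spurious** (probability `f_random`): the two fragment ends are drawn
#'   independently and uniformly over the pooled fragment-end library of all
#'   cells of all species — the random-ligation model. In a species mixture
#'   this is the only source of hybrid di-tags.
#'
#' If `model$bias_injection` is set, candidate di-tags are accepted with
#' probability proportional to the product of the true bias-matrix entries
#' of their two fragment ends (fragment-length and/or GC matrices over the
#' quantile feature bins of [fend_features()]).
#'
#' Read positions are placed near the ligated fragment end: a read on the
#' "+" strand sits upstream of its fragment's right end, a "-" strand read
#' downstream of the left end, at an exponentially distributed offset
#' (mean 150 bp, capped at the fragment length).
#'
#' @param maps A `fragment_map` or list of per-species maps (one per species
#'   in `mix`).
#' @param mix A [mixture_spec()].
#' @param model A [contact_model()].
#' @param n_ditags Number of di-tags to generate (> 0).
#' @param seed Integer master seed.
#' @return A `ditag_table`: data.table with columns readID, chrom1, pos1,
#'   strand1, chrom2, pos2, strand2, frag1, frag2, species1, species2, and
#'   the hidden ground-truth column `truth` ("intra_complex"/"spurious").
#'   Chromosome names are species-prefixed (`"mm.chr1"`). Carries the pooled
#'   map's chromosome lengths as attribute.
#' @export
simulate_ditags <- function(maps, mix, model, n_ditags, seed = 1L) {
  stopifnot(inherits(mix, "mixture_spec"), inherits(model, "contact_model"),
            n_ditags > 0)
  if (inherits(maps, "fragment_map")) maps <- list(maps)
  if (is.null(names(maps)))
    names(maps) <- vapply(maps, function(m) attr(m, "species_label"),
                          character(1))
  species <- names(mix$cells)[mix$cells > 0]
  if (!all(species %in% names(maps)))
    stop("every species in the mixture needs a fragment map")
  pooled <- pool_fragment_maps(maps[species])
  set.seed(derive_seed(seed, 2))

  feats <- NULL
  if (!is.null(model$bias_injection)) feats <- fend_features(pooled)

  # per-chromosome fragment index
  chrom_tab <- pooled[, .(n_frag = .N, chrom_len = max(end)), by = .(species, chrom)]
  chrom_idx <- split(pooled[, .(frag_id, start, end, length, chrom, species)],
                     by = "chrom", keep.by = TRUE)
  sp_frags <- chrom_tab[, .(n_frag = sum(n_frag)), by = species]
  sp_frags <- sp_frags[match(species, sp_frags$species)]
  cells <- mix$cells[species]
  w_sp <- cells * sp_frags$n_frag      # fend-pool weight per species

  f_random <- model$random_ligation_fraction
  tw <- model$trans_background_weight

  draw_fends_uniform <- function(n) {
    # species ~ pooled fend weights, chromosome ~ fragment counts, fragment
    # uniform within chromosome
    sp <- sample(species, n, replace = TRUE, prob = w_sp)
    out <- vector("list", length(species))
    for (k in seq_along(species)) {
      sp_k <- species[k]
      rows <- which(sp == sp_k)
      if (!length(rows)) next
      ct <- chrom_tab[chrom_tab$species == sp_k]
      ch <- sample(ct$chrom, length(rows), replace = TRUE, prob = ct$n_frag)
      loc <- stats::runif(length(rows))
      frag <- integer(length(rows)); chl <- character(length(rows))
      for (cc in unique(ch)) {
        ci <- chrom_idx[[cc]]
        sel <- which(ch == cc)
        frag[sel] <- ci$frag_id[ceiling(loc[sel] * nrow(ci))]
      }
      out[[k]] <- data.table::data.table(row = rows, frag = frag)
    }
    res <- data.table::rbindlist(out)
    data.table::setorder(res, row)
    res$frag
  }

  comp_label_num <- function(pos) {
    ((floor(pos / model$compartment_binsize) %/% model$compartment_block_bins) %% 2)
  }
  tad_bounds_for <- function(chrom) {
    tb <- model$tad_boundaries
    if (is.null(tb)) return(NULL)
    if (!is.null(tb[[chrom]])) return(sort(tb[[chrom]]))
    bare <- sub("^[^.]*\\.", "", chrom)
    if (!is.null(tb[[bare]])) return(sort(tb[[bare]]))
    NULL
  }

  draw_cis_pairs <- function(n) {
    # returns data.table(chrom, frag1, frag2): planted-structure rejection
    alpha <- model$decay_exponent
    wmax <- model$tad_enrichment * model$checkerboard_enrichment
    ct <- chrom_tab
    acc <- list(); got <- 0L
    while (got < n) {
      nb <- max(1000L, ceiling((n - got) * 2.8))
      ch <- sample(ct$chrom, nb, replace = TRUE,
                   prob = cells[ct$species] * ct$n_frag)
      L <- ct$chrom_len[match(ch, ct$chrom)]
      smin <- model$min_distance
      u <- stats::runif(nb)
      if (abs(alpha - 1) < 1e-12) {
        s <- smin * (L / smin)^u
      } else {
        a1 <- 1 - alpha
        s <- (smin^a1 + u * (L^a1 - smin^a1))^(1 / a1)
      }
      pos1 <- stats::runif(nb, 0, L)
      pos2 <- pos1 + ifelse(stats::runif(nb) < 0.5, -1, 1) * s
      ok <- pos2 >= 0 & pos2 < L
      if (wmax > 1 + 1e-12) {
        w <- rep(1, nb)
        if (model$checkerboard_enrichment > 1) {
          same <- comp_label_num(pos1) == comp_label_num(pos2)
          w <- w * ifelse(same, model$checkerboard_enrichment, 1)
        }
        if (model$tad_enrichment > 1 && !is.null(model$tad_boundaries)) {
          for (cc in unique(ch)) {
            tb <- tad_bounds_for(cc)
            if (is.null(tb)) next
            sel <- which(ch == cc)
            same_dom <- findInterval(pos1[sel], tb) == findInterval(pos2[sel], tb)
            w[sel] <- w[sel] * ifelse(same_dom, model$tad_enrichment, 1)
          }
        }
        ok <- ok & (stats::runif(nb) < w / wmax)
      }
      if (any(ok)) {
        ch <- ch[ok]; pos1 <- pos1[ok]; pos2 <- pos2[ok]
        frag1 <- integer(length(ch)); frag2 <- integer(length(ch))
        for (cc in unique(ch)) {
          ci <- chrom_idx[[cc]]
          sel <- which(ch == cc)
          frag1[sel] <- ci$frag_id[findInterval(pos1[sel], ci$start)]
          frag2[sel] <- ci$frag_id[findInterval(pos2[sel], ci$start)]
        }
        acc[[length(acc) + 1L]] <- data.table::data.table(frag1, frag2)
        got <- got + length(ch)
      }
    }
    res <- data.table::rbindlist(acc)
    res[seq_len(n)]
  }

  draw_trans_pairs <- function(n) {
    # intra-complex trans: one cell, two different chromosomes of its species
    sp <- sample(species, n, replace = TRUE, prob = cells * sp_frags$n_frag)
    frag1 <- integer(n); frag2 <- integer(n)
    for (k in seq_along(species)) {
      sp_k <- species[k]
      rows <- which(sp == sp_k)
      if (!length(rows)) next
      ct <- chrom_tab[chrom_tab$species == sp_k]
      if (nrow(ct) < 2L) { # single-chromosome genome: fall back to cis
        cp <- draw_cis_pairs(length(rows))
        frag1[rows] <- cp$frag1; frag2[rows] <- cp$frag2
        next
      }
      ch1 <- sample(ct$chrom, length(rows), replace = TRUE, prob = ct$n_frag)
      ch2 <- sample(ct$chrom, length(rows), replace = TRUE, prob = ct$n_frag)
      while (any(bad <- ch1 == ch2)) {
        ch2[bad] <- sample(ct$chrom, sum(bad), replace = TRUE, prob = ct$n_frag)
      }
      pick <- function(ch) {
        fr <- integer(length(ch))
        for (cc in unique(ch)) {
          ci <- chrom_idx[[cc]]
          sel <- which(ch == cc)
          fr[sel] <- ci$frag_id[ceiling(stats::runif(length(sel)) * nrow(ci))]
        }
        fr
      }
      frag1[rows] <- pick(ch1); frag2[rows] <- pick(ch2)
    }
    data.table::data.table(frag1, frag2)
  }

  fend_to_read <- function(frag) {
    # choose ligated side, offset ~ Exp(150) capped, derive read pos/strand
    n <- length(frag)
    side_r <- stats::runif(n) < 0.5
    st <- pooled$start[frag]; en <- pooled$end[frag]
    len <- pooled$length[frag]
    off <- pmin(floor(stats::rexp(n, 1 / 150)), pmax(len - 1, 0))
    pos <- ifelse(side_r, en - off, st + off)
    list(pos = pos, strand = ifelse(side_r, "+", "-"),
         side = ifelse(side_r, "R", "L"))
  }

  gen_batch <- function(nb) {
    n_spur <- stats::rbinom(1L, nb, f_random)
    n_intra <- nb - n_spur
    n_trans <- stats::rbinom(1L, n_intra, tw)
    n_cis <- n_intra - n_trans
    parts <- list()
    if (n_spur > 0)
      parts$spur <- data.table::data.table(
        frag1 = draw_fends_uniform(n_spur), frag2 = draw_fends_uniform(n_spur),
        truth = "spurious")
    if (n_trans > 0)
      parts$trans <- cbind(draw_trans_pairs(n_trans), truth = "intra_complex")
    if (n_cis > 0)
      parts$cis <- cbind(draw_cis_pairs(n_cis), truth = "intra_complex")
    b <- data.table::rbindlist(parts)
    b[sample.int(nrow(b))]
  }

  bias_accept <- function(b) {
    inj <- model$bias_injection
    e1 <- fend_to_read(b$frag1); e2 <- fend_to_read(b$frag2)
    b[, `:=`(pos1 = e1$pos, strand1 = e1$strand, side1 = e1$side,
             pos2 = e2$pos, strand2 = e2$strand, side2 = e2$side)]
    if (is.null(inj)) return(b)
    fe <- feats$fends
    key1 <- paste(b$frag1, b$side1); key2 <- paste(b$frag2, b$side2)
    fkey <- paste(fe$frag_id, fe$side)
    i1 <- match(key1, fkey); i2 <- match(key2, fkey)
    w <- rep(1, nrow(b))
    if (!is.null(inj$length))
      w <- w * inj$length[cbind(fe$len_bin[i1], fe$len_bin[i2])]
    if (!is.null(inj$gc))
      w <- w * inj$gc[cbind(fe$gc_bin[i1], fe$gc_bin[i2])]
    wmax <- max(vapply(inj, max, numeric(1)))^length(inj)
    b[stats::runif(nrow(b)) < w / wmax]
  }

  out <- list(); got <- 0L
  while (got < n_ditags) {
    need <- n_ditags - got
    nb <- if (is.null(model$bias_injection)) need else ceiling(need * 1.6) + 50L
    b <- bias_accept(gen_batch(nb))
    if (nrow(b) > need) b <- b[seq_len(need)]
    out[[length(out) + 1L]] <- b
    got <- got + nrow(b)
  }
  tags <- data.table::rbindlist(out)
  tags[, `:=`(chrom1 = pooled$chrom[frag1], chrom2 = pooled$chrom[frag2],
              species1 = pooled$species[frag1], species2 = pooled$species[frag2])]
  tags[, readID := sprintf("dt%07d", seq_len(.N))]
  tags[, c("side1", "side2") := NULL]
  data.table::setcolorder(tags, c("readID", "chrom1", "pos1", "strand1",
                                  "chrom2", "pos2", "strand2", "frag1",
                                  "frag2", "species1", "species2", "truth"))
  data.table::setattr(tags, "chromosome_lengths",
                      attr(pooled, "chromosome_lengths"))
  data.table::setattr(tags, "class",
                      c("ditag_table", "data.table", "data.frame"))
  tags[]
}

#' Generate a synthetic activity track over compartment-truth bins
#'
#' Emulates an active-chromatin signal (e.g. H3K4me3 coverage per bin) used
#' to orient compartment eigenvectors: bins labeled A draw from a higher-mean
#' distribution than B bins (Gaussian, truncated at zero).
#'
#' @param truth A bin table with columns chrom, start, end, label ("A"/"B"),
#'   e.g. from [compartment_truth()]; labels must cover all bins.
#' @param seed Integer seed.
#' @param a_mean,b_mean Mean signal in A and B bins.
#' @param sd Common standard deviation.
#' @return The bin table with an added `signal` column (class `bin_track`).
#' @export
generate_activity_track <- function(truth, seed = 1L, a_mean = 2,
                                    b_mean = 0.5, sd = 0.3) {
  stopifnot(all(c("chrom", "start", "end", "label") %in% names(truth)),
            !anyNA(truth$label))
  set.seed(derive_seed(seed, 3))
  trk <- data.table::as.data.table(truth)
  mu <- ifelse(trk$label == "A", a_mean, b_mean)
  trk[, signal := pmax(0, stats::rnorm(.N, mu, sd))]
  data.table::setattr(trk, "class", c("bin_track", "data.table", "data.frame"))
  trk[]
}
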