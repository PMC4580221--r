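#' Expected hybrid di-tag fraction under random ligation
#'
#' In a two-species cell-mixing experiment, assuming complete restriction
#' digestion and fully random ligation of the pooled fragment ends, the
#' expected proportion of cross-species (hybrid) di-tags is
#' \deqn{p_{hybrid} = \frac{2\, n_1 n_2}{(n_1 + n_2)^2}}
#' where \eqn{n_s = \mathrm{cells}_s \times 2 \times \mathrm{fragments}_s}
#' is the number of fragment ends species \eqn{s} contributes to the pool.
#' The value is symmetric in the two species and at most 0.5 (equal pools).
#'
#' @param cells Length-2 numeric vector of cell counts per species.
#' @param fragments_per_genome Length-2 numeric vector of restriction
#'   fragment counts per genome (e.g. HindIII: mouse 823,379; human 837,163).
#' @return The expected hybrid proportion in \[0, 0.5\].
#' @examples
#' expected_hybrid_fraction(c(5, 1), c(823379, 837163)) # ~0.281
#' @export
expected_hybrid_fraction <- function(cells, fragments_per_genome) {
  stopifnot(length(cells) == 2L, length(fragments_per_genome) == 2L,
            all(cells >= 0), all(fragments_per_genome > 0))
  n <- as.numeric(cells) * 2 * as.numeric(fragments_per_genome)
  if (sum(n) <= 0) stop("total fragment-end count is zero")
  2 * n[1] * n[2] / sum(n)^2
}

#' Library locality ratios: trans fraction and far-cis fraction
#'
#' Two complementary indicators of random-ligation noise: the fraction of
#' trans-chromosomal di-tags among all unique di-tags, and the fraction of
#' far-cis di-tags (end separation beyond `far_threshold`) among cis
#' di-tags. Both rise together as spurious ligation increases.
#'
#' @param table A classified `ditag_table` (with a `locality` column; see
#'   [classify_ditags()]). Records without a locality label are ignored.
#' @param far_threshold Far-cis distance threshold in bp. Default 20 Mb;
#'   10 Mb is the common alternative convention and is used by
#'   [contamination_sweep()].
#' @return List with `trans_over_all` and `far_cis_over_cis` (the latter
#'   `NA` when there are no cis di-tags).
#' @export
locality_ratios <- function(table, far_threshold = 2e7) {
  loc <- table$locality
  keep <- !is.na(loc)
  n_all <- sum(keep)
  if (n_all == 0) stop("no classified unique di-tags")
  n_trans <- sum(loc[keep] == "trans")
  cis <- keep & loc == "cis"
  n_cis <- sum(cis)
  far <- if (n_cis > 0)
    sum(abs(table$pos1[cis] - table$pos2[cis]) > far_threshold) / n_cis
  else NA_real_
  list(trans_over_all = n_trans / n_all, far_cis_over_cis = far)
}

#' Cis contact distance-decay (powerlaw) curve
#'
#' Bins unique cis di-tags by end separation into bins of equal width in
#' log10 genomic distance (50 bins over 10 kb – 100 Mb by default) and
#' reports, per bin, the di-tag count and the frequency density
#' (count divided by the linear bp width of the bin), so that on log-log
#' axes the slope of the density estimates the distance-decay exponent.
#' Distances are measured between the 5' read positions of the two ends.
#'
#' @param table A classified `ditag_table`.
#' @param n_bins Number of log10 bins (default 50).
#' @param range Length-2 distance range in bp (default `c(1e4, 1e8)`).
#' @return List of class `powerlaw_curve` with `bins` (pooled curve:
#'   log10_lo/log10_hi/mid bp, count, density), `per_chrom` (same per
#'   chromosome), and `summary` (mean and SD of density across chromosomes
#'   per bin).
#' @export
powerlaw_curve <- function(table, n_bins = 50L, range = c(1e4, 1e8)) {
  cis <- table[!is.na(table$locality) & table$locality == "cis"]
  edges <- 10^seq(log10(range[1]), log10(range[2]), length.out = n_bins + 1)
  mids <- sqrt(edges[-1] * edges[-(n_bins + 1)])
  widths <- diff(edges)
  empty <- data.table::data.table(
    bin = seq_len(n_bins), lo = edges[-(n_bins + 1)], hi = edges[-1],
    mid = mids, count = 0L, density = 0)
  if (nrow(cis) == 0)
    return(structure(list(bins = empty[0], per_chrom = empty[0],
                          summary = empty[0]), class = "powerlaw_curve"))
  d <- abs(cis$pos1 - cis$pos2)
  inr <- d >= range[1] & d <= range[2]
  bin <- findInterval(d[inr], edges, rightmost.closed = TRUE)
  pooled <- data.table::copy(empty)
  tb <- tabulate(bin, nbins = n_bins)
  pooled[, `:=`(count = tb, density = tb / widths)]
  per <- cis[inr][, .(chrom = chrom1, bin)]
  per <- per[, .(count = .N), by = .(chrom, bin)]
  grid <- data.table::CJ(chrom = unique(cis$chrom1), bin = seq_len(n_bins))
  per <- per[grid, on = c("chrom", "bin")]
  per[is.na(count), count := 0L]
  per[, `:=`(lo = edges[bin], hi = edges[bin + 1L], mid = mids[bin],
             density = count / widths[bin])]
  summ <- per[, .(mean_density = mean(density), sd_density = stats::sd(density),
                  total_count = sum(count)), by = bin]
  summ[, mid := mids[bin]]
  structure(list(bins = pooled[], per_chrom = per[], summary = summ[]),
            class = "powerlaw_curve")
}

#' Sweep the random-ligation fraction and collect locality ratios
#'
#' Runs [simulate_ditags()] and [classify_ditags()] over a grid of
#' `random_ligation_fraction` values on an otherwise identical contact
#' model, and records the trans ratio and far-cis ratio per level. The
#' Pearson correlation of the two ratios across levels mirrors the
#' trans-vs-far-cis coupling expected when datasets differ only in their
#' spurious-ligation load.
#'
#' @param maps,mix Fragment maps and mixture passed to [simulate_ditags()].
#' @param model Base [contact_model()]; its `random_ligation_fraction` is
#'   overridden per level.
#' @param f_grid Numeric vector of random-ligation fractions.
#' @param n_ditags Di-tags per level.
#' @param far_threshold Far-cis threshold in bp (default 10 Mb).
#' @param seed Master seed; each level uses a sub-seed derived from it.
#' @return data.table with f_random, percent_trans, far_cis_ratio, plus the
#'   Pearson correlation as attribute `pearson_r`.
#' @export
contamination_sweep <- function(maps, mix, model, f_grid, n_ditags,
                                far_threshold = 1e7, seed = 1L) {
  rows <- lapply(seq_along(f_grid), function(i) {
    m <- model
    m$random_ligation_fraction <- f_grid[i]
    tags <- simulate_ditags(maps, mix, m, n_ditags, seed = derive_seed(seed, 10 + i))
    cl <- classify_ditags(tags, maps)
    lr <- locality_ratios(cl$table, far_threshold = far_threshold)
    data.table::data.table(f_random = f_grid[i],
                           percent_trans = 100 * lr$trans_over_all,
                           far_cis_ratio = lr$far_cis_over_cis)
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "pearson_r",
                      stats::cor(out$percent_trans, out$far_cis_ratio))
  out[]
}
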