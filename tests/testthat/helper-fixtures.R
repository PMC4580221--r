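# shared fixtures: tiny genomes, hand-built tables and constructed matrices

tiny_spec <- function(n_chrom = 2, len = 1e7, mean_len = 2000, label = "mm") {
  genome_spec(label, stats::setNames(rep(len, n_chrom),
                                     paste0("chr", seq_len(n_chrom))),
              mean_fragment_length = mean_len)
}

# fragment map with fixed 100-bp fragments on one chromosome, for hand cases
hand_map <- function(n_frag = 10, frag_len = 100, species = "mm",
                     chrom = "chr1") {
  map <- data.table::data.table(
    species = species, chrom = chrom, frag_id = seq_len(n_frag),
    start = (seq_len(n_frag) - 1) * frag_len,
    end = seq_len(n_frag) * frag_len,
    length = frag_len, gc_left = 0.5, gc_right = 0.5, mappable = TRUE)
  data.table::setattr(map, "species_label", species)
  data.table::setattr(map, "chromosome_lengths",
                      stats::setNames(n_frag * frag_len, chrom))
  data.table::setattr(map, "class",
                      c("fragment_map", "data.table", "data.frame"))
  map[]
}

hand_ditag <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                       frag1, frag2) {
  tab <- data.table::data.table(
    readID = sprintf("r%03d", seq_along(chrom1)),
    chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
    chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
    frag1 = as.integer(frag1), frag2 = as.integer(frag2))
  data.table::setattr(tab, "class", c("ditag_table", "data.table", "data.frame"))
  tab[]
}

# hic_matrix built directly from a counts matrix (one chromosome unless
# a bins table is given)
hand_matrix <- function(counts, binsize = 1e6, chrom = "chr1", bins = NULL) {
  n <- nrow(counts)
  if (is.null(bins))
    bins <- data.table::data.table(chrom = chrom, start = (seq_len(n) - 1) * binsize,
                                   end = seq_len(n) * binsize,
                                   bin_id = seq_len(n))
  structure(list(bins = bins, counts = counts, binsize = binsize,
                 mask = NULL, bias = NULL, corrected = NULL, oe = NULL),
            class = "hic_matrix")
}

# block-diagonal TAD matrix at 5-kb bins: n_tads equal domains, noise-free
tad_block_matrix <- function(n_tads = 3, tad_bins = 200, step = 5000,
                             inside = 12, background = 1, chrom = "mm.chr1") {
  n <- n_tads * tad_bins
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  M <- background * 100 / (d + 1)    # smooth decay background
  dom <- (seq_len(n) - 1) %/% tad_bins
  same <- outer(dom, dom, "==")
  M[same] <- M[same] * inside
  hand_matrix(M, binsize = step, chrom = chrom)
}

# ditag table + classified pipeline from a quick simulation
quick_sim <- function(n = 5e4, f_random = 0.02, seed = 1, n_chrom = 2,
                      len = 1e7, model = NULL) {
  gs <- tiny_spec(n_chrom = n_chrom, len = len, mean_len = 3000)
  mp <- generate_fragment_map(gs, seed = seed)
  mx <- mixture_spec(c(mm = 1), list(gs))
  if (is.null(model)) model <- contact_model(random_ligation_fraction = f_random)
  tags <- simulate_ditags(mp, mx, model, n, seed = seed + 1)
  list(spec = gs, map = mp, mix = mx, tags = tags,
       classified = classify_ditags(tags, mp))
}

# independent two-sided Fisher oracle: full hypergeometric enumeration
fisher_enum_p <- function(tt) {
  m <- sum(tt[1, ]); n2 <- sum(tt[2, ]); k <- sum(tt[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tt[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tiny two-genome tracks plus hybrid tables realizing a given 2x2 count
hybrid_fixture <- function(counts) {
  mktrack <- function(chrom) {
    tr <- data.table::data.table(chrom = chrom, start = c(0, 1e6),
                                 end = c(1e6, 2e6), value = c(1, -1),
                                 label = c("A", "B"))
    data.table::setattr(tr, "class", c("eigen_track", "data.table", "data.frame"))
    tr[]
  }
  tx <- mktrack("mm.chr1"); ty <- mktrack("hs.chr1")
  pos_of <- function(lab) ifelse(lab == "A", 5e5, 1.5e6)
  labs <- expand.grid(x = c("A", "B"), y = c("A", "B"))
  n <- c(counts[1, 1], counts[2, 1], counts[1, 2], counts[2, 2])
  lx <- rep(as.character(labs$x), n); ly <- rep(as.character(labs$y), n)
  tab <- data.table::data.table(
    readID = sprintf("h%04d", seq_along(lx)),
    chrom1 = "mm.chr1", pos1 = pos_of(lx), strand1 = "+",
    chrom2 = "hs.chr1", pos2 = pos_of(ly), strand2 = "-",
    frag1 = 1L, frag2 = 1L, locality = "hybrid")
  list(tab = tab, tx = tx, ty = ty)
}
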