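test_that("directionality index matches brute-force window sums", {
  set.seed(5)
  n <- 60
  M <- matrix(rpois(n * n, 8), n, n); M <- M + t(M)
  m <- hand_matrix(M, binsize = 5000)
  p <- directionality_index(m, max_dist = 5e4, window = 25000)
  # brute force: A/B sums and the signed chi-square formula
  cov <- rowSums(M); mu <- mean(cov[cov > 0])
  inc <- cov > 0 & cov >= 0.15 * mu &
    (cov - mu) <= 4 * stats::sd(cov[cov > 0])
  Mm <- M; Mm[!inc, ] <- 0; Mm[, !inc] <- 0
  for (c0 in c(5, 17, 40)) {
    W <- (c0 - 2):(c0 + 2)
    up <- max(c0 - 2 - 10, 1):(c0 - 3)
    dn <- (c0 + 3):min(c0 + 2 + 10, n)
    A <- sum(Mm[W, up]); B <- sum(Mm[W, dn]); E <- (A + B) / 2
    want <- if (E <= 0 || A == B) 0 else
      sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
    got <- p[pos == (c0 - 1) * 5000 + 2500]$di
    if (inc[c0]) expect_equal(got, want) else expect_true(is.na(got))
  }
  # hand values of the formula itself: A=0,B=10 -> +10; A=10,B=0 -> -10
  di_of <- function(A, B) {
    E <- (A + B) / 2
    if (E <= 0 || A == B) 0 else sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  expect_equal(di_of(0, 10), 10)
  expect_equal(di_of(10, 0), -10)
  expect_equal(di_of(7, 7), 0)
})

test_that("reversing the coordinate axis negates the DI profile", {
  set.seed(6)
  n <- 80
  M <- matrix(rpois(n * n, 10), n, n); M <- M + t(M)
  m <- hand_matrix(M, binsize = 5000)
  mr <- hand_matrix(M[n:1, n:1], binsize = 5000)
  p <- directionality_index(m, max_dist = 1e5)
  pr <- directionality_index(mr, max_dist = 1e5)
  expect_equal(pr$di, -rev(p$di))
})

test_that("smoothing is a truncated NA-aware running average", {
  step <- 5000
  prof <- data.table::data.table(chrom = "c", pos = (0:40) * step + 2500,
                                 di = 0, included = TRUE)
  data.table::setattr(prof, "step", step)
  # constant profile unchanged
  const <- data.table::copy(prof)[, di := 3]
  data.table::setattr(const, "step", step)
  expect_equal(smooth_di(const)$di_smooth, rep(3, 41))
  # a single spike spreads over 11 positions (+/- 25 kb at 5-kb step)
  spike <- data.table::copy(prof)[21, di := 11]
  data.table::setattr(spike, "step", step)
  sm <- smooth_di(spike)$di_smooth
  expect_equal(sum(sm > 0), 11)
  expect_equal(sm[21], 1)
  # edges: truncated window mean
  edge <- data.table::copy(prof)[, di := 1]
  edge[1, di := 12]
  data.table::setattr(edge, "step", step)
  sme <- smooth_di(edge)$di_smooth
  expect_equal(sme[1], mean(c(12, rep(1, 5))))   # 6 positions at the edge
})

test_that("boundaries are recovered on a noise-free block-diagonal matrix", {
  m <- tad_block_matrix(n_tads = 3, tad_bins = 200)   # 3 x 1 Mb domains
  p <- smooth_di(directionality_index(m))
  bs <- call_boundaries(p)
  truth <- c(1e6, 2e6)
  expect_equal(nrow(bs), 2)
  expect_true(all(vapply(truth, function(x) min(abs(bs$pos - x)) <= 25000,
                         logical(1))))
  # flat matrix: no boundaries
  flat <- hand_matrix(matrix(1, 300, 300), binsize = 5000)
  expect_equal(nrow(call_boundaries(smooth_di(directionality_index(flat)))), 0)
})

test_that("lowering the extremum threshold never removes called boundaries", {
  gs <- genome_spec("mm", c(chr1 = 9e6), mean_fragment_length = 3000)
  mp <- generate_fragment_map(gs, seed = 1)
  mx <- mixture_spec(c(mm = 1), list(gs))
  cm <- contact_model(tad_boundaries = list(chr1 = seq(1e6, 8e6, by = 1e6)),
                      tad_enrichment = 4, trans_background_weight = 0,
                      random_ligation_fraction = 0.02)
  cl <- classify_ditags(simulate_ditags(mp, mx, cm, 2e5, seed = 5), mp)
  m <- ice_correct(mask_bins(bin_contacts(cl$table, binsize = 5000),
                             low_fraction = 0.15), tol = 1e-4)
  p <- smooth_di(directionality_index(m))
  sets <- lapply(c(1.0, 0.75, 0.5), function(z) call_boundaries(p, z))
  for (k in 1:2) {
    higher <- sets[[k]]; lower <- sets[[k + 1]]
    expect_true(all(paste(higher$chrom, higher$pos) %in%
                      paste(lower$chrom, lower$pos)))
  }
})

test_that("consensus boundaries use exact 25-kb lattice matching", {
  mk <- function(pos) {
    b <- data.table::data.table(chrom = "chr1", pos = pos)
    data.table::setattr(b, "class", c("boundary_set", "data.table", "data.frame"))
    b[]
  }
  a <- mk(c(100012, 5e6)); b <- mk(c(99991, 7e6))
  cons <- consensus_boundaries(a, b)
  expect_equal(cons$pos, 100000)          # both round to the same lattice point
  expect_equal(nrow(consensus_boundaries(mk(1e6), mk(1e6))), 1)
  expect_equal(nrow(consensus_boundaries(mk(1e6), mk(3e6))), 0)
  # one lattice step apart: only kept with slop
  expect_equal(nrow(consensus_boundaries(mk(1e6), mk(1e6 + 25000))), 0)
  expect_equal(nrow(consensus_boundaries(mk(1e6), mk(1e6 + 25000), slop = 1)), 1)
})

test_that("boundary overlap fraction matches a hand count", {
  mk <- function(pos, chrom = "chr1") {
    b <- data.table::data.table(chrom = chrom, pos = pos)
    data.table::setattr(b, "class", c("boundary_set", "data.table", "data.frame"))
    b[]
  }
  a <- mk(c(1e6, 2e6, 3e6, 4e6, 5e6))
  b <- mk(c(1.05e6, 2.08e6, 3.02e6, 9e6))
  expect_equal(boundary_overlap(a, b, window = 1e5), 0.6)   # 3 of 5 within 100 kb
  expect_equal(boundary_overlap(mk(c(1e6, 2e6)), mk(c(1e6, 2e6, 3e6))), 1)
  expect_equal(boundary_overlap(mk(1e6), mk(2e6)), 0)
  expect_warning(r <- boundary_overlap(mk(numeric(0)), a), "empty")
  expect_true(is.na(r))
})

test_that("aggregate DI profiles cross zero at planted boundaries, controls stay flat", {
  m <- tad_block_matrix(n_tads = 4, tad_bins = 150)   # 4 x 750 kb domains
  p <- smooth_di(directionality_index(m))
  bs <- call_boundaries(p)
  expect_gte(nrow(bs), 2)
  ag <- aggregate_boundary_profile(bs, p, n_random = 400, flank = 2e5,
                                   seed = 2)
  off <- ag$offsets
  expect_lt(mean(ag$mean_zdi[off < -5e4], na.rm = TRUE), 0)
  expect_gt(mean(ag$mean_zdi[off > 5e4], na.rm = TRUE), 0)
  # random control: flat, near zero
  expect_lt(max(abs(ag$control_zdi), na.rm = TRUE), 0.5)
  # control is stable in n_random
  ag2 <- aggregate_boundary_profile(bs, p, n_random = 800, flank = 2e5,
                                    seed = 3)
  expect_lt(max(abs(ag$control_zdi - ag2$control_zdi), na.rm = TRUE), 0.4)
})
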