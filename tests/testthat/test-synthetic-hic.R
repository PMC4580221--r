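test_that("fragment maps tile chromosomes exactly and are deterministic", {
  gs <- genome_spec("mm", c(chr1 = 10000), mean_fragment_length = 2000)
  mp <- generate_fragment_map(gs, seed = 7)
  expect_equal(mp$start[1], 0)
  expect_equal(max(mp$end), 10000)
  expect_true(all(mp$start[-1] == mp$end[-nrow(mp)]))  # no gaps, no overlaps
  expect_true(all(mp$length >= 100 | mp$end == 10000)) # only last may be short
  expect_true(all(mp$gc_left >= 0 & mp$gc_left <= 1))

  mp2 <- generate_fragment_map(gs, seed = 7)
  expect_identical(mp, mp2)
  mp3 <- generate_fragment_map(gs, seed = 8)
  expect_false(identical(mp$end, mp3$end))
})

test_that("empirical mean fragment length matches the spec mean", {
  gs <- genome_spec("mm", c(chr1 = 1e7), mean_fragment_length = 2000)
  mp <- generate_fragment_map(gs, seed = 1)
  expect_lt(abs(mean(mp$length) - 2000) / 2000, 0.05)
})

test_that("invalid genome specs are rejected", {
  expect_error(genome_spec("mm", c(chr1 = -5)), "positive")
  expect_error(genome_spec("mm", c(chr1 = 1e6), mean_fragment_length = 50),
               ">= 100")
  expect_error(mixture_spec(c(mm = 0), list(tiny_spec())), "0 cells")
})

test_that("ground-truth labels are conserved and respect f_random bounds", {
  sim0 <- quick_sim(n = 5000, f_random = 0, seed = 3)
  expect_equal(nrow(sim0$tags), 5000)
  expect_true(all(sim0$tags$truth == "intra_complex"))

  sim <- quick_sim(n = 5000, f_random = 0.3, seed = 3)
  expect_equal(sum(sim$tags$truth == "intra_complex") +
                 sum(sim$tags$truth == "spurious"), 5000)
  # determinism under a fixed master seed
  sim2 <- quick_sim(n = 5000, f_random = 0.3, seed = 3)
  expect_identical(sim$tags, sim2$tags)
})

test_that("pure random ligation on 20 equal chromosomes gives cis ~ 1/20", {
  gs <- tiny_spec(n_chrom = 20, len = 5e6)
  mp <- generate_fragment_map(gs, seed = 5)
  mx <- mixture_spec(c(mm = 1), list(gs))
  tags <- simulate_ditags(mp, mx, contact_model(random_ligation_fraction = 1),
                          4e4, seed = 6)
  cis_frac <- mean(tags$chrom1 == tags$chrom2)
  # closed form: sum (L_i/L)^2 = 1/20; allow 4 binomial SE
  se <- sqrt(0.05 * 0.95 / 4e4)
  expect_lt(abs(cis_frac - 1 / 20), 4 * se)
})

test_that("hybrid di-tags occur only among spurious records", {
  smm <- tiny_spec(2, 5e6, label = "mm")
  shs <- tiny_spec(2, 5e6, label = "hs")
  maps <- list(mm = generate_fragment_map(smm, 1),
               hs = generate_fragment_map(shs, 2))
  mx <- mixture_spec(c(mm = 1, hs = 1), list(smm, shs))
  tags <- simulate_ditags(maps, mx, contact_model(random_ligation_fraction = 0.5),
                          2e4, seed = 9)
  hybrid <- tags$species1 != tags$species2
  expect_gt(sum(hybrid), 0)
  expect_true(all(tags$truth[hybrid] == "spurious"))
})

test_that("downstream %trans is monotone in the random-ligation fraction", {
  gs <- tiny_spec(n_chrom = 4, len = 1e7)
  mp <- generate_fragment_map(gs, seed = 2)
  mx <- mixture_spec(c(mm = 1), list(gs))
  pt <- vapply(c(0, 0.3, 0.6, 1), function(f) {
    tags <- simulate_ditags(mp, mx,
                            contact_model(random_ligation_fraction = f),
                            3e4, seed = 17)
    cl <- classify_ditags(tags, mp)
    cl$summary$percent_trans
  }, numeric(1))
  expect_true(all(diff(pt) > 0))
})

test_that("activity tracks separate planted compartments and are seeded", {
  truth <- compartment_truth(c(chr1 = 2e8), binsize = 1e6, block_bins = 5)
  expect_equal(nrow(truth), 200)
  trk <- generate_activity_track(truth, seed = 4, a_mean = 2, b_mean = 0.5,
                                 sd = 0.3)
  ind <- as.numeric(trk$label == "A")
  expect_gt(stats::cor(trk$signal, ind), 0.5)
  expect_identical(trk, generate_activity_track(truth, seed = 4,
                                                a_mean = 2, b_mean = 0.5,
                                                sd = 0.3))
  # all-A truth: one distribution, mean near a_mean
  allA <- data.table::copy(truth)[, label := "A"]
  trkA <- generate_activity_track(allA, seed = 4)
  expect_lt(abs(mean(trkA$signal) - 2), 0.1)
})

test_that("injected bias shifts feature-stratified counts in the right direction", {
  gs <- tiny_spec(n_chrom = 10, len = 6e6)
  mp <- generate_fragment_map(gs, seed = 21)
  mx <- mixture_spec(c(mm = 1), list(gs))
  fe <- fend_features(mp)
  g <- seq(-0.8, 0.8, length.out = 20)
  Ftrue <- exp(outer(g, g, "+"))
  cm_unb <- contact_model(random_ligation_fraction = 1)
  cm_inj <- contact_model(random_ligation_fraction = 1,
                          bias_injection = list(length = Ftrue))
  n <- 8e4
  count_cells <- function(tags) {
    side <- function(s) ifelse(s == "+", "R", "L")
    fkey <- paste(fe$fends$frag_id, fe$fends$side)
    l1 <- fe$fends$len_bin[match(paste(tags$frag1, side(tags$strand1)), fkey)]
    l2 <- fe$fends$len_bin[match(paste(tags$frag2, side(tags$strand2)), fkey)]
    tt <- table(factor(c(l1, l2), 1:20), factor(c(l2, l1), 1:20))
    matrix(as.numeric(tt), 20, 20)
  }
  t_unb <- count_cells(simulate_ditags(mp, mx, cm_unb, n, seed = 22))
  t_inj <- count_cells(simulate_ditags(mp, mx, cm_inj, n, seed = 23))
  sel <- t_unb >= 50 & t_inj >= 50
  dev <- (t_inj / sum(t_inj)) - (t_unb / sum(t_unb))
  # a cell is enriched iff its acceptance exceeds the occupancy-weighted
  # mean acceptance, not 1 (the normalized shares must sum to 1)
  w_mean <- sum((t_unb / sum(t_unb)) * Ftrue)
  agree <- sign(dev[sel]) == sign(Ftrue[sel] - w_mean)
  expect_gte(mean(agree), 0.9)
})

test_that("fragment maps and di-tag tables round-trip through files", {
  gs <- tiny_spec(1, 2e6)
  mp <- generate_fragment_map(gs, seed = 3)
  bed <- tempfile(fileext = ".bed")
  write_fragment_map(mp, bed)
  mp2 <- read_fragment_map(bed)
  expect_equal(mp2$start, mp$start)
  expect_equal(mp2$gc_left, mp$gc_left, tolerance = 1e-9)
  expect_equal(attr(mp2, "chromosome_lengths"),
               attr(mp, "chromosome_lengths"))
})
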