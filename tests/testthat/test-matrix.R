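test_that("binning conserves di-tag counts in the upper triangle", {
  lens <- c(chr1 = 1e7)
  one <- data.table::data.table(locality = "cis", chrom1 = "chr1",
                                chrom2 = "chr1", pos1 = 2.2e6, pos2 = 2.4e6)
  m <- bin_contacts(one, binsize = 1e6, chrom_lengths = lens)
  expect_equal(sum(m$counts[upper.tri(m$counts, diag = TRUE)]), 1)
  expect_equal(m$counts[3, 3], 1)   # both ends in bin 3 -> diagonal
  expect_true(isSymmetric(m$counts))

  set.seed(1)
  many <- data.table::data.table(
    locality = "cis", chrom1 = "chr1", chrom2 = "chr1",
    pos1 = runif(100, 0, 1e7), pos2 = runif(100, 0, 1e7))
  m2 <- bin_contacts(many, binsize = 1e6, chrom_lengths = lens)
  expect_equal(sum(m2$counts[upper.tri(m2$counts, diag = TRUE)]), 100)
  expect_error(bin_contacts(many, binsize = 0, chrom_lengths = lens), "binsize")
})

test_that("bin masking applies the low-coverage and z-score rules", {
  n <- 100
  M <- matrix(1, n, n); diag(M) <- 5
  m <- mask_bins(hand_matrix(M))
  expect_true(all(m$mask))          # uniform coverage: nothing masked

  M2 <- M
  M2[1, ] <- M2[, 1] <- 0.05 * mean(rowSums(M))  / n  # ~5% of mean coverage
  m2 <- mask_bins(hand_matrix(M2))
  expect_false(m2$mask[1])

  # one outlier bin among 100: masked iff its z-score exceeds 4
  M3 <- matrix(1, n, n)
  M3[7, ] <- M3[, 7] <- 10
  cov <- rowSums(M3)
  z <- abs(cov[7] - mean(cov[cov > 0])) / stats::sd(cov[cov > 0])
  m3 <- mask_bins(hand_matrix(M3))
  expect_equal(!m3$mask[7], z > 4)

  expect_error(mask_bins(hand_matrix(matrix(0, 4, 4))), "zero coverage")
})

test_that("iterative correction reaches a uniform-coverage fixed point", {
  # already-uniform matrix: b ~ 1, T ~ O
  n <- 30
  O <- matrix(1, n, n)
  m <- ice_correct(mask_bins(hand_matrix(O)))
  expect_lt(attr(m, "ice_cv"), 1e-6)
  expect_equal(m$bias, rep(1, n), tolerance = 1e-6)
  expect_equal(m$corrected, O, tolerance = 1e-6)

  # 2x2 symmetric off-diagonal matrix is already balanced
  m2 <- hand_matrix(matrix(c(0, 4, 4, 0), 2, 2))
  m2$mask <- c(TRUE, TRUE)
  r2 <- ice_correct(m2)
  expect_equal(r2$corrected[1, 2], r2$corrected[2, 1])
  expect_equal(r2$bias, c(1, 1), tolerance = 1e-6)
})

test_that("iterative correction recovers a constructed bias vector", {
  set.seed(42)
  n <- 60
  Tb <- matrix(1, n, n)                 # balanced truth
  b_true <- exp(rnorm(n, 0, 0.4))
  O <- (b_true %o% b_true) * Tb
  m <- hand_matrix(O); m$mask <- rep(TRUE, n)
  r <- ice_correct(m)
  cosine <- sum(r$bias * b_true) / sqrt(sum(r$bias^2) * sum(b_true^2))
  expect_gt(cosine, 0.999)
  # factorization: O = mu * b_i b_j T_ij with T uniform coverage
  s <- rowSums(r$corrected)
  expect_lt(stats::sd(s) / mean(s), 1e-6)
  # total conserved under the documented normalization
  expect_equal(sum(r$corrected), sum(O), tolerance = 1e-9)
})

test_that("iterative correction is idempotent and permutation-equivariant", {
  set.seed(7)
  n <- 40
  b_true <- exp(rnorm(n, 0, 0.3))
  O <- (b_true %o% b_true) * (1 + 0.1 * abs(outer(1:n, 1:n, "-")))^-1 * 50
  O <- (O + t(O)) / 2
  m <- hand_matrix(O); m$mask <- rep(TRUE, n)
  r1 <- ice_correct(m)
  # re-balancing the corrected matrix changes the bias by < tol
  m2 <- hand_matrix(r1$corrected); m2$mask <- rep(TRUE, n)
  r2 <- ice_correct(m2)
  expect_lt(max(abs(r2$bias - 1)), 1e-4)

  set.seed(8)
  p <- sample.int(n)
  mp <- hand_matrix(O[p, p]); mp$mask <- rep(TRUE, n)
  rp <- ice_correct(mp)
  expect_equal(rp$bias, r1$bias[p], tolerance = 1e-6)
  expect_equal(rp$corrected, r1$corrected[p, p], tolerance = 1e-4)
})

test_that("distance correction yields mean-1 observed/expected matrices", {
  n <- 80
  d <- abs(outer(1:n, 1:n, "-"))
  prof <- 100 / (d + 1)
  m <- hand_matrix(prof)
  m$mask <- rep(TRUE, n); m$corrected <- prof
  r <- distance_correct(m)
  off <- r$oe[upper.tri(r$oe)]
  expect_equal(off, rep(1, length(off)), tolerance = 1e-9)  # equals its profile
  expect_true(all(is.na(diag(r$oe))))                       # distance 0 dropped

  # per-distance mean exactly 1 on an arbitrary matrix
  set.seed(3)
  V <- prof * exp(matrix(rnorm(n * n, 0, 0.2), n, n))
  V <- (V + t(V)) / 2
  m2 <- hand_matrix(V); m2$mask <- rep(TRUE, n); m2$corrected <- V
  r2 <- distance_correct(m2)
  for (dd in c(1, 5, 20)) {
    sel <- which(d == dd & upper.tri(d))
    expect_equal(mean(r2$oe[sel]), 1, tolerance = 1e-9)
  }
})

test_that("a planted enrichment block survives distance correction", {
  n <- 100
  d <- abs(outer(1:n, 1:n, "-"))
  prof <- 100 / (d + 1)
  block <- 30:34
  prof[block, block] <- prof[block, block] * 2
  prof <- (prof + t(prof)) / 2
  m <- hand_matrix(prof); m$mask <- rep(TRUE, n); m$corrected <- prof
  r <- distance_correct(m)
  bo <- r$oe[block, block][upper.tri(matrix(0, 5, 5))]
  expect_lt(abs(mean(bo) - 2), 0.2)
})

test_that("contact matrices round-trip through COO triplets", {
  sim <- quick_sim(n = 1e4, f_random = 0.1, seed = 19)
  m <- bin_contacts(sim$classified$table, binsize = 1e6)
  f <- tempfile(fileext = ".coo")
  write_matrix_coo(m, f)
  back <- read_matrix_coo(f)
  expect_equal(back$counts, m$counts)
  expect_equal(back$bins$start, m$bins$start)
  expect_equal(back$binsize, m$binsize)
})
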