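test_that("bin grids reproduce the published chromosome bin counts", {
  sizes <- readChromSizes(system.file("extdata", "hg19.chrom.sizes",
                                      package = "ntbaZones"))
  expect_equal(length(makeBins(sizes[["chr17"]], 250000, "chr17")), 325L)
  expect_equal(length(makeBins(sizes[["chr20"]], 250000, "chr20")), 253L)
  one <- makeBins(250000, 250000)
  expect_length(one, 1L)
  bins <- makeBins(1000001, 250000)
  expect_length(bins, 5L)
  expect_equal(GenomicRanges::end(bins)[5L], 1000001L)  # last partial bin
})

test_that("contact matrices Z-score over finite off-diagonal entries", {
  m <- matrix(c(0, 1, 2,
                1, 0, 3,
                2, 3, 0), 3L, 3L)
  cm <- new("ContactMatrix", chrom = "c", resolution = 10L, matrix = m,
            zscored = FALSE)
  z <- zscoreMatrix(cm)
  zm <- contactValues(z)
  expect_equal(sort(zm[upper.tri(zm)]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_true(all(is.na(diag(zm))))
  expect_equal(zm, t(zm))
  # idempotence on standardized input
  z2 <- zscoreMatrix(z)
  expect_equal(contactValues(z2)[upper.tri(zm)], zm[upper.tri(zm)],
               tolerance = 1e-10)
  flat <- new("ContactMatrix", chrom = "c", resolution = 10L,
              matrix = matrix(1, 3, 3), zscored = FALSE)
  expect_error(zscoreMatrix(flat), "variance")
})

test_that("contact matrices round-trip as dense TSV and as triplets", {
  set.seed(18)
  m <- matrix(rnorm(36), 6L)
  m <- (m + t(m)) / 2
  cm <- new("ContactMatrix", chrom = "c", resolution = 100L, matrix = m,
            zscored = FALSE)
  dense <- tempfile()
  writeContactMatrix(cm, dense)
  expect_equal(contactValues(readContactMatrix(dense, "c", 100, nt = 6)),
               m, tolerance = 1e-12)
  trip <- tempfile()
  idx <- which(upper.tri(m, diag = TRUE), arr.ind = TRUE)
  write.table(data.frame(idx[, 1L] - 1L, idx[, 2L] - 1L, m[idx]),
              trip, sep = "\t", row.names = FALSE, col.names = FALSE)
  expect_equal(contactValues(readContactMatrix(trip, "c", 100, nt = 6)),
               m, tolerance = 1e-12)
})

test_that("detected interactions are the strictly positive upper-triangle Zs", {
  m <- matrix(0, 4L, 4L)
  m[1L, 2L] <- 5; m[3L, 4L] <- 2; m[1L, 4L] <- -1; m[2L, 3L] <- 0.5
  m <- m + t(m)
  cm <- new("ContactMatrix", chrom = "c", resolution = 10L, matrix = m,
            zscored = FALSE)
  det <- detectedInteractions(zscoreMatrix(cm))
  # z > 0 strictly, i < j, each unordered pair once
  expect_true(all(det$z > 0))
  expect_true(all(det$i < det$j))
  expect_false(any(duplicated(det[c("i", "j")])))
  raw <- m[upper.tri(m)]
  expect_equal(nrow(det), sum(raw > mean(raw)))
})

test_that("marker bin values use the mean rule for markers, sum for nTBA", {
  tr <- toyTrack(rep(c(1.2, 1, 3, 0.5, 0.7), each = 10), binWidth = 100L)
  # bins of 1000 bp; features sit in bin 1..5 at the flat plateaus
  w1 <- toyWindows(500L)
  one <- markerBinValues(w1, tr, nt = 5, resolution = 1000, "mean")
  expect_equal(one$combined[1L], 1.2)
  expect_equal(one$combined[2L], NA_real_)

  w2 <- toyWindows(c(3500L, 4500L), class = "hot")
  sums <- markerBinValues(w2, tr, nt = 5, resolution = 1000, "sum")
  expect_true(all(is.na(sums$combined[1:3])))
  expect_equal(sums$combined[4:5], c(0.5, 0.7))

  # two HOT windows in one bin: nTBA values 0.5 and 0.7 sum to 1.2,
  # marker values 0.5 and 0.7 average to 0.6
  trc <- toyTrack(rep(c(0.5, 0.7), c(35, 35)), binWidth = 100L)
  w4 <- toyWindows(c(800L, 6200L))          # windows [300,1300) and [5700,6700)
  mv <- markerBinValues(w4, trc, nt = 1, resolution = 7000, "sum")
  expect_equal(mv$combined[1L], 1.2)
  expect_equal(mv$perFeature[[1L]], c(0.5, 0.7))
  mvMean <- markerBinValues(w4, trc, nt = 1, resolution = 7000, "mean")
  expect_equal(mvMean$combined[1L], 0.6)
})

test_that("rank-sum Z matches exhaustive rank computation and wilcox.test", {
  # complete separation at n_A = 2, n_B = 200
  b <- rnorm(200)
  a <- max(b) + c(1, 2)
  zsep <- rankSumZ(a, b)
  expect_equal(zsep, (400 - 200) / sqrt(2 * 200 * 203 / 12),
               tolerance = 1e-12)
  expect_equal(zsep, 2.431, tolerance = 1e-3)
  # complete ties
  expect_equal(rankSumZ(rep(1, 5), rep(1, 50)), 0)
  # antisymmetry
  set.seed(19)
  x <- rnorm(20); y <- rnorm(35)
  expect_equal(rankSumZ(x, y), -rankSumZ(y, x), tolerance = 1e-12)
  # exhaustive oracle incl. ties, and U against stats::wilcox.test
  for (i in 1:5) {
    a2 <- sample(rep(rnorm(8), 2), 10)
    b2 <- sample(rep(rnorm(15), 2), 25)
    expect_equal(rankSumZ(a2, b2), oracleRankSumZ(a2, b2), tolerance = 1e-12)
    W <- suppressWarnings(stats::wilcox.test(a2, b2))$statistic
    r <- rank(c(a2, b2))
    expect_equal(unname(W), sum(r[1:10]) - 55)
  }
  # invariance under strictly monotone transforms
  expect_equal(rankSumZ(exp(x), exp(y)), rankSumZ(x, y), tolerance = 1e-12)
})

test_that("enrichment tables share draws across markers and respect missing", {
  set.seed(20)
  nt <- 12L
  pf <- lapply(seq_len(nt), function(b) rnorm(3, mean = ifelse(b <= 4, 3, 0)))
  mv1 <- list(combined = vapply(pf, mean, 0), perFeature = pf,
              combine = "mean")
  mv2 <- mv1   # identical marker must give identical Z columns
  empty <- rep(list(numeric(0)), nt)
  mvNA <- list(combined = rep(NA_real_, nt), perFeature = empty,
               combine = "mean")
  pairs <- data.frame(i = c(1L, 2L, 5L), j = c(3L, 4L, 9L), z = 1)
  zt <- enrichmentTable(pairs, list(a = mv1, b = mv2, miss = mvNA), nt,
                        nRandom = 20, seed = 5)
  expect_identical(zt[, "a"], zt[, "b"])
  expect_true(all(is.na(zt[, "miss"])))
  # pairs inside the high block score higher than mixed/low pairs
  expect_gt(zt[1L, "a"], zt[3L, "a"])
  # bins mode uses the two combined values (n_A = 2)
  zb <- enrichmentTable(pairs, list(a = mv1), nt, nRandom = 20, seed = 5,
                        mode = "bins")
  expect_lte(max(abs(zb[, "a"]), na.rm = TRUE), 2.44)
})

test_that("bin frequencies count detected and highly enriched interactions", {
  # toy 6-bin chromosome: hand-built detected set
  pairs <- data.frame(i = c(1L, 1L, 2L, 3L, 5L),
                      j = c(2L, 4L, 6L, 4L, 6L), z = 1)
  zt <- cbind(mk1 = c(3.2, 1.0, 4.0, NA, 2.9),
              mk2 = c(-1, 5, 3, 3, 3))
  bf <- binFrequencies(pairs, zt, nt = 6, chrom = "toy", threshold = 3)
  expect_equal(bf@nvi, c(2L, 2L, 1L, 2L, 1L, 2L))        # hand count
  expect_equal(sum(bf@nvi), 2L * nrow(pairs))
  expect_equal(interactionFrequency(bf), bf@nvi / 6)
  expect_equal(bf@nei[, "mk1"], c(1L, 2L, 0L, 0L, 0L, 1L))
  expect_equal(bf@nei[, "mk2"], c(1L, 1L, 1L, 2L, 1L, 2L))
  expect_true(all(bf@nei <= bf@nvi))
  expect_equal(enrichedFrequency(bf), bf@nei / 6)
  # the published denominators: chr17 and chr20 at 250 kb
  expect_equal(binCount(binFrequencies(pairs, zt, nt = 325)), 325L)
})

test_that("planted high-contact blocks gain F_i and F_he over background", {
  spec <- fixtureSpec(seed = 23, binsPerRegime = c(10L, 10L, 10L),
                      featuresPerBin = 5L)
  zd <- genZoneDataset(spec)
  cm <- zscoreMatrix(zd$contact)
  pairs <- detectedInteractions(cm)
  norm <- normalizeTracks(zd$tracks)
  names(norm) <- vapply(norm, markerName, "")
  tss <- preprocessFeatures(zd$tss)
  mv <- list(H3K27ac = markerBinValues(tss, norm[["H3K27ac"]], zd$nt,
                                       spec$resolution, "mean"))
  zt <- enrichmentTable(pairs, mv, zd$nt, nRandom = 50, seed = 23)
  bf <- binFrequencies(pairs, zt, zd$nt)
  hi <- zd$truth == 3
  lo <- zd$truth == 1
  expect_gt(mean(bf@fi[hi]), mean(bf@fi[lo]))
  expect_gt(mean(bf@fhe[hi, 1L]), mean(bf@fhe[lo, 1L]))
})
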