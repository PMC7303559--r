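library(GenomicRanges)

test_that("feature preprocessing filters, centers, windows and deduplicates", {
  gr <- GRanges("chr1",
                IRanges(start = c(1001, 2001, 5001, 5101),
                        end = c(1099, 2200, 5300, 5200)))
  mcols(gr)$featureClass <- "enhancer"
  mcols(gr)$label <- NA_character_
  win <- preprocessFeatures(gr)
  # the 99 bp element is dropped; the last two share midpoint 5150 and
  # collapse to one window
  expect_length(win, 2L)
  # element [2000, 2200) in 0-based terms: center 2100, window [1600, 2600)
  expect_equal(start(win)[1L], 1601L)
  expect_equal(end(win)[1L], 2600L)
  expect_equal(mcols(win)$center[1L], 2100L)
  expect_true(all(width(win) == 1000L))

  # identical midpoints collapse to one window
  dup <- GRanges("chr1", IRanges(c(1001, 901), c(1200, 1300)))
  mcols(dup)$featureClass <- "peak"
  expect_length(preprocessFeatures(dup), 1L)

  # idempotence
  again <- preprocessFeatures(win)
  expect_identical(start(again), start(win))
  expect_identical(mcols(again)$center, mcols(win)$center)
})

test_that("TSS features center on the strand-aware 5' end", {
  gr <- GRanges("chr1", IRanges(c(1001, 1001), c(1500, 1500)),
                strand = c("+", "-"))
  mcols(gr)$featureClass <- "tss"
  win <- preprocessFeatures(gr)
  expect_equal(mcols(win)$center, c(1000L, 1499L))  # 0-based 5' ends
})

test_that("windows reaching below the origin are clipped and flagged", {
  gr <- GRanges("chr1", IRanges(101, 400))
  mcols(gr)$featureClass <- "peak"
  win <- expect_silent(preprocessFeatures(gr))
  expect_true(mcols(win)$clipped)
  expect_equal(start(win), 1L)
})

test_that("profile aggregation reduces stacked windows by sum or mean", {
  # a track whose value is the bin index, for easy hand computation
  tr <- toyTrack(seq_len(200), binWidth = 100L)
  w1 <- toyWindows(10000L)
  single <- aggregateProfile(w1, tr, mode = "mean", seed = 1)
  expect_equal(nrow(single), 1000L)
  expect_equal(single$offset, seq(-500L, 499L))
  # identity: the curve is the signal slice (position 9500 sits in bin 96),
  # zero SD
  expect_equal(single$mean[1L], 96)
  expect_equal(single$mean[1000L], 105)   # position 10499 -> bin 105
  expect_true(all(single$sd == 0))

  wset <- toyWindows(c(10000L, 14000L))
  tot <- aggregateProfile(wset, tr, mode = "total", subsample = 2, seed = 1)
  avg <- aggregateProfile(wset, tr, mode = "mean", subsample = 2, seed = 1)
  expect_equal(tot$mean, 2 * avg$mean, tolerance = 1e-12)

  zero <- aggregateProfile(wset, toyTrack(numeric(200)), mode = "total",
                           seed = 1)
  expect_true(all(zero$mean == 0) && all(zero$sd == 0))
  expect_error(aggregateProfile(wset[0], tr), "empty")
})

test_that("profile curves peak where the signal is planted", {
  set.seed(31)
  centers <- sample(seq(5000L, 95000L, by = 100L), 30L)
  vals <- numeric(1000L)
  for (ct in centers) {
    b <- ct %/% 100L + 1L
    vals[(b - 2L):(b + 2L)] <- vals[(b - 2L):(b + 2L)] + 1
  }
  vals <- vals + rnorm(1000L, sd = 0.01)
  curve <- aggregateProfile(toyWindows(centers), toyTrack(vals),
                            mode = "mean", subsample = 20, seed = 2)
  expect_lte(abs(curve$offset[which.max(curve$mean)]), 25L)
})

test_that("state overlap percentages count >= 1 bp segment intersections", {
  zones <- toyZones(rep(c("I", "II", "III"), each = 2), resolution = 1000L)
  # bins: I = [0,2000), II = [2000,4000), III = [4000,6000)
  seg <- GRanges("chrS", IRanges(start = c(4001, 4501, 3901, 101, 2101),
                                 end = c(4100, 4600, 4100, 300, 2200)))
  mcols(seg)$label <- c("E", "E", "E", "TSS", "PF")
  warnsAll <- testthat::capture_warnings(tab <- stateOverlap(zones, seg))
  expect_equal(dim(tab), c(3L, 7L))
  # all three E segments touch type III; one spans the II/III boundary
  expect_equal(unname(tab["III", "E"]), 100)
  expect_equal(unname(tab["II", "E"]), 100 / 3)
  expect_equal(unname(tab["I", "TSS"]), 100)
  expect_equal(unname(tab["II", "PF"]), 100)
  # rows are percentages
  expect_true(all(tab >= 0 & tab <= 100))
  # empty state classes give zero columns with warnings
  expect_true(any(grepl("WE", warnsAll)))
  expect_true(all(tab[, "WE"] == 0))
  mcols(seg)$label[1L] <- "BOGUS"
  expect_error(suppressWarnings(stateOverlap(zones, seg)), "BOGUS")
})

test_that("core bins intersect labelings and count Venn patterns", {
  za <- toyZones(rep(c("I", "II", "III"), each = 4))
  identical3 <- list(K562 = za, GM = za, MCF7 = za)
  core <- coreBins(identical3)
  expect_equal(core$core$I, 1:4)
  expect_equal(core$core$III, 9:12)
  expect_equal(unname(core$venn$I["K562&GM&MCF7"]), 4L)

  zb <- toyZones(rep(c("II", "III", "I"), each = 4),
                 fi = rep(c(0.4, 0.7, 0.1), each = 4))
  disjoint <- coreBins(list(a = za, b = zb))
  expect_length(disjoint$core$I, 0L)
  expect_length(disjoint$core$III, 0L)

  # planted overlap: construct three labelings sharing exactly 2 bins per type
  base <- rep(c("I", "II", "III"), each = 4)
  shift1 <- base[c(3:12, 1:2)]
  shift2 <- base[c(5:12, 1:4)]
  mk <- function(tt) toyZones(tt, fi = c(I = 0.1, II = 0.4, III = 0.7)[tt])
  planted <- coreBins(list(mk(base), mk(shift1), mk(shift2)))
  manual <- vapply(c("I", "II", "III"), function(ty)
    sum(base == ty & shift1 == ty & shift2 == ty), 1L)
  expect_equal(lengths(planted$core), manual)

  zc <- toyZones(rep(c("I", "II", "III"), each = 2))
  expect_error(coreBins(list(za, zc)), "mismatched")
})
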