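test_that("JASPAR and plain motif files parse with records in file order", {
  path <- writeTempMotifs(c(
    ">MA0001.1 FIRST",
    "A  [ 0  3 79 40 66 48 65 11 ]",
    "C  [94 75  4  3  1  2  5  2 ]",
    "G  [ 1  0  3  4  1  0  5  3 ]",
    "T  [ 2 19 11 50 29 47 22 81 ]",
    ">MA0002.1",
    "A [ 4 19  0 ]",
    "C [16  0 20 ]",
    "G [ 0  1  0 ]",
    "T [ 0  0  0 ]",
    ">MA0003.1",
    "A [ 1 1 ]", "C [ 1 1 ]", "G [ 1 1 ]", "T [ 1 1 ]"))
  mots <- readMotifs(path, "jaspar")
  expect_length(mots, 3L)
  expect_identical(vapply(mots, motifId, ""),
                   c("MA0001.1", "MA0002.1", "MA0003.1"))
  expect_identical(vapply(mots, motifLength, 1L), c(8L, 3L, 2L))
  expect_equal(motifValues(mots[[1L]])[1L, ], c(A = 0, C = 94, G = 1, T = 2))

  plain <- tempfile()
  writeLines(c(">m1", "1 2 3 4", "4 3 2 1", ">m2", "0.25 0.25 0.25 0.25"),
             plain)
  pm <- readMotifs(plain, "plain")
  expect_length(pm, 2L)
  expect_identical(pm[[2L]]@type, "frequencies")
})

test_that("malformed or degenerate motif records are rejected by id", {
  neg <- writeTempMotifs(c(">BAD1", "A [ 1 -2 ]", "C [ 1 1 ]",
                           "G [ 1 1 ]", "T [ 1 1 ]"))
  expect_error(readMotifs(neg), "BAD1")
  empty <- writeTempMotifs(c(">EMPTY", "A [ ]", "C [ ]", "G [ ]", "T [ ]"))
  expect_error(readMotifs(empty), "EMPTY")
  threeRows <- writeTempMotifs(c(">SHORT", "A [1]", "C [1]", "G [1]"))
  expect_error(readMotifs(threeRows), "SHORT")
})

test_that("energy derivation follows the mismatch form with pseudocount", {
  uniform <- new("MotifMatrix", id = "u", type = "frequencies",
                 values = matrix(0.25, 2L, 4L,
                                 dimnames = list(NULL, BASES)))
  expect_equal(energies(toEnergyMatrix(uniform)),
               matrix(0, 2L, 4L, dimnames = list(NULL, BASES)))

  sharp <- new("MotifMatrix", id = "s", type = "frequencies",
               values = matrix(c(0.97, 0.01, 0.01, 0.01), 1L, 4L,
                               dimnames = list(NULL, BASES)))
  e <- energies(toEnergyMatrix(sharp, p0 = 0.01))
  expect_equal(unname(e[1L, "A"]), 0)
  expect_equal(unname(e[1L, "C"]), log(0.98 / 0.02), tolerance = 1e-12)

  counts <- new("MotifMatrix", id = "c", type = "counts",
                values = matrix(c(10, 0, 0, 0), 1L, 4L,
                                dimnames = list(NULL, BASES)))
  ec <- energies(toEnergyMatrix(counts, p0 = 0.01))
  expect_equal(unname(ec[1L, "A"]), 0)
  expect_length(unique(round(ec[1L, c("C", "G", "T")], 12)), 1L)

  expect_error(toEnergyMatrix(sharp, p0 = 0), "positive")
  expect_error(toEnergyMatrix(sharp, p0 = -1), "positive")
})

test_that("energies are invariant to rescaling a count matrix", {
  set.seed(42)
  v <- matrix(sample(0:50, 24, replace = TRUE), 6L, 4L,
              dimnames = list(NULL, BASES))
  v[cbind(1:6, max.col(v))] <- v[cbind(1:6, max.col(v))] + 1L  # break ties
  m1 <- new("MotifMatrix", id = "a", values = v, type = "counts")
  m2 <- new("MotifMatrix", id = "a", values = v * 7.3, type = "counts")
  expect_equal(energies(toEnergyMatrix(m1)), energies(toEnergyMatrix(m2)),
               tolerance = 1e-12)
})

test_that("site energies are additive, consensus-minimal, and average N", {
  set.seed(7)
  for (m in 2:4) {
    E <- randomEnergy(m)
    # additivity against the per-position lookup loop
    for (rep in 1:5) {
      site <- randomSeq(m)
      expect_equal(siteEnergy(E, site), oracleSiteEnergy(E, site),
                   tolerance = 1e-12)
    }
    # consensus minimizes over all 4^m sites and scores exactly 0
    sites <- do.call(expand.grid, rep(list(BASES), m))
    all4 <- apply(sites, 1L, paste, collapse = "")
    vals <- vapply(all4, function(s) siteEnergy(E, s), 0)
    expect_equal(min(vals), 0)
    cons <- paste(BASES[apply(energies(E), 1L, which.min)], collapse = "")
    expect_equal(siteEnergy(E, cons), 0)
    # all-N equals the sum of per-position means, which (by additivity) is
    # the brute-force average over all 4^m resolved sites
    expect_equal(siteEnergy(E, strrep("N", m)), sum(rowMeans(energies(E))),
                 tolerance = 1e-12)
    expect_equal(siteEnergy(E, strrep("N", m)), mean(vals),
                 tolerance = 1e-10)
  }
  E <- energyFromMatrix(matrix(c(0, 2, 3, 1), 1L, 4L))
  expect_equal(siteEnergy(E, "G"), 3)
  expect_error(siteEnergy(E, "GG"), "length")
  expect_error(siteEnergy(E, "X"), "outside")
})
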