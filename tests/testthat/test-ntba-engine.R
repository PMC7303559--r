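test_that("the sliding-window grid satisfies the full-window count", {
  g <- makeGrid(50, 50, 5)
  expect_equal(windowCount(g), 1L)
  expect_identical(windowStarts(g), 0L)
  # enumeration oracle: all starts 0,5,...,950
  g2 <- makeGrid(1000, 50, 5)
  expect_equal(windowCount(g2), 191L)
  expect_identical(windowStarts(g2), as.integer(seq(0, 950, 5)))
  expect_identical(windowCenters(g2), as.integer(seq(25, 975, 5)))
  expect_equal(windowCount(makeGrid(49, 50, 5)), 0L)
})

test_that("binding probabilities follow the Fermi-Dirac and Boltzmann forms", {
  fd10 <- chemicalPotential("fermi_dirac", -10)
  expect_equal(bindingProbability(-10, fd10), 0.5)
  expect_equal(bindingProbability(0, chemicalPotential("boltzmann")), 1)
  expect_equal(bindingProbability(0, fd10), 1 / (1 + exp(10)),
               tolerance = 1e-12)
  # strictly decreasing in energy, increasing in mu
  e <- seq(0, 20, by = 0.5)
  expect_true(all(diff(bindingProbability(e, fd10)) < 0))
  p_mu <- vapply(seq(-20, 0, by = 1), function(mu)
    bindingProbability(5, chemicalPotential("fermi_dirac", mu)), 0)
  expect_true(all(diff(p_mu) > 0))
  # huge energies underflow to 0 without overflow
  expect_equal(bindingProbability(1e6, fd10), 0)
})

test_that("Fermi-Dirac matches the Boltzmann-form limit for energy - mu >= 5", {
  for (mu in c(0, -10, -15)) {
    pot <- chemicalPotential("fermi_dirac", mu)
    e <- mu + seq(5, 30, by = 0.5)
    fd <- bindingProbability(e, pot)
    mb <- exp(-(e - mu))
    expect_lt(max(abs(fd - mb) / mb), 0.01)
  }
})

test_that("window affinity equals the brute-force per-offset sum", {
  set.seed(11)
  pot <- chemicalPotential("boltzmann")
  E <- randomEnergy(8)
  w <- randomSeq(50)
  expect_equal(windowAffinity(w, E, pot),
               oracleWindowAffinity(w, E, pot), tolerance = 1e-12)
  fd <- chemicalPotential("fermi_dirac", -3)
  expect_equal(windowAffinity(w, E, fd, p = 0.4),
               oracleWindowAffinity(w, E, fd, p = 0.4), tolerance = 1e-12)
  expect_equal(windowAffinity(w, E, fd, strands = "forward"),
               oracleWindowAffinity(w, E, fd, both = FALSE),
               tolerance = 1e-12)
  # single-offset boundary: consensus window of length m
  cons <- paste(BASES[apply(energies(E), 1L, which.min)], collapse = "")
  a <- windowAffinity(cons, E, pot)
  expect_equal(a, 1 + exp(-oracleSiteEnergy(E, revcompChar(cons))),
               tolerance = 1e-12)
  # the prior annihilates
  expect_equal(windowAffinity(w, E, pot, p = 0), 0)
  # m > L gives the empty-sum value
  expect_equal(windowAffinity("ACGT", randomEnergy(10), pot), 0)
})

test_that("shuffled background preserves composition and converges", {
  pot <- chemicalPotential("boltzmann")
  E <- randomEnergy(3)
  # homopolymer: every shuffle is the window itself
  hp <- strrep("A", 30)
  expect_equal(shuffledBackground(hp, E, pot, R = 7, seed = 5),
               windowAffinity(hp, E, pot), tolerance = 1e-12)
  # reproducibility at R = 1
  w <- randomSeq(30)
  b1 <- shuffledBackground(w, E, pot, R = 1, seed = 9)
  b2 <- shuffledBackground(w, E, pot, R = 1, seed = 9)
  expect_identical(b1, b2)
  # exhaustive permutation average on L = 6, m = 2
  E2 <- randomEnergy(2)
  w6 <- "ACGTTG"
  chars <- strsplit(w6, "")[[1L]]
  perms <- expand.grid(rep(list(1:6), 6))
  perms <- perms[apply(perms, 1L, function(p) all(sort(p) == 1:6)), ]
  exact <- mean(apply(perms, 1L, function(p)
    oracleWindowAffinity(paste(chars[p], collapse = ""), E2, pot)))
  mc <- shuffledBackground(w6, E2, pot, R = 3000, seed = 3)
  expect_equal(mc, exact, tolerance = 0.02)
})

test_that("differential affinity removes composition bias", {
  pot <- chemicalPotential("boltzmann")
  E <- randomEnergy(4)
  expect_equal(diffBindingAffinity(strrep("C", 20), E, pot, R = 5, seed = 2),
               0)
  # flat energies score every site identically
  flat <- energyFromMatrix(matrix(1, 4L, 4L))
  expect_equal(diffBindingAffinity(randomSeq(40), flat, pot, R = 5, seed = 2),
               0)
  # a planted consensus site raises dbA above the shuffled background
  set.seed(21)
  E8 <- energyFromMatrix(matrix(rep(c(0, 5, 5, 5), each = 1), 8L, 4L,
                                byrow = TRUE) + runif(32, 0, 0.5))
  cons <- paste(BASES[apply(energies(E8), 1L, which.min)], collapse = "")
  hits <- vapply(1:10, function(s) {
    w <- randomSeq(50)
    substr(w, 20, 27) <- cons
    diffBindingAffinity(w, E8, pot, R = 50, seed = s) > 0
  }, TRUE)
  expect_gte(sum(hits), 9L)
})

test_that("the scan equals the naive triple-loop oracle to 1e-10", {
  set.seed(33)
  motifs <- lapply(1:3, function(i) randomEnergy(sample(4:9, 1),
                                                 id = paste0("m", i)))
  seqc <- randomSeq(600)
  pots <- list(chemicalPotential("fermi_dirac", 0),
               chemicalPotential("fermi_dirac", -10),
               chemicalPotential("boltzmann"))
  prof <- ntbaScan(seqc, motifs, pots, L = 50, st = 5, R = 4, seed = 17)
  oracle <- oracleScan(seqc, motifs, pots, L = 50, st = 5, R = 4, seed = 17)
  expect_identical(windowCenters(prof), as.integer(oracle$centers))
  expect_lt(max(abs(profileValues(prof) - oracle$values)), 1e-10)
})

test_that("scan handles N runs, flat motifs, and worker/order invariance", {
  set.seed(4)
  pot <- list(chemicalPotential("fermi_dirac", 0))
  flat <- energyFromMatrix(matrix(2, 5L, 4L))
  seqc <- randomSeq(300)
  expect_equal(max(abs(profileValues(ntbaScan(seqc, list(flat), pot,
                                              R = 2, seed = 1)))), 0)
  # a long N run yields missing values in the covered windows
  nseq <- paste0(randomSeq(100), strrep("N", 80), randomSeq(100))
  prof <- ntbaScan(nseq, list(randomEnergy(5)), pot, R = 2, seed = 1)
  expect_true(anyNA(profileValues(prof)))
  expect_false(all(is.na(profileValues(prof))))
  # worker count and motif order leave the profile bit-identical
  motifs <- lapply(1:4, function(i) randomEnergy(6, id = paste0("m", i)))
  p1 <- ntbaScan(seqc, motifs, pot, R = 3, seed = 8, workers = 1)
  p2 <- ntbaScan(seqc, motifs, pot, R = 3, seed = 8, workers = 2)
  p3 <- ntbaScan(seqc, rev(motifs), pot, R = 3, seed = 8)
  expect_identical(profileValues(p1), profileValues(p2))
  expect_equal(profileValues(p1), profileValues(p3), tolerance = 1e-12)
  # no usable motif (the too-wide motif is first skipped with a warning)
  expect_error(suppressWarnings(
    ntbaScan(randomSeq(30), list(randomEnergy(40)), pot, L = 20)),
    "no usable motif")
})

test_that("profiles vanish as the chemical potential becomes strongly negative", {
  spec <- fixtureSpec(seed = 6, length = 3000, nMotifs = 3)
  motifs <- lapply(genMotifs(spec), toEnergyMatrix)
  gs <- genSequence(spec, genMotifs(spec))
  pots <- lapply(c(0, -10, -20), function(m)
    chemicalPotential("fermi_dirac", m))
  prof <- ntbaScan(gs$sequence, motifs, pots, seed = 6)
  mx <- apply(abs(profileValues(prof)), 2L, max, na.rm = TRUE)
  expect_true(mx[1L] > mx[2L] && mx[2L] > mx[3L])
})

test_that("profile TSV and bedGraph outputs round-trip", {
  set.seed(12)
  prof <- ntbaScan(randomSeq(400), list(randomEnergy(5)),
                   defaultPotentials(), R = 2, seed = 3, seqname = "chrT")
  tsv <- tempfile(fileext = ".tsv")
  writeProfileTSV(prof, tsv)
  back <- readProfileTSV(tsv)
  expect_identical(windowCenters(back), windowCenters(prof))
  expect_equal(profileValues(back), profileValues(prof), tolerance = 1e-10)
  expect_equal(potentials(back), potentials(prof))
  dir <- tempfile()
  paths <- writeProfileBedGraph(prof, dir)
  expect_length(paths, 2L)
  bg <- read.table(paths[1L], sep = "\t")
  expect_equal(bg$V2, windowCenters(prof)[!is.na(profileValues(prof)[, 1L])])
})
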