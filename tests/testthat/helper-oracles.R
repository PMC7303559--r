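# Independent oracles and small constructors used across the suite.
# Everything here recomputes quantities by the most literal route available
# (character-level loops, exhaustive enumeration) and never calls into the
# vectorized scan internals it is checking.

BASES <- c("A", "C", "G", "T")

# EnergyMatrix straight from a numeric m x 4 matrix (rows re-anchored at 0)
energyFromMatrix <- function(e, id = "toy") {
  e <- e - apply(e, 1L, min)
  new("EnergyMatrix", id = id, energies = e, pseudocount = 0.01)
}

randomEnergy <- function(m, id = "rnd") {
  energyFromMatrix(matrix(runif(m * 4L, 0, 4), m, 4L), id = id)
}

randomSeq <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

revcompChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# per-position lookup loop, N as the mean of the four energies
oracleSiteEnergy <- function(E, site) {
  e <- energies(E)
  chars <- strsplit(site, "")[[1L]]
  tot <- 0
  for (j in seq_along(chars)) {
    tot <- tot + if (chars[j] == "N") mean(e[j, ])
                 else e[j, match(chars[j], BASES)]
  }
  tot
}

oracleProb <- function(energy, potential) {
  if (potential$mode == "boltzmann") exp(-energy)
  else 1 / (1 + exp(energy - potential$mu))
}

# brute-force window affinity: loop every offset on both strands
oracleWindowAffinity <- function(window, E, potential, p = 1, both = TRUE) {
  m <- motifLength(E)
  L <- nchar(window)
  if (m > L) return(0)
  rc <- revcompChar(window)
  tot <- 0
  for (l in seq_len(L - m + 1L)) {
    tot <- tot + oracleProb(oracleSiteEnergy(E, substr(window, l, l + m - 1L)),
                            potential)
    if (both) {
      # offset l on the reverse strand corresponds to offset L-m-l+2 of the
      # reverse complement string
      lr <- L - m - l + 2L
      tot <- tot + oracleProb(oracleSiteEnergy(E, substr(rc, lr, lr + m - 1L)),
                              potential)
    }
  }
  p * tot
}

# naive triple loop (windows x motifs x offsets); consumes the same shuffle
# permutations as the scan but recomputes every affinity character by
# character
oracleScan <- function(sequence, motifs, potentials, L = 50L, st = 5L,
                       p = 1, R = 10L, seed = 1L, both = TRUE) {
  N <- nchar(sequence)
  starts0 <- if (N >= L) seq.int(0L, N - L, by = st) else integer(0)
  out <- matrix(NA_real_, length(starts0), length(potentials))
  for (w in seq_along(starts0)) {
    window <- substr(sequence, starts0[w] + 1L, starts0[w] + L)
    chars <- strsplit(window, "")[[1L]]
    if (sum(chars == "N") > L / 2) next
    perms <- shuffleIndices(seed, w, 1L, R, L)
    for (q in seq_along(potentials)) {
      acc <- 0
      for (E in motifs) {
        fg <- oracleWindowAffinity(window, E, potentials[[q]], p, both)
        bgv <- vapply(seq_len(R), function(r)
          oracleWindowAffinity(paste(chars[perms[, r]], collapse = ""),
                               E, potentials[[q]], p, both), 0)
        acc <- acc + (fg - mean(bgv))
      }
      out[w, q] <- acc / length(motifs)
    }
  }
  list(centers = starts0 + L %/% 2L, values = out)
}

# midpoint histogram oracle for interval binning
oracleMidpointHistogram <- function(start0, end0, chromLength, binWidth) {
  nBins <- ceiling(chromLength / binWidth)
  counts <- numeric(nBins)
  for (i in seq_along(start0)) {
    mid <- (start0[i] + min(end0[i], chromLength)) %/% 2L
    b <- mid %/% binWidth + 1L
    if (b >= 1 && b <= nBins) counts[b] <- counts[b] + 1
  }
  counts
}

# exhaustive rank-sum Z: U by direct pair counting, tie term by value counts
oracleRankSumZ <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  U <- 0
  for (x in a) U <- U + sum(x > b) + 0.5 * sum(x == b)
  n <- n1 + n2
  tie <- as.numeric(table(c(a, b)))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (U - n1 * n2 / 2) / sqrt(sigma2)
}

# NormalizedTrack with prescribed per-bin values (tests only)
toyTrack <- function(values, marker = "toy", binWidth = 100L,
                     chrom = "chr") {
  new("NormalizedTrack", marker = marker, cellLine = "test", chrom = chrom,
      binWidth = as.integer(binWidth), values = as.numeric(values))
}

# feature windows centered at given 0-based positions
toyWindows <- function(centers, chrom = "chr", class = "tss") {
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = centers - 500L + 1L, end = centers + 500L))
  S4Vectors::mcols(gr)$center <- as.integer(centers)
  S4Vectors::mcols(gr)$clipped <- FALSE
  S4Vectors::mcols(gr)$featureClass <- class
  S4Vectors::mcols(gr)$label <- NA_character_
  gr
}

# ZoneLabels with consistent mean-F_i ordering
toyZones <- function(types, fi = NULL, chrom = "chrS",
                     resolution = 250000L, cellLine = "test") {
  types <- factor(types, levels = c("I", "II", "III"))
  if (is.null(fi)) fi <- c(I = 0.1, II = 0.4, III = 0.7)[as.character(types)]
  new("ZoneLabels", chrom = chrom, resolution = as.integer(resolution),
      type = types, fi = unname(fi), cellLine = cellLine)
}

writeTempMotifs <- function(text) {
  path <- tempfile(fileext = ".jaspar")
  writeLines(text, path)
  path
}
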