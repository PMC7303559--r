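#' Tile a chromosome into fixed-resolution genomic window bins
#'
#' \code{Nt = ceiling(length/resolution)} bins \code{[k*res, min((k+1)*res,
#' length))}; the last bin may be partial. At the 250 kb default this gives
#' Nt = 325 for a chromosome of 81,195,210 bp and 253 for 63,025,520 bp.
#'
#' @param chromLength chromosome length in bp.
#' @param resolution bin size in bp (default 250000).
#' @param chrom chromosome name.
#' @return a GRanges of bins (1-based closed); its length is Nt.
#' @export
makeBins <- function(chromLength, resolution = 250000L, chrom = "chr") {
  chromLength <- as.numeric(chromLength)
  resolution <- as.numeric(resolution)
  stopifnot(chromLength >= 1, resolution >= 1)
  nt <- as.integer(ceiling(chromLength / resolution))
  starts0 <- (seq_len(nt) - 1) * resolution
  ends0 <- pmin(starts0 + resolution, chromLength)
  GRanges(chrom, IRanges(start = starts0 + 1, end = ends0))
}

#' Read an intra-chromosomal contact matrix
#'
#' Accepts a dense Nt x Nt TSV or 3-column triplets (bin_i, bin_j, value).
#' Triplet indices are 0-based by default; absent triplet cells are 0. The
#' matrix is expected to be normalized upstream (e.g. KR or ICE balanced);
#' balancing itself is out of scope here.
#'
#' @param path file path.
#' @param chrom chromosome name.
#' @param resolution bin size in bp.
#' @param nt bin count; required for triplet input, checked for dense input.
#' @param indexBase 0 or 1, the origin of triplet bin indices.
#' @param format "auto" (triplet iff 3 columns and nt != 3), "dense" or
#'   "triplet".
#' @return a \linkS4class{ContactMatrix}.
#' @export
readContactMatrix <- function(path, chrom = "chr", resolution = 250000L,
                              nt = NULL, indexBase = 0L,
                              format = c("auto", "dense", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("contact matrix not found: ", path)
  df <- data.table::fread(path, header = FALSE, sep = "\t")
  isTriplet <- switch(format,
    triplet = TRUE, dense = FALSE,
    auto = ncol(df) == 3L && (is.null(nt) || nt != 3L))
  if (isTriplet) {
    if (is.null(nt)) stop("nt is required for triplet input")
    m <- matrix(0, nt, nt)
    i <- as.integer(df[[1L]]) - indexBase + 1L
    j <- as.integer(df[[2L]]) - indexBase + 1L
    if (any(i < 1L | i > nt | j < 1L | j > nt))
      stop("triplet bin index outside [", indexBase, ", ",
           nt - 1L + indexBase, "]")
    m[cbind(i, j)] <- df[[3L]]
    m[cbind(j, i)] <- df[[3L]]
  } else {
    m <- as.matrix(df)
    dimnames(m) <- NULL
    if (!is.null(nt) && nrow(m) != nt)
      stop("dense matrix has ", nrow(m), " rows, expected nt = ", nt)
  }
  new("ContactMatrix", chrom = chrom, resolution = as.integer(resolution),
      matrix = m, zscored = FALSE)
}

#' Write a contact matrix as dense TSV
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeContactMatrix <- function(cm, path) {
  data.table::fwrite(as.data.frame(cm@matrix), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Z-score a contact matrix
#'
#' Standardizes over the finite off-diagonal upper-triangle entries (mean
#' subtracted, population SD divided), mirrors the result to keep symmetry,
#' and sets the diagonal to NA. Standardizing an already-standardized matrix
#' leaves it unchanged.
#'
#' @param cm a \linkS4class{ContactMatrix}.
#' @return a Z-scored \linkS4class{ContactMatrix}.
#' @export
zscoreMatrix <- function(cm) {
  stopifnot(is(cm, "ContactMatrix"))
  m <- cm@matrix
  ut <- upper.tri(m)
  vals <- m[ut]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L)
    stop("need at least 2 finite off-diagonal entries")
  mu <- mean(vals)
  sdv <- sqrt(mean((vals - mu)^2))
  if (sdv == 0) stop("zero variance in off-diagonal contacts")
  z <- (m - mu) / sdv
  diag(z) <- NA_real_
  new("ContactMatrix", chrom = cm@chrom, resolution = cm@resolution,
      matrix = z, zscored = TRUE)
}

#' Detected intra-chromosomal interactions
#'
#' The bin pairs whose contact Z-score is strictly positive, i.e. more
#' frequent than the chromosome-wide average.
#'
#' @param cm a Z-scored \linkS4class{ContactMatrix}.
#' @return data.frame with columns i, j (1-based, i < j) and z.
#' @export
detectedInteractions <- function(cm) {
  stopifnot(is(cm, "ContactMatrix"))
  if (!cm@zscored) cm <- zscoreMatrix(cm)
  m <- cm@matrix
  idx <- which(upper.tri(m) & !is.na(m) & m > 0, arr.ind = TRUE)
  ord <- order(idx[, 1L], idx[, 2L])
  data.frame(i = idx[ord, 1L], j = idx[ord, 2L], z = m[idx][ord])
}

#' Per-bin marker values from feature windows
#'
#' For each genomic window bin, markers are evaluated only at the
#' preprocessed 1000 bp windows (+-500 bp of a TSS or HOT center) whose
#' center falls in the bin: each feature contributes the mean signal across
#' its window, and features within a bin are combined by mean for epigenomic
#' markers or by sum for nTBA channels (the affinity of clustered regulatory
#' sequence is additive). Bins with no feature get NA.
#'
#' @param windows preprocessed feature windows
#'   (\code{\link{preprocessFeatures}}).
#' @param signal a \linkS4class{NormalizedTrack} or
#'   \linkS4class{AffinityProfile}.
#' @param nt number of bins.
#' @param resolution bin size in bp.
#' @param combine "mean" (epigenomic markers) or "sum" (nTBA).
#' @param potentialIndex potential column for AffinityProfile signals.
#' @return list with \code{combined} (length-nt numeric, NA where no
#'   feature) and \code{perFeature} (length-nt list of per-feature values).
#' @export
markerBinValues <- function(windows, signal, nt, resolution,
                            combine = c("mean", "sum"),
                            potentialIndex = 1L) {
  combine <- match.arg(combine)
  stopifnot(is(windows, "GRanges"))
  centers <- as.integer(mcols(windows)$center)
  if (is.null(centers)) stop("windows must carry a 'center' column")
  flank <- as.integer(end(windows)[1L]) - centers[1L]
  bin <- centers %/% as.numeric(resolution) + 1L
  perFeature <- rep(list(numeric(0)), nt)
  ok <- bin >= 1L & bin <= nt
  featVal <- vapply(centers, function(ct) {
    v <- signalAtOffsets(ct, flank, signal, potentialIndex)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  for (f in which(ok & !is.na(featVal)))
    perFeature[[bin[f]]] <- c(perFeature[[bin[f]]], featVal[f])
  combined <- vapply(perFeature, function(v) {
    if (length(v) == 0L) NA_real_
    else if (combine == "sum") sum(v) else mean(v)
  }, 0)
  list(combined = combined, perFeature = perFeature, combine = combine)
}

#' Rank-sum (Mann-Whitney) Z statistic
#'
#' Two-sample rank-sum Z from the normal approximation with tie correction:
#' \eqn{Z = (U - n_A n_B/2)/\sigma_U}. Complete ties give Z = 0; swapping the
#' samples flips the sign.
#'
#' @param a,b numeric samples.
#' @return the signed Z value.
#' @export
rankSumZ <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 1L, n2 >= 1L)
  x <- c(a, b)
  n <- n1 + n2
  # midranks and tie-group sizes from a single sort
  o <- order(x)
  xs <- x[o]
  grp <- cumsum(c(TRUE, xs[-1L] != xs[-n]))
  gs <- tabulate(grp)
  startRank <- cumsum(c(1, gs[-length(gs)]))
  mid <- startRank + (gs - 1) / 2
  r <- numeric(n)
  r[o] <- mid[grp]
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(gs^3 - gs) / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (U - n1 * n2 / 2) / sqrt(sigma2)
}

allPairs <- function(nt) {
  idx <- which(upper.tri(matrix(0, nt, nt)), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Marker enrichment in detected interactions
#'
#' For every detected bin pair and every marker, compares the marker in the
#' pair against an ensemble of randomly selected intra-chromosomal pairs with
#' a rank-sum test. Sample A holds the tested pair's values, sample B pools
#' the values of \code{nRandom} random pairs (drawn uniformly without
#' replacement over all unordered bin pairs of the chromosome excluding the
#' tested pair; one draw is shared across all markers of a pair). In
#' \code{mode = "bins"} the per-bin combined value is used (n_A = 2), the
#' normal approximation of which caps |Z| near 2.43; \code{mode = "features"}
#' instead enters every individual feature value of the two bins, which is
#' required for the high-enrichment threshold Z >= 3 to be reachable and is
#' the pipeline default.
#'
#' @param pairs data.frame of detected pairs
#'   (\code{\link{detectedInteractions}}).
#' @param markerValues named list (one element per marker) of
#'   \code{\link{markerBinValues}} results.
#' @param nt number of bins.
#' @param nRandom number of random pairs (default 100).
#' @param seed integer seed.
#' @param mode "features" or "bins".
#' @param minRandom minimum random pairs with non-missing values required
#'   (default 10), else the pair's Z is NA.
#' @return numeric matrix, one row per pair, one column per marker.
#' @export
enrichmentTable <- function(pairs, markerValues, nt, nRandom = 100L,
                            seed = 1L, mode = c("features", "bins"),
                            minRandom = 10L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(pairs), length(markerValues) >= 1L)
  if (is.null(names(markerValues)))
    stop("markerValues must be a named list")
  ap <- allPairs(nt)
  total <- nrow(ap)
  pairKey <- (pairs$i - 1) * nt + pairs$j
  apKey <- (ap[, 1L] - 1) * nt + ap[, 2L]
  testedIdx <- match(pairKey, apKey)
  nP <- nrow(pairs)
  out <- matrix(NA_real_, nP, length(markerValues),
                dimnames = list(NULL, names(markerValues)))
  if (nP == 0L) return(out)
  draws <- withSeed(seed, lapply(seq_len(nP), function(pi) {
    s <- sample.int(total - 1L, min(nRandom, total - 1L))
    s + (s >= testedIdx[pi])      # skip the tested pair itself
  }))
  valueOf <- function(mv, bins) {
    if (mode == "bins") mv$combined[bins]
    else unlist(mv$perFeature[bins], use.names = FALSE)
  }
  for (pi in seq_len(nP)) {
    i <- pairs$i[pi]; j <- pairs$j[pi]
    rp <- ap[draws[[pi]], , drop = FALSE]
    bBins <- as.vector(t(rp))
    for (mi in seq_along(markerValues)) {
      mv <- markerValues[[mi]]
      a <- valueOf(mv, c(i, j))
      a <- a[!is.na(a)]
      bothPresent <- if (mode == "bins")
        !is.na(mv$combined[i]) && !is.na(mv$combined[j])
      else length(mv$perFeature[[i]]) > 0L && length(mv$perFeature[[j]]) > 0L
      if (!bothPresent || length(a) == 0L) next
      b <- valueOf(mv, bBins)
      b <- b[!is.na(b)]
      okPairs <- !is.na(mv$combined[rp[, 1L]]) | !is.na(mv$combined[rp[, 2L]])
      if (sum(okPairs) < minRandom || length(b) == 0L) next
      out[pi, mi] <- rankSumZ(a, b)
    }
  }
  out
}

#' Per-bin interaction and high-enrichment frequencies
#'
#' For each bin: Nvi = number of detected interactions involving the bin and
#' F_i = Nvi/Nt; per marker, Nei = number of those interactions whose
#' enrichment Z-value meets the threshold (>= 3 by default, inclusive) and
#' F_he = Nei/Nt.
#'
#' @param pairs detected pairs (\code{\link{detectedInteractions}}).
#' @param zTable enrichment matrix (\code{\link{enrichmentTable}}).
#' @param nt number of bins (the denominator Nt).
#' @param chrom chromosome name.
#' @param threshold high-enrichment threshold (default 3).
#' @return a \linkS4class{BinFrequencies}.
#' @export
binFrequencies <- function(pairs, zTable, nt, chrom = "chr", threshold = 3) {
  stopifnot(nrow(zTable) == nrow(pairs))
  nt <- as.integer(nt)
  nvi <- tabulate(c(pairs$i, pairs$j), nbins = nt)
  markers <- colnames(zTable)
  nei <- matrix(0L, nt, ncol(zTable), dimnames = list(NULL, markers))
  for (mi in seq_len(ncol(zTable))) {
    hit <- !is.na(zTable[, mi]) & zTable[, mi] >= threshold
    nei[, mi] <- tabulate(c(pairs$i[hit], pairs$j[hit]), nbins = nt)
  }
  new("BinFrequencies", chrom = chrom, nt = nt, nvi = as.integer(nvi),
      fi = nvi / nt, nei = nei, fhe = nei / nt, threshold = threshold)
}

#' Feature-vector table for zone clustering
#'
#' The bins x markers F_he matrix used as clustering input. Bins without any
#' feature are carried as all-zero rows and flagged in the "noFeature"
#' attribute.
#'
#' @param bf a \linkS4class{BinFrequencies}.
#' @param markerValues optional named list of \code{\link{markerBinValues}}
#'   results used to flag featureless bins.
#' @return numeric matrix with a "noFeature" logical attribute.
#' @export
featureTable <- function(bf, markerValues = NULL) {
  tab <- bf@fhe
  noFeat <- if (!is.null(markerValues)) {
    Reduce(`&`, lapply(markerValues, function(mv) is.na(mv$combined)))
  } else rep(FALSE, nrow(tab))
  tab[is.na(tab)] <- 0
  attr(tab, "noFeature") <- noFeat
  tab
}
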