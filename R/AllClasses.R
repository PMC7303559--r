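#' @import methods
#' @importFrom stats kmeans rnorm runif sd setNames dnorm
#' @importFrom utils head tail
NULL

DNA_BASES5 <- c("A", "C", "G", "T", "N")

#' MotifMatrix: a position-specific base count or frequency matrix
#'
#' Holds one motif as an m x 4 matrix over the alphabet (A, C, G, T), where m
#' is the binding-site length. Rows are positions, columns bases. A matrix may
#' carry raw counts (as read from a JASPAR record) or frequencies; frequencies
#' must sum to 1 per position.
#'
#' @slot id character identifier of the motif.
#' @slot values numeric m x 4 matrix of non-negative counts or frequencies.
#' @slot type either "counts" or "frequencies".
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(id = "character", values = "matrix", type = "character"))

setValidity("MotifMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v) || nrow(v) < 1L || ncol(v) != 4L)
    return("values must be a numeric m x 4 matrix with m >= 1")
  if (anyNA(v) || any(v < 0))
    return(sprintf("motif '%s': values must be non-negative and finite",
                   object@id))
  if (!object@type %in% c("counts", "frequencies"))
    return("type must be 'counts' or 'frequencies'")
  if (object@type == "frequencies" &&
      any(abs(rowSums(v) - 1) > 1e-6))
    return(sprintf("motif '%s': frequency rows must sum to 1", object@id))
  TRUE
})

#' EnergyMatrix: per-position, per-base binding energies
#'
#' A protein binding energy matrix (PBEM) derived from a motif: dimensionless
#' mismatch energies in thermal units, with the consensus base at each position
#' as the zero-energy reference (the per-position minimum is exactly 0).
#'
#' @slot id character identifier.
#' @slot energies numeric m x 4 matrix, all entries finite and >= 0 with a 0
#'   in every row.
#' @slot pseudocount the pseudocount used in the derivation.
#' @exportClass EnergyMatrix
setClass("EnergyMatrix",
  representation(id = "character", energies = "matrix",
                 pseudocount = "numeric"))

setValidity("EnergyMatrix", function(object) {
  e <- object@energies
  if (!is.numeric(e) || nrow(e) < 1L || ncol(e) != 4L)
    return("energies must be a numeric m x 4 matrix with m >= 1")
  if (anyNA(e) || any(!is.finite(e)) || any(e < 0))
    return(sprintf("'%s': energies must be finite and >= 0", object@id))
  if (any(abs(apply(e, 1L, min)) > 1e-12))
    return(sprintf("'%s': per-position minimum energy must be 0", object@id))
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    return("pseudocount must be a single positive number")
  TRUE
})

#' SlidingWindowGrid: the sliding-window layout of a scan
#'
#' Windows of size \code{L} advance by \code{st} along a sequence of length
#' \code{N}; the window count is \code{k = floor((N - L)/st) + 1} when
#' \code{N >= L} and 0 otherwise. Coordinates are 0-based; each window is
#' \code{[start, start + L)} and its value is assigned to the center
#' \code{start + L \%/\% 2}.
#'
#' @slot N,L,st integers: sequence length, window size, step size.
#' @slot starts integer vector of 0-based window starts.
#' @exportClass SlidingWindowGrid
setClass("SlidingWindowGrid",
  representation(N = "integer", L = "integer", st = "integer",
                 starts = "integer"))

setValidity("SlidingWindowGrid", function(object) {
  k <- if (object@N >= object@L)
    (object@N - object@L) %/% object@st + 1L else 0L
  if (length(object@starts) != k)
    return("window count does not satisfy k = floor((N - L)/st) + 1")
  if (k > 0L && (object@starts[1L] != 0L ||
                 max(object@starts) + object@L > object@N))
    return("windows must start at 0 and lie within [0, N)")
  TRUE
})

#' AffinityProfile: expected nTBA along a sequence
#'
#' Per-window expected nonspecific TF binding affinity: for each window center
#' one value per chemical potential, averaged over the motif ensemble.
#'
#' @slot seqname sequence/chromosome identifier.
#' @slot centers integer 0-based window-center coordinates, strictly
#'   increasing with spacing \code{st}.
#' @slot values numeric matrix, one row per center, one column per potential.
#' @slot potentials data.frame with columns \code{mode} and \code{mu}.
#' @slot nMotifs number of motifs in the ensemble average.
#' @slot L,st window size and step size used by the scan.
#' @exportClass AffinityProfile
setClass("AffinityProfile",
  representation(seqname = "character", centers = "integer",
                 values = "matrix", potentials = "data.frame",
                 nMotifs = "integer", L = "integer", st = "integer"))

setValidity("AffinityProfile", function(object) {
  if (nrow(object@values) != length(object@centers))
    return("one row of values per center required")
  if (ncol(object@values) != nrow(object@potentials))
    return("one column of values per potential required")
  if (length(object@centers) > 1L) {
    d <- diff(object@centers)
    if (any(d != object@st))
      return("centers must be strictly increasing with spacing st")
  }
  TRUE
})

#' CoverageTrack: binned read/interval counts for one marker
#'
#' @slot marker marker name (e.g. "H3K27ac").
#' @slot cellLine cell line the track belongs to.
#' @slot chrom chromosome.
#' @slot binWidth bin width in bp (100 by default in the pipeline).
#' @slot counts non-negative per-bin counts tiling the chromosome.
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(marker = "character", cellLine = "character",
                 chrom = "character", binWidth = "integer",
                 counts = "numeric"))

setValidity("CoverageTrack", function(object) {
  if (any(object@counts < 0, na.rm = TRUE))
    return("counts must be >= 0")
  if (object@binWidth < 1L) return("binWidth must be >= 1")
  TRUE
})

#' NormalizedTrack: per-bin Z-scores of one marker
#'
#' Counts scaled for library size, replicate-averaged, log-transformed and
#' standardized per chromosome; over covered bins the values have mean 0 and
#' (population) SD 1.
#'
#' @slot marker,cellLine,chrom,binWidth as in \linkS4class{CoverageTrack}.
#' @slot values per-bin Z-scores (NA allowed for uncovered bins).
#' @exportClass NormalizedTrack
setClass("NormalizedTrack",
  representation(marker = "character", cellLine = "character",
                 chrom = "character", binWidth = "integer",
                 values = "numeric"))

setValidity("NormalizedTrack", function(object) {
  if (any(is.infinite(object@values)))
    return(sprintf("'%s': Z-scores must be finite (or NA)", object@marker))
  if (object@binWidth < 1L) return("binWidth must be >= 1")
  TRUE
})

#' ContactMatrix: a normalized intra-chromosomal Hi-C contact matrix
#'
#' Symmetric Nt x Nt matrix of (upstream-normalized) contact values at a fixed
#' bin resolution; after Z-scoring the diagonal is NA.
#'
#' @slot chrom chromosome.
#' @slot resolution bin size in bp.
#' @slot matrix symmetric numeric matrix.
#' @slot zscored logical, TRUE once standardized.
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(chrom = "character", resolution = "integer",
                 matrix = "matrix", zscored = "logical"))

setValidity("ContactMatrix", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("matrix must be square")
  d <- abs(m - t(m))
  if (any(d[!is.na(d)] > 1e-6)) return("matrix must be symmetric within 1e-6")
  if (object@resolution < 1L) return("resolution must be >= 1")
  TRUE
})

#' BinFrequencies: per-bin interaction and high-enrichment frequencies
#'
#' For each genomic window bin, Nvi counts the detected interactions (contact
#' Z > 0) it participates in and F_i = Nvi/Nt; for each marker, Nei counts the
#' detected interactions of the bin in which the marker is highly enriched
#' (rank-sum Z >= threshold) and F_he = Nei/Nt.
#'
#' @slot chrom chromosome.
#' @slot nt total number of bins (the denominator Nt).
#' @slot nvi integer per-bin detected-interaction counts.
#' @slot fi numeric per-bin interaction frequencies.
#' @slot nei integer bins x markers matrix of high-enrichment counts.
#' @slot fhe numeric bins x markers matrix of high-enrichment frequencies.
#' @slot threshold the rank-sum Z threshold used.
#' @exportClass BinFrequencies
setClass("BinFrequencies",
  representation(chrom = "character", nt = "integer", nvi = "integer",
                 fi = "numeric", nei = "matrix", fhe = "matrix",
                 threshold = "numeric"))

setValidity("BinFrequencies", function(object) {
  if (length(object@nvi) != object@nt) return("nvi must have one entry per bin")
  if (any(object@nei > object@nvi))
    return("Nei must never exceed Nvi")
  if (any(object@fi < 0) || any(object@fi > (object@nt - 1L) / object@nt))
    return("F_i must lie in [0, (Nt-1)/Nt]")
  TRUE
})

#' ZoneModel: combined k-means + Gaussian-mixture clustering of bins
#'
#' @slot k number of clusters.
#' @slot centroids k x p k-means centroids.
#' @slot pDist,pMix per-bin probability matrices from inverse centroid
#'   distance and from the mixture posterior (rows sum to 1).
#' @slot w mixing weight on the distance probabilities.
#' @slot probabilities the weighted-sum probabilities.
#' @slot labels integer cluster assignment (argmax of probabilities).
#' @exportClass ZoneModel
setClass("ZoneModel",
  representation(k = "integer", centroids = "matrix", pDist = "matrix",
                 pMix = "matrix", w = "numeric", probabilities = "matrix",
                 labels = "integer"))

setValidity("ZoneModel", function(object) {
  for (nm in c("pDist", "pMix", "probabilities")) {
    p <- slot(object, nm)
    if (nrow(p) > 0L && any(abs(rowSums(p) - 1) > 1e-9))
      return(sprintf("%s rows must sum to 1 within 1e-9", nm))
  }
  if (length(object@labels) != nrow(object@probabilities))
    return("one label per bin required")
  TRUE
})

#' ZoneLabels: genomic window bins typed I/II/III
#'
#' Types are ordered by mean intra-chromosomal interaction frequency F_i:
#' I (Inactive Genomic Zones) < II (Poised) < III (Active).
#'
#' @slot chrom chromosome.
#' @slot resolution bin size in bp.
#' @slot type factor with levels I, II, III, one per bin.
#' @slot fi per-bin interaction frequency used for the ordering.
#' @slot cellLine cell line.
#' @exportClass ZoneLabels
setClass("ZoneLabels",
  representation(chrom = "character", resolution = "integer",
                 type = "factor", fi = "numeric", cellLine = "character"))

setValidity("ZoneLabels", function(object) {
  if (!identical(levels(object@type), c("I", "II", "III")))
    return("type must be a factor with levels I, II, III")
  if (length(object@fi) != length(object@type))
    return("fi must have one entry per bin")
  mfi <- tapply(object@fi, object@type, mean)
  mfi <- mfi[!is.na(mfi)]
  if (length(mfi) > 1L && any(diff(mfi) <= 0))
    return("mean F_i must be strictly increasing over types I < II < III")
  TRUE
})

ZONE_NAMES <- c(I = "Inactive Genomic Zones", II = "Poised Genomic Zones",
                III = "Active Genomic Zones")
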