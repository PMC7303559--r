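#' @importFrom GenomicRanges GRanges seqnames start end width strand mcols
#'   mcols<- countOverlaps findOverlaps strand<- GRangesList
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

FEATURE_CLASSES <- c("gene", "tss", "enhancer", "super_enhancer",
                     "hub_enhancer", "hot", "chromatin_state", "peak")
STATE_CODES <- c("TSS", "PF", "E", "WE", "CTCF", "T", "R")

#' Read genomic features from a BED file
#'
#' BED3/BED4/BED6 reader (0-based half-open on disk, 1-based closed in the
#' returned GRanges, as usual for Bioconductor). The name column, when
#' present, is kept as \code{label} (e.g. a chromatin-state code).
#'
#' @param path BED file path.
#' @param featureClass one of gene, tss, enhancer, super_enhancer,
#'   hub_enhancer, hot, chromatin_state, peak.
#' @return a GRanges with metadata columns \code{featureClass} and
#'   \code{label}.
#' @export
readFeatureBed <- function(path, featureClass = "peak") {
  featureClass <- match.arg(featureClass, FEATURE_CLASSES)
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  mcols(gr)$featureClass <- featureClass
  mcols(gr)$label <- if (!is.null(mcols(gr)$name)) mcols(gr)$name
                     else NA_character_
  gr
}

#' Extract deduplicated 1000 bp windows centered on features
#'
#' Uniform preprocessing ahead of profile aggregation and bin-level marker
#' extraction: elements shorter than \code{minWidth} (100 bp) are removed, a
#' window of \code{2*flank} bp centered on each element is extracted, and
#' duplicate windows are deleted. The center is the interval midpoint,
#' except for tss-class features where the strand-aware 5' end (the annotated
#' TSS base) is used. Inputs that already carry a \code{center} metadata
#' column are re-windowed from that center unchanged, which makes the
#' operation idempotent. Windows that would extend below position 1 are
#' clipped and flagged.
#'
#' @param features GRanges with a \code{featureClass} metadata column (see
#'   \code{\link{readFeatureBed}}); plain GRanges are treated as class
#'   "peak".
#' @param flank half-window in bp (default 500, i.e. 1000 bp windows).
#' @param minWidth minimum element width kept (default 100 bp).
#' @return GRanges of windows with metadata \code{center}, \code{clipped},
#'   \code{featureClass}, \code{label}.
#' @export
preprocessFeatures <- function(features, flank = 500L, minWidth = 100L) {
  stopifnot(is(features, "GRanges"))
  fc <- mcols(features)$featureClass
  if (is.null(fc)) fc <- rep("peak", length(features))
  lab <- mcols(features)$label
  if (is.null(lab)) lab <- rep(NA_character_, length(features))

  center <- mcols(features)$center
  if (is.null(center)) {
    keep <- width(features) >= minWidth
    features <- features[keep]; fc <- fc[keep]; lab <- lab[keep]
    # midpoint of the 0-based half-open interval [start-1, end)
    center <- (start(features) - 1L + end(features)) %/% 2L
    isTss <- fc == "tss"
    if (any(isTss)) {
      s <- as.character(strand(features))
      center[isTss] <- ifelse(s[isTss] == "-",
                              end(features)[isTss] - 1L,     # 0-based 5' end
                              start(features)[isTss] - 1L)
    }
  } else {
    center <- as.integer(center)
  }

  ws <- center - flank + 1L                 # 1-based window start
  we <- center + flank                      # 1-based window end (inclusive)
  clipped <- ws < 1L
  ws[clipped] <- 1L
  out <- GRanges(seqnames(features), IRanges(ws, we),
                 strand = strand(features))
  mcols(out)$center <- as.integer(center)
  mcols(out)$clipped <- clipped
  mcols(out)$featureClass <- fc
  mcols(out)$label <- lab

  dup <- duplicated(paste(as.character(seqnames(out)), start(out), end(out)))
  out[!dup]
}

#' Values of a signal across a 1000 bp feature window
#'
#' Internal helper: the signal value at every offset of one window. For an
#' AffinityProfile, values exist only at window centers spaced st apart;
#' other offsets are NA. For a NormalizedTrack, each position inherits the
#' Z-score of its bin.
#'
#' @noRd
signalAtOffsets <- function(center, flank, signal, potentialIndex = 1L) {
  pos <- (center - flank):(center + flank - 1L)    # 0-based positions
  if (is(signal, "AffinityProfile")) {
    idx <- match(pos, signal@centers)
    v <- rep(NA_real_, length(pos))
    hit <- !is.na(idx)
    v[hit] <- signal@values[idx[hit], potentialIndex]
    v
  } else if (is(signal, "NormalizedTrack")) {
    bin <- pos %/% signal@binWidth + 1L
    v <- rep(NA_real_, length(pos))
    ok <- bin >= 1L & bin <= length(signal@values)
    v[ok] <- signal@values[bin[ok]]
    v
  } else stop("signal must be an AffinityProfile or a NormalizedTrack")
}

#' Aggregate a signal over feature windows with subsample replicates
#'
#' Builds the mean +- SD curve of a signal across feature-centered windows:
#' in each of \code{draws} replicates, \code{subsample} windows are sampled
#' without replacement (all windows if fewer are available), the signal is
#' stacked by offset relative to the center and reduced by sum
#' (\code{mode = "total"}) or mean (\code{mode = "mean"}), ignoring missing
#' values; the across-draw mean and SD are reported per offset.
#'
#' @param windows preprocessed feature windows
#'   (\code{\link{preprocessFeatures}}).
#' @param signal an \linkS4class{AffinityProfile} or
#'   \linkS4class{NormalizedTrack}.
#' @param mode "total" or "mean".
#' @param subsample windows per draw (default 200).
#' @param draws number of replicate draws (default 5).
#' @param seed integer seed.
#' @param potentialIndex which potential column of an AffinityProfile to use.
#' @return a data.frame with columns offset, mean, sd.
#' @export
aggregateProfile <- function(windows, signal, mode = c("total", "mean"),
                             subsample = 200L, draws = 5L, seed = 1L,
                             potentialIndex = 1L) {
  mode <- match.arg(mode)
  stopifnot(is(windows, "GRanges"))
  if (length(windows) == 0L) stop("empty window list")
  centers <- mcols(windows)$center
  if (is.null(centers)) stop("windows must carry a 'center' column; run preprocessFeatures()")
  flank <- as.integer(end(windows)[1L]) - as.integer(centers[1L])
  stack <- t(vapply(as.integer(centers), signalAtOffsets,
                    numeric(2L * flank), flank = flank, signal = signal,
                    potentialIndex = potentialIndex))
  n <- nrow(stack)
  take <- min(subsample, n)
  reduce <- if (mode == "total") {
    function(m) colSums(m, na.rm = TRUE) * ifelse(colSums(!is.na(m)) > 0, 1, NA)
  } else {
    function(m) colMeans(m, na.rm = TRUE)
  }
  curves <- withSeed(seed, {
    vapply(seq_len(draws), function(d) {
      idx <- sample.int(n, take)
      reduce(stack[idx, , drop = FALSE])
    }, numeric(ncol(stack)))
  })
  mu <- rowMeans(curves)
  sdv <- apply(curves, 1L, stats::sd)
  sdv[is.na(sdv)] <- 0
  data.frame(offset = seq.int(-flank, flank - 1L), mean = mu, sd = sdv)
}

#' Overlap of chromatin states with the three zone types
#'
#' For each chromatin-state code (TSS, PF, E, WE, CTCF, T, R) and each zone
#' type, the percentage of state segments overlapping (>= 1 bp) bins of that
#' type: \code{100 * overlapping / total segments of the code}. A segment
#' spanning a type boundary counts once for every type it touches.
#'
#' @param zones a \linkS4class{ZoneLabels}.
#' @param states GRanges of chromatin-state segments with the state code in
#'   the \code{label} metadata column.
#' @return a 3 x 7 numeric matrix (rows I, II, III; columns the state codes).
#' @export
stateOverlap <- function(zones, states) {
  stopifnot(is(zones, "ZoneLabels"), is(states, "GRanges"))
  lab <- mcols(states)$label
  if (is.null(lab)) stop("state segments need the code in the 'label' column")
  bad <- setdiff(unique(lab), STATE_CODES)
  if (length(bad))
    stop("unknown chromatin-state code(s): ", paste(bad, collapse = ", "))
  bins <- zoneBins(zones)
  out <- matrix(0, 3L, length(STATE_CODES),
                dimnames = list(c("I", "II", "III"), STATE_CODES))
  for (code in STATE_CODES) {
    seg <- states[lab == code]
    if (length(seg) == 0L) {
      warning("no segments for chromatin state '", code, "'; column set to 0")
      next
    }
    for (ty in c("I", "II", "III")) {
      tb <- bins[zones@type == ty]
      out[ty, code] <- 100 * sum(countOverlaps(seg, tb) > 0) / length(seg)
    }
  }
  out
}

zoneBins <- function(zones) {
  n <- length(zones@type)
  res <- zones@resolution
  GRanges(zones@chrom,
          IRanges(start = (seq_len(n) - 1L) * res + 1L,
                  end = seq_len(n) * res))
}

#' Core bins shared across cell lines
#'
#' Given zone labelings of the same bin grid in two or more cell lines,
#' returns per type the set of bins assigned that type in every cell line
#' (the core type I/II/III bins) plus the counts of every cell-line
#' membership combination (Venn counts).
#'
#' @param labelsList named list of \linkS4class{ZoneLabels} on one grid.
#' @return list with elements \code{core} (per type, integer bin indices) and
#'   \code{venn} (per type, a table over membership patterns).
#' @export
coreBins <- function(labelsList) {
  stopifnot(is.list(labelsList), length(labelsList) >= 2L)
  n <- length(labelsList[[1L]]@type)
  same <- vapply(labelsList, function(z)
    length(z@type) == n && z@chrom == labelsList[[1L]]@chrom &&
      z@resolution == labelsList[[1L]]@resolution, TRUE)
  if (!all(same)) stop("mismatched bin grids across cell lines")
  if (is.null(names(labelsList)))
    names(labelsList) <- paste0("cellLine", seq_along(labelsList))
  types <- c("I", "II", "III")
  core <- venn <- setNames(vector("list", 3L), types)
  for (ty in types) {
    member <- vapply(labelsList, function(z) z@type == ty,
                     logical(n))                      # n x cellLines
    core[[ty]] <- which(rowSums(member) == ncol(member))
    pattern <- apply(member, 1L, function(r)
      paste(names(labelsList)[r], collapse = "&"))
    pattern[pattern == ""] <- "none"
    venn[[ty]] <- table(pattern)
  }
  list(core = core, venn = venn)
}

#' Write core bins as a BED file
#'
#' @param core result of \code{\link{coreBins}}.
#' @param zones any of the input \linkS4class{ZoneLabels} (for the grid).
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
writeCoreBinsBed <- function(core, zones, path) {
  bins <- zoneBins(zones)
  rows <- do.call(rbind, lapply(names(core$core), function(ty) {
    idx <- core$core[[ty]]
    if (length(idx) == 0L) return(NULL)
    data.frame(chrom = zones@chrom, start = start(bins)[idx] - 1L,
               end = end(bins)[idx], name = paste0("core_", ty))
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), name = character(0))
  data.table::fwrite(rows, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
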