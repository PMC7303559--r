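#' Bin intervals/reads into fixed-width coverage bins
#'
#' Counts input intervals (reads, fragments) into contiguous bins tiling the
#' chromosome. An interval is assigned to the bin containing its midpoint
#' (floor of the 0-based half-open midpoint); the midpoint rule keeps the
#' total conserved: the bin counts sum to the number of unclipped intervals.
#' The last partial bin is included. Intervals extending beyond the
#' chromosome are clipped with a warning.
#'
#' @param intervals a GRanges, or a data.frame with 0-based half-open
#'   \code{start}/\code{end} columns.
#' @param chromLength chromosome length in bp.
#' @param binWidth bin width in bp (default 100).
#' @param marker,cellLine,chrom labels stored on the track.
#' @return a \linkS4class{CoverageTrack}.
#' @export
binCounts <- function(intervals, chromLength, binWidth = 100L,
                      marker = "signal", cellLine = "NA", chrom = "chr") {
  chromLength <- as.integer(chromLength)
  binWidth <- as.integer(binWidth)
  stopifnot(binWidth >= 1L, chromLength >= 1L)
  if (is(intervals, "GRanges")) {
    s0 <- start(intervals) - 1L
    e0 <- end(intervals)
    chrom0 <- as.character(seqnames(intervals))
    if (length(chrom0)) chrom <- chrom0[1L]
  } else {
    s0 <- as.integer(intervals$start)
    e0 <- as.integer(intervals$end)
  }
  nBins <- as.integer(ceiling(chromLength / binWidth))
  if (length(s0) == 0L)
    return(new("CoverageTrack", marker = marker, cellLine = cellLine,
               chrom = chrom, binWidth = binWidth,
               counts = numeric(nBins)))
  if (any(e0 > chromLength)) {
    warning(sum(e0 > chromLength),
            " interval(s) beyond the chromosome length clipped")
    e0 <- pmin(e0, chromLength)
  }
  keep <- e0 > s0 & s0 >= 0L
  mid <- (s0[keep] + e0[keep]) %/% 2L
  bin <- mid %/% binWidth + 1L
  bin <- bin[bin >= 1L & bin <= nBins]
  counts <- tabulate(bin, nbins = nBins)
  new("CoverageTrack", marker = marker, cellLine = cellLine, chrom = chrom,
      binWidth = binWidth, counts = as.numeric(counts))
}

#' Normalize coverage tracks to per-marker Z-scores
#'
#' Per track, counts are scaled to counts per \code{scaleTo} (10 million by
#' default) of the track total, so a global library-size factor cancels.
#' Replicate tracks (same marker, cell line, chromosome) are then averaged
#' bin-wise, the result is log2(x+1)-transformed, and finally standardized to
#' Z-scores per marker and chromosome (population SD). A zero-total track or
#' a constant track after transform is an error, named.
#'
#' @param tracks list of \linkS4class{CoverageTrack} objects on one binning.
#' @param scaleTo library-size scaling target (default 1e7).
#' @return a list of \linkS4class{NormalizedTrack}, one per marker/cell
#'   line/chromosome group, in first-appearance order.
#' @export
normalizeTracks <- function(tracks, scaleTo = 1e7) {
  if (is(tracks, "CoverageTrack")) tracks <- list(tracks)
  stopifnot(length(tracks) >= 1L,
            all(vapply(tracks, is, TRUE, "CoverageTrack")))
  nb <- vapply(tracks, function(t) length(t@counts), 1L)
  bw <- vapply(tracks, function(t) t@binWidth, 1L)
  if (length(unique(nb)) != 1L || length(unique(bw)) != 1L)
    stop("all tracks must share an identical binning")
  key <- vapply(tracks, function(t)
    paste(t@marker, t@cellLine, t@chrom, sep = "\r"), "")
  out <- list()
  for (k in unique(key)) {
    grp <- tracks[key == k]
    scaled <- lapply(grp, function(t) {
      tot <- sum(t@counts)
      if (tot <= 0)
        stop("zero-total track for marker '", t@marker, "'")
      t@counts / tot * scaleTo
    })
    avg <- Reduce(`+`, scaled) / length(scaled)
    lg <- log2(avg + 1)
    mu <- mean(lg)
    sdv <- sqrt(mean((lg - mu)^2))
    if (sdv == 0)
      stop("constant track after transform for marker '", grp[[1L]]@marker,
           "': no Z-score exists")
    out[[length(out) + 1L]] <- new("NormalizedTrack",
      marker = grp[[1L]]@marker, cellLine = grp[[1L]]@cellLine,
      chrom = grp[[1L]]@chrom, binWidth = grp[[1L]]@binWidth,
      values = (lg - mu) / sdv)
  }
  out
}

#' Read a per-bin bedGraph into a CoverageTrack
#'
#' Expects fixed-width bins (the pipeline's 100 bp convention); bins absent
#' from the file get count 0.
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param chromLength chromosome length in bp.
#' @param binWidth bin width in bp.
#' @param marker,cellLine labels stored on the track.
#' @return a \linkS4class{CoverageTrack}.
#' @export
readBedGraphTrack <- function(path, chromLength, binWidth = 100L,
                              marker = "signal", cellLine = "NA") {
  bg <- readBedGraphBins(path, chromLength, binWidth, fill = 0)
  new("CoverageTrack", marker = marker, cellLine = cellLine,
      chrom = bg$chrom, binWidth = as.integer(binWidth), counts = bg$values)
}

# shared per-bin bedGraph reader; fill value covers bins absent from the file
readBedGraphBins <- function(path, chromLength, binWidth, fill = NA_real_) {
  if (!file.exists(path)) stop("bedGraph not found: ", path)
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  nBins <- as.integer(ceiling(chromLength / binWidth))
  values <- rep(fill, nBins)
  if (nrow(df)) {
    bin <- as.integer(df$start) %/% as.integer(binWidth) + 1L
    ok <- bin >= 1L & bin <= nBins
    values[bin[ok]] <- df$value[ok]
  }
  list(chrom = if (nrow(df)) as.character(df$chrom[1L]) else "chr",
       values = values)
}

#' Write a track as bedGraph
#'
#' @param track a \linkS4class{CoverageTrack} or
#'   \linkS4class{NormalizedTrack}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrackBedGraph <- function(track, path) {
  v <- trackValues(track)
  bw <- track@binWidth
  keep <- !is.na(v)
  df <- data.frame(chrom = track@chrom,
                   start = (which(keep) - 1L) * bw,
                   end = (which(keep)) * bw,
                   value = v[keep])
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read UCSC chrom.sizes
#'
#' @param path two-column whitespace-delimited file: chromosome, length.
#' @return named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes not found: ", path)
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  setNames(as.integer(df$length), df$chrom)
}
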