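#' Specification of the synthetic fixtures
#'
#' A seeded description of every input the pipeline consumes, with planted
#' structure so each stage has a known ground truth. Defaults are chosen to
#' keep full-pipeline runs at desk scale (a few kb of sequence, tens of
#' 250 kb bins) while preserving the statistical shape of the real inputs:
#' human-like GC content, one dominant base per motif position, three
#' contact-frequency regimes with correlated marker enrichment.
#'
#' @param seed master seed; every generator is a pure function of the spec.
#' @param length sequence length in bp for \code{\link{genSequence}}.
#' @param gc GC fraction of the background sequence.
#' @param nMotifs,motifWidth motif collection size and width.
#' @param concentration Dirichlet dominance of the consensus base (larger =
#'   sharper motifs).
#' @param plantCenter,plantWidth,plantCount center/width of the planted
#'   cluster region and the number of consensus instances planted there
#'   (\code{plantCount = 0} gives pure background).
#' @param resolution genomic bin size in bp for the zone dataset.
#' @param binsPerRegime bins in the low/medium/high-contact regimes.
#' @param contactStrength per-regime contact propensity (strictly
#'   increasing).
#' @param contactNoise SD of the pairwise contact noise.
#' @param featuresPerBin TSS (and HOT) features planted per bin.
#' @param markerNoise lognormal noise sdlog of the marker tracks.
#' @param markerEffect per-regime signal boost, in units of
#'   \code{markerNoise}, for active marks and nTBA surrogates; repressive
#'   marks get the regime-2 boost in both regimes 2 and 3.
#' @param trackBinWidth marker track bin width in bp (default 100).
#' @return a classed list ("FixtureSpec").
#' @export
fixtureSpec <- function(seed = 1L, length = 5000L, gc = 0.41,
                        nMotifs = 5L, motifWidth = 8L, concentration = 50,
                        plantCenter = NULL, plantWidth = 200L,
                        plantCount = 10L,
                        resolution = 250000L, binsPerRegime = c(20L, 20L, 20L),
                        contactStrength = c(1, 2, 3), contactNoise = 0.5,
                        featuresPerBin = 10L, markerNoise = 0.25,
                        markerEffect = c(0, 2.5, 5), trackBinWidth = 100L) {
  if (is.null(plantCenter)) plantCenter <- length %/% 2L
  spec <- list(seed = as.integer(seed), length = as.integer(length), gc = gc,
               nMotifs = as.integer(nMotifs),
               motifWidth = as.integer(motifWidth),
               concentration = concentration,
               plantCenter = as.integer(plantCenter),
               plantWidth = as.integer(plantWidth),
               plantCount = as.integer(plantCount),
               resolution = as.integer(resolution),
               binsPerRegime = as.integer(binsPerRegime),
               contactStrength = contactStrength,
               contactNoise = contactNoise,
               featuresPerBin = as.integer(featuresPerBin),
               markerNoise = markerNoise, markerEffect = markerEffect,
               trackBinWidth = as.integer(trackBinWidth))
  stopifnot(spec$length >= 1L, spec$gc > 0, spec$gc < 1,
            spec$plantCount >= 0L, spec$nMotifs >= 0L,
            length(spec$binsPerRegime) == 3L,
            all(diff(spec$contactStrength) > 0))
  structure(spec, class = "FixtureSpec")
}

#' Generate a motif collection
#'
#' Frequency columns drawn from a Dirichlet with one dominant base per
#' position: the dominant base's concentration parameter is
#' \code{concentration}, the others 1, so larger values give sharper
#' (higher-information) motifs.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return list of \linkS4class{MotifMatrix} (frequencies).
#' @export
genMotifs <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"), spec$motifWidth >= 4L)
  withSeed(deriveSeed(spec$seed, 1L, 101L), {
    lapply(seq_len(spec$nMotifs), function(t) {
      m <- spec$motifWidth
      vals <- t(vapply(seq_len(m), function(j) {
        alpha <- rep(1, 4L)
        alpha[sample.int(4L, 1L)] <- spec$concentration
        g <- stats::rgamma(4L, shape = alpha)
        g / sum(g)
      }, numeric(4L)))
      colnames(vals) <- c("A", "C", "G", "T")
      new("MotifMatrix", id = sprintf("SYN%03d", t), values = vals,
          type = "frequencies")
    })
  })
}

#' Write motifs in JASPAR text format
#'
#' @param motifs list of \linkS4class{MotifMatrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMotifsJaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (mo in motifs) {
    writeLines(paste0(">", mo@id), con)
    v <- mo@values
    if (mo@type == "frequencies") v <- round(v * 1000)
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(v[, b], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(path)
}

consensusOf <- function(motif) {
  v <- if (is(motif, "MotifMatrix")) motif@values else -energies(motif)
  paste(c("A", "C", "G", "T")[max.col(v, ties.method = "first")],
        collapse = "")
}

#' Generate a DNA sequence with a planted motif cluster
#'
#' I.i.d. background at the requested GC fraction, with exact consensus
#' instances of the motif collection inserted at positions drawn inside the
#' planted region (each on the forward or reverse strand with probability
#' 1/2). Overlapping placements are repositioned with a warning. The
#' instance manifest (0-based position, motif id, strand) is returned with
#' the sequence.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param motifs optional motif collection (default \code{genMotifs(spec)}).
#' @param fastaPath optional path; when given the record is written as FASTA.
#' @return list with \code{sequence} (character), \code{manifest}
#'   (data.frame pos0, motif, strand) and \code{center} (the planted-cluster
#'   center).
#' @export
genSequence <- function(spec, motifs = NULL, fastaPath = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (is.null(motifs)) motifs <- genMotifs(spec)
  withSeed(deriveSeed(spec$seed, 2L, 102L), {
    probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2,
               G = spec$gc / 2, T = (1 - spec$gc) / 2)
    chars <- sample(names(probs), spec$length, replace = TRUE, prob = probs)
    manifest <- data.frame(pos0 = integer(0), motif = character(0),
                           strand = character(0))
    if (spec$plantCount > 0L && length(motifs) > 0L) {
      m <- spec$motifWidth
      lo <- max(0L, spec$plantCenter - spec$plantWidth %/% 2L)
      hi <- min(spec$length - m, spec$plantCenter + spec$plantWidth %/% 2L - m)
      if (hi < lo) stop("planted region too small for the motif width")
      taken <- integer(0)
      for (s in seq_len(spec$plantCount)) {
        mo <- motifs[[(s - 1L) %% length(motifs) + 1L]]
        pos <- NA_integer_
        for (try in 1:200) {
          cand <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          if (!any(abs(cand - taken) < m)) { pos <- cand; break }
        }
        if (is.na(pos)) {
          warning("could not place a non-overlapping instance; repositioned ",
                  "outside the crowded area")
          free <- setdiff(seq.int(lo, hi), unlist(lapply(taken, function(t)
            seq.int(t - m + 1L, t + m - 1L))))
          if (length(free) == 0L) next
          pos <- free[sample.int(length(free), 1L)]
        }
        taken <- c(taken, pos)
        cons <- consensusOf(mo)
        strand <- if (runif(1) < 0.5) "+" else "-"
        inst <- if (strand == "+") cons else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
        chars[(pos + 1L):(pos + m)] <- strsplit(inst, "")[[1L]]
        manifest <- rbind(manifest,
                          data.frame(pos0 = pos, motif = mo@id,
                                     strand = strand))
      }
    }
    sequence <- paste(chars, collapse = "")
    if (!is.null(fastaPath)) {
      dss <- Biostrings::DNAStringSet(sequence)
      names(dss) <- "synthetic"
      Biostrings::writeXStringSet(dss, fastaPath)
    }
    list(sequence = sequence, manifest = manifest,
         center = spec$plantCenter)
  })
}

#' Generate a full zone-classification dataset with known truth
#'
#' Emulates the three-regime structure behind zone classification: bins are
#' partitioned into low/medium/high-contact regimes; the contact value of a
#' pair is the sum of its bins' regime strengths plus Gaussian noise, so
#' detected-interaction frequency rises with regime; TSS and HOT features
#' are planted in every bin; marker tracks carry lognormal noise plus a
#' regime-dependent boost inside the feature windows (active marks and nTBA
#' surrogates elevated with regime; repressive marks moderately elevated in
#' regimes 2-3). When \code{dir} is given, everything is written in the
#' formats the pipeline reads (BED, bedGraph, dense TSV, chrom.sizes, JSON
#' truth manifest).
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir optional output directory.
#' @return list with elements \code{truth} (regime per bin, shuffled order),
#'   \code{contact} (\linkS4class{ContactMatrix}), \code{tss}, \code{hot}
#'   (GRanges), \code{tracks} (list of \linkS4class{CoverageTrack}),
#'   \code{chromLength}, \code{nt} and, when written, \code{paths}.
#' @export
genZoneDataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "FixtureSpec"), all(spec$binsPerRegime >= 2L))
  res <- spec$resolution
  nt <- sum(spec$binsPerRegime)
  chromLength <- nt * res
  chrom <- "chrS"
  withSeed(deriveSeed(spec$seed, 3L, 103L), {
    regime <- sample(rep.int(1:3, spec$binsPerRegime))

    s <- spec$contactStrength[regime]
    m <- outer(s, s, `+`) + matrix(rnorm(nt * nt, sd = spec$contactNoise),
                                   nt, nt)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    contact <- new("ContactMatrix", chrom = chrom,
                   resolution = res, matrix = m, zscored = FALSE)

    # TSS/HOT features per bin, kept >= 600 bp from bin edges so the 1000 bp
    # windows stay inside their bin
    margin <- 600L
    placeFeatures <- function(widthRange) {
      do.call(rbind, lapply(seq_len(nt), function(b) {
        lo <- (b - 1L) * res + margin
        hi <- b * res - margin
        ctr <- sort(sample.int(hi - lo, spec$featuresPerBin) + lo)
        w <- sample(seq(widthRange[1L], widthRange[2L]), spec$featuresPerBin,
                    replace = TRUE)
        data.frame(start0 = ctr - w %/% 2L, end0 = ctr + w %/% 2L, bin = b)
      }))
    }
    tssDf <- placeFeatures(c(200L, 1000L))
    hotDf <- placeFeatures(c(400L, 2000L))
    tss <- GRanges(chrom, IRanges(tssDf$start0 + 1L, tssDf$end0),
                   strand = sample(c("+", "-"), nrow(tssDf), replace = TRUE))
    mcols(tss)$featureClass <- "tss"
    mcols(tss)$label <- NA_character_
    hot <- GRanges(chrom, IRanges(hotDf$start0 + 1L, hotDf$end0))
    mcols(hot)$featureClass <- "hot"
    mcols(hot)$label <- NA_character_

    markers <- c("ntba_mu0", "ntba_mu-10", "DNase", "Pol2", "H3K4me3",
                 "H3K4me1", "H3K27ac", "H3K27me3", "H3K9me3", "CTCF")
    repressive <- c("H3K27me3", "H3K9me3")
    nBins <- as.integer(ceiling(chromLength / spec$trackBinWidth))
    # feature windows (TSS 5' end for tss class, midpoints otherwise)
    tssCtr <- ifelse(as.character(strand(tss)) == "-",
                     end(tss) - 1L, start(tss) - 1L)
    hotCtr <- (start(hot) - 1L + end(hot)) %/% 2L
    featBinIdx <- unique(unlist(lapply(c(tssCtr, hotCtr), function(ct)
      (ct - 500L):(ct + 499L) %/% spec$trackBinWidth + 1L)))
    featBinIdx <- featBinIdx[featBinIdx >= 1L & featBinIdx <= nBins]
    binRegime <- regime[pmin(((seq_len(nBins) - 1L) * spec$trackBinWidth)
                             %/% res + 1L, nt)]
    tracks <- lapply(markers, function(mk) {
      eff <- spec$markerEffect
      if (mk %in% repressive) eff <- c(eff[1L], eff[2L], eff[2L])
      mu <- rep(0, nBins)
      mu[featBinIdx] <- eff[binRegime[featBinIdx]] * spec$markerNoise
      counts <- exp(rnorm(nBins, mean = mu, sd = spec$markerNoise))
      new("CoverageTrack", marker = mk, cellLine = "synthetic",
          chrom = chrom, binWidth = spec$trackBinWidth, counts = counts)
    })
    names(tracks) <- markers

    out <- list(truth = regime, contact = contact, tss = tss, hot = hot,
                tracks = tracks, chromLength = chromLength, nt = nt,
                chrom = chrom)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      paths <- list(
        contact = file.path(dir, "contact_matrix.tsv"),
        tss = file.path(dir, "tss.bed"),
        hot = file.path(dir, "hot.bed"),
        chromSizes = file.path(dir, "chrom.sizes"),
        truth = file.path(dir, "truth.json"))
      writeContactMatrix(contact, paths$contact)
      data.table::fwrite(data.frame(chrom, tssDf$start0, tssDf$end0, "tss",
                                    0L, as.character(strand(tss))),
                         paths$tss, sep = "\t", col.names = FALSE)
      data.table::fwrite(data.frame(chrom, hotDf$start0, hotDf$end0),
                         paths$hot, sep = "\t", col.names = FALSE)
      writeLines(sprintf("%s\t%d", chrom, chromLength), paths$chromSizes)
      jsonlite::write_json(list(regime = regime, resolution = res,
                                nt = nt, seed = spec$seed),
                           paths$truth, auto_unbox = TRUE)
      paths$tracks <- vapply(markers, function(mk) {
        p <- file.path(dir, sprintf("track_%s.bedGraph", mk))
        writeTrackBedGraph(tracks[[mk]], p)
        p
      }, "")
      out$paths <- paths
    }
    out
  })
}
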