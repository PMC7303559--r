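#' Pipeline run configuration
#'
#' Collects paths and parameters for \code{\link{runStage}} with the standard
#' defaults: 50 bp scan windows stepping 5 bp, 10 shuffles, prior 1,
#' Fermi-Dirac potentials 0 and -10, 250 kb genomic bins, 100 random pairs
#' per enrichment test, high-enrichment threshold Z >= 3, k = 3 clusters and
#' weight 0.5 on the distance probabilities. Every parameter can be
#' overridden; the configuration is echoed into the output directory with
#' each run manifest.
#'
#' @param outDir output directory (required).
#' @param fasta,motifs,tssBed,hotBed,contactMatrix,chromSizes,trackDir input
#'   paths; stages validate the ones they need.
#' @param profileBed optional BED of regions for the profile stage; when
#'   absent the TSS BED is used (strand-aware centers).
#' @param motifFormat "jaspar" or "plain".
#' @param chrom chromosome to process (default: first in chromSizes).
#' @param L,st,R,p scan parameters.
#' @param mu chemical potentials (Fermi-Dirac) scanned.
#' @param resolution genomic bin size in bp.
#' @param nRandom random pairs per enrichment test.
#' @param threshold high-enrichment Z threshold.
#' @param k,w cluster count and distance-probability weight.
#' @param seed master seed.
#' @param workers parallel workers for the scan.
#' @param enrichMode "features" or "bins" (see
#'   \code{\link{enrichmentTable}}).
#' @param trackBinWidth coverage bin width in bp.
#' @param subsample,draws profile aggregation parameters.
#' @param cellLine label attached to outputs.
#' @return a classed list ("RunConfig").
#' @export
runConfig <- function(outDir, fasta = NULL, motifs = NULL,
                      motifFormat = "jaspar", tssBed = NULL, hotBed = NULL,
                      contactMatrix = NULL, chromSizes = NULL,
                      trackDir = NULL, chrom = NULL, profileBed = NULL,
                      L = 50L, st = 5L, R = 10L, p = 1, mu = c(0, -10),
                      resolution = 250000L, nRandom = 100L, threshold = 3,
                      k = 3L, w = 0.5, seed = 1L, workers = 1L,
                      enrichMode = c("features", "bins"),
                      trackBinWidth = 100L, subsample = 200L, draws = 5L,
                      cellLine = "NA") {
  enrichMode <- match.arg(enrichMode)
  cfg <- list(outDir = outDir, fasta = fasta, motifs = motifs,
              motifFormat = motifFormat, tssBed = tssBed, hotBed = hotBed,
              contactMatrix = contactMatrix, chromSizes = chromSizes,
              trackDir = trackDir, chrom = chrom, profileBed = profileBed,
              L = as.integer(L),
              st = as.integer(st), R = as.integer(R), p = p, mu = mu,
              resolution = as.integer(resolution),
              nRandom = as.integer(nRandom), threshold = threshold,
              k = as.integer(k), w = w, seed = as.integer(seed),
              workers = as.integer(workers), enrichMode = enrichMode,
              trackBinWidth = as.integer(trackBinWidth),
              subsample = as.integer(subsample), draws = as.integer(draws),
              cellLine = cellLine)
  stopifnot(cfg$L >= 1L, cfg$st >= 1L, cfg$R >= 1L, cfg$p >= 0, cfg$p <= 1,
            cfg$resolution >= 1L, cfg$nRandom >= 1L, cfg$k >= 1L,
            cfg$w >= 0, cfg$w <= 1)
  structure(cfg, class = "RunConfig")
}

requireInputs <- function(cfg, keys) {
  for (key in keys) {
    path <- cfg[[key]]
    if (is.null(path))
      stop("stage requires config field '", key, "'")
    if (!all(file.exists(path)))
      stop("missing input for '", key, "': ",
           paste(path[!file.exists(path)], collapse = ", "))
  }
}

writeManifest <- function(cfg, stage, outputs) {
  outputs <- unlist(outputs, use.names = FALSE)
  manifest <- list(stage = stage,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   parameters = unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                   outputs = outputs,
                   checksums = as.list(tools::md5sum(outputs)))
  path <- file.path(cfg$outDir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Orchestrates the five stages end to end:
#' \describe{
#'   \item{simulate}{generate the synthetic inputs into
#'     \code{outDir/sim} (sequence + motifs + zone dataset) and point the
#'     config's input paths there.}
#'   \item{ntba}{scan the FASTA with the motif collection; writes a wide TSV
#'     and one bedGraph per potential.}
#'   \item{profile}{aggregate the nTBA profile over TSS windows.}
#'   \item{tracks}{normalize all marker bedGraphs to Z-score tracks.}
#'   \item{hic-enrich}{Z-score the contact matrix, call detected pairs, test
#'     the 12-feature marker enrichment and write per-bin F_i/F_he tables.}
#'   \item{zones}{cluster the F_he table (k = 3) and write zone labels.}
#'   \item{all}{simulate, then every stage in order on the simulated data.}
#' }
#' Outputs are written atomically (temp file + rename) and each stage leaves
#' a JSON manifest with parameters and output checksums; rerunning an
#' identical config reproduces identical outputs.
#'
#' @param stage one of "simulate", "ntba", "profile", "tracks",
#'   "hic-enrich", "zones", "all".
#' @param config a \code{\link{runConfig}}.
#' @return a list of the stage's artifact paths, invisibly; "all" returns
#'   the concatenation.
#' @export
runStage <- function(stage = c("simulate", "ntba", "profile", "tracks",
                               "hic-enrich", "zones", "all"),
                     config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(config$outDir))
    dir.create(config$outDir, recursive = TRUE)
  switch(stage,
    "simulate" = stageSimulate(config),
    "ntba" = stageNtba(config),
    "profile" = stageProfile(config),
    "tracks" = stageTracks(config),
    "hic-enrich" = stageHicEnrich(config),
    "zones" = stageZones(config),
    "all" = {
      cfg <- stageSimulate(config)$config
      out <- list()
      for (s in c("ntba", "profile", "tracks", "hic-enrich", "zones"))
        out[[s]] <- runStage(s, cfg)
      invisible(out)
    })
}

stageSimulate <- function(cfg) {
  simDir <- file.path(cfg$outDir, "sim")
  spec <- fixtureSpec(seed = cfg$seed, resolution = cfg$resolution,
                      trackBinWidth = cfg$trackBinWidth)
  motifs <- genMotifs(spec)
  motifPath <- file.path(simDir, "motifs.jaspar")
  fastaPath <- file.path(simDir, "sequence.fa")
  if (!dir.exists(simDir)) dir.create(simDir, recursive = TRUE)
  writeMotifsJaspar(motifs, motifPath)
  gs <- genSequence(spec, motifs, fastaPath = fastaPath)
  # a feature record over the planted cluster so the profile stage has a
  # region to aggregate on the scanned sequence
  seqFeatPath <- file.path(simDir, "sequence_features.bed")
  data.table::fwrite(data.frame("synthetic", gs$center - 100L,
                                gs$center + 100L),
                     seqFeatPath, sep = "\t", col.names = FALSE)
  zd <- genZoneDataset(spec, dir = simDir)
  cfg$fasta <- fastaPath
  cfg$motifs <- motifPath
  cfg$motifFormat <- "jaspar"
  cfg$tssBed <- zd$paths$tss
  cfg$hotBed <- zd$paths$hot
  cfg$contactMatrix <- zd$paths$contact
  cfg$chromSizes <- zd$paths$chromSizes
  cfg$trackDir <- simDir
  cfg$chrom <- zd$chrom
  cfg$profileBed <- seqFeatPath
  manifest <- writeManifest(cfg, "simulate",
                            c(motifPath, fastaPath, seqFeatPath,
                              unlist(zd$paths)))
  invisible(list(config = cfg, paths = zd$paths, manifest = manifest))
}

stageNtba <- function(cfg) {
  requireInputs(cfg, c("fasta", "motifs"))
  motifs <- lapply(readMotifs(cfg$motifs, cfg$motifFormat), toEnergyMatrix)
  seqs <- Biostrings::readDNAStringSet(cfg$fasta)
  pots <- lapply(cfg$mu, function(m) chemicalPotential("fermi_dirac", m))
  outs <- character(0)
  for (i in seq_along(seqs)) {
    nm <- sub("\\s.*", "", names(seqs)[i])
    prof <- ntbaScan(as.character(seqs[[i]]), motifs, pots,
                     L = cfg$L, st = cfg$st, p = cfg$p, R = cfg$R,
                     seed = cfg$seed, workers = cfg$workers, seqname = nm)
    tsv <- file.path(cfg$outDir, sprintf("ntba_%s.tsv", nm))
    atomically(tsv, function(tmp) writeProfileTSV(prof, tmp))
    bgs <- writeProfileBedGraph(prof, cfg$outDir,
                                prefix = sprintf("ntba_%s", nm))
    outs <- c(outs, tsv, bgs)
  }
  writeManifest(cfg, "ntba", outs)
  invisible(outs)
}

stageProfile <- function(cfg) {
  profPaths <- list.files(cfg$outDir, "^ntba_.*\\.tsv$", full.names = TRUE)
  if (length(profPaths) == 0L)
    stop("missing artifact: no nTBA profile TSV in ", cfg$outDir,
         "; run the 'ntba' stage first")
  tss <- if (!is.null(cfg$profileBed)) {
    requireInputs(cfg, "profileBed")
    preprocessFeatures(readFeatureBed(cfg$profileBed, "peak"))
  } else {
    requireInputs(cfg, "tssBed")
    preprocessFeatures(readFeatureBed(cfg$tssBed, "tss"))
  }
  outs <- character(0)
  for (pp in profPaths) {
    prof <- readProfileTSV(pp)
    keep <- as.character(seqnames(tss)) == prof@seqname
    if (!any(keep)) next
    for (q in seq_len(ncol(prof@values))) {
      curve <- aggregateProfile(tss[keep], prof, mode = "total",
                                subsample = cfg$subsample, draws = cfg$draws,
                                seed = cfg$seed, potentialIndex = q)
      out <- file.path(cfg$outDir,
                       sprintf("profile_tss_%s_%s.tsv", prof@seqname,
                               colnames(prof@values)[q]))
      atomically(out, function(tmp)
        data.table::fwrite(curve, tmp, sep = "\t"))
      outs <- c(outs, out)
    }
  }
  writeManifest(cfg, "profile", outs)
  invisible(outs)
}

trackPaths <- function(cfg) {
  requireInputs(cfg, "trackDir")
  paths <- list.files(cfg$trackDir, "^track_.*\\.bedGraph$",
                      full.names = TRUE)
  if (length(paths) == 0L)
    stop("no marker bedGraphs (track_*.bedGraph) in ", cfg$trackDir)
  setNames(paths, sub("^track_(.*)\\.bedGraph$", "\\1", basename(paths)))
}

stageTracks <- function(cfg) {
  requireInputs(cfg, "chromSizes")
  sizes <- readChromSizes(cfg$chromSizes)
  chrom <- if (is.null(cfg$chrom)) names(sizes)[1L] else cfg$chrom
  paths <- trackPaths(cfg)
  raw <- lapply(names(paths), function(mk)
    readBedGraphTrack(paths[[mk]], sizes[[chrom]], cfg$trackBinWidth,
                      marker = mk, cellLine = cfg$cellLine))
  norm <- normalizeTracks(raw)
  outs <- vapply(norm, function(tr) {
    out <- file.path(cfg$outDir, sprintf("z_%s.bedGraph", tr@marker))
    atomically(out, function(tmp) writeTrackBedGraph(tr, tmp))
    out
  }, "")
  writeManifest(cfg, "tracks", outs)
  invisible(outs)
}

readNormalizedTracks <- function(cfg, chromLength) {
  paths <- list.files(cfg$outDir, "^z_.*\\.bedGraph$", full.names = TRUE)
  if (length(paths) == 0L)
    stop("missing artifact: no normalized tracks (z_*.bedGraph) in ",
         cfg$outDir, "; run the 'tracks' stage first")
  trs <- lapply(paths, function(p) {
    mk <- sub("^z_(.*)\\.bedGraph$", "\\1", basename(p))
    bg <- readBedGraphBins(p, chromLength, cfg$trackBinWidth)
    new("NormalizedTrack", marker = mk, cellLine = cfg$cellLine,
        chrom = bg$chrom, binWidth = as.integer(cfg$trackBinWidth),
        values = bg$values)
  })
  setNames(trs, vapply(trs, function(t) t@marker, ""))
}

stageHicEnrich <- function(cfg) {
  requireInputs(cfg, c("contactMatrix", "chromSizes", "tssBed", "hotBed"))
  sizes <- readChromSizes(cfg$chromSizes)
  chrom <- if (is.null(cfg$chrom)) names(sizes)[1L] else cfg$chrom
  chromLength <- sizes[[chrom]]
  nt <- length(makeBins(chromLength, cfg$resolution, chrom))
  cm <- zscoreMatrix(readContactMatrix(cfg$contactMatrix, chrom,
                                       cfg$resolution, nt = nt))
  pairs <- detectedInteractions(cm)
  tss <- preprocessFeatures(readFeatureBed(cfg$tssBed, "tss"))
  hot <- preprocessFeatures(readFeatureBed(cfg$hotBed, "hot"))
  both <- suppressWarnings(c(tss, hot))
  tracks <- readNormalizedTracks(cfg, chromLength)
  isNtba <- grepl("^ntba", names(tracks))
  mv <- list()
  for (mk in names(tracks)[isNtba]) {
    mv[[paste0(mk, "_tss")]] <-
      markerBinValues(tss, tracks[[mk]], nt, cfg$resolution, "sum")
    mv[[paste0(mk, "_hot")]] <-
      markerBinValues(hot, tracks[[mk]], nt, cfg$resolution, "sum")
  }
  for (mk in names(tracks)[!isNtba])
    mv[[mk]] <- markerBinValues(both, tracks[[mk]], nt, cfg$resolution,
                                "mean")
  zt <- enrichmentTable(pairs, mv, nt, nRandom = cfg$nRandom,
                        seed = cfg$seed, mode = cfg$enrichMode)
  bf <- binFrequencies(pairs, zt, nt, chrom = chrom,
                       threshold = cfg$threshold)
  tab <- featureTable(bf, mv)
  pairsOut <- file.path(cfg$outDir, "enrichment_pairs.tsv")
  atomically(pairsOut, function(tmp)
    data.table::fwrite(cbind(pairs, as.data.frame(zt)), tmp, sep = "\t"))
  freqOut <- file.path(cfg$outDir, "bin_frequencies.tsv")
  freqDf <- data.frame(chrom = chrom,
                       start = (seq_len(nt) - 1L) * cfg$resolution,
                       end = pmin(seq_len(nt) * cfg$resolution, chromLength),
                       nvi = bf@nvi, fi = bf@fi,
                       noFeature = attr(tab, "noFeature"))
  freqDf <- cbind(freqDf, as.data.frame(unclass(tab)))
  atomically(freqOut, function(tmp)
    data.table::fwrite(freqDf, tmp, sep = "\t"))
  writeManifest(cfg, "hic-enrich", c(pairsOut, freqOut))
  invisible(list(pairs = pairsOut, frequencies = freqOut))
}

stageZones <- function(cfg) {
  freqPath <- file.path(cfg$outDir, "bin_frequencies.tsv")
  if (!file.exists(freqPath))
    stop("missing artifact: ", freqPath, "; run the 'hic-enrich' stage first")
  df <- data.table::fread(freqPath, sep = "\t", data.table = FALSE)
  meta <- c("chrom", "start", "end", "nvi", "fi", "noFeature")
  tab <- as.matrix(df[, setdiff(colnames(df), meta), drop = FALSE])
  model <- clusterBins(tab, k = cfg$k, w = cfg$w, seed = cfg$seed)
  zones <- labelZones(model, df$fi, cellLine = cfg$cellLine,
                      resolution = cfg$resolution)
  zones@chrom <- as.character(df$chrom[1L])
  out <- file.path(cfg$outDir, "zones.tsv")
  atomically(out, function(tmp) writeZoneTable(zones, model, tmp))
  writeManifest(cfg, "zones", out)
  invisible(out)
}

# write via temp file in the same directory, then rename
atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
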