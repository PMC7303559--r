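# In-memory composition of the zone-classification pipeline
# (tracks -> hic-enrich -> zones) on the synthetic zone dataset, with a small
# cache so several tests can share one run.

.zoneCache <- new.env(parent = emptyenv())

zonePipeline <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.zoneCache[[key]])) return(.zoneCache[[key]])
  spec <- fixtureSpec(seed = seed)
  zd <- genZoneDataset(spec)
  norm <- normalizeTracks(zd$tracks)
  names(norm) <- vapply(norm, markerName, "")
  tss <- preprocessFeatures(zd$tss)
  hot <- preprocessFeatures(zd$hot)
  both <- c(tss, hot)
  isNtba <- grepl("^ntba", names(norm))
  mv <- list()
  for (mk in names(norm)[isNtba]) {
    mv[[paste0(mk, "_tss")]] <-
      markerBinValues(tss, norm[[mk]], zd$nt, spec$resolution, "sum")
    mv[[paste0(mk, "_hot")]] <-
      markerBinValues(hot, norm[[mk]], zd$nt, spec$resolution, "sum")
  }
  for (mk in names(norm)[!isNtba])
    mv[[mk]] <- markerBinValues(both, norm[[mk]], zd$nt, spec$resolution,
                                "mean")
  cm <- zscoreMatrix(zd$contact)
  pairs <- detectedInteractions(cm)
  zt <- enrichmentTable(pairs, mv, zd$nt, nRandom = 100, seed = seed)
  bf <- binFrequencies(pairs, zt, zd$nt, chrom = zd$chrom)
  model <- suppressWarnings(
    clusterBins(featureTable(bf, mv), k = 3, seed = seed))
  zones <- labelZones(model, bf, resolution = spec$resolution)
  out <- list(zones = zones, truth = zd$truth, bf = bf, model = model,
              pairs = pairs, norm = norm)
  .zoneCache[[key]] <- out
  out
}
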