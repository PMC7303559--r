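#' Accessors for the core classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x an object of one of the package's S4 classes.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))
#' @rdname accessors
#' @export
setMethod("motifId", "MotifMatrix", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("motifId", "EnergyMatrix", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("motifLength", function(x) standardGeneric("motifLength"))
#' @rdname accessors
#' @export
setMethod("motifLength", "MotifMatrix", function(x) nrow(x@values))
#' @rdname accessors
#' @export
setMethod("motifLength", "EnergyMatrix", function(x) nrow(x@energies))

#' @rdname accessors
#' @export
setGeneric("motifValues", function(x) standardGeneric("motifValues"))
#' @rdname accessors
#' @export
setMethod("motifValues", "MotifMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))
#' @rdname accessors
#' @export
setMethod("energies", "EnergyMatrix", function(x) x@energies)

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setMethod("windowStarts", "SlidingWindowGrid", function(x) x@starts)

#' @rdname accessors
#' @export
setGeneric("windowCenters", function(x) standardGeneric("windowCenters"))
#' @rdname accessors
#' @export
setMethod("windowCenters", "SlidingWindowGrid",
          function(x) x@starts + x@L %/% 2L)
#' @rdname accessors
#' @export
setMethod("windowCenters", "AffinityProfile", function(x) x@centers)

#' @rdname accessors
#' @export
setGeneric("windowCount", function(x) standardGeneric("windowCount"))
#' @rdname accessors
#' @export
setMethod("windowCount", "SlidingWindowGrid", function(x) length(x@starts))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "AffinityProfile", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("potentials", function(x) standardGeneric("potentials"))
#' @rdname accessors
#' @export
setMethod("potentials", "AffinityProfile", function(x) x@potentials)

#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("trackValues", "NormalizedTrack", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("markerName", function(x) standardGeneric("markerName"))
#' @rdname accessors
#' @export
setMethod("markerName", "CoverageTrack", function(x) x@marker)
#' @rdname accessors
#' @export
setMethod("markerName", "NormalizedTrack", function(x) x@marker)

#' @rdname accessors
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))
#' @rdname accessors
#' @export
setMethod("contactValues", "ContactMatrix", function(x) x@matrix)

#' @rdname accessors
#' @export
setGeneric("binCount", function(x) standardGeneric("binCount"))
#' @rdname accessors
#' @export
setMethod("binCount", "ContactMatrix", function(x) nrow(x@matrix))
#' @rdname accessors
#' @export
setMethod("binCount", "BinFrequencies", function(x) x@nt)

#' @rdname accessors
#' @export
setGeneric("interactionFrequency", function(x) standardGeneric("interactionFrequency"))
#' @rdname accessors
#' @export
setMethod("interactionFrequency", "BinFrequencies", function(x) x@fi)

#' @rdname accessors
#' @export
setGeneric("enrichedFrequency", function(x) standardGeneric("enrichedFrequency"))
#' @rdname accessors
#' @export
setMethod("enrichedFrequency", "BinFrequencies", function(x) x@fhe)

#' @rdname accessors
#' @export
setGeneric("zoneType", function(x) standardGeneric("zoneType"))
#' @rdname accessors
#' @export
setMethod("zoneType", "ZoneLabels", function(x) x@type)

#' @rdname accessors
#' @export
setGeneric("zoneName", function(x) standardGeneric("zoneName"))
#' @rdname accessors
#' @export
setMethod("zoneName", "ZoneLabels",
          function(x) unname(ZONE_NAMES[as.character(x@type)]))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ZoneModel", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("clusterProbabilities", function(x) standardGeneric("clusterProbabilities"))
#' @rdname accessors
#' @export
setMethod("clusterProbabilities", "ZoneModel", function(x) x@probabilities)

setMethod("show", "MotifMatrix", function(object) {
  cat(sprintf("MotifMatrix '%s': m = %d (%s)\n",
              object@id, nrow(object@values), object@type))
})

setMethod("show", "EnergyMatrix", function(object) {
  cat(sprintf("EnergyMatrix '%s': m = %d, pseudocount = %g\n",
              object@id, nrow(object@energies), object@pseudocount))
})

setMethod("show", "SlidingWindowGrid", function(object) {
  cat(sprintf("SlidingWindowGrid: N = %d, L = %d, st = %d, k = %d\n",
              object@N, object@L, object@st, length(object@starts)))
})

setMethod("show", "AffinityProfile", function(object) {
  cat(sprintf("AffinityProfile on '%s': %d windows (L = %d, st = %d), %d motif(s)\n",
              object@seqname, length(object@centers), object@L, object@st,
              object@nMotifs))
  cat("  potentials:",
      paste(sprintf("%s(mu=%g)", object@potentials$mode, object@potentials$mu),
            collapse = ", "), "\n")
})

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack %s [%s, %s]: %d bins of %d bp, total %.0f\n",
              object@marker, object@cellLine, object@chrom,
              length(object@counts), object@binWidth, sum(object@counts)))
})

setMethod("show", "NormalizedTrack", function(object) {
  cat(sprintf("NormalizedTrack %s [%s, %s]: %d bins of %d bp (Z-scores)\n",
              object@marker, object@cellLine, object@chrom,
              length(object@values), object@binWidth))
})

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix %s: %d bins at %d bp%s\n", object@chrom,
              nrow(object@matrix), object@resolution,
              if (object@zscored) " (Z-scored)" else ""))
})

setMethod("show", "BinFrequencies", function(object) {
  cat(sprintf("BinFrequencies %s: Nt = %d, %d marker(s), threshold Z >= %g\n",
              object@chrom, object@nt, ncol(object@nei), object@threshold))
})

setMethod("show", "ZoneModel", function(object) {
  cat(sprintf("ZoneModel: k = %d, w = %g, %d bins\n",
              object@k, object@w, length(object@labels)))
})

setMethod("show", "ZoneLabels", function(object) {
  tab <- table(object@type)
  cat(sprintf("ZoneLabels %s [%s]: %s\n", object@chrom, object@cellLine,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})
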