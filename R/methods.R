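#' Accessors for the package's S4 containers
#'
#' Small read-only accessors so that downstream code never touches slots
#' directly: `jonesData()` returns the complex `(frames, lateral, depth, 2, 2)`
#' array of a [JonesVolume-class]; `entropyValues()` / `validMask()` the
#' entropy array and validity mask of an [EntropyVolume-class];
#' `mapValues()` the matrix of an [EnFaceMap-class]; `delineationPoints()`
#' the `(frame, lateral, depth, label)` table of a [Delineation-class];
#' `layerMask()`, `melaninField()`, `boundaryCurves()` and `roiTruth()` the
#' ground-truth slots of a [PhantomTruth-class]; `noiseVariance()` the
#' recorded per-element noise power; `provenance()` the provenance record.
#'
#' @param x the object.
#' @return the slot value (see above).
#' @name accessors
NULL

#' @rdname accessors
setMethod("jonesData", "JonesVolume", function(x) x@data)

#' @rdname accessors
setMethod("noiseVariance", "JonesVolume", function(x) x@noiseVariance)

#' @rdname accessors
setMethod("entropyValues", "EntropyVolume", function(x) x@entropy)

#' @rdname accessors
setMethod("validMask", "EntropyVolume", function(x) x@valid)

#' @rdname accessors
setMethod("provenance", "EntropyVolume", function(x) x@provenance)

#' @rdname accessors
setMethod("mapValues", "EnFaceMap", function(x) x@values)

#' @rdname accessors
setMethod("delineationPoints", "Delineation", function(x) x@points)

#' @rdname accessors
setMethod("provenance", "Delineation", function(x) x@provenance)

#' @rdname accessors
setMethod("layerMask", "PhantomTruth", function(x) x@layerMask)

#' @rdname accessors
setMethod("melaninField", "PhantomTruth", function(x) x@melaninField)

#' @rdname accessors
setMethod("boundaryCurves", "PhantomTruth", function(x) x@boundaryCurves)

#' @rdname accessors
setMethod("roiTruth", "PhantomTruth", function(x) x@roiTruth)

setMethod("intensityVolume", "JonesVolume", function(x) {
  .intensityVolumeCpp(x@data, dim(x@data)[1:3])
})

setMethod("show", "JonesVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("JonesVolume: %d frames x %d lateral x %d depth\n",
              d[1], d[2], d[3]))
  cat(sprintf("  lateral extent %.2f mm, depth pitch %.2f um/px\n",
              object@lateralExtentMm, object@depthPitchUm))
  nv <- object@noiseVariance
  cat(sprintf("  noise variance per element: %s\n",
              if (is.na(nv)) "unknown" else format(nv, digits = 4)))
})

setMethod("show", "EntropyVolume", function(object) {
  d <- dim(object@entropy)
  cat(sprintf("EntropyVolume: %d frames x %d lateral x %d depth\n",
              d[1], d[2], d[3]))
  cat(sprintf("  kernel halfwidths (depth, lateral, frame): %s\n",
              paste(object@kernel, collapse = ", ")))
  cat(sprintf("  valid voxels: %.1f%%; noise-corrected: %s\n",
              100 * mean(object@valid),
              isTRUE(object@provenance$noiseCorrected)))
})

setMethod("show", "EnFaceMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("EnFaceMap (%s, rule %s): %d x %d\n",
              object@kind, object@rule, d[1], d[2]))
  v <- object@values[!is.na(object@values)]
  if (length(v))
    cat(sprintf("  range %.4f .. %.4f, %d sentinel positions\n",
                min(v), max(v), sum(is.na(object@values))))
})

setMethod("show", "Delineation", function(object) {
  p <- object@points
  cat(sprintf("Delineation (%s): %d points, %d frame(s)\n",
              object@provenance, nrow(p),
              length(unique(p$frame))))
  if (nrow(p)) {
    tab <- table(p$label)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab),
                           collapse = ", "), "\n")
  }
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec (%s): grid %s, %.1f mm lateral, %.2f um/px, SNR %s dB\n",
              object@scene, paste(object@grid, collapse = " x "),
              object@lateralExtentMm, object@depthPitchUm,
              format(object@snrDb)))
  for (ly in object@layers)
    cat(sprintf("  layer %-16s depth [%s, %s) refl %.2f\n", ly@name,
                format(min(ly@top)), format(max(ly@bottom)),
                ly@reflectivity))
})

setMethod("show", "DensityMatrix", function(object) {
  ev <- sort(eigen(object@rho, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  cat(sprintf("DensityMatrix: n = %d samples, corrected = %s\n",
              object@nSamples, object@noiseCorrected))
  cat("  eigenvalues:", paste(sprintf("%.4f", pmax(ev, 0)), collapse = ", "),
      "\n")
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@layerMask)
  cat(sprintf("PhantomTruth: %d x %d x %d voxels, layers: %s\n",
              d[1], d[2], d[3], paste(object@layerNames, collapse = ", ")))
})
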