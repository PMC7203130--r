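#' @rdname accessors
#' @export
setGeneric("jonesData", function(x) standardGeneric("jonesData"))

#' @rdname accessors
#' @export
setGeneric("entropyValues", function(x) standardGeneric("entropyValues"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("delineationPoints", function(x) standardGeneric("delineationPoints"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("layerMask", function(x) standardGeneric("layerMask"))

#' @rdname accessors
#' @export
setGeneric("melaninField", function(x) standardGeneric("melaninField"))

#' @rdname accessors
#' @export
setGeneric("boundaryCurves", function(x) standardGeneric("boundaryCurves"))

#' @rdname accessors
#' @export
setGeneric("roiTruth", function(x) standardGeneric("roiTruth"))

#' @rdname accessors
#' @export
setGeneric("noiseVariance", function(x) standardGeneric("noiseVariance"))

#' Per-voxel backscatter intensity
#'
#' Intensity is the sum of squared moduli of the four Jones-matrix elements,
#' i.e. the squared Frobenius norm of the local Jones matrix.
#'
#' @param x a [JonesVolume-class].
#' @return numeric array `(frames, lateral, depth)`.
#' @export
setGeneric("intensityVolume", function(x) standardGeneric("intensityVolume"))
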