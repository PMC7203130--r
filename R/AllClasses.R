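#' @import methods
NULL

.LAYER_NAMES <- c("membrane", "cells_no_melanin", "rpe", "collagen",
                  "retina_inner", "choroid", "background")

.DELINEATION_LABELS <- c("membrane_top", "rpe", "graft", "atrophic")

#' LayerSpec: one tissue layer of a phantom scene
#'
#' Describes a single layer of a simulated sample: its depth extent, melanin
#' concentration, mean backscatter amplitude, deterministic birefringence and
#' (for the transwell membrane) a structural depolarization strength that is
#' independent of melanin.
#'
#' @slot name layer name; one of `membrane`, `cells_no_melanin`, `rpe`,
#'   `collagen`, `retina_inner`, `choroid`, `background`.
#' @slot top,bottom depth extent in voxel units (half-open `[top, bottom)`,
#'   0-based depth coordinate); either a scalar or a `n_frames x n_lateral`
#'   matrix for sloped/curved surfaces.
#' @slot melanin melanin concentration in `[0, 1]`; scalar or
#'   `n_frames x n_lateral` matrix.
#' @slot reflectivity mean backscatter amplitude (arbitrary linear units).
#' @slot birefringence deterministic retardance per depth voxel (radians).
#' @slot depolarizationStrength structural scrambling dispersion in `[0, 1]`
#'   applied regardless of melanin (porous membrane microstructure); 0 for
#'   ordinary tissue.
#' @slot smoothAmplitude amplitude (radians) of the smooth, spatially
#'   correlated retardance variation of non-melanin tissue.
#' @slot correlationLength correlation length (voxels) of that smooth
#'   variation; must be >= 5 so that melanin-free tissue stays locally uniform.
#' @export
setClass("LayerSpec",
  representation(name = "character", top = "ANY", bottom = "ANY",
                 melanin = "ANY", reflectivity = "numeric",
                 birefringence = "numeric",
                 depolarizationStrength = "numeric",
                 smoothAmplitude = "numeric", correlationLength = "numeric"))

setValidity("LayerSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !object@name %in% .LAYER_NAMES)
    msg <- c(msg, sprintf("layer name must be one of: %s",
                          paste(.LAYER_NAMES, collapse = ", ")))
  mel <- object@melanin
  if (any(!is.finite(mel)) || any(mel < 0) || any(mel > 1))
    msg <- c(msg, "melanin concentration must lie in [0, 1] everywhere")
  if (object@reflectivity < 0)
    msg <- c(msg, "reflectivity must be non-negative")
  if (object@depolarizationStrength < 0 || object@depolarizationStrength > 1)
    msg <- c(msg, "depolarizationStrength must lie in [0, 1]")
  if (object@correlationLength < 5)
    msg <- c(msg, "correlationLength must be >= 5 voxels")
  if (length(msg)) msg else TRUE
})

#' PhantomSpec: full description of a simulated PS-OCT acquisition
#'
#' @slot scene `"invitro"` (transwell preparation) or `"invivo"` (retina).
#' @slot grid integer vector `(n_frames, n_lateral, n_depth)`. The default
#'   retinal raster is 256 frames x 1024 A-scans over a 6 x 6 mm area.
#' @slot lateralExtentMm physical width of the raster (mm).
#' @slot depthPitchUm axial pixel pitch (micrometres / voxel).
#' @slot layers ordered list of [LayerSpec-class] objects; layers must not
#'   overlap in depth at any lateral position.
#' @slot snrDb per-volume detection signal-to-noise ratio (dB); `Inf`
#'   disables additive noise.
#' @slot seed integer RNG seed; identical spec (including seed) gives a
#'   bit-identical volume.
#' @export
setClass("PhantomSpec",
  representation(scene = "character", grid = "integer",
                 lateralExtentMm = "numeric", depthPitchUm = "numeric",
                 layers = "list", snrDb = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!object@scene %in% c("invitro", "invivo"))
    msg <- c(msg, "scene must be 'invitro' or 'invivo'")
  if (length(object@grid) != 3L || any(object@grid <= 0L))
    msg <- c(msg, "grid must be three positive voxel counts (frames, lateral, depth)")
  if (object@lateralExtentMm <= 0 || object@depthPitchUm <= 0)
    msg <- c(msg, "physical calibration must be positive")
  if (!all(vapply(object@layers, is, logical(1), "LayerSpec")))
    msg <- c(msg, "layers must be a list of LayerSpec objects")
  if (length(object@snrDb) != 1L || is.na(object@snrDb))
    msg <- c(msg, "snrDb must be a single finite value or Inf")
  if (length(msg)) msg else TRUE
})

#' JonesVolume: complex 2x2 Jones matrix per voxel
#'
#' The measured (or simulated) polarimetric response of the sample: one
#' complex 2x2 Jones matrix per voxel over a `(frame, lateral, depth)` raster,
#' stored as a complex array of dimension `(n_frames, n_lateral, n_depth, 2, 2)`.
#'
#' @slot data complex 5-D array as above.
#' @slot lateralExtentMm physical width of the raster (mm).
#' @slot depthPitchUm axial pixel pitch (micrometres / voxel).
#' @slot noiseVariance per-element additive circular Gaussian noise power;
#'   0 when noise-free, `NA` when unknown.
#' @slot seed integer seed used to generate the volume (`NA` for measured data).
#' @export
setClass("JonesVolume",
  representation(data = "array", lateralExtentMm = "numeric",
                 depthPitchUm = "numeric", noiseVariance = "numeric",
                 seed = "integer"))

setValidity("JonesVolume", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 5L || d[4] != 2L || d[5] != 2L)
    msg <- c(msg, "data must have dimension (frames, lateral, depth, 2, 2)")
  if (!is.complex(object@data))
    msg <- c(msg, "data must be a complex array")
  else if (anyNA(object@data) || any(!is.finite(Re(object@data))) ||
           any(!is.finite(Im(object@data))))
    msg <- c(msg, "all Jones matrix entries must be finite")
  if (length(msg)) msg else TRUE
})

#' DensityMatrix: local 4x4 coherency matrix
#'
#' The rank-4 density (coherency) matrix statistically accumulated from the
#' vectorized Jones matrices of a local window: Hermitian, positive
#' semi-definite, unit trace. Its eigenvalue spectrum carries the
#' Cloude-Pottier entropy.
#'
#' @slot rho complex 4x4 Hermitian matrix with unit trace.
#' @slot nSamples number of voxels averaged into the matrix.
#' @slot noiseCorrected has the additive-noise bias been subtracted?
#' @slot signalFree `TRUE` when the estimated noise power exceeded the total
#'   power and the matrix was forced to the maximally mixed state.
#' @export
setClass("DensityMatrix",
  representation(rho = "matrix", nSamples = "integer",
                 noiseCorrected = "logical", signalFree = "logical"),
  prototype(noiseCorrected = FALSE, signalFree = FALSE))

setValidity("DensityMatrix", function(object) {
  r <- object@rho
  msg <- character()
  if (!is.complex(r) || !identical(dim(r), c(4L, 4L)))
    msg <- c(msg, "rho must be a complex 4x4 matrix")
  else {
    sc <- max(abs(r), 1e-300)
    if (max(abs(r - Conj(t(r)))) > 1e-10 * sc)
      msg <- c(msg, "rho must be Hermitian (1e-10 relative tolerance)")
    tr <- Re(sum(diag(r)))
    if (abs(tr - 1) > 1e-10)
      msg <- c(msg, "rho must have unit trace (|trace - 1| < 1e-10)")
    ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10 * tr)
      msg <- c(msg, "rho must be positive semi-definite")
  }
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
  if (length(msg)) msg else TRUE
})

#' EntropyVolume: per-voxel polarimetric entropy
#'
#' @slot entropy numeric array `(frames, lateral, depth)`; values in `[0, 1]`
#'   where valid, `NA` sentinel elsewhere (never silently 0).
#' @slot valid logical array of the same shape; `FALSE` where the window had
#'   fewer than 4 samples or fell below the SNR floor.
#' @slot kernel integer halfwidths `(depth, lateral, frame)` of the averaging
#'   window.
#' @slot provenance list recording the correction settings
#'   (`noiseVariance`, `snrFloorDb`, `noiseCorrected`).
#' @export
setClass("EntropyVolume",
  representation(entropy = "array", valid = "array", kernel = "integer",
                 provenance = "list"))

setValidity("EntropyVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@entropy), dim(object@valid)))
    msg <- c(msg, "entropy and valid arrays must share dimensions")
  v <- object@entropy[object@valid]
  if (length(v) && (anyNA(v) || any(v < 0) || any(v > 1)))
    msg <- c(msg, "valid entropy values must lie in [0, 1]")
  iv <- object@entropy[!object@valid]
  if (length(iv) && !all(is.na(iv)))
    msg <- c(msg, "invalid voxels must carry the NA sentinel")
  if (length(object@kernel) != 3L || any(object@kernel < 0L))
    msg <- c(msg, "kernel must be three non-negative halfwidths")
  if (length(msg)) msg else TRUE
})

#' Delineation: per-(frame, lateral) boundary depth curves with labels
#'
#' Holds the boundary curves used to exclude depolarizing non-RPE structures
#' (transwell membrane, choroid) and to label segments of each B-scan as
#' intact RPE, atrophic, or graft. Indices are 0-based to match the on-disk
#' CSV interface; depth increases towards deeper voxels.
#'
#' @slot points `data.frame` with integer columns `frame`, `lateral`, `depth`
#'   and character column `label` (one of `membrane_top`, `rpe`, `graft`,
#'   `atrophic`); at most one row per `(frame, lateral, label)`.
#' @slot provenance `"auto"`, `"manual_file"` or `"phantom_truth"`.
#' @export
setClass("Delineation",
  representation(points = "data.frame", provenance = "character"))

setValidity("Delineation", function(object) {
  p <- object@points
  msg <- character()
  need <- c("frame", "lateral", "depth", "label")
  if (!all(need %in% names(p)))
    msg <- c(msg, "points must have columns frame, lateral, depth, label")
  else {
    if (nrow(p) && any(p$depth < 0 | p$frame < 0 | p$lateral < 0))
      msg <- c(msg, "indices must be non-negative (0-based)")
    if (nrow(p) && !all(p$label %in% .DELINEATION_LABELS))
      msg <- c(msg, sprintf("labels must be one of: %s",
                            paste(.DELINEATION_LABELS, collapse = ", ")))
    if (anyDuplicated(p[c("frame", "lateral", "label")]))
      msg <- c(msg, "at most one depth per (frame, lateral, label)")
  }
  if (!object@provenance %in% c("auto", "manual_file", "phantom_truth"))
    msg <- c(msg, "provenance must be auto, manual_file or phantom_truth")
  if (length(msg)) msg else TRUE
})

#' PhantomTruth: ground truth emitted alongside a simulated volume
#'
#' @slot layerMask integer array `(frames, lateral, depth)` of layer codes;
#'   0 is background, other codes index into `layerNames`.
#' @slot layerNames character vector naming the non-zero codes.
#' @slot melaninField numeric array of per-voxel melanin concentration.
#' @slot boundaryCurves exact [Delineation-class] for the membrane top
#'   (in vitro) or the RPE/graft/atrophic depth (in vivo).
#' @slot roiTruth `data.frame` of `(label, concentration)` pairs describing
#'   nominally homogeneous regions for parameter-recovery checks.
#' @export
setClass("PhantomTruth",
  representation(layerMask = "array", layerNames = "character",
                 melaninField = "array", boundaryCurves = "Delineation",
                 roiTruth = "data.frame"))

setValidity("PhantomTruth", function(object) {
  msg <- character()
  if (!identical(dim(object@layerMask), dim(object@melaninField)))
    msg <- c(msg, "layerMask and melaninField must share dimensions")
  # boundary curves must land inside the layer they name
  p <- object@boundaryCurves@points
  if (nrow(p)) {
    d <- dim(object@layerMask)
    if (any(p$frame >= d[1] | p$lateral >= d[2] | p$depth >= d[3]))
      msg <- c(msg, "boundary curve indices exceed volume bounds")
  }
  if (length(msg)) msg else TRUE
})

#' EnFaceMap: depth-projected 2-D map
#'
#' A 2-D image over `(frame, lateral)` produced by projecting entropy or
#' intensity along depth under a stated exclusion rule. Maps built under
#' different rules are not comparable, so the rule and its parameters travel
#' with the values.
#'
#' @slot values numeric `n_frames x n_lateral` matrix; `NA` sentinel where no
#'   valid voxel entered the projection (distinct from a true 0).
#' @slot kind `"entropy"` or `"intensity"`.
#' @slot rule `"max_above_boundary"`, `"band_at_delineation"` or
#'   `"full_depth_max"`.
#' @slot bandHalfwidth depth halfwidth (pixels) for the band rule.
#' @slot sourceIds list of provenance identifiers (volume seed, delineation
#'   provenance, ...).
#' @export
setClass("EnFaceMap",
  representation(values = "matrix", kind = "character", rule = "character",
                 bandHalfwidth = "integer", sourceIds = "list"))

setValidity("EnFaceMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("entropy", "intensity"))
    msg <- c(msg, "kind must be 'entropy' or 'intensity'")
  if (!object@rule %in% c("max_above_boundary", "band_at_delineation",
                          "full_depth_max"))
    msg <- c(msg, "unknown projection rule")
  if (object@kind == "entropy") {
    v <- object@values[!is.na(object@values)]
    if (length(v) && (any(v < 0) || any(v > 1)))
      msg <- c(msg, "entropy map values must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
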