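#' Construct a layer specification
#'
#' @param name layer name: one of `membrane`, `cells_no_melanin`, `rpe`,
#'   `collagen`, `retina_inner`, `choroid`, `background`.
#' @param top,bottom depth extent in voxels, half-open `[top, bottom)`
#'   (0-based depth index, increasing towards deeper voxels); scalars or
#'   `n_frames x n_lateral` matrices.
#' @param melanin melanin concentration in `[0, 1]`; scalar or matrix. The
#'   local scattering statistics of melanin-bearing voxels are scrambled with
#'   dispersion [melaninToScrambling]`(melanin)`.
#' @param reflectivity mean backscatter amplitude.
#' @param birefringence deterministic retardance per depth voxel (radians).
#' @param depolarizationStrength structural scrambling in `[0, 1]` applied
#'   regardless of melanin; use 1 for the porous transwell membrane, which
#'   depolarizes for structural rather than pigmentary reasons.
#' @param smoothAmplitude amplitude (radians) of the smooth spatial variation
#'   of the local retardance in non-scrambling tissue; set 0 for a perfectly
#'   homogeneous layer.
#' @param correlationLength correlation length (voxels, >= 5) of that smooth
#'   variation.
#' @return a [LayerSpec-class] object.
#' @export
layerSpec <- function(name, top, bottom, melanin = 0, reflectivity = 1,
                      birefringence = 0, depolarizationStrength = 0,
                      smoothAmplitude = 0.1, correlationLength = 8) {
  new("LayerSpec", name = name, top = top, bottom = bottom, melanin = melanin,
      reflectivity = reflectivity, birefringence = birefringence,
      depolarizationStrength = depolarizationStrength,
      smoothAmplitude = smoothAmplitude, correlationLength = correlationLength)
}

#' Construct a phantom acquisition specification
#'
#' The default grid mirrors the clinical raster: 256 B-scan frames of 1024
#' A-scans covering a 6 x 6 mm macular area, with an axial pitch of
#' 4.2 um/voxel (so that a 3-voxel band spans 12.6 um).
#'
#' @param scene `"invitro"` or `"invivo"`.
#' @param grid integer `(n_frames, n_lateral, n_depth)`.
#' @param lateralExtentMm physical raster width (mm).
#' @param depthPitchUm axial pixel pitch (um/voxel).
#' @param layers ordered list of [layerSpec] objects; must not overlap in
#'   depth anywhere.
#' @param snrDb per-volume detection SNR in dB; `Inf` for noise-free.
#' @param seed integer RNG seed.
#' @return a [PhantomSpec-class] object.
#' @export
phantomSpec <- function(scene = c("invivo", "invitro"),
                        grid = c(256L, 1024L, 64L),
                        lateralExtentMm = 6, depthPitchUm = 4.2,
                        layers = list(), snrDb = Inf, seed = 1L) {
  scene <- match.arg(scene)
  new("PhantomSpec", scene = scene, grid = as.integer(grid),
      lateralExtentMm = lateralExtentMm, depthPitchUm = depthPitchUm,
      layers = layers, snrDb = snrDb, seed = as.integer(seed))
}

#' Melanin concentration to polarization-scrambling dispersion
#'
#' Maps a melanin concentration in `[0, 1]` to the dispersion (radians) of
#' the per-voxel random retardance draws of the simulator. The map is the
#' simplest monotone choice: linear, `0` at concentration 0 (melanin-free
#' tissue must not scramble) and saturating at `pi` for concentration 1,
#' where the retardance magnitude is drawn uniformly on `[0, pi]` with a
#' uniformly random axis on the Poincare sphere (completely random
#' polarization).
#'
#' @param concentration numeric vector in `[0, 1]`.
#' @return retardance dispersion in radians, same length as the input.
#' @export
melaninToScrambling <- function(concentration) {
  if (any(!is.finite(concentration)) || any(concentration < 0) ||
      any(concentration > 1))
    stop("melanin concentration must lie in [0, 1]")
  pi * concentration
}

# Random elliptical retarder / diattenuator elements, vectorized over voxels.
# Retarder R = cos(d/2) I - i sin(d/2) (n . sigma) with axis n on the unit
# sphere; diattenuator D = a I + b (n . sigma) with eigenvalues sqrt(1 +/- dia).
# Returns the four elements of the 2x2 product matrix M = R %*% D.
.randomScatterElements <- function(m, scale) {
  # axis uniform on the sphere
  z <- stats::runif(m, -1, 1)
  phi <- stats::runif(m, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  n1 <- r * cos(phi); n2 <- r * sin(phi); n3 <- z
  delta <- scale * stats::runif(m)              # retardance in [0, scale]
  dia <- (scale / pi) * 0.3 * stats::runif(m)   # bounded diattenuation
  cR <- cos(delta / 2); sR <- sin(delta / 2)
  R11 <- complex(real = cR, imaginary = -sR * n1)
  R12 <- complex(real = -sR * n3, imaginary = -sR * n2)
  R21 <- complex(real = sR * n3, imaginary = -sR * n2)
  R22 <- complex(real = cR, imaginary = sR * n1)
  a <- (sqrt(1 + dia) + sqrt(1 - dia)) / 2
  b <- (sqrt(1 + dia) - sqrt(1 - dia)) / 2
  D11 <- a + b * n1; D12 <- b * complex(real = n2, imaginary = -n3)
  D21 <- b * complex(real = n2, imaginary = n3); D22 <- a - b * n1
  list(e11 = R11 * D11 + R12 * D21, e12 = R11 * D12 + R12 * D22,
       e21 = R21 * D11 + R22 * D21, e22 = R21 * D12 + R22 * D22)
}

# Smooth (spatially correlated) retarder about a fixed axis; d is the
# per-voxel retardance vector.
.smoothRetarderElements <- function(d) {
  cR <- cos(d / 2); sR <- sin(d / 2)
  # fixed axis (0, 1, 0): R = [[c, -i s], [-i s, c]]
  list(e11 = complex(real = cR), e12 = complex(imaginary = -sR),
       e21 = complex(imaginary = -sR), e22 = complex(real = cR))
}

#' Simulate a Jones-matrix PS-OCT volume with known ground truth
#'
#' Builds a seeded phantom volume voxel by voxel as
#' `J = B(z) S_local * amplitude`, where `B(z)` is the cumulative
#' deterministic birefringence accumulated along the A-scan, `S_local` is the
#' local scattering matrix, and the amplitude is
#' `reflectivity x fully-developed speckle` (one circular complex Gaussian
#' factor per voxel, shared across the four matrix elements so that speckle
#' alone never depolarizes). In melanin-bearing voxels the local scattering
#' matrix's retardance axis, magnitude, and diattenuation are drawn i.i.d.
#' per voxel with dispersion [melaninToScrambling]`(concentration)`; the
#' transwell membrane uses maximal dispersion regardless of melanin; all
#' other tissue varies smoothly (correlation length >= 5 voxels).
#'
#' @param spec a [phantomSpec].
#' @return `list(volume = JonesVolume, truth = PhantomTruth)`.
#' @export
buildPhantom <- function(spec) {
  validObject(spec)
  for (ly in spec@layers) validObject(ly)
  nf <- spec@grid[1]; nl <- spec@grid[2]; nd <- spec@grid[3]
  nvox <- as.double(nf) * nl * nd
  if (nvox <= 0) stop("zero-size grid")

  .withSeed(spec@seed, {
    e11 <- e12 <- e21 <- e22 <- array(0 + 0i, dim = c(nf, nl, nd))
    mask <- array(0L, dim = c(nf, nl, nd))
    mel <- array(0, dim = c(nf, nl, nd))
    birefVox <- array(0, dim = c(nf, nl, nd))

    layerNames <- vapply(spec@layers, function(l) l@name, character(1))
    segMatrix <- NULL   # per-(frame, lateral) segment labels from rpe layer

    for (li in seq_along(spec@layers)) {
      ly <- spec@layers[[li]]
      top <- .expandField(ly@top, nf, nl, sprintf("layer '%s' top", ly@name))
      bot <- .expandField(ly@bottom, nf, nl, sprintf("layer '%s' bottom", ly@name))
      conc <- .expandField(ly@melanin, nf, nl,
                           sprintf("layer '%s' melanin", ly@name))
      if (any(bot < top)) stop(sprintf("layer '%s': bottom above top", ly@name))
      # voxel membership: depth d (0-based) occupied iff top <= d < bottom
      inLayer <- array(FALSE, dim = c(nf, nl, nd))
      for (d in seq_len(nd) - 1L)
        inLayer[, , d + 1L] <- top <= d & d < bot
      idx <- which(inLayer)
      if (!length(idx)) next
      clash <- mask[idx] != 0L
      if (any(clash))
        stop(sprintf("layers overlap in depth: '%s' and '%s'",
                     layerNames[mask[idx][clash][1]], ly@name))
      mask[idx] <- li
      # melanin per voxel: replicate the (frame, lateral) field along depth
      concVox <- array(rep(conc, nd), dim = c(nf, nl, nd))
      mel[idx] <- concVox[idx]
      birefVox[idx] <- ly@birefringence

      m <- length(idx)
      # dispersion: melanin link, overridden upward by structural scrambling
      sVox <- pmax(melaninToScrambling(concVox[idx]),
                   pi * ly@depolarizationStrength)

      # smooth spatially correlated component (always drawn, for determinism)
      smooth <- if (ly@smoothAmplitude > 0)
        ly@smoothAmplitude * .smoothField3(nf, nl, nd, ly@correlationLength)
      else array(0, dim = c(nf, nl, nd))
      sm <- .smoothRetarderElements(smooth[idx])

      # per-voxel i.i.d. scattering draws (identity where dispersion is 0)
      rs <- .randomScatterElements(m, sVox)

      # S = R_smooth %*% R_random D_random
      s11 <- sm$e11 * rs$e11 + sm$e12 * rs$e21
      s12 <- sm$e11 * rs$e12 + sm$e12 * rs$e22
      s21 <- sm$e21 * rs$e11 + sm$e22 * rs$e21
      s22 <- sm$e21 * rs$e12 + sm$e22 * rs$e22

      # amplitude: reflectivity x fully developed speckle (shared factor)
      amp <- ly@reflectivity *
        complex(real = stats::rnorm(m), imaginary = stats::rnorm(m)) / sqrt(2)

      e11[idx] <- amp * s11; e12[idx] <- amp * s12
      e21[idx] <- amp * s21; e22[idx] <- amp * s22

      if (ly@name == "rpe" && is.null(segMatrix)) {
        segAttr <- attr(ly@melanin, "segment")
        segMatrix <- if (!is.null(segAttr)) segAttr
        else matrix(ifelse(conc < 0.05, "atrophic", "rpe"), nf, nl)
      }
    }

    # cumulative deterministic birefringence along depth (diagonal linear
    # retarder, axis fixed): J <- B(z) S
    cumBiref <- aperm(apply(birefVox, c(1, 2), cumsum), c(2, 3, 1))
    phase <- exp(complex(imaginary = -cumBiref / 2))
    e11 <- e11 * phase; e12 <- e12 * phase
    e21 <- e21 * Conj(phase); e22 <- e22 * Conj(phase)

    data <- array(0 + 0i, dim = c(nf, nl, nd, 2, 2))
    data[, , , 1, 1] <- e11; data[, , , 1, 2] <- e12
    data[, , , 2, 1] <- e21; data[, , , 2, 2] <- e22

    noiseVar <- 0
    if (is.finite(spec@snrDb)) {
      meanPower <- mean(Mod(data)^2)
      noiseVar <- meanPower / 10^(spec@snrDb / 10)
      data <- .addNoiseCore(data, noiseVar)
    }

    volume <- new("JonesVolume", data = data,
                  lateralExtentMm = spec@lateralExtentMm,
                  depthPitchUm = spec@depthPitchUm,
                  noiseVariance = noiseVar, seed = spec@seed)

    truth <- .phantomTruth(spec, mask, layerNames, mel, segMatrix)
    list(volume = volume, truth = truth)
  })
}

# Exact boundary curves and ROI truth from the layer geometry.
.phantomTruth <- function(spec, mask, layerNames, mel, segMatrix) {
  nf <- spec@grid[1]; nl <- spec@grid[2]
  pts <- list()
  if (spec@scene == "invitro") {
    mi <- which(layerNames == "membrane")[1]
    if (!is.na(mi)) {
      ly <- spec@layers[[mi]]
      top <- .expandField(ly@top, nf, nl, "membrane top")
      pts[[length(pts) + 1L]] <- data.frame(
        frame = rep(seq_len(nf) - 1L, nl),
        lateral = rep(seq_len(nl) - 1L, each = nf),
        depth = as.integer(top), label = "membrane_top")
    }
  } else {
    ri <- which(layerNames == "rpe")[1]
    if (!is.na(ri)) {
      ly <- spec@layers[[ri]]
      top <- .expandField(ly@top, nf, nl, "rpe top")
      bot <- .expandField(ly@bottom, nf, nl, "rpe bottom")
      centre <- floor((top + bot - 1) / 2)   # half rounds shallower
      lab <- if (!is.null(segMatrix)) segMatrix else matrix("rpe", nf, nl)
      pts[[length(pts) + 1L]] <- data.frame(
        frame = rep(seq_len(nf) - 1L, nl),
        lateral = rep(seq_len(nl) - 1L, each = nf),
        depth = as.integer(centre), label = as.character(lab))
    }
  }
  points <- if (length(pts)) do.call(rbind, pts)
  else data.frame(frame = integer(), lateral = integer(),
                  depth = integer(), label = character())
  curves <- new("Delineation", points = points, provenance = "phantom_truth")

  roiTruth <- if (!is.null(segMatrix)) {
    rpeConc <- matrix(0, nf, nl)
    ri <- which(layerNames == "rpe")[1]
    if (!is.na(ri))
      rpeConc <- .expandField(spec@layers[[ri]]@melanin, nf, nl, "rpe melanin")
    do.call(rbind, lapply(unique(as.character(segMatrix)), function(lb) {
      data.frame(label = lb,
                 concentration = mean(rpeConc[segMatrix == lb]))
    }))
  } else data.frame(label = character(), concentration = numeric())

  new("PhantomTruth", layerMask = mask, layerNames = layerNames,
      melaninField = mel, boundaryCurves = curves, roiTruth = roiTruth)
}

# Add circular complex Gaussian noise of per-element variance sigma2 using
# the current RNG stream.
.addNoiseCore <- function(data, sigma2) {
  n <- length(data)
  data + complex(real = stats::rnorm(n, sd = sqrt(sigma2 / 2)),
                 imaginary = stats::rnorm(n, sd = sqrt(sigma2 / 2)))
}

#' Add detection noise to a Jones-matrix volume
#'
#' Adds i.i.d. circular complex Gaussian noise independently to each of the
#' four matrix elements, scaled so that the volume's mean per-element signal
#' power divided by the per-element noise power equals the requested SNR.
#' The exact noise variance is recorded in the volume metadata and is used
#' downstream as the known noise covariance by the bias correction.
#'
#' @param volume a [JonesVolume-class].
#' @param snrDb target SNR in dB; `Inf` returns the input unchanged.
#' @param seed integer RNG seed.
#' @return a [JonesVolume-class] with noise added and
#'   `noiseVariance` set.
#' @export
applyNoise <- function(volume, snrDb, seed = 1L) {
  stopifnot(is(volume, "JonesVolume"))
  if (is.infinite(snrDb)) return(volume)
  meanPower <- mean(Mod(volume@data)^2)
  sigma2 <- meanPower / 10^(snrDb / 10)
  .withSeed(seed, {
    new("JonesVolume", data = .addNoiseCore(volume@data, sigma2),
        lateralExtentMm = volume@lateralExtentMm,
        depthPitchUm = volume@depthPitchUm,
        noiseVariance = sigma2 + max(0, volume@noiseVariance, na.rm = TRUE),
        seed = volume@seed)
  })
}

#' Standard in vitro transwell scene
#'
#' A cultured-cell preparation on a porous transwell insert: a cell layer
#' (melanin-free control or pigmented RPE) resting on the intrinsically
#' depolarizing membrane, mimicking the stereotypical transwell B-scan: low
#' entropy cells over a bright, high-entropy membrane band.
#'
#' @param grid `(frames, lateral, depth)` voxel counts.
#' @param cellMelanin scalar or `frames x lateral` matrix of melanin
#'   concentration for the cell layer; 0 gives a melanin-free control layer.
#' @param cellTop,cellBottom,membraneTop,membraneBottom depth extents (voxels).
#' @param snrDb detection SNR (dB).
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
invitroPhantomSpec <- function(grid = c(8L, 128L, 64L), cellMelanin = 0,
                               cellTop = 14, cellBottom = 26,
                               membraneTop = 28, membraneBottom = 40,
                               snrDb = Inf, seed = 1L) {
  cellName <- if (all(cellMelanin == 0)) "cells_no_melanin" else "rpe"
  layers <- list(
    layerSpec(cellName, top = cellTop, bottom = cellBottom,
              melanin = cellMelanin, reflectivity = 0.8),
    layerSpec("membrane", top = membraneTop, bottom = membraneBottom,
              melanin = 0, reflectivity = 1.5, depolarizationStrength = 1))
  phantomSpec("invitro", grid = grid, layers = layers, snrDb = snrDb,
              seed = seed)
}

#' Standard in vivo retina scene with atrophy and an optional graft
#'
#' A parametric macular scene: inner retina over a thin melanin-bearing RPE
#' band over a depolarizing, melanin-rich choroid. A central disc of the RPE
#' is atrophic (melanin 0); optionally a smaller concentric disc carries a
#' transplanted RPE sheet (graft) with its own melanin concentration. The
#' ground-truth delineation labels each A-scan `rpe`, `atrophic` or `graft`.
#'
#' @param grid `(frames, lateral, depth)` voxel counts.
#' @param rpeMelanin intact-RPE melanin concentration.
#' @param atrophyRadiusFrac radius of the atrophic disc as a fraction of the
#'   lateral extent (0 disables).
#' @param graftRadiusFrac radius of the graft disc (0 disables; must be
#'   smaller than the atrophy radius).
#' @param graftMelanin graft melanin concentration.
#' @param rpeTop depth (voxels) of the RPE band top; the band is 3 voxels
#'   thick (12.6 um at the default pitch).
#' @param rpeThickness RPE band thickness in voxels.
#' @param snrDb detection SNR (dB).
#' @param seed RNG seed.
#' @return a [PhantomSpec-class].
#' @export
invivoPhantomSpec <- function(grid = c(16L, 192L, 72L), rpeMelanin = 0.8,
                              atrophyRadiusFrac = 0.3, graftRadiusFrac = 0,
                              graftMelanin = 0.8, rpeTop = 36,
                              rpeThickness = 3, snrDb = Inf, seed = 1L) {
  nf <- grid[1]; nl <- grid[2]
  fx <- (seq_len(nf) - (nf + 1) / 2) / nf
  lx <- (seq_len(nl) - (nl + 1) / 2) / nl
  rr <- sqrt(outer(fx^2, lx^2, `+`))
  conc <- matrix(rpeMelanin, nf, nl)
  seg <- matrix("rpe", nf, nl)
  if (atrophyRadiusFrac > 0) {
    conc[rr < atrophyRadiusFrac] <- 0
    seg[rr < atrophyRadiusFrac] <- "atrophic"
  }
  if (graftRadiusFrac > 0) {
    conc[rr < graftRadiusFrac] <- graftMelanin
    seg[rr < graftRadiusFrac] <- "graft"
  }
  attr(conc, "segment") <- seg
  rpeBot <- rpeTop + rpeThickness
  layers <- list(
    layerSpec("retina_inner", top = 4, bottom = rpeTop, melanin = 0,
              reflectivity = 0.5, birefringence = 0.002),
    layerSpec("rpe", top = rpeTop, bottom = rpeBot, melanin = conc,
              reflectivity = 1.0),
    layerSpec("choroid", top = rpeBot + 2, bottom = grid[3] - 2,
              melanin = 0.9, reflectivity = 0.9))
  phantomSpec("invivo", grid = grid, layers = layers, snrDb = snrDb,
              seed = seed)
}

#' Render a synthetic grey-scale pigmentation photograph
#'
#' Renders the stand-in for the registered grey-scale photograph of a
#' cultured RPE sheet: grey value `255 x (1 - concentration)` plus bounded
#' Gaussian noise, clipped to `[0, 255]`, so that darker pixels mean more
#' pigment (higher grey = less pigmentation).
#'
#' @param concentration `frames x lateral` matrix of melanin concentration.
#' @param noiseSd Gaussian noise standard deviation in grey levels.
#' @param seed RNG seed.
#' @return numeric matrix of grey values in `[0, 255]`.
#' @export
renderPigmentPhoto <- function(concentration, noiseSd = 5, seed = 1L) {
  stopifnot(is.matrix(concentration))
  .withSeed(seed, {
    g <- 255 * (1 - concentration) +
      stats::rnorm(length(concentration), sd = noiseSd)
    matrix(pmin(255, pmax(0, g)), nrow(concentration), ncol(concentration))
  })
}
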