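#' Write / read a Jones-matrix volume as a float TIFF container
#'
#' The on-disk container is a multi-page 32-bit float TIFF: for each frame,
#' eight `lateral x depth` pages in fixed order (real parts of J11, J12,
#' J21, J22, then the four imaginary parts). TIFF float samples are stored
#' on the `[0, 1]` scale, so the pages hold `(x - lo) / (hi - lo)` with the
#' affine range `(lo, hi)` recorded — together with the grid and calibration
#' metadata `{lateral_extent_mm, depth_pitch_um, noise_variance, seed}` — in
#' a JSON sidecar (`<path>.json`). `readJonesVolume(writeJonesVolume(v))`
#' round-trips the volume to within float32 precision of the dynamic range.
#'
#' @param volume a [JonesVolume-class].
#' @param path TIFF file path.
#' @return `path` (write) or a [JonesVolume-class] (read).
#' @export
writeJonesVolume <- function(volume, path) {
  stopifnot(is(volume, "JonesVolume"))
  d <- dim(volume@data)
  lo <- min(Re(volume@data), Im(volume@data))
  hi <- max(Re(volume@data), Im(volume@data))
  if (hi <= lo) hi <- lo + 1
  pages <- vector("list", d[1] * 8L)
  n <- 0L
  order <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (f in seq_len(d[1])) {
    for (part in c("re", "im")) {
      for (ij in order) {
        n <- n + 1L
        plane <- volume@data[f, , , ij[1], ij[2]]
        plane <- if (part == "re") Re(plane) else Im(plane)
        pages[[n]] <- (plane - lo) / (hi - lo)
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(lo = lo, hi = hi,
               n_frames = d[1], n_lateral = d[2], n_depth = d[3],
               lateral_extent_mm = volume@lateralExtentMm,
               depth_pitch_um = volume@depthPitchUm,
               noise_variance = volume@noiseVariance,
               seed = volume@seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeJonesVolume
#' @export
readJonesVolume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  nf <- meta$n_frames; nl <- meta$n_lateral; nd <- meta$n_depth
  if (length(pages) != nf * 8L)
    stop("TIFF page count does not match the sidecar grid")
  data <- array(0 + 0i, dim = c(nf, nl, nd, 2, 2))
  order <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  n <- 0L
  for (f in seq_len(nf)) {
    re <- list(); im <- list()
    for (part in c("re", "im")) {
      for (e in 1:4) {
        n <- n + 1L
        if (part == "re") re[[e]] <- pages[[n]] else im[[e]] <- pages[[n]]
      }
    }
    for (e in 1:4) {
      ij <- order[[e]]
      data[f, , , ij[1], ij[2]] <- complex(
        real = re[[e]] * (meta$hi - meta$lo) + meta$lo,
        imaginary = im[[e]] * (meta$hi - meta$lo) + meta$lo)
    }
  }
  new("JonesVolume", data = data, lateralExtentMm = meta$lateral_extent_mm,
      depthPitchUm = meta$depth_pitch_um,
      noiseVariance = meta$noise_variance,
      seed = as.integer(meta$seed))
}

#' Write phantom ground truth alongside a simulated volume
#'
#' Writes the layer mask as an unsigned-integer TIFF (one page per frame),
#' the melanin field as a float TIFF, the exact boundary curves as the
#' delineation CSV, and the layer names plus ROI truth as JSON.
#'
#' @param truth a [PhantomTruth-class].
#' @param prefix output path prefix; files `<prefix>_mask.tif`,
#'   `<prefix>_melanin.tif`, `<prefix>_curves.csv`, `<prefix>_truth.json`
#'   are created.
#' @return `prefix`, invisibly.
#' @export
writePhantomTruth <- function(truth, prefix) {
  stopifnot(is(truth, "PhantomTruth"))
  d <- dim(truth@layerMask)
  maskPages <- lapply(seq_len(d[1]), function(f)
    truth@layerMask[f, , ] / 255)  # 8-bit code channel
  tiff::writeTIFF(maskPages, paste0(prefix, "_mask.tif"),
                  bits.per.sample = 8L, reduce = FALSE)
  melPages <- lapply(seq_len(d[1]), function(f) truth@melaninField[f, , ])
  tiff::writeTIFF(melPages, paste0(prefix, "_melanin.tif"),
                  bits.per.sample = 32L, reduce = FALSE)
  writeDelineation(truth@boundaryCurves, paste0(prefix, "_curves.csv"))
  jsonlite::write_json(list(layer_names = truth@layerNames,
                            roi_truth = truth@roiTruth),
                       paste0(prefix, "_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read / write a phantom specification as a YAML config
#'
#' The config mirrors [phantomSpec]: top-level keys `scene`, `grid`,
#' `lateral_extent_mm`, `depth_pitch_um`, `snr_db`, `seed` and a `layers`
#' list whose entries carry the [layerSpec] fields (`name`, `top`, `bottom`,
#' `melanin`, `reflectivity`, `birefringence`, `depolarization_strength`,
#' `smooth_amplitude`, `correlation_length`). Matrix-valued fields are not
#' representable in the flat config and must be built in code.
#'
#' @param path YAML file path.
#' @return `readPhantomSpec` returns a [PhantomSpec-class];
#'   `writePhantomSpec` returns `path` invisibly.
#' @export
readPhantomSpec <- function(path) {
  cfg <- yaml::read_yaml(path)
  layers <- lapply(cfg$layers, function(l)
    layerSpec(l$name, top = l$top, bottom = l$bottom,
              melanin = l$melanin %||% 0,
              reflectivity = l$reflectivity %||% 1,
              birefringence = l$birefringence %||% 0,
              depolarizationStrength = l$depolarization_strength %||% 0,
              smoothAmplitude = l$smooth_amplitude %||% 0.1,
              correlationLength = l$correlation_length %||% 8))
  phantomSpec(cfg$scene, grid = unlist(cfg$grid),
              lateralExtentMm = cfg$lateral_extent_mm %||% 6,
              depthPitchUm = cfg$depth_pitch_um %||% 4.2,
              layers = layers, snrDb = cfg$snr_db %||% Inf,
              seed = cfg$seed %||% 1L)
}

#' @rdname readPhantomSpec
#' @param spec a [PhantomSpec-class] with scalar layer fields.
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  layers <- lapply(spec@layers, function(l) {
    if (is.matrix(l@top) || is.matrix(l@bottom) || is.matrix(l@melanin))
      stop("matrix-valued layer fields are not representable in the config")
    list(name = l@name, top = l@top, bottom = l@bottom, melanin = l@melanin,
         reflectivity = l@reflectivity, birefringence = l@birefringence,
         depolarization_strength = l@depolarizationStrength,
         smooth_amplitude = l@smoothAmplitude,
         correlation_length = l@correlationLength)
  })
  yaml::write_yaml(list(scene = spec@scene, grid = as.list(spec@grid),
                        lateral_extent_mm = spec@lateralExtentMm,
                        depth_pitch_um = spec@depthPitchUm,
                        snr_db = if (is.finite(spec@snrDb)) spec@snrDb
                        else ".inf",
                        seed = spec@seed, layers = layers), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write ROI definitions as JSON
#'
#' The ROI JSON is a list of objects: en face rectangles
#' `{label, space: "enface", units: "px"|"mm", rect: [r0, c0, r1, c1]}`
#' (half-open, 0-based) and B-scan strips
#' `{label, space: "bscan", strip: {frame, lateral_centre, width_px,
#' depth_px}}`.
#'
#' @param path JSON file path.
#' @return `readRoiJson` returns a list of `ROI` objects; `writeRoiJson`
#'   returns `path` invisibly.
#' @export
readRoiJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r) {
    if (identical(r$space, "enface"))
      roiRect(r$label, unlist(r$rect), units = r$units %||% "px")
    else if (identical(r$space, "bscan"))
      roiStrip(r$label, r$strip$frame, r$strip$lateral_centre,
               widthPx = r$strip$width_px %||% 100L,
               depthPx = r$strip$depth_px %||% 3L)
    else stop("ROI space must be 'enface' or 'bscan'")
  })
}

#' @rdname readRoiJson
#' @param rois list of `ROI` objects.
#' @export
writeRoiJson <- function(rois, path) {
  out <- lapply(rois, function(r) {
    if (r$space == "enface")
      list(label = r$label, space = "enface", units = r$units,
           rect = r$rect)
    else
      list(label = r$label, space = "bscan",
           strip = list(frame = r$frame, lateral_centre = r$lateralCentre,
                        width_px = r$widthPx, depth_px = r$depthPx))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an 8-bit grey-scale photograph
#'
#' Reads a PNG or TIFF photograph and returns grey values in `[0, 255]`;
#' colour images are converted with the Rec. 601 luma weights.
#'
#' @param path PNG or TIFF file path.
#' @return numeric matrix of grey values.
#' @export
readGreyPhoto <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L)
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img <- img[, , 1]
  }
  img * 255
}
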