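#' Convert a pixel count to micrometres along the raster
#'
#' `n_pixels x (extent_mm x 1000 / n_samples_across)`, rounded to the nearest
#' micrometre. For the clinical raster (6 mm sampled by 1024 A-scans), 100
#' lateral pixels convert to 586 um.
#'
#' @param nPixels number of pixels.
#' @param extentMm physical extent covered by the raster (mm).
#' @param nSamplesAcross number of samples across that extent.
#' @return extent in micrometres (integer-valued numeric).
#' @export
roiExtentUm <- function(nPixels, extentMm, nSamplesAcross) {
  stopifnot(nPixels >= 0, extentMm > 0)
  if (nSamplesAcross <= 0) stop("nSamplesAcross must be positive")
  round(nPixels * extentMm * 1000 / nSamplesAcross)
}

#' Define regions of interest
#'
#' `roiRect` defines an en face rectangle in pixel or millimetre units
#' (half-open `[r0, r1) x [c0, c1)`, 0-based); `roiStrip` defines a B-scan
#' measurement strip of `widthPx x depthPx` pixels (default 100 x 3,
#' i.e. 586 x 12.6 um on the clinical raster) centred at a lateral position
#' and a delineated depth.
#'
#' @param label ROI label.
#' @param rect numeric `(r0, c0, r1, c1)`.
#' @param units `"px"` or `"mm"` (millimetres are converted with the map's
#'   calibration at evaluation time).
#' @return a list of class `ROI`.
#' @export
roiRect <- function(label, rect, units = c("px", "mm")) {
  units <- match.arg(units)
  stopifnot(length(rect) == 4L, rect[3] > rect[1], rect[4] > rect[2])
  structure(list(label = label, space = "enface", units = units,
                 rect = as.numeric(rect)), class = "ROI")
}

#' @rdname roiRect
#' @param frame B-scan frame index (0-based).
#' @param lateralCentre lateral centre pixel (0-based).
#' @param widthPx,depthPx strip size in pixels.
#' @export
roiStrip <- function(label, frame, lateralCentre, widthPx = 100L,
                     depthPx = 3L) {
  stopifnot(widthPx > 0, depthPx > 0)
  structure(list(label = label, space = "bscan", frame = as.integer(frame),
                 lateralCentre = as.integer(lateralCentre),
                 widthPx = as.integer(widthPx), depthPx = as.integer(depthPx)),
            class = "ROI")
}

# Resolve an en face rect ROI to 1-based row/col index vectors.
.resolveRect <- function(roi, nrow, ncol, extentMm = NULL) {
  r <- roi$rect
  if (roi$units == "mm") {
    if (is.null(extentMm)) stop("mm ROI requires the map's physical extent")
    pxPerMm <- ncol / extentMm      # lateral sampling density
    r <- r * pxPerMm
  }
  r0 <- floor(r[1]) + 1L; c0 <- floor(r[2]) + 1L
  r1 <- ceiling(r[3]); c1 <- ceiling(r[4])
  if (r0 < 1L || c0 < 1L || r1 > nrow || c1 > ncol)
    stop(sprintf("ROI '%s' falls outside the image bounds", roi$label))
  list(rows = r0:r1, cols = c0:c1)
}

#' Grey-scale pigmentation statistics in a photograph ROI
#'
#' Mean and population standard deviation of 8-bit grey values over the
#' photograph pixels of an en face ROI, the degree-of-pigmentation read-out
#' (a higher mean means less pigmentation). The manual registration of the
#' photograph to the en face grid is replaced by an explicit affine map from
#' en face `(row, col)` pixel coordinates to photograph coordinates:
#' `photo = A %*% c(row, col) + b` with nearest-pixel lookup. The identity
#' map (the default) is appropriate for phantom-rendered photographs.
#'
#' @param photo numeric matrix of grey values in `[0, 255]`.
#' @param roi an en face [roiRect].
#' @param registration `list(A = 2x2 matrix, b = length-2 offset)`.
#' @param extentMm physical extent for mm-unit ROIs.
#' @return one-row `data.frame` with `label`, `metric`, `n_pixels`, `mean`,
#'   `sd`, `median`, `skewness`.
#' @export
greyRoiStats <- function(photo, roi,
                         registration = list(A = diag(2), b = c(0, 0)),
                         extentMm = NULL) {
  stopifnot(is.matrix(photo), inherits(roi, "ROI"), roi$space == "enface")
  px <- .resolveRect(roi, nrow(photo), ncol(photo), extentMm)
  grid <- as.matrix(expand.grid(row = px$rows, col = px$cols))
  mapped <- t(registration$A %*% t(grid - 1)) +
    matrix(registration$b, nrow(grid), 2, byrow = TRUE)  # 0-based affine
  ri <- round(mapped[, 1]) + 1L
  ci <- round(mapped[, 2]) + 1L
  if (any(ri < 1L | ri > nrow(photo) | ci < 1L | ci > ncol(photo)))
    stop(sprintf("ROI '%s' maps outside the photograph", roi$label))
  v <- photo[cbind(ri, ci)]
  data.frame(label = roi$label, metric = "grey", n_pixels = length(v),
             mean = mean(v), sd = .popSd(v), median = stats::median(v),
             skewness = .skewness(v))
}

#' Entropy statistics in a region of interest
#'
#' Mean and population standard deviation of entropy over the valid pixels
#' of an ROI, taken either from an en face map (rectangle ROI) or from an
#' entropy B-scan (strip ROI centred at a delineated depth). Sentinel (`NA`)
#' pixels are excluded and their count reported; an ROI with no valid pixel
#' is an error. Median and skewness are reported alongside so that the
#' symmetry assumption behind using the mean as the representative value can
#' be checked.
#'
#' @param x an [EnFaceMap-class] (for rectangle ROIs) or an
#'   [EntropyVolume-class] (for strip ROIs).
#' @param roi a [roiRect] or [roiStrip].
#' @param depthCentre 0-based depth at which a strip ROI is centred
#'   (typically the delineated depth); required for strip ROIs.
#' @param extentMm physical extent for mm-unit rectangle ROIs (defaults to
#'   6 mm rasters when omitted).
#' @return one-row `data.frame` with `label`, `metric`, `n_pixels`,
#'   `n_excluded`, `mean`, `sd`, `median`, `skewness`.
#' @export
entropyRoiStats <- function(x, roi, depthCentre = NULL, extentMm = NULL) {
  stopifnot(inherits(roi, "ROI"))
  if (roi$space == "enface") {
    stopifnot(is(x, "EnFaceMap"))
    m <- x@values
    px <- .resolveRect(roi, nrow(m), ncol(m), extentMm)
    v <- as.vector(m[px$rows, px$cols])
  } else {
    stopifnot(is(x, "EntropyVolume"), !is.null(depthCentre))
    e <- x@entropy
    hw <- (roi$widthPx - 1L) %/% 2L
    hd <- (roi$depthPx - 1L) %/% 2L
    lat <- (roi$lateralCentre - hw):(roi$lateralCentre + (roi$widthPx - 1L - hw))
    dep <- (depthCentre - hd):(depthCentre + (roi$depthPx - 1L - hd))
    if (roi$frame < 0L || roi$frame >= dim(e)[1] ||
        min(lat) < 0L || max(lat) >= dim(e)[2] ||
        min(dep) < 0L || max(dep) >= dim(e)[3])
      stop(sprintf("strip ROI '%s' falls outside the volume", roi$label))
    v <- as.vector(e[roi$frame + 1L, lat + 1L, dep + 1L])
  }
  nExcluded <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (!length(v))
    stop(sprintf("ROI '%s' contains no valid pixel", roi$label))
  data.frame(label = roi$label, metric = "entropy", n_pixels = length(v),
             n_excluded = nExcluded, mean = mean(v), sd = .popSd(v),
             median = stats::median(v), skewness = .skewness(v))
}

#' Relation between pigmentation and entropy over paired ROIs
#'
#' Pearson correlation between the mean grey values (degree of absence of
#' pigmentation) and the mean entropies of paired ROIs. For pigment-driven
#' scrambling the expected relation is inverse: whiter regions carry less
#' melanin and lower entropy. Degenerate inputs (zero variance in either
#' variable) are flagged rather than raising an error.
#'
#' @param greyStats `data.frame` of [greyRoiStats] rows.
#' @param entropyStats `data.frame` of [entropyRoiStats] rows, in the same
#'   ROI order.
#' @return list with `correlation`, `sign` (`"negative"`, `"positive"`,
#'   `"none"`), `degenerate` flag and the paired `scatter` table for
#'   plotting.
#' @export
pigmentationEntropyRelation <- function(greyStats, entropyStats) {
  if (nrow(greyStats) < 3L || nrow(entropyStats) < 3L)
    stop("at least 3 ROI pairs are required")
  if (nrow(greyStats) != nrow(entropyStats))
    stop("grey and entropy tables must pair up row by row")
  g <- greyStats$mean; h <- entropyStats$mean
  scatter <- data.frame(label = greyStats$label, grey_mean = g,
                        grey_sd = greyStats$sd, entropy_mean = h,
                        entropy_sd = entropyStats$sd)
  if (.popSd(g) == 0 || .popSd(h) == 0)
    return(list(correlation = NA_real_, sign = "none", degenerate = TRUE,
                scatter = scatter))
  r <- stats::cor(g, h)
  list(correlation = r,
       sign = if (r < 0) "negative" else if (r > 0) "positive" else "none",
       degenerate = FALSE, scatter = scatter)
}

#' Per-segment B-scan entropy report
#'
#' The quantitative in vivo read-out: for each requested B-scan frame and
#' each delineated segment label (`rpe` = intact RPE, `atrophic`, `graft`),
#' measurement strips of `widthPx x depthPx` pixels (default 100 x 3,
#' i.e. 586 x 12.6 um on the clinical raster) centred at the delineated
#' depths are summarised as mean, population SD, median and skewness.
#' Strips are placed at the lateral centre of each contiguous labelled run
#' unless explicit strip ROIs are supplied. Labels with no delineated run
#' are omitted with a warning.
#'
#' @param ev an [EntropyVolume-class].
#' @param d a [Delineation-class].
#' @param frames 0-based frame indices to analyse (default: every frame
#'   present in the delineation).
#' @param strips optional list of [roiStrip] ROIs; when supplied, the
#'   delineated depth at each strip's centre position is used as the depth
#'   centre.
#' @param widthPx,depthPx strip size for auto-placed strips.
#' @return `data.frame` with one row per strip: `frame`, `label`,
#'   `lateral_centre`, `depth_centre`, `n_pixels`, `n_excluded`, `mean`,
#'   `sd`, `median`, `skewness`.
#' @export
segmentReport <- function(ev, d, frames = NULL, strips = NULL,
                          widthPx = 100L, depthPx = 3L) {
  stopifnot(is(ev, "EntropyVolume"), is(d, "Delineation"))
  p <- d@points[d@points$label %in% c("rpe", "graft", "atrophic"), ,
                drop = FALSE]
  if (!nrow(p)) {
    warning("delineation has no rpe/graft/atrophic points; empty report")
    return(data.frame(frame = integer(), label = character(),
                      lateral_centre = integer(), depth_centre = integer(),
                      n_pixels = integer(), n_excluded = integer(),
                      mean = numeric(), sd = numeric(), median = numeric(),
                      skewness = numeric()))
  }
  rows <- list()
  if (is.null(strips)) {
    if (is.null(frames)) frames <- sort(unique(p$frame))
    for (f in frames) {
      pf <- p[p$frame == f, , drop = FALSE]
      pf <- pf[order(pf$lateral), , drop = FALSE]
      for (lb in unique(pf$label)) {
        lat <- sort(pf$lateral[pf$label == lb])
        # contiguous lateral runs of this label
        brk <- c(0L, which(diff(lat) > 1L), length(lat))
        for (i in seq_len(length(brk) - 1L)) {
          run <- lat[(brk[i] + 1L):brk[i + 1L]]
          centre <- run[ceiling(length(run) / 2)]
          w <- min(widthPx, length(run))  # shrink strips to short runs
          rows[[length(rows) + 1L]] <-
            list(frame = f, label = lb, lateralCentre = centre, widthPx = w)
        }
      }
    }
  } else {
    for (s in strips)
      rows[[length(rows) + 1L]] <-
        list(frame = s$frame, label = s$label, lateralCentre = s$lateralCentre,
             widthPx = s$widthPx)
  }
  out <- list()
  for (r in rows) {
    sel <- p$frame == r$frame & p$lateral == r$lateralCentre
    if (!any(sel)) next
    depthCentre <- p$depth[sel][1]
    lb <- p$label[sel][1]
    st <- entropyRoiStats(ev,
                          roiStrip(lb, r$frame, r$lateralCentre,
                                   widthPx = r$widthPx, depthPx = depthPx),
                          depthCentre = depthCentre)
    out[[length(out) + 1L]] <- data.frame(
      frame = r$frame, label = lb, lateral_centre = r$lateralCentre,
      depth_centre = depthCentre, n_pixels = st$n_pixels,
      n_excluded = st$n_excluded, mean = st$mean, sd = st$sd,
      median = st$median, skewness = st$skewness)
  }
  missing <- setdiff(unique(p$label), unique(vapply(out, function(x) x$label,
                                                    character(1))))
  if (length(missing))
    warning("labels with no measurable run omitted: ",
            paste(missing, collapse = ", "))
  do.call(rbind, out)
}

#' Entropy-versus-lateral-position profile of one B-scan
#'
#' The per-B-scan profile that accompanies the segment report: for each
#' delineated lateral position of the frame, the mean entropy over the
#' `2 x bandHalfwidth + 1` depth pixels centred at the delineated depth,
#' together with the segment label.
#'
#' @param ev an [EntropyVolume-class].
#' @param d a [Delineation-class].
#' @param frame 0-based frame index.
#' @param bandHalfwidth depth halfwidth of the averaging band.
#' @return `data.frame` with `lateral`, `depth`, `label`, `entropy` (`NA`
#'   where no valid voxel fell inside the band).
#' @export
segmentProfile <- function(ev, d, frame, bandHalfwidth = 1L) {
  stopifnot(is(ev, "EntropyVolume"), is(d, "Delineation"))
  p <- d@points[d@points$frame == frame &
                  d@points$label %in% c("rpe", "graft", "atrophic"), ,
                drop = FALSE]
  p <- p[order(p$lateral), , drop = FALSE]
  nd <- dim(ev@entropy)[3]
  ent <- vapply(seq_len(nrow(p)), function(i) {
    dep <- max(0L, p$depth[i] - bandHalfwidth):
      min(nd - 1L, p$depth[i] + bandHalfwidth)
    v <- ev@entropy[frame + 1L, p$lateral[i] + 1L, dep + 1L]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  data.frame(lateral = p$lateral, depth = p$depth, label = p$label,
             entropy = ent)
}

#' Write a quantification report as CSV plus a plain-text summary
#'
#' @param stats `data.frame` of ROI/segment statistics rows.
#' @param path output CSV path; a `.txt` summary is written alongside.
#' @return `path`, invisibly.
#' @export
writeReport <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  lines <- c("Entropy quantification summary", "")
  if (nrow(stats) && all(c("label", "mean", "sd") %in% names(stats))) {
    agg <- stats::aggregate(stats$mean, by = list(label = stats$label), mean)
    lines <- c(lines, sprintf("%-12s mean entropy %.3f", agg$label, agg$x))
  }
  writeLines(lines, txt)
  invisible(path)
}
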