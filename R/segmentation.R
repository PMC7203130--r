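#' Construct a delineation from a points table
#'
#' @param points `data.frame` with columns `frame`, `lateral`, `depth`
#'   (0-based integer indices; depth increases towards deeper voxels) and
#'   `label` (`membrane_top`, `rpe`, `graft` or `atrophic`).
#' @param provenance `"auto"`, `"manual_file"` or `"phantom_truth"`.
#' @return a [Delineation-class].
#' @export
delineation <- function(points, provenance = c("manual_file", "auto",
                                               "phantom_truth")) {
  provenance <- match.arg(provenance)
  points$frame <- as.integer(points$frame)
  points$lateral <- as.integer(points$lateral)
  points$depth <- as.integer(points$depth)
  points$label <- as.character(points$label)
  new("Delineation", points = points, provenance = provenance)
}

#' Detect the top of the transwell membrane in an intensity volume
#'
#' The porous insert membrane appears as the strongest high-intensity band of
#' each A-scan. Per A-scan, voxels above an adaptive (Otsu) threshold are
#' grouped into contiguous bands; the band with the largest integrated
#' intensity wins and its shallowest depth index is taken as the membrane
#' top. The resulting curve is smoothed laterally by a running median
#' (window of 15 A-scans) to suppress speckle outliers. A-scans with no
#' band above threshold are left missing and their count is reported.
#'
#' @param volume a [JonesVolume-class] (in vitro preparation) or a numeric
#'   intensity array `(frames, lateral, depth)`.
#' @param medianWindow odd lateral window of the running median.
#' @param speckleWindow odd lateral window of the running-mean speckle
#'   suppression applied before thresholding (fully developed speckle is
#'   exponentially distributed, which defeats a histogram threshold on raw
#'   single-A-scan profiles).
#' @return a [Delineation-class] with label `membrane_top` (provenance
#'   `"auto"`).
#' @export
detectMembraneTop <- function(volume, medianWindow = 15L,
                              speckleWindow = 9L) {
  intens <- if (is(volume, "JonesVolume")) intensityVolume(volume) else volume
  stopifnot(length(dim(intens)) == 3L)
  nf <- dim(intens)[1]; nl <- dim(intens)[2]
  smoothed <- .lateralRunningMean(intens, speckleWindow)
  depth <- matrix(NA_integer_, nf, nl)
  for (f in seq_len(nf)) {
    for (l in seq_len(nl)) {
      a <- smoothed[f, l, ]
      if (all(a == 0)) next
      thr <- .otsuThreshold(a)
      runs <- .trueRuns(a > thr)
      if (!nrow(runs)) next
      strength <- vapply(seq_len(nrow(runs)), function(i)
        sum(a[runs[i, 1]:runs[i, 2]]), numeric(1))
      top <- runs[which.max(strength), 1]
      # hysteresis: walk the band edge up while voxels stay above half the
      # threshold, so a speckle dip at the band top does not push the curve
      # deeper into the band
      while (top > 1L && a[top - 1L] > 0.5 * thr) top <- top - 1L
      depth[f, l] <- top - 1L  # 0-based
    }
  }
  nMissing <- sum(is.na(depth))
  if (nMissing == nf * nl) {
    warning("no membrane band detected in any A-scan")
    return(delineation(data.frame(frame = integer(), lateral = integer(),
                                  depth = integer(), label = character()),
                       "auto"))
  }
  if (nMissing > 0)
    message(nMissing, " A-scan(s) had no band above threshold")
  # lateral running median per frame (missing positions carried through)
  k <- as.integer(medianWindow)
  if (k %% 2L == 0L) k <- k + 1L
  for (f in seq_len(nf)) {
    v <- depth[f, ]
    ok <- !is.na(v)
    if (sum(ok) > k)
      v[ok] <- as.integer(stats::runmed(v[ok], k, endrule = "median"))
    depth[f, ] <- v
  }
  idx <- which(!is.na(depth), arr.ind = TRUE)
  delineation(data.frame(frame = idx[, 1] - 1L, lateral = idx[, 2] - 1L,
                         depth = depth[!is.na(depth)], label = "membrane_top"),
              "auto")
}

#' Re-centre graft curves at the axial centre of the graft band
#'
#' A transplanted RPE sheet has appreciable thickness in the OCT image, so
#' its delineation is placed at the axial centre of the detected band rather
#' than at a surface. For every `graft`-labelled point, the contiguous
#' above-threshold band containing (or nearest to) the current depth is
#' found in the A-scan intensity profile and the depth is replaced by the
#' integer midpoint of the band's top and bottom; a half-integer midpoint
#' rounds towards the shallower depth. A-scans whose band cannot be resolved
#' keep their input depth and are counted.
#'
#' @param volume a [JonesVolume-class] or numeric intensity array.
#' @param d a [Delineation-class] containing `graft`-labelled points.
#' @return the updated [Delineation-class].
#' @export
graftAxialCentre <- function(volume, d) {
  stopifnot(is(d, "Delineation"))
  intens <- if (is(volume, "JonesVolume")) intensityVolume(volume) else volume
  p <- d@points
  gi <- which(p$label == "graft")
  if (!length(gi)) {
    warning("no graft-labelled points in delineation")
    return(d)
  }
  nFlagged <- 0L
  for (i in gi) {
    a <- intens[p$frame[i] + 1L, p$lateral[i] + 1L, ]
    thr <- .otsuThreshold(a)
    runs <- .trueRuns(a > thr)
    if (!nrow(runs)) { nFlagged <- nFlagged + 1L; next }
    d0 <- p$depth[i] + 1L  # 1-based
    inside <- runs[, 1] <= d0 & d0 <= runs[, 2]
    ri <- if (any(inside)) which(inside)[1]
    else which.min(pmin(abs(runs[, 1] - d0), abs(runs[, 2] - d0)))
    top <- runs[ri, 1] - 1L; bottom <- runs[ri, 2] - 1L  # 0-based
    p$depth[i] <- as.integer(floor((top + bottom) / 2))
  }
  if (nFlagged > 0)
    message(nFlagged, " graft A-scan(s) had no resolvable band; depth kept")
  new("Delineation", points = p, provenance = d@provenance)
}

#' Read / write delineation curves as CSV
#'
#' The on-disk interface for manually delineated boundary curves: a UTF-8
#' CSV with header `frame,lateral,depth,label`, 0-based integer indices
#' (depth is the voxel index along the A-scan, increasing towards deeper
#' voxels), one row per `(frame, lateral, label)`. The round trip
#' `writeDelineation()` then `readDelineation()` is lossless.
#'
#' @param path CSV file path.
#' @param maxDepth optional exclusive depth bound used to validate rows.
#' @return `readDelineation` returns a [Delineation-class] with provenance
#'   `"manual_file"`; `writeDelineation` returns `path` invisibly.
#' @export
readDelineation <- function(path, maxDepth = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "lateral", "depth", "label")
  if (!all(need %in% names(tab)))
    stop("delineation CSV must have header frame,lateral,depth,label")
  bad <- which(tab$depth < 0 | tab$frame < 0 | tab$lateral < 0)
  if (length(bad))
    stop(sprintf("negative index at line %d of %s", bad[1] + 1L, path))
  if (!is.null(maxDepth)) {
    bad <- which(tab$depth >= maxDepth)
    if (length(bad))
      stop(sprintf("depth out of bounds at line %d of %s", bad[1] + 1L, path))
  }
  dup <- which(duplicated(tab[c("frame", "lateral", "label")]))
  if (length(dup))
    stop(sprintf("duplicate (frame, lateral, label) at line %d of %s",
                 dup[1] + 1L, path))
  bad <- which(!tab$label %in% .DELINEATION_LABELS)
  if (length(bad))
    stop(sprintf("unknown label '%s' at line %d of %s",
                 tab$label[bad[1]], bad[1] + 1L, path))
  delineation(tab, "manual_file")
}

#' @rdname readDelineation
#' @param d a [Delineation-class].
#' @export
writeDelineation <- function(d, path) {
  stopifnot(is(d, "Delineation"))
  utils::write.csv(d@points[c("frame", "lateral", "depth", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
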