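# Depth curve lookup table: (frames x lateral) matrix of 0-based depths (NA
# where the delineation has no point), restricted to the given labels.
.curveMatrix <- function(d, nf, nl, labels) {
  p <- d@points[d@points$label %in% labels, , drop = FALSE]
  m <- matrix(NA_integer_, nf, nl)
  if (nrow(p))
    m[cbind(p$frame + 1L, p$lateral + 1L)] <- p$depth
  m
}

# Shared projection engine: per (frame, lateral), the maximum of `arr` over
# the allowed depth range; NA sentinel where no finite voxel is allowed.
.projectMax <- function(arr, from, to) {
  nf <- dim(arr)[1]; nl <- dim(arr)[2]; nd <- dim(arr)[3]
  out <- matrix(NA_real_, nf, nl)
  for (f in seq_len(nf)) {
    for (l in seq_len(nl)) {
      a <- from[f, l]; b <- to[f, l]
      if (is.na(a) || is.na(b)) next
      a <- max(1L, a); b <- min(nd, b)
      if (a > b) next
      v <- arr[f, l, a:b]
      v <- v[!is.na(v)]
      if (length(v)) out[f, l] <- max(v)
    }
  }
  out
}

#' En face map: maximum entropy above an exclusion boundary
#'
#' The in vitro projection rule: per A-scan, the highest valid entropy at
#' depths strictly shallower than the membrane-top boundary, so that the
#' intrinsically depolarizing porous membrane never contributes to the map.
#' Positions with a missing boundary, or with no valid voxel above it, carry
#' the `NA` sentinel (distinct from entropy 0).
#'
#' @param ev an [EntropyVolume-class].
#' @param boundary a [Delineation-class] with `membrane_top` points.
#' @return an [EnFaceMap-class] (`kind = "entropy"`,
#'   `rule = "max_above_boundary"`).
#' @export
enfaceMaxAbove <- function(ev, boundary) {
  stopifnot(is(ev, "EntropyVolume"), is(boundary, "Delineation"))
  nf <- dim(ev@entropy)[1]; nl <- dim(ev@entropy)[2]
  cm <- .curveMatrix(boundary, nf, nl, "membrane_top")
  if (all(is.na(cm)))
    stop("boundary has no membrane_top label")
  vals <- .projectMax(ev@entropy,
                      from = matrix(1L, nf, nl),
                      to = cm)  # depths 0 .. curve-1 (0-based) = 1 .. curve (1-based)
  new("EnFaceMap", values = vals, kind = "entropy",
      rule = "max_above_boundary", bandHalfwidth = NA_integer_,
      sourceIds = list(delineation = boundary@provenance,
                       entropy = ev@provenance))
}

#' En face map: maximum entropy in a band at the delineated depth
#'
#' The in vivo projection rule: per A-scan, the highest valid entropy within
#' `bandHalfwidth` depth pixels of the delineated RPE/graft/atrophic curve.
#' Depths below the band never contribute, which is the mechanism that
#' excludes the melanin-rich (and therefore strongly depolarizing) choroid
#' from the map. The default halfwidth of 1 gives a 3-pixel band, matching
#' the 3-depth-pixel measurement band of the B-scan statistics.
#'
#' @param ev an [EntropyVolume-class].
#' @param curve a [Delineation-class] with `rpe`/`graft`/`atrophic` points.
#' @param bandHalfwidth band halfwidth in depth pixels.
#' @return an [EnFaceMap-class] (`kind = "entropy"`,
#'   `rule = "band_at_delineation"`).
#' @export
enfaceBand <- function(ev, curve, bandHalfwidth = 1L) {
  stopifnot(is(ev, "EntropyVolume"), is(curve, "Delineation"))
  bandHalfwidth <- as.integer(bandHalfwidth)
  stopifnot(bandHalfwidth >= 0L)
  nf <- dim(ev@entropy)[1]; nl <- dim(ev@entropy)[2]
  cm <- .curveMatrix(curve, nf, nl, c("rpe", "graft", "atrophic"))
  if (all(is.na(cm)))
    stop("curve has no rpe/graft/atrophic label")
  vals <- .projectMax(ev@entropy,
                      from = cm + 1L - bandHalfwidth,
                      to = cm + 1L + bandHalfwidth)
  if (any(!is.na(cm) & is.na(vals)))
    message(sum(!is.na(cm) & is.na(vals)),
            " position(s) had an empty band after truncation")
  new("EnFaceMap", values = vals, kind = "entropy",
      rule = "band_at_delineation", bandHalfwidth = bandHalfwidth,
      sourceIds = list(delineation = curve@provenance,
                       entropy = ev@provenance))
}

#' En face intensity map under the same projection rules
#'
#' Applies the above-boundary or band projection (or a plain full-depth
#' maximum) to per-voxel intensity, the sum of squared moduli of the four
#' Jones elements. Intensity maps are shown alongside entropy maps: atrophy
#' that is prominent in entropy is typically invisible in intensity.
#'
#' @param volume a [JonesVolume-class].
#' @param rule `"max_above_boundary"`, `"band_at_delineation"` or
#'   `"full_depth_max"`.
#' @param boundary a [Delineation-class] (required for the first two rules).
#' @param bandHalfwidth band halfwidth for the band rule.
#' @return an [EnFaceMap-class] with `kind = "intensity"`.
#' @export
enfaceIntensity <- function(volume, rule = c("band_at_delineation",
                                             "max_above_boundary",
                                             "full_depth_max"),
                            boundary = NULL, bandHalfwidth = 1L) {
  rule <- match.arg(rule)
  intens <- intensityVolume(volume)
  nf <- dim(intens)[1]; nl <- dim(intens)[2]; nd <- dim(intens)[3]
  if (rule != "full_depth_max") {
    stopifnot(is(boundary, "Delineation"))
    labels <- if (rule == "max_above_boundary") "membrane_top"
    else c("rpe", "graft", "atrophic")
    cm <- .curveMatrix(boundary, nf, nl, labels)
    if (all(is.na(cm)))
      stop("boundary lacks the labels required by rule ", rule)
  }
  vals <- switch(rule,
    full_depth_max = .projectMax(intens, matrix(1L, nf, nl),
                                 matrix(nd, nf, nl)),
    max_above_boundary = .projectMax(intens, matrix(1L, nf, nl), cm),
    band_at_delineation = .projectMax(intens,
                                      cm + 1L - as.integer(bandHalfwidth),
                                      cm + 1L + as.integer(bandHalfwidth)))
  new("EnFaceMap", values = vals, kind = "intensity", rule = rule,
      bandHalfwidth = if (rule == "band_at_delineation")
        as.integer(bandHalfwidth) else NA_integer_,
      sourceIds = list(delineation = if (!is.null(boundary))
        boundary@provenance else NA_character_))
}

#' Export an en face map
#'
#' `writeEnFaceTiff` writes a two-page 32-bit float TIFF: page 1 holds the
#' values scaled to `[0, 1]` (the affine range is recorded in a JSON
#' sidecar `<path>.json`; entropy maps are stored unscaled since they are
#' already in range) and page 2 a validity mask (1 = data, 0 = sentinel).
#' `writeEnFacePng` writes an 8-bit grey PNG with entropy linearly scaled
#' (0 to 0, 1 to 255; intensity scaled by its maximum) and the sentinel
#' encoded as alpha 0, so "no data" is distinguishable from a true zero.
#'
#' @param map an [EnFaceMap-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEnFaceTiff <- function(map, path) {
  stopifnot(is(map, "EnFaceMap"))
  v <- map@values
  if (map@kind == "entropy") { lo <- 0; hi <- 1 }
  else {
    lo <- min(0, v, na.rm = TRUE)
    hi <- max(v, lo + 1, na.rm = TRUE)
  }
  scaled <- (v - lo) / (hi - lo)
  scaled[is.na(scaled)] <- 0
  valid <- ifelse(is.na(v), 0, 1)
  tiff::writeTIFF(list(scaled, valid), path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(list(kind = map@kind, rule = map@rule,
                            lo = lo, hi = hi),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeEnFaceTiff
#' @export
writeEnFacePng <- function(map, path) {
  stopifnot(is(map, "EnFaceMap"))
  v <- map@values
  scale <- if (map@kind == "entropy") 1 else max(v, 0, na.rm = TRUE)
  g <- pmin(1, pmax(0, v / max(scale, .Machine$double.eps)))
  alpha <- ifelse(is.na(v), 0, 1)
  g[is.na(g)] <- 0
  img <- array(c(g, g, g, alpha), dim = c(nrow(v), ncol(v), 4))
  png::writePNG(img, path)
  invisible(path)
}
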