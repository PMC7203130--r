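# A tiny hand-built entropy volume for projection-rule checks.
makeEntropyVolume <- function(values) {
  new("EntropyVolume", entropy = values, valid = !is.na(values),
      kernel = c(1L, 3L, 0L), provenance = list())
}

flatCurve <- function(nf, nl, depth, label) {
  delineation(data.frame(frame = rep(seq_len(nf) - 1L, nl),
                         lateral = rep(seq_len(nl) - 1L, each = nf),
                         depth = depth, label = label), "phantom_truth")
}

test_that("max-above projection never sees the boundary or anything below it", {
  nf <- 3L; nl <- 5L; nd <- 12L
  e <- array(0.3, c(nf, nl, nd))
  b <- flatCurve(nf, nl, 7L, "membrane_top")
  m0 <- enfaceMaxAbove(makeEntropyVolume(e), b)
  expect_true(all(mapValues(m0) == 0.3))

  # poison the boundary and everything below with entropy 1
  ep <- e
  ep[, , 8:nd] <- 1
  m1 <- enfaceMaxAbove(makeEntropyVolume(ep), b)
  expect_identical(mapValues(m1), mapValues(m0))

  # boundary at depth 0: nothing above -> all-sentinel map
  m2 <- enfaceMaxAbove(makeEntropyVolume(e), flatCurve(nf, nl, 0L,
                                                       "membrane_top"))
  expect_true(all(is.na(mapValues(m2))))

  expect_error(enfaceMaxAbove(makeEntropyVolume(e),
                              flatCurve(nf, nl, 7L, "rpe")),
               "membrane_top")
})

test_that("band projection sees only the band around the delineated depth", {
  nf <- 2L; nl <- 6L; nd <- 16L
  e <- array(0.2, c(nf, nl, nd))
  e[, , 9] <- 0.4            # the delineated depth (0-based 8)
  curve <- flatCurve(nf, nl, 8L, "rpe")
  m <- enfaceBand(makeEntropyVolume(e), curve, bandHalfwidth = 1L)
  expect_true(all(mapValues(m) == 0.4))

  # poison everything outside the +/-1 band with entropy 1
  ep <- e
  ep[, , c(1:7, 11:nd)] <- 1
  m1 <- enfaceBand(makeEntropyVolume(ep), curve, bandHalfwidth = 1L)
  expect_identical(mapValues(m1), mapValues(m))

  # halfwidth 0 reads exactly the delineated depth
  m0 <- enfaceBand(makeEntropyVolume(e), curve, bandHalfwidth = 0L)
  expect_true(all(mapValues(m0) == 0.4))

  expect_error(enfaceBand(makeEntropyVolume(e),
                          flatCurve(nf, nl, 8L, "membrane_top")),
               "rpe/graft/atrophic")
})

test_that("the band rule excludes a depolarizing choroid under atrophic RPE", {
  s <- smallInvivo(seed = 41L, atrophyRadiusFrac = 0.35)
  p <- buildPhantom(s)
  ev <- entropyVolume(p$volume)
  m <- enfaceBand(ev, boundaryCurves(p$truth))
  seg <- segmentMatrixOf(s)
  v <- mapValues(m)
  # interior of the atrophic disc (eroded to avoid windows mixing regions)
  atr <- v[seg == "atrophic"]
  intact <- v[seg == "rpe"]
  expect_lt(stats::median(atr, na.rm = TRUE), 0.05)
  expect_gt(mean(intact, na.rm = TRUE), 0.4)
  # the choroid itself is strongly depolarizing
  h <- entropyValues(ev)
  choroidCode <- which(p$truth@layerNames == "choroid")
  expect_gt(mean(h[layerMask(p$truth) == choroidCode], na.rm = TRUE), 0.5)
})

test_that("intensity maps use the same rules and a zero volume maps to zero", {
  zero <- new("JonesVolume", data = array(0 + 0i, c(2, 6, 10, 2, 2)),
              lateralExtentMm = 6, depthPitchUm = 4.2, noiseVariance = 0,
              seed = 1L)
  m <- enfaceIntensity(zero, "full_depth_max")
  expect_true(all(mapValues(m) == 0))

  s <- smallInvivo(seed = 42L, atrophyRadiusFrac = 0)
  p <- buildPhantom(s)
  mi <- enfaceIntensity(p$volume, "band_at_delineation",
                        boundaryCurves(p$truth))
  expect_identical(mapValues(mi),
                   mapValues(enfaceIntensity(p$volume, "band_at_delineation",
                                             boundaryCurves(p$truth))))
  expect_true(all(mapValues(mi) >= 0, na.rm = TRUE))
})

test_that("en face maps export to float TIFF and alpha-masked PNG", {
  vals <- matrix(c(0.1, 0.9, NA, 0.5), 2, 2)
  m <- new("EnFaceMap", values = vals, kind = "entropy",
           rule = "band_at_delineation", bandHalfwidth = 1L,
           sourceIds = list())
  tf <- tempfile(fileext = ".tif")
  writeEnFaceTiff(m, tf)
  pages <- tiff::readTIFF(tf, all = TRUE)
  back <- pages[[1]]; validPage <- pages[[2]]
  expect_equal(back[!is.na(vals)], vals[!is.na(vals)], tolerance = 1e-6)
  expect_equal(validPage[1, 2], 0)   # sentinel flagged invalid
  expect_equal(validPage[2, 2], 1)

  pf <- tempfile(fileext = ".png")
  writeEnFacePng(m, pf)
  img <- png::readPNG(pf)
  expect_equal(dim(img)[3], 4)
  expect_equal(img[1, 2, 4], 0)  # sentinel encodes as alpha 0
  expect_equal(img[2, 1, 1], 0.9, tolerance = 0.01)
})
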