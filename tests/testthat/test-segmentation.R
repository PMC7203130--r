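test_that("membrane top is recovered within one pixel on flat and sloped phantoms", {
  # flat membrane
  s <- smallInvitro(seed = 21L)
  p <- buildPhantom(s)
  det <- detectMembraneTop(p$volume)
  truth <- delineationPoints(boundaryCurves(p$truth))
  got <- delineationPoints(det)
  m <- merge(truth, got, by = c("frame", "lateral"),
             suffixes = c("_true", "_det"))
  expect_gte(nrow(m) / nrow(truth), 0.99)
  expect_gte(mean(abs(m$depth_det - m$depth_true) <= 1), 0.99)

  # sloped membrane: top rises 8 voxels across the lateral field
  nf <- 4L; nl <- 64L
  slope <- matrix(rep(round(seq(20, 28, length.out = nl)), each = nf), nf, nl)
  layers <- list(layerSpec("cells_no_melanin", top = 4, bottom = 16,
                           reflectivity = 0.8),
                 layerSpec("membrane", top = slope, bottom = slope + 10,
                           reflectivity = 1.5, depolarizationStrength = 1))
  sp <- phantomSpec("invitro", grid = c(nf, nl, 48L), layers = layers,
                    seed = 22L)
  pp <- buildPhantom(sp)
  det <- detectMembraneTop(pp$volume)
  got <- delineationPoints(det)
  truthDepth <- slope[cbind(got$frame + 1L, got$lateral + 1L)]
  expect_gte(mean(abs(got$depth - truthDepth) <= 1), 0.99)
})

test_that("membrane detection degrades gracefully at 10 dB and on empty input", {
  s <- smallInvitro(seed = 23L, snrDb = 10)
  p <- buildPhantom(s)
  det <- detectMembraneTop(p$volume)
  truth <- delineationPoints(boundaryCurves(p$truth))
  m <- merge(truth, delineationPoints(det), by = c("frame", "lateral"),
             suffixes = c("_true", "_det"))
  expect_gte(mean(abs(m$depth_det - m$depth_true) <= 2), 0.99)

  zero <- new("JonesVolume", data = array(0 + 0i, c(2, 8, 16, 2, 2)),
              lateralExtentMm = 6, depthPitchUm = 4.2, noiseVariance = 0,
              seed = 1L)
  expect_warning(d0 <- detectMembraneTop(zero), "no membrane band")
  expect_equal(nrow(delineationPoints(d0)), 0)
})

test_that("delineation CSV round trip is lossless and validation names the line", {
  d <- delineation(data.frame(frame = c(0L, 0L, 1L, 1L),
                              lateral = c(0L, 1L, 0L, 1L),
                              depth = c(5L, 6L, 5L, 7L),
                              label = c("rpe", "rpe", "graft", "atrophic")))
  path <- tempfile(fileext = ".csv")
  writeDelineation(d, path)
  d2 <- readDelineation(path)
  expect_identical(delineationPoints(d2), delineationPoints(d))
  expect_equal(length(unique(delineationPoints(d2)$frame)), 2L)

  writeLines(c("frame,lateral,depth,label", "0,0,-1,rpe"), path)
  expect_error(readDelineation(path), "line 2")
  writeLines(c("frame,lateral,depth,label", "0,0,5,rpe", "0,0,7,rpe"), path)
  expect_error(readDelineation(path), "duplicate.*line 3")
  writeLines(c("frame,lateral,depth,label", "0,0,99,rpe"), path)
  expect_error(readDelineation(path, maxDepth = 50), "out of bounds")
  writeLines(c("frame,lateral,depth,label", "0,0,5,ilm"), path)
  expect_error(readDelineation(path), "unknown label")
})

test_that("graft curves are re-centred at the axial middle of the band", {
  # synthetic intensity volume: one A-scan band per case
  nd <- 80L
  intens <- array(0.01, c(1, 3, nd))
  intens[1, 1, 41:61] <- 1   # band at depths 40..60 (0-based) -> centre 50
  intens[1, 2, 43:61] <- 1   # top 42, bottom 60 -> midpoint 51 (half down)
  intens[1, 3, 31] <- 1      # thickness 1 at depth 30
  d <- delineation(data.frame(frame = 0L, lateral = 0:2,
                              depth = c(45L, 45L, 30L), label = "graft"))
  out <- delineationPoints(graftAxialCentre(intens, d))
  expect_equal(out$depth, c(50L, 51L, 30L))

  # unresolvable band: depth kept
  flat <- array(1, c(1, 1, nd))
  dk <- delineation(data.frame(frame = 0L, lateral = 0L, depth = 12L,
                               label = "graft"))
  expect_message(kept <- graftAxialCentre(flat, dk), "no resolvable band")
  expect_equal(delineationPoints(kept)$depth, 12L)

  expect_warning(graftAxialCentre(intens, delineation(
    data.frame(frame = 0L, lateral = 0L, depth = 1L, label = "rpe"))),
    "no graft")
})

test_that("delineations reject overlapping or malformed labels", {
  expect_error(delineation(data.frame(frame = 0L, lateral = 0L, depth = 3L,
                                      label = "choroid")), "label")
  expect_error(delineation(data.frame(frame = c(0L, 0L), lateral = c(0L, 0L),
                                      depth = c(3L, 4L),
                                      label = c("rpe", "rpe"))),
               "at most one depth")
})
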