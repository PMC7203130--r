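test_that("melanin-to-scrambling map is monotone with fixed endpoints", {
  expect_identical(melaninToScrambling(0), 0)
  expect_equal(melaninToScrambling(1), pi)
  cc <- seq(0, 1, by = 0.05)
  disp <- melaninToScrambling(cc)
  expect_true(all(diff(disp) > 0))
  mid <- melaninToScrambling(0.5)
  expect_gt(mid, 0); expect_lt(mid, pi)
  expect_equal(mid, pi / 2)  # linear map midpoint
  expect_error(melaninToScrambling(1.2), "\\[0, 1\\]")
  expect_error(melaninToScrambling(-0.1), "\\[0, 1\\]")
})

test_that("identical spec and seed give a bit-identical volume and truth", {
  s <- smallInvivo(seed = 9L, snrDb = 20)
  p1 <- buildPhantom(s)
  p2 <- buildPhantom(s)
  expect_identical(jonesData(p1$volume), jonesData(p2$volume))
  expect_identical(layerMask(p1$truth), layerMask(p2$truth))
  p3 <- buildPhantom(smallInvivo(seed = 10L, snrDb = 20))
  expect_false(identical(jonesData(p1$volume), jonesData(p3$volume)))
})

test_that("overlapping layers and degenerate grids are rejected by name", {
  layers <- list(layerSpec("retina_inner", top = 0, bottom = 20),
                 layerSpec("rpe", top = 15, bottom = 25, melanin = 0.5))
  s <- phantomSpec("invivo", grid = c(2L, 8L, 32L), layers = layers)
  expect_error(buildPhantom(s), "retina_inner.*rpe")
  expect_error(phantomSpec("invivo", grid = c(0L, 8L, 32L)), "positive")
  expect_error(layerSpec("rpe", 0, 10, melanin = 1.5), "\\[0, 1\\]")
})

test_that("a homogeneous melanin-free layer gives rank-1 window statistics", {
  # no randomness injected: smoothAmplitude 0, no melanin, no noise
  layers <- list(layerSpec("cells_no_melanin", top = 0, bottom = 32,
                           melanin = 0, birefringence = 0.02,
                           smoothAmplitude = 0))
  s <- phantomSpec("invitro", grid = c(2L, 16L, 32L), layers = layers,
                   seed = 4L)
  v <- buildPhantom(s)$volume
  # within a small window at fixed depth, all Jones matrices are mutually
  # proportional: entropy of the window ensemble is 0
  ks <- sapply(1:8, function(l) vectorizeJones(jonesData(v)[1, l, 10, , ]))
  expect_lt(vonNeumannEntropy(localDensityMatrix(ks)), 1e-9)
  # across depth the only change is the deterministic birefringence factor
  ev <- entropyVolume(v, kernel = c(1L, 3L, 0L))
  inner <- entropyValues(ev)[, 4:13, 5:28]
  expect_lt(max(inner, na.rm = TRUE), 0.05)
})

test_that("phantom truth curves land inside their named layer", {
  for (builder in list(function() smallInvitro(seed = 2L),
                       function() smallInvivo(seed = 2L,
                                              graftRadiusFrac = 0.15))) {
    s <- builder()
    p <- buildPhantom(s)
    pts <- delineationPoints(boundaryCurves(p$truth))
    expect_gt(nrow(pts), 0)
    codes <- layerMask(p$truth)[cbind(pts$frame + 1L, pts$lateral + 1L,
                                      pts$depth + 1L)]
    names <- p$truth@layerNames[codes]
    expected <- ifelse(pts$label == "membrane_top", "membrane", "rpe")
    expect_true(all(names == expected))
  }
})

test_that("ground-truth ROI table distinguishes atrophic, graft and intact RPE", {
  s <- smallInvivo(seed = 3L, graftRadiusFrac = 0.15, graftMelanin = 0.7)
  tr <- buildPhantom(s)$truth
  rt <- roiTruth(tr)
  expect_setequal(rt$label, c("rpe", "atrophic", "graft"))
  expect_equal(rt$concentration[rt$label == "atrophic"], 0)
  expect_equal(rt$concentration[rt$label == "rpe"], 0.8)
  expect_equal(rt$concentration[rt$label == "graft"], 0.7)
})

test_that("applyNoise hits the requested SNR, is seeded, and Inf is identity", {
  s <- smallInvitro(seed = 6L)
  v <- buildPhantom(s)$volume
  expect_identical(applyNoise(v, Inf), v)

  n1 <- applyNoise(v, 0, seed = 8L)
  n2 <- applyNoise(v, 0, seed = 8L)
  expect_identical(jonesData(n1), jonesData(n2))
  expect_false(identical(jonesData(applyNoise(v, 0, seed = 9L)),
                         jonesData(n1)))

  # 0 dB: recorded per-element noise variance equals mean signal power
  meanPower <- mean(Mod(jonesData(v))^2)
  expect_equal(noiseVariance(n1), meanPower, tolerance = 1e-12)
  # realized noise power matches the recorded variance
  realized <- mean(Mod(jonesData(n1) - jonesData(v))^2)
  expect_equal(realized, noiseVariance(n1), tolerance = 0.05)
})

test_that("rendered pigmentation photo darkens with concentration", {
  conc <- matrix(c(0, 0.5, 1), 3, 10)
  g <- renderPigmentPhoto(conc, noiseSd = 0, seed = 1L)
  expect_equal(g[1, 1], 255)
  expect_equal(g[2, 1], 127.5)
  expect_equal(g[3, 1], 0)
  g2 <- renderPigmentPhoto(conc, noiseSd = 5, seed = 2L)
  expect_true(all(g2 >= 0 & g2 <= 255))
  expect_identical(renderPigmentPhoto(conc, noiseSd = 5, seed = 2L), g2)
})
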