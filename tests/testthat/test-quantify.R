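test_that("pixel-to-micrometre conversion matches the raster geometry", {
  expect_equal(roiExtentUm(100, 6, 1024), 586)
  expect_equal(roiExtentUm(1024, 6, 1024), 6000)  # the full raster width
  expect_equal(roiExtentUm(0, 6, 1024), 0)
  # axial: 3 voxels at 4.2 um pitch span 12.6 um (reported as 13 um)
  expect_equal(roiExtentUm(3, 0.0042 * 64, 64), 13)
  expect_error(roiExtentUm(100, 6, 0), "positive")
})

test_that("grey-scale ROI statistics match direct and histogram oracles", {
  photo <- matrix(42, 20, 20)
  st <- greyRoiStats(photo, roiRect("uniform", c(2, 2, 10, 10)))
  expect_equal(st$mean, 42)
  expect_equal(st$sd, 0)

  set.seed(3)
  photo <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  st <- greyRoiStats(photo, roiRect("full", c(0, 0, 20, 20)))
  tab <- table(photo)
  histMean <- sum(as.numeric(names(tab)) * tab) / sum(tab)
  expect_equal(st$mean, histMean, tolerance = 1e-12)
  expect_equal(st$n_pixels, 400)

  expect_error(greyRoiStats(photo, roiRect("out", c(0, 0, 30, 30))),
               "outside")
  # a shifting registration can push the ROI off the photograph
  expect_error(greyRoiStats(photo, roiRect("shifted", c(10, 10, 20, 20)),
                            registration = list(A = diag(2), b = c(15, 0))),
               "outside")
})

test_that("rendered-photo ROI statistics recover the nominal pigmentation", {
  conc <- matrix(0.85, 40, 40)
  photo <- renderPigmentPhoto(conc, noiseSd = 5, seed = 7L)
  st <- greyRoiStats(photo, roiRect("dark", c(5, 5, 35, 35)))
  expect_equal(st$mean, 255 * 0.15, tolerance = 1)  # ~38 within noise
  expect_lt(st$sd, 10)
})

test_that("entropy ROI statistics skip sentinels and match a two-pass oracle", {
  vals <- matrix(0.4, 10, 10)
  m <- new("EnFaceMap", values = vals, kind = "entropy",
           rule = "full_depth_max", bandHalfwidth = NA_integer_,
           sourceIds = list())
  st <- entropyRoiStats(m, roiRect("const", c(0, 0, 10, 10)))
  expect_equal(st$mean, 0.4)
  expect_equal(st$sd, 0)

  set.seed(9)
  vals <- matrix(runif(100), 10, 10)
  vals[1:3, 1] <- NA
  m <- new("EnFaceMap", values = vals, kind = "entropy",
           rule = "full_depth_max", bandHalfwidth = NA_integer_,
           sourceIds = list())
  st <- entropyRoiStats(m, roiRect("rnd", c(0, 0, 10, 10)))
  v <- vals[!is.na(vals)]
  # streaming two-pass oracle
  mu <- sum(v) / length(v)
  sd2 <- sqrt(sum((v - mu)^2) / length(v))
  expect_equal(st$mean, mu, tolerance = 1e-12)
  expect_equal(st$sd, sd2, tolerance = 1e-12)
  expect_equal(st$n_excluded, 3)

  allNA <- new("EnFaceMap", values = matrix(NA_real_, 4, 4),
               kind = "entropy", rule = "full_depth_max",
               bandHalfwidth = NA_integer_, sourceIds = list())
  expect_error(entropyRoiStats(allNA, roiRect("x", c(0, 0, 4, 4))),
               "no valid pixel")
})

test_that("pigmentation-entropy relation reports sign and degeneracy", {
  g <- data.frame(label = letters[1:4], mean = c(10, 20, 30, 40),
                  sd = 1)
  h <- data.frame(label = letters[1:4], mean = c(0.8, 0.6, 0.4, 0.2),
                  sd = 0.01)
  rel <- pigmentationEntropyRelation(g, h)
  expect_equal(rel$correlation, -1)
  expect_equal(rel$sign, "negative")
  expect_false(rel$degenerate)
  expect_equal(nrow(rel$scatter), 4)

  gd <- data.frame(label = letters[1:3], mean = c(5, 5, 5), sd = 0)
  hd <- data.frame(label = letters[1:3], mean = c(0.1, 0.2, 0.3), sd = 0)
  rel <- pigmentationEntropyRelation(gd, hd)
  expect_true(rel$degenerate)
  expect_true(is.na(rel$correlation))

  expect_error(pigmentationEntropyRelation(g[1:2, ], h[1:2, ]), "3 ROI")
})

test_that("segment report preserves the graft ~ intact >> atrophic ordering", {
  s <- smallInvivo(seed = 55L, graftRadiusFrac = 0.15, graftMelanin = 0.8,
                   grid = c(8L, 192L, 64L))
  p <- buildPhantom(s)
  ev <- entropyVolume(p$volume)
  rep <- segmentReport(ev, boundaryCurves(p$truth), frames = 3:4)
  expect_true(all(c("rpe", "atrophic", "graft") %in% rep$label))
  agg <- tapply(rep$mean, rep$label, mean)
  expect_gt(agg[["rpe"]], 5 * agg[["atrophic"]])
  expect_lt(abs(agg[["graft"]] - agg[["rpe"]]) / agg[["rpe"]], 0.25)

  empty <- delineation(data.frame(frame = integer(), lateral = integer(),
                                  depth = integer(), label = character()))
  expect_warning(r0 <- segmentReport(ev, empty), "empty report")
  expect_equal(nrow(r0), 0)
})

test_that("explicit strips give one report row per region and frame", {
  s <- smallInvivo(seed = 56L, atrophyRadiusFrac = 0, grid = c(4L, 160L, 64L))
  p <- buildPhantom(s)
  ev <- entropyVolume(p$volume)
  strips <- lapply(c(20L, 60L, 100L, 140L), function(lc)
    roiStrip("rpe", frame = 1L, lateralCentre = lc, widthPx = 30L))
  rep <- segmentReport(ev, boundaryCurves(p$truth), strips = strips)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$frame == 1L))
  expect_true(all(rep$n_pixels <= 30 * 3))
  expect_true(all(rep$mean > 0.3))  # melanin 0.8 band
})

test_that("segment profiles follow the delineated curve labels", {
  s <- smallInvivo(seed = 57L, atrophyRadiusFrac = 0.35)
  p <- buildPhantom(s)
  ev <- entropyVolume(p$volume)
  prof <- segmentProfile(ev, boundaryCurves(p$truth), frame = 4L)
  expect_setequal(unique(prof$label), c("rpe", "atrophic"))
  expect_gt(mean(prof$entropy[prof$label == "rpe"], na.rm = TRUE),
            mean(prof$entropy[prof$label == "atrophic"], na.rm = TRUE))
})

test_that("reports round-trip through CSV with a text summary", {
  stats <- data.frame(label = c("rpe", "atrophic"), metric = "entropy",
                      n_pixels = c(300L, 300L), mean = c(0.45, 0.05),
                      sd = c(0.1, 0.02), median = c(0.44, 0.05))
  path <- tempfile(fileext = ".csv")
  writeReport(stats, path)
  back <- read.csv(path)
  expect_equal(back$mean, stats$mean)
  expect_true(file.exists(sub("\\.csv$", ".txt", path)))
})
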