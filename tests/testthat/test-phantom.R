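test_that("noiseless constant-HU lobes are reproduced exactly", {
  vol <- generatePhantom(phantomParams(), seed = 1)
  expect_true(all(huVolume(vol)[lobeMask(vol, "left")] == 114.3))
  expect_true(all(huVolume(vol, "enhanced")[lobeMask(vol, "right")] == 202.5))
  expect_true(all(huVolume(vol)[lobeMask(vol, "trachea")] == -1000))
  expect_equal(measureRoiHu(vol, defaultRoi(vol, "left")), 114.3)
  # ROI mean is invariant to ROI radius on constant lobes
  roiSmall <- roiSpec(defaultRoi(vol, "left")@center, radius = 1)
  expect_equal(measureRoiHu(vol, roiSmall), 114.3)
})

test_that("phantom generation is seed-deterministic", {
  p <- phantomParams(noiseSd = 8, inhomAmplitude = 20)
  a <- generatePhantom(p, seed = 4)
  b <- generatePhantom(p, seed = 4)
  expect_identical(huVolume(a), huVolume(b))
  expect_identical(huVolume(a, "enhanced"), huVolume(b, "enhanced"))
  expect_false(identical(huVolume(a), huVolume(generatePhantom(p, seed = 5))))
})

test_that("ROI mean obeys the CLT bound under sensor noise", {
  p <- phantomParams(lobeHu = c(100, 100), lobeDiameterAP = c(3, 3),
                     lobeWidth = 12, noiseSd = 10)
  vol <- generatePhantom(p, seed = 6)
  roi <- roiSpec(defaultRoi(vol, "left")@center, radius = 7)   # > 500 voxels
  nVox <- sum((outer(((seq_len(dim(huVolume(vol))[1])) - roi@center[1]) * 0.5, rep(1, dim(huVolume(vol))[2]))^2 +
                 outer(rep(1, dim(huVolume(vol))[1]), ((seq_len(dim(huVolume(vol))[2])) - roi@center[2]) * 0.5)^2) <= 49)
  expect_gte(nVox, 500)
  expect_lt(abs(measureRoiHu(vol, roi) - 100), 3 * 10 / sqrt(500))
})

test_that("ROI contract violations raise errors", {
  vol <- generatePhantom(phantomParams(), seed = 1)
  dims <- dim(huVolume(vol))
  centerVoxel <- as.integer(c(round(dims[1] / 2), round(dims[2] / 2), ceiling(dims[3] / 2)))
  expect_error(measureRoiHu(vol, roiSpec(centerVoxel, 2)), "single lobe")   # trachea
  big <- roiSpec(defaultRoi(vol, "left")@center, radius = 7.4)   # touches boundary
  expect_error(measureRoiHu(vol, big), "boundary|single lobe")
})

test_that("averaging the two lobes matches the midpoint", {
  p <- phantomParams(lobeHu = c(90, 110))
  vol <- generatePhantom(p, seed = 1)
  expect_equal(averageLobeHu(vol), 100)
  pSame <- phantomParams(lobeHu = c(94.5, 94.5), lobeHuEnhanced = c(187.6, 187.6))
  volSame <- generatePhantom(pSame, seed = 1)
  expect_equal(averageLobeHu(volSame), 94.5)
  expect_equal(averageLobeHu(volSame, phase = "enhanced"), 187.6)
  # symmetric noise, large ROIs: within CLT tolerance of the midpoint
  pNoise <- phantomParams(lobeHu = c(90, 110), noiseSd = 10)
  volNoise <- generatePhantom(pNoise, seed = 8)
  expect_lt(abs(averageLobeHu(volNoise) - 100), 3 * 10 / sqrt(2 * 90))
})

test_that("AP size measurement recovers the generating diameter and bands it", {
  for (case in list(list(d = 1.5, cat = "normal"), list(d = 2.4, cat = "increased"),
                    list(d = 0.8, cat = "decreased"))) {
    vol <- generatePhantom(phantomParams(lobeDiameterAP = c(case$d, case$d)), seed = 1)
    sz <- extractSizeCategory(vol)
    expect_lt(abs(sz$diameterCm - case$d), 0.5 * 0.05)   # half an in-plane voxel
    expect_equal(as.character(sz$category), case$cat)
  }
})

test_that("margin classification separates smooth from lobulated shapes", {
  smooth <- generatePhantom(phantomParams(), seed = 1)
  m <- extractMargin(smooth)
  expect_equal(as.character(m$margin), "smooth")
  expect_equal(unname(max(m$deficiency)), 0)

  lob <- generatePhantom(phantomParams(lobulationAmplitude = 0.2,
                                       lobulationLobes = 5), seed = 1)
  expect_equal(as.character(extractMargin(lob)$margin), "lobulated")
  # calibrated boundary: amplitude 0.15 separates at >= 4 undulations
  for (m in 4:5) {
    v <- generatePhantom(phantomParams(lobulationAmplitude = 0.15 + (m == 4) * 0.05,
                                       lobulationLobes = m), seed = 1)
    expect_equal(as.character(extractMargin(v)$margin), "lobulated")
  }
  # degenerate threshold: everything is smooth
  expect_equal(as.character(extractMargin(lob, threshold = 1.0)$margin), "smooth")
})

test_that("convexity deficiency grows monotonically with lobulation amplitude", {
  amps <- seq(0, 0.25, by = 0.05)
  defs <- vapply(amps, function(A) {
    v <- generatePhantom(phantomParams(lobulationAmplitude = A,
                                       lobulationLobes = 5), seed = 1)
    max(extractMargin(v)$deficiency)
  }, numeric(1))
  expect_true(all(diff(defs) >= -1e-9))
  # monotonicity of the class: no lobulated -> smooth flip as amplitude rises
  calls <- defs > 0.02
  expect_true(all(diff(as.integer(calls)) >= 0))
})

test_that("pattern rule finds its boundary near the configured SD threshold", {
  pat <- function(amp, seed = 2) {
    v <- generatePhantom(phantomParams(inhomAmplitude = amp, inhomScale = 4), seed = seed)
    extractPattern(v)
  }
  expect_equal(as.character(pat(0)$pattern), "homogeneous")
  sweep <- vapply(seq(5, 30, by = 5), function(a) as.character(pat(a)$pattern),
                  character(1))
  expect_equal(sweep[1], "homogeneous")                       # 5 HU
  expect_equal(sweep[length(sweep)], "inhomogeneous")          # 30 HU
  first <- seq(5, 30, by = 5)[match("inhomogeneous", sweep)]
  expect_true(first > 10 && first <= 20)                       # boundary ~15 HU
  # monotone: residual SD rises with amplitude, never inhom -> hom
  sds <- vapply(seq(5, 30, by = 5), function(a) pat(a)$residualSd, numeric(1))
  expect_true(all(diff(sds) >= -1e-9))
})

test_that("focal lesions trigger the heterogeneous rule on the right phase", {
  les <- data.frame(lobe = "left", dx = 0, dy = 0, dz = 0, radius = 3,
                    huOffset = -80, phase = "nonenhanced")
  vol <- generatePhantom(phantomParams(lesions = les), seed = 3)
  pN <- extractPattern(vol, "nonenhanced")
  expect_equal(as.character(pN$pattern), "heterogeneous")
  expect_gte(pN$maxFocalFraction, 0.10)
  expect_equal(as.character(extractPattern(vol, "enhanced")$pattern), "homogeneous")
  # brute-force check of the focal rule on the mid slice
  dims <- dim(huVolume(vol))
  zMid <- ceiling(dims[3] / 2)
  slice <- lobeMask(vol, "left")[, , zMid]
  med <- median(huVolume(vol)[lobeMask(vol, "left")])
  frac <- sum(abs(huVolume(vol)[, , zMid] - med) >= 50 & slice) / sum(slice)
  expect_gte(frac, 0.10)
})

test_that("noise correction keeps noisy homogeneous lobes homogeneous", {
  v <- generatePhantom(phantomParams(noiseSd = 10), seed = 9)
  p <- extractPattern(v)
  expect_equal(as.character(p$pattern), "homogeneous")
  expect_lt(p$residualSd, 5)
})

test_that("geometry violations are rejected", {
  expect_error(generatePhantom(phantomParams(lobulationAmplitude = 0.4, lobeGap = 1)),
               "geometry error")
  expect_error(phantomParams(lobeDiameterAP = c(-1, 1)), "positive")
  expect_error(phantomParams(noiseSd = -1), "noiseSd")
})

test_that("phantoms round-trip through NIfTI with spacing and params intact", {
  p <- phantomParams(noiseSd = 5, inhomAmplitude = c(20, 10),
                     lobulationAmplitude = 0.15, lobulationLobes = 5,
                     lesions = data.frame(lobe = "right", dx = 1, dy = 0, dz = 0,
                                          radius = 2.5, huOffset = 60,
                                          phase = "both"))
  vol <- generatePhantom(p, seed = 10)
  prefix <- file.path(withr::local_tempdir(), "ph")
  writePhantom(vol, prefix)
  back <- readPhantom(prefix)
  expect_equal(voxelSpacing(back), voxelSpacing(vol))
  expect_identical(back@labels, vol@labels)
  # int16 encoding quantises HU to whole numbers
  expect_lt(max(abs(huVolume(back) - huVolume(vol))), 0.5 + 1e-9)
  expect_equal(generatingParams(back)@inhomAmplitude,
               generatingParams(vol)@inhomAmplitude)
  expect_equal(generatingParams(back)@lesions$huOffset, 60)
  expect_equal(back@seed, 10L)
})
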