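test_that("sampleCohort is seed-deterministic and honors class sizes", {
  p <- cohortParams()
  a <- sampleCohort(p, seed = 11)
  b <- sampleCohort(p, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, sampleCohort(p, seed = 12)))
  expect_equal(nrow(a), 209L)
  expect_equal(unname(table(a$histopath_class)[c("normal", "hashimoto",
                                                 "non_hashimoto_lt",
                                                 "diffuse_hyperplasia")]),
               c(157L, 17L, 34L, 1L), ignore_attr = TRUE)
  expect_no_error(validateCohort(a))
})

test_that("large-sample marginals converge to the generator parameters", {
  # 10,000 DTD patients: lobulated-margin fraction and HU mean within 3 SE
  pDtd <- cohortParams(classSizes = c(non_hashimoto_lt = 10000L))
  dtd <- sampleCohort(pDtd, seed = 21)
  pLob <- 12 / 52
  seLob <- sqrt(pLob * (1 - pLob) / 10000)
  expect_lt(abs(mean(dtd$margin == "lobulated") - pLob), 3 * seLob)

  pNorm <- cohortParams(classSizes = c(normal = 10000L))
  nor <- sampleCohort(pNorm, seed = 22)
  expect_lt(abs(mean(nor$hu_nonenhanced) - 114.3), 3 * 21.2 / sqrt(10000))
  expect_lt(abs(mean(nor$hu_enhanced) - 202.5), 3 * 29.3 / sqrt(10000))
  # every other simplex marginal, same tolerance
  probs <- cohortParams()$featureProbs$normal
  for (feat in names(probs)) {
    for (lv in names(probs[[feat]])) {
      p <- probs[[feat]][[lv]]
      se <- sqrt(p * (1 - p) / 10000)
      expect_lt(abs(mean(nor[[feat]] == lv) - p), max(3 * se, 1e-12))
    }
  }
})

test_that("latent coupling concentrates abnormalities without moving marginals", {
  p0 <- cohortParams(classSizes = c(non_hashimoto_lt = 4000L))
  p9 <- cohortParams(classSizes = c(non_hashimoto_lt = 4000L), correlation = 0.8)
  ind <- sampleCohort(p0, seed = 31)
  cor <- sampleCohort(p9, seed = 31)
  # marginals preserved (3-SE check on the rarest feature)
  se <- sqrt((12 / 52) * (40 / 52) / 4000)
  expect_lt(abs(mean(cor$margin == "lobulated") - 12 / 52), 3 * se)
  # but high counts become more frequent under positive dependence
  expect_gt(mean(abnormalCount(cor) >= 3), mean(abnormalCount(ind) >= 3))
})

test_that("generator rejects invalid parameters", {
  expect_error(cohortParams(classSizes = c(normal = -1)), ">= 0")
  badHu <- list(
    normal = c(mean = 114.3, sd = 0, meanEnh = 202.5, sdEnh = 29.3),
    dtd = c(mean = 94.5, sd = 21.3, meanEnh = 187.6, sdEnh = 29.9))
  expect_error(cohortParams(huParams = badHu), "standard deviations")
  probs <- cohortParams()$featureProbs
  probs$dtd$margin <- c(smooth = 0.6, lobulated = 0.5)
  expect_error(cohortParams(featureProbs = probs), "simplex")
  expect_error(cohortParams(correlation = 1.2), "correlation")
})

test_that("cohort CSV round-trips losslessly and rejects bad input", {
  coh <- sampleCohort(cohortParams(), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeCohortCsv(coh, path)
  back <- readCohortCsv(path)
  expect_equal(back$hu_nonenhanced, coh$hu_nonenhanced, tolerance = 1e-12)
  back$hu_nonenhanced <- coh$hu_nonenhanced
  back$hu_enhanced <- coh$hu_enhanced
  expect_identical(back, coh[names(back)])

  # unknown category: error names the file line (header = line 1)
  bad <- coh
  bad$size_category[3] <- "huge"
  lines <- utils::capture.output(utils::write.csv(bad, row.names = FALSE, quote = FALSE))
  badPath <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, badPath)
  expect_error(readCohortCsv(badPath), "line 4.*size_category")

  # header-only file is an empty cohort, not an error
  emptyPath <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(colnames(coh), collapse = ","), emptyPath)
  empty <- readCohortCsv(emptyPath)
  expect_equal(nrow(empty), 0L)

  expect_error(readCohortCsv(withr::local_tempfile()), "no such file")
})

test_that("validateCohort enforces label derivation consistency", {
  coh <- makeCohort(c(95, 115))
  coh$attenuation_degree[1] <- "iso"   # contradicts 95 HU
  expect_error(validateCohort(coh), "banding rule")
})
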