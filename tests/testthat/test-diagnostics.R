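test_that("diagnostic indices reproduce the headline operating point", {
  di <- diagnosticIndices(confusionCounts(29, 7, 23, 150))
  expect_equal(pct1(sensitivity(di)), 55.8)
  expect_equal(pct1(specificity(di)), 95.5)
  expect_equal(pct1(ppv(di)), 80.6)
  expect_equal(pct1(npv(di)), 86.7)
  expect_equal(pct1(accuracy(di)), 85.6)
  expect_equal(roundHalfUp(auc(di), 4), 0.7566)
})

test_that("every printed feature-table cell follows from its fractions", {
  # one printed specificity (size normal, 14.7) is a typo for 23/157 = 14.6
  # and is encoded at its arithmetic value in the reference data
  for (i in seq_len(nrow(refFeatureTable))) {
    row <- refFeatureTable[i, ]
    di <- diagnosticIndices(countsFromRefRow(row))
    expect_equal(pct1(sensitivity(di)), row$sens, info = paste(row$feature, row$category))
    expect_equal(pct1(specificity(di)), row$spec, info = paste(row$feature, row$category))
    expect_equal(pct1(ppv(di)), row$ppv, info = paste(row$feature, row$category))
    expect_equal(pct1(npv(di)), row$npv, info = paste(row$feature, row$category))
    expect_equal(pct1(accuracy(di)), row$acc, info = paste(row$feature, row$category))
  }
})

test_that("zero denominators yield flagged-undefined indices, not errors", {
  di <- diagnosticIndices(confusionCounts(0, 0, 0, 157))
  expect_true(is.na(sensitivity(di)))
  expect_true(is.na(ppv(di)))
  expect_equal(specificity(di), 1)
  expect_equal(accuracy(di), 1)
  expect_true(is.na(auc(di)))
  expect_warning(diagnosticIndices(confusionCounts(0, 0, 0, 0)), "undefined")
})

test_that("confusionFromCohort tallies against the derived DTD label", {
  fix <- reconstructFixtureCohort("table4")
  allNeg <- confusionFromCohort(fix, rep(FALSE, nrow(fix)))
  expect_equal(truePositives(allNeg) + falsePositives(allNeg), 0L)
  oracle <- confusionFromCohort(fix, dtdLabel)
  expect_equal(falsePositives(oracle) + falseNegatives(oracle), 0L)
  expect_equal(truePositives(oracle), 52L)
  expect_error(confusionFromCohort(fix[0, ], rep(TRUE, 0)), "non-empty")
})

test_that("two-point AUC equals balanced accuracy and stays bracketed", {
  expect_equal(twoPointAuc(1, 1), 1)
  set.seed(99)
  s <- runif(200); p <- runif(200)
  a <- twoPointAuc(s, p)
  expect_true(all(a >= pmin(s, p) - 1e-12 & a <= pmax(s, p) + 1e-12))
  expect_equal(a, (s + p) / 2)
  expect_error(twoPointAuc(1.2, 0.5), "\\[0, 1\\]")
})

test_that("Hanley-McNeil interval behaves and concords with a bootstrap", {
  ci <- aucCi(0.5, 100, 100)
  expect_equal(mean(ci), 0.5, tolerance = 1e-12)
  wide <- diff(aucCi(0.75, 30, 60))
  narrow <- diff(aucCi(0.75, 300, 600))
  expect_lt(narrow, wide)
  expect_true(all(aucCi(0.99, 5, 5) <= 1))

  # bootstrap oracle on the table4 fixture: resample patients, recompute the
  # k=3 two-point AUC, compare the SD of the bootstrap distribution with the
  # Hanley-McNeil SE (coarse concordance; HM is conservative here)
  fix <- reconstructFixtureCohort("table4")
  pos <- abnormalCount(fix) >= 3
  truth <- dtdLabel(fix)
  hm <- attr(aucCi(twoPointAuc(29 / 52, 150 / 157), 52, 157), "se")
  boots <- withr::with_seed(123, replicate(2000, {
    i <- sample.int(209, replace = TRUE)
    tpb <- sum(pos[i] & truth[i]); fnb <- sum(!pos[i] & truth[i])
    tnb <- sum(!pos[i] & !truth[i]); fpb <- sum(pos[i] & !truth[i])
    if (tpb + fnb == 0 || tnb + fpb == 0) NA_real_
    else (tpb / (tpb + fnb) + tnb / (tnb + fpb)) / 2
  }))
  expect_lt(abs(sd(boots, na.rm = TRUE) - hm), 0.01)
})

test_that("selectCutoff is order-invariant and breaks ties upward", {
  fix <- reconstructFixtureCohort("table4")
  a <- selectCutoff(fix, c(100, 80, 90))
  b <- selectCutoff(fix, c(80, 90, 100))
  expect_identical(a, b)
  expect_equal(selectCutoff(fix, 90)$cutoff, 90)   # single candidate
  # candidates with identical confusion counts: larger returned
  coh <- makeCohort(c(70, 70, 120, 120), dtd = c(TRUE, TRUE, FALSE, FALSE))
  tie <- selectCutoff(coh, c(80, 90, 100))
  expect_equal(tie$cutoff, 100)
})

test_that("chi-square matches the closed 2x2 form and the published margin signal", {
  marginTab <- matrix(c(153, 4, 40, 12), 2)   # smooth/lobulated x normal/DTD
  res <- chiSquareRx2(marginTab)
  expect_lt(res$p, 1e-4)
  # independent textbook recomputation
  a <- 153; b <- 40; c <- 4; d <- 12; N <- a + b + c + d
  expect_equal(res$statistic,
               N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d)),
               tolerance = 1e-12)

  propTab <- matrix(c(30, 60, 10, 20), 2)     # proportional rows
  res0 <- chiSquareRx2(propTab)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1)

  # all-zero rows are dropped, df follows retained rows
  res3 <- chiSquareRx2(rbind(c(130, 18), c(27, 34), c(0, 0)))
  expect_equal(res3$df, 1)
  expect_error(chiSquareRx2(rbind(c(5, 5), c(0, 0))), "non-empty")
})

test_that("chi-square agrees with the closed form on 1000 random 2x2 tables", {
  withr::with_seed(2024, {
    for (i in 1:1000) {
      tab <- matrix(rpois(4, lambda = 20) + 1, 2)
      res <- chiSquareRx2(tab)
      a <- tab[1, 1]; c <- tab[2, 1]; b <- tab[1, 2]; d <- tab[2, 2]
      N <- sum(tab)
      closed <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
      expect_equal(res$statistic, closed, tolerance = 1e-10)
    }
  })
})

test_that("logistic fit recovers truth, detects nulls and flags separation", {
  # parameter recovery at n = 5000
  withr::with_seed(77, {
    x <- rnorm(5000, mean = 105, sd = 20)
    eta <- 10 - 0.1 * x
    y <- rbinom(5000, 1, plogis(eta))
  })
  fit <- logisticFit(x, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept - 10), 3 * fit$se[["intercept"]])
  expect_lt(abs(fit$slope + 0.1), 3 * fit$se[["slope"]])

  # permuted labels: slope indistinguishable from zero
  withr::with_seed(78, yPerm <- sample(y))
  nullFit <- logisticFit(x, yPerm)
  expect_lt(abs(nullFit$slope), 3 * nullFit$se[["slope"]])

  # complete separation: flagged, not fatal
  sepFit <- logisticFit(1:10, c(rep(0, 5), rep(1, 5)))
  expect_true(sepFit$separation)
  expect_false(sepFit$converged)

  expect_error(logisticFit(1:5, rep(1, 5)), "both classes")
})
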