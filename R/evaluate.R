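# End-to-end cohort evaluation: cut-off sweep, per-feature indices,
# per-threshold indices, best operating points; text and JSON reports.

#' @rdname evaluateCohort
#' @export
setClass("CohortEvaluation",
  representation(
    cutoffTable    = "data.frame",
    featureTable   = "data.frame",
    thresholdTable = "data.frame",
    bestCutoffHu   = "numeric",
    bestK          = "integer",
    config         = "ClassifierConfig",
    n              = "integer"
  )
)

.indicesRow <- function(counts, level = 0.95) {
  di <- diagnosticIndices(counts, level = level)
  data.frame(tp = counts@tp, fp = counts@fp, fn = counts@fn, tn = counts@tn,
             sensitivity = di@sensitivity, specificity = di@specificity,
             ppv = di@ppv, npv = di@npv, accuracy = di@accuracy,
             auc = di@auc, ciLow = di@aucCi[1], ciHigh = di@aucCi[2])
}

#' Evaluate the CT score on a cohort
#'
#' Reproduces the full diagnostic-accuracy evaluation on any cohort:
#'
#' * a nonenhanced-HU *cut-off sweep* ("x or less" positive) over
#'   `cutoffs`, with indices and two-point AUC per candidate;
#' * *per-feature indices*, treating each category of each CT feature as a
#'   standalone predictor;
#' * *per-threshold indices* for the "k or more abnormal features" rules,
#'   k = 1..5.
#'
#' The best cut-off maximises the two-point AUC (ties to the larger value);
#' the best count threshold maximises accuracy (ties to the larger k, the
#' more specific rule). On the `table4` reference fixture this reproduces
#' the published operating point: cut-off 100 HU and k = 3 with
#' sensitivity/specificity/PPV/NPV/accuracy of 55.8/95.5/80.6/86.7/85.6%.
#'
#' @param cohort a validated cohort data.frame (at least one patient).
#' @param config a [classifierConfig()].
#' @param cutoffs candidate HU cut-offs (default `c(80, 90, 100)`).
#' @param level confidence level for AUC intervals.
#' @return A `CohortEvaluation`; `show()` prints the three aligned tables.
#' @export
#' @examples
#' evaluateCohort(reconstructFixtureCohort("table4"))
evaluateCohort <- function(cohort, config = classifierConfig(),
                           cutoffs = c(80, 90, 100), level = 0.95) {
  validateCohort(cohort, config)
  .stopIf(nrow(cohort) == 0L, "cannot evaluate an empty cohort")
  flags <- flagAbnormal(cohort, config)

  sel <- selectCutoff(cohort, cutoffs, comparison = config@comparison, level = level)
  cutoffTable <- sel$sweep

  featRows <- list()
  for (feat in names(cohortLevels)[-1]) {
    for (lv in cohortLevels[[feat]]) {
      pred <- as.character(cohort[[feat]]) == lv
      if (!any(pred)) next   # unobserved category: no usable predictor
      cnt <- confusionFromCohort(cohort, pred)
      featRows[[paste(feat, lv)]] <-
        cbind(data.frame(feature = feat, category = lv), .indicesRow(cnt, level))
    }
  }
  featureTable <- do.call(rbind, featRows)
  rownames(featureTable) <- NULL

  thrRows <- lapply(1:5, function(k) {
    cnt <- confusionFromCohort(cohort, flags$count >= k)
    cbind(data.frame(k = k), .indicesRow(cnt, level))
  })
  thresholdTable <- do.call(rbind, thrRows)

  acc <- thresholdTable$accuracy
  bestK <- if (all(is.na(acc))) NA_integer_ else max(which(acc == max(acc, na.rm = TRUE)))

  new("CohortEvaluation",
      cutoffTable = cutoffTable, featureTable = featureTable,
      thresholdTable = thresholdTable,
      bestCutoffHu = sel$cutoff, bestK = as.integer(bestK),
      config = config, n = nrow(cohort))
}

.fmtIndexCols <- function(df) {
  out <- df
  for (col in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    out[[col]] <- .fmtPct(df[[col]])
  }
  for (col in intersect(c("auc", "ciLow", "ciHigh"), names(df))) {
    out[[col]] <- ifelse(is.na(df[[col]]), "NA",
                         formatC(df[[col]], format = "f", digits = 4))
  }
  out
}

#' Format an evaluation as aligned text tables
#'
#' @param evaluation a [CohortEvaluation][evaluateCohort].
#' @return character vector of report lines (also used by `show()`).
#' @export
formatEvaluation <- function(evaluation) {
  e <- evaluation
  cap <- function(df) utils::capture.output(print(.fmtIndexCols(df), row.names = FALSE))
  c(sprintf("Cohort evaluation (n = %d)", e@n),
    "",
    sprintf("HU cut-off sweep ('%s'):", e@config@comparison),
    cap(e@cutoffTable),
    sprintf("best cut-off by two-point AUC: %g HU", e@bestCutoffHu),
    "",
    "Individual CT feature categories as predictors:",
    cap(e@featureTable),
    "",
    "'k or more abnormal features' classification:",
    cap(e@thresholdTable),
    sprintf("best threshold by accuracy: %d or more", e@bestK))
}

setMethod("show", "CohortEvaluation", function(object) {
  writeLines(formatEvaluation(object))
})

#' Write an evaluation report to JSON and text
#'
#' The JSON report carries the three tables plus run metadata: package
#' version, seed, and an md5 hash of the configuration.
#'
#' @param evaluation a [CohortEvaluation][evaluateCohort].
#' @param path output path without extension; writes `<path>.json` and
#'   `<path>.txt`.
#' @param seed the seed of the run that produced the cohort (recorded in the
#'   metadata; use `NA` for deterministic inputs).
#' @return The two file paths, invisibly.
#' @export
writeEvaluationReport <- function(evaluation, path, seed = NA_integer_) {
  e <- evaluation
  cfg <- list(lowHuCutoff = e@config@lowHuCutoff, highHuCutoff = e@config@highHuCutoff,
              sizeBand = e@config@sizeBand, k = e@config@k,
              comparison = e@config@comparison)
  payload <- list(
    metadata = list(package = "thyroCT",
                    version = as.character(utils::packageVersion("thyroCT")),
                    seed = seed, configHash = .configHash(cfg), config = cfg,
                    n = e@n),
    cutoffTable = e@cutoffTable,
    featureTable = e@featureTable,
    thresholdTable = e@thresholdTable,
    bestCutoffHu = e@bestCutoffHu,
    bestK = e@bestK
  )
  jsonPath <- paste0(path, ".json")
  txtPath <- paste0(path, ".txt")
  jsonlite::write_json(payload, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  writeLines(formatEvaluation(e), txtPath)
  invisible(c(json = jsonPath, text = txtPath))
}
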