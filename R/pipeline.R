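# File-based pipeline stages: simulate -> (phantoms) -> extract -> evaluate.
# Each stage is composable via files on disk and records seed + version +
# config hash in a metadata sidecar, so every stochastic run is replayable.

.runMetadata <- function(seed, extra = list()) {
  c(list(package = "thyroCT",
         version = as.character(utils::packageVersion("thyroCT")),
         seed = seed, timestamp = format(Sys.time(), tz = "UTC")),
    extra)
}

#' Simulate (or reconstruct) a cohort and write it to disk
#'
#' Wraps [sampleCohort()] / [reconstructFixtureCohort()]: writes
#' `cohort.csv` and `metadata.json` (seed, version, parameter hash) into
#' `outDir`. An empty request produces an empty CSV with a warning rather
#' than an error.
#'
#' @param outDir output directory (created if needed).
#' @param params a [cohortParams()] object (ignored when `fixture` is given).
#' @param fixture `NULL` (default; sample from `params`) or `"table4"` /
#'   `"section3"` for the deterministic 209-patient reference fixtures.
#' @param seed integer seed.
#' @return list with `cohort` and the written `paths`, invisibly.
#' @export
runSimulateCohort <- function(outDir, params = cohortParams(), fixture = NULL,
                              seed = 1L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(fixture)) {
    cohort <- sampleCohort(params, seed = seed)
    desc <- list(mode = "sampled", classSizes = as.list(params$classSizes),
                 correlation = params$correlation)
  } else {
    cohort <- reconstructFixtureCohort(fixture, seed = seed)
    desc <- list(mode = paste0("fixture:", fixture),
                 marginalResidual = fixtureResidual(cohort)$totalL1)
  }
  if (nrow(cohort) == 0L) warning("simulated cohort is empty")
  csvPath <- file.path(outDir, "cohort.csv")
  if (nrow(cohort) > 0L) writeCohortCsv(cohort, csvPath)
  else utils::write.csv(cohort[.cohortColumns], csvPath, row.names = FALSE, quote = FALSE)
  meta <- .runMetadata(seed, c(desc, list(configHash = .configHash(desc),
                                          nPatients = nrow(cohort))))
  metaPath <- file.path(outDir, "metadata.json")
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, paths = c(cohort = csvPath, metadata = metaPath)))
}

#' Evaluate a cohort CSV and write the report
#'
#' Reads a cohort (path or data.frame), runs [evaluateCohort()] and writes
#' `report.json` / `report.txt` into `outDir`.
#'
#' @param cohort a cohort data.frame or a path to a cohort CSV.
#' @param outDir output directory (created if needed).
#' @param config a [classifierConfig()].
#' @param cutoffs candidate HU cut-offs for the sweep.
#' @param seed seed recorded in the report metadata (`NA` for deterministic
#'   input).
#' @return The [CohortEvaluation][evaluateCohort], invisibly.
#' @export
runEvaluate <- function(cohort, outDir, config = classifierConfig(),
                        cutoffs = c(80, 90, 100), seed = NA_integer_) {
  if (is.character(cohort)) cohort <- readCohortCsv(cohort)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  ev <- evaluateCohort(cohort, config = config, cutoffs = cutoffs)
  writeEvaluationReport(ev, file.path(outDir, "report"), seed = seed)
  invisible(ev)
}

#' Phantom parameters realising a tabular feature profile
#'
#' Maps one profile row of a cohort onto [phantomParams()] whose noiseless
#' measurement recovers the profile: lobe HU from the profile's HU values;
#' AP diameter 1.5 / 2.4 / 0.8 cm for normal / increased / decreased size;
#' lobulation amplitude 0.2 with 5 undulations for a lobulated margin;
#' inhomogeneity of 20 HU at 4 mm scale on the affected phase(s) for an
#' inhomogeneous pattern; a focal -80 HU lesion covering >= 10% of the
#' mid-slice for a heterogeneous pattern (hosted in a widened lobe, offset
#' from the centre, so the measurement ROI never overlaps it). The texture
#' amplitude sits well above the 15 HU pattern threshold yet below the regime
#' where a smooth Gaussian field produces spurious >= 50 HU focal blobs, so
#' the extracted pattern matches the generating one reliably.
#'
#' @param profile one cohort row (or any one-row data.frame with the profile
#'   columns).
#' @param noiseSd sensor-noise SD for the generated phantom (default 0).
#' @param inhomAmplitude texture SD used for inhomogeneous patterns
#'   (default 20 HU).
#' @return A [phantomParams()] object.
#' @export
profileToPhantomParams <- function(profile, noiseSd = 0, inhomAmplitude = 20) {
  .stopIf(nrow(profile) != 1L, "profile must be a single row")
  size <- as.character(profile$size_category)
  ap <- switch(size, normal = 1.5, increased = 2.4, decreased = 0.8)
  attPat <- as.character(profile$attenuation_pattern)
  enhPat <- as.character(profile$enhancement_pattern)
  inhom <- c(if (attPat == "inhomogeneous") inhomAmplitude else 0,
             if (enhPat == "inhomogeneous") inhomAmplitude else 0)
  lesions <- data.frame()
  lobeWidth <- 7
  lobeGap <- 2
  hetPhases <- c("nonenhanced", "enhanced")[c(attPat, enhPat) == "heterogeneous"]
  if (length(hetPhases)) {
    # widen the lobe and park the lesion laterally: sized to ~14% of the mid
    # slice (comfortably over the 10% focal rule even after boundary
    # clipping) and placed clear of the central measurement ROI
    lobeWidth <- 16
    lobeGap <- 4
    bMm <- ap * 10 / 2
    rLes <- sqrt(0.14 * lobeWidth * bMm)
    rRoi <- 0.4 * min(lobeWidth, bMm)
    lesions <- data.frame(lobe = "left", dx = rRoi + rLes + 1, dy = 0, dz = 0,
                          radius = rLes, huOffset = -80,
                          phase = if (length(hetPhases) == 2L) "both" else hetPhases)
  }
  phantomParams(
    lobeDiameterAP = c(ap, ap),
    lobeHu = rep(profile$hu_nonenhanced, 2),
    lobeHuEnhanced = rep(profile$hu_enhanced, 2),
    noiseSd = noiseSd,
    inhomAmplitude = inhom,
    inhomScale = 4,
    lesions = lesions,
    lobeWidth = lobeWidth,
    lobeGap = lobeGap,
    lobulationAmplitude = if (as.character(profile$margin) == "lobulated") 0.2 else 0,
    lobulationLobes = 5L
  )
}

#' Run the imaging pipeline over a cohort of profiles
#'
#' For every patient, builds a phantom realising the tabular profile
#' ([profileToPhantomParams()]), extracts the profile back from the image
#' ([extractProfile()]), and evaluates the extracted cohort exactly like a
#' tabular one. The tabular evaluation of the same profiles is the natural
#' oracle: with no noise the two agree feature-for-feature.
#'
#' @param cohort a cohort data.frame (e.g. from [sampleCohort()]); the
#'   histopathology labels are carried through to the extracted cohort.
#' @param outDir optional output directory; when given, the extracted cohort
#'   CSV, the evaluation report and a concordance table are written. Set
#'   `writeVolumes = TRUE` to also write every phantom as NIfTI.
#' @param config a [classifierConfig()].
#' @param noiseSd,inhomAmplitude forwarded to [profileToPhantomParams()]
#'   (defaults 0 and 20 HU).
#' @param seed integer seed; phantom i uses `seed + i`.
#' @param writeVolumes write NIfTI phantoms under `outDir/phantoms/`.
#' @return list with `extractedCohort`, `evaluation`
#'   ([CohortEvaluation][evaluateCohort]), and `concordance` — the
#'   per-feature agreement fraction between generating and extracted
#'   profiles.
#' @export
runPhantomPipeline <- function(cohort, outDir = NULL,
                               config = classifierConfig(),
                               noiseSd = 0, inhomAmplitude = 20,
                               seed = 1L, writeVolumes = FALSE) {
  validateCohort(cohort, config)
  .stopIf(nrow(cohort) == 0L, "cohort must contain at least one patient")
  featCols <- c("attenuation_degree", "attenuation_pattern", "size_category",
                "margin", "enhancement_pattern")
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    pp <- profileToPhantomParams(cohort[i, , drop = FALSE],
                                 noiseSd = noiseSd, inhomAmplitude = inhomAmplitude)
    vol <- generatePhantom(pp, seed = seed + i)
    if (writeVolumes && !is.null(outDir)) {
      dir.create(file.path(outDir, "phantoms"), recursive = TRUE, showWarnings = FALSE)
      writePhantom(vol, file.path(outDir, "phantoms", cohort$patient_id[i]))
    }
    rows[[i]] <- extractProfile(vol, config)
  }
  extracted <- cbind(
    data.frame(patient_id = cohort$patient_id,
               histopath_class = cohort$histopath_class,
               stringsAsFactors = FALSE),
    do.call(rbind, rows))
  extracted <- extracted[.cohortColumns]
  concordance <- vapply(featCols, function(col) {
    mean(as.character(extracted[[col]]) == as.character(cohort[[col]]))
  }, numeric(1))
  ev <- evaluateCohort(extracted, config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeCohortCsv(extracted, file.path(outDir, "extracted_cohort.csv"))
    writeEvaluationReport(ev, file.path(outDir, "report"), seed = seed)
    jsonlite::write_json(
      c(.runMetadata(seed), list(concordance = as.list(concordance))),
      file.path(outDir, "concordance.json"), auto_unbox = TRUE, digits = NA)
  }
  list(extractedCohort = extracted, evaluation = ev, concordance = concordance)
}
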