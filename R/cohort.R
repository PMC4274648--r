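# Synthetic cohort generation and cohort CSV I/O.
#
# A "cohort" is a plain data.frame with the columns
#   patient_id, histopath_class, hu_nonenhanced, hu_enhanced,
#   attenuation_degree, attenuation_pattern, size_category, margin,
#   enhancement_pattern
# The DTD label is always *derived* (histopath_class != "normal"), never stored.

.cohortColumns <- c("patient_id", "histopath_class", "hu_nonenhanced", "hu_enhanced",
                    "attenuation_degree", "attenuation_pattern", "size_category",
                    "margin", "enhancement_pattern")

# reference per-class frequencies (proportions) of the categorical features,
# normal thyroid n = 157 vs DTD n = 52
.referenceFeatureProbs <- function() {
  list(
    normal = list(
      attenuation_pattern = c(homogeneous = 142, inhomogeneous = 14, heterogeneous = 1) / 157,
      size_category       = c(normal = 134, increased = 22, decreased = 1) / 157,
      margin              = c(smooth = 153, lobulated = 4) / 157,
      enhancement_pattern = c(homogeneous = 152, inhomogeneous = 5, heterogeneous = 0) / 157
    ),
    dtd = list(
      attenuation_pattern = c(homogeneous = 17, inhomogeneous = 35, heterogeneous = 0) / 52,
      size_category       = c(normal = 38, increased = 14, decreased = 0) / 52,
      margin              = c(smooth = 40, lobulated = 12) / 52,
      enhancement_pattern = c(homogeneous = 22, inhomogeneous = 30, heterogeneous = 0) / 52
    )
  )
}

# reference per-class HU moments: mean/sd on nonenhanced and enhanced CT
.referenceHuParams <- function() {
  list(normal = c(mean = 114.3, sd = 21.2, meanEnh = 202.5, sdEnh = 29.3),
       dtd    = c(mean = 94.5,  sd = 21.3, meanEnh = 187.6, sdEnh = 29.9))
}

#' Cohort generator parameters
#'
#' Defaults reproduce the reference study population: 209 patients
#' (157 normal, 17 Hashimoto thyroiditis, 34 non-Hashimoto lymphocytic
#' thyroiditis, 1 diffuse hyperplasia), per-class Gaussian HU distributions
#' (normal 114.3 +/- 21.2 nonenhanced and 202.5 +/- 29.3 enhanced; DTD
#' 94.5 +/- 21.3 and 187.6 +/- 29.9) and per-class categorical feature
#' frequencies from the reference frequency table. All three DTD
#' histopathology classes share the DTD distributions (only marginals by
#' normal/DTD group are published).
#'
#' The attenuation *degree* is never sampled from a simplex: it is derived
#' from the sampled nonenhanced HU by the banding rule, which keeps the
#' profile invariant (degree consistent with HU) true by construction.
#'
#' @param classSizes named integer vector over the histopathology classes
#'   (`normal`, `hashimoto`, `non_hashimoto_lt`, `diffuse_hyperplasia`).
#' @param huParams named list `normal`/`dtd`, each `c(mean, sd, meanEnh, sdEnh)`.
#' @param featureProbs named list `normal`/`dtd` of per-feature probability
#'   simplices (must sum to 1 within 1e-9).
#' @param correlation inter-feature dependence strength in `[0, 1)`: 0
#'   (default) samples features independently; larger values couple all
#'   features and the HU values through a shared latent Gaussian (copula), so
#'   abnormalities co-occur while every marginal is preserved exactly.
#' @return A list of class `CohortGeneratorParams`.
#' @seealso [sampleCohort()]
#' @export
#' @examples
#' cohortParams(classSizes = c(normal = 0, non_hashimoto_lt = 100))
cohortParams <- function(classSizes = c(normal = 157L, hashimoto = 17L,
                                        non_hashimoto_lt = 34L,
                                        diffuse_hyperplasia = 1L),
                         huParams = .referenceHuParams(),
                         featureProbs = .referenceFeatureProbs(),
                         correlation = 0) {
  full <- c(normal = 0L, hashimoto = 0L, non_hashimoto_lt = 0L, diffuse_hyperplasia = 0L)
  .stopIf(is.null(names(classSizes)) || !all(names(classSizes) %in% names(full)),
          "classSizes must be named with histopathology classes")
  full[names(classSizes)] <- as.integer(classSizes)
  .stopIf(any(full < 0L), "class sizes must be >= 0")
  for (grp in c("normal", "dtd")) {
    hp <- huParams[[grp]]
    .stopIf(is.null(hp) || hp[["sd"]] <= 0 || hp[["sdEnh"]] <= 0,
            "HU standard deviations must be > 0 for group '", grp, "'")
    for (feat in names(featureProbs[[grp]])) {
      p <- featureProbs[[grp]][[feat]]
      .stopIf(any(p < 0) || abs(sum(p) - 1) > 1e-9,
              "feature probabilities for ", grp, "/", feat,
              " must be a simplex (non-negative, sum 1 within 1e-9)")
      .stopIf(!all(names(p) %in% cohortLevels[[feat]]),
              "unknown category in ", grp, "/", feat)
    }
  }
  .stopIf(length(correlation) != 1L || correlation < 0 || correlation >= 1,
          "correlation must be in [0, 1)")
  structure(list(classSizes = full, huParams = huParams,
                 featureProbs = featureProbs, correlation = correlation),
            class = "CohortGeneratorParams")
}

# categories ordered least-abnormal first, so the abnormal category occupies
# the upper tail of the latent uniform (positive correlation couples
# abnormalities across features)
.copulaOrder <- list(
  attenuation_pattern = c("homogeneous", "heterogeneous", "inhomogeneous"),
  size_category       = c("normal", "decreased", "increased"),
  margin              = c("smooth", "lobulated"),
  enhancement_pattern = c("homogeneous", "heterogeneous", "inhomogeneous")
)

#' Sample a synthetic patient cohort
#'
#' Draws per-patient HU values from the per-class Gaussian distributions and
#' categorical features from the per-class simplices. With
#' `params$correlation > 0` a shared standard-normal latent per patient
#' couples all features (Gaussian copula through a latent-threshold map), and
#' the nonenhanced HU is tied to the same latent with *negative* loading (low
#' HU is the abnormal direction); marginals are unchanged either way.
#'
#' @param params a [cohortParams()] object.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return A cohort data.frame (one row per patient) with the documented
#'   column contract; see [writeCohortCsv()].
#' @export
#' @examples
#' coh <- sampleCohort(cohortParams(), seed = 1)
#' table(coh$histopath_class)
sampleCohort <- function(params = cohortParams(), seed = 1L) {
  .stopIf(!inherits(params, "CohortGeneratorParams"),
          "params must come from cohortParams()")
  sizes <- params$classSizes
  n <- sum(sizes)
  classes <- rep(names(sizes), times = sizes)
  if (n == 0L) {
    coh <- as.data.frame(stats::setNames(rep(list(character(0)), length(.cohortColumns)),
                                         .cohortColumns))
    coh$hu_nonenhanced <- numeric(0)
    coh$hu_enhanced <- numeric(0)
    return(coh)
  }
  grp <- ifelse(classes == "normal", "normal", "dtd")
  rho <- params$correlation

  .withSeed(seed, {
    z0 <- stats::rnorm(n)
    latent <- function() {
      if (rho > 0) stats::pnorm(sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n))
      else stats::runif(n)
    }
    # nonenhanced HU: low HU is abnormal, so load the shared latent negatively
    uHu <- latent()
    huN <- numeric(n)
    huE <- numeric(n)
    uEnh <- stats::runif(n)
    for (g in c("normal", "dtd")) {
      i <- grp == g
      hp <- params$huParams[[g]]
      huN[i] <- hp[["mean"]] + hp[["sd"]] * stats::qnorm(1 - uHu[i])
      huE[i] <- huN[i] - hp[["mean"]] + hp[["meanEnh"]] +
        sqrt(max(hp[["sdEnh"]]^2 - hp[["sd"]]^2, 0)) * stats::qnorm(uEnh[i])
    }
    feats <- list()
    for (feat in names(.copulaOrder)) {
      u <- latent()
      out <- character(n)
      for (g in c("normal", "dtd")) {
        i <- grp == g
        p <- params$featureProbs[[g]][[feat]]
        ord <- intersect(.copulaOrder[[feat]], names(p))
        cum <- cumsum(p[ord])
        out[i] <- ord[findInterval(u[i], c(0, cum), rightmost.closed = TRUE,
                                   left.open = TRUE)]
      }
      feats[[feat]] <- out
    }
  })

  data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    histopath_class = classes,
    hu_nonenhanced = huN,
    hu_enhanced = huE,
    attenuation_degree = as.character(classifyAttenuationDegree(huN)),
    attenuation_pattern = feats$attenuation_pattern,
    size_category = feats$size_category,
    margin = feats$margin,
    enhancement_pattern = feats$enhancement_pattern,
    stringsAsFactors = FALSE
  )
}

#' Derive the DTD labels of a cohort
#'
#' @param cohort a cohort data.frame.
#' @return logical vector: `TRUE` iff `histopath_class != "normal"`.
#' @export
dtdLabel <- function(cohort) {
  .stopIf(!"histopath_class" %in% names(cohort),
          "cohort must have a histopath_class column")
  as.character(cohort$histopath_class) != "normal"
}

#' Validate the cohort column contract
#'
#' Checks columns, category vocabularies, HU finiteness and the consistency
#' of `attenuation_degree` with the HU banding rule.
#'
#' @param cohort a cohort data.frame.
#' @param config a [classifierConfig()] supplying the banding cutoffs.
#' @return `cohort`, invisibly; errors describe the first offending row.
#' @export
validateCohort <- function(cohort, config = classifierConfig()) {
  .stopIf(!is.data.frame(cohort), "cohort must be a data.frame")
  missing <- setdiff(.cohortColumns, names(cohort))
  .stopIf(length(missing) > 0, "cohort is missing columns: ",
          paste(missing, collapse = ", "))
  if (nrow(cohort) == 0L) return(invisible(cohort))
  for (col in c("histopath_class", names(cohortLevels)[-1])) {
    lv <- if (col == "histopath_class") cohortLevels$histopath else cohortLevels[[col]]
    bad <- which(!as.character(cohort[[col]]) %in% lv)
    .stopIf(length(bad) > 0, "row ", bad[1], ": invalid ", col, " value '",
            as.character(cohort[[col]])[bad[1]], "'")
  }
  for (col in c("hu_nonenhanced", "hu_enhanced")) {
    bad <- which(!is.finite(cohort[[col]]))
    .stopIf(length(bad) > 0, "row ", bad[1], ": non-finite ", col)
  }
  expected <- as.character(classifyAttenuationDegree(cohort$hu_nonenhanced, config))
  bad <- which(expected != as.character(cohort$attenuation_degree))
  .stopIf(length(bad) > 0, "row ", bad[1],
          ": attenuation_degree inconsistent with hu_nonenhanced under the banding rule")
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' Lossless round-trip of the cohort column contract (`patient_id`,
#' `histopath_class`, `hu_nonenhanced`, `hu_enhanced`, `attenuation_degree`,
#' `attenuation_pattern`, `size_category`, `margin`, `enhancement_pattern`;
#' UTF-8, comma-separated, mandatory header). Unknown categories and
#' malformed rows are rejected with the offending file line number; a file
#' holding only the header yields an empty cohort.
#'
#' @param path file path.
#' @param cohort a validated cohort data.frame.
#' @return `readCohortCsv`: the cohort data.frame. `writeCohortCsv`: `path`,
#'   invisibly.
#' @export
readCohortCsv <- function(path) {
  .stopIf(!file.exists(path), "no such file: ", path)
  coh <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(.cohortColumns, names(coh))
  .stopIf(length(missing) > 0, "invalid cohort header, missing: ",
          paste(missing, collapse = ", "))
  coh <- coh[.cohortColumns]
  for (col in c("hu_nonenhanced", "hu_enhanced")) {
    num <- suppressWarnings(as.numeric(coh[[col]]))
    bad <- which(is.na(num) & nzchar(coh[[col]]))
    .stopIf(length(bad) > 0, path, " line ", bad[1] + 1L,
            ": cannot parse ", col, " value '", coh[[col]][bad[1]], "'")
    coh[[col]] <- num
  }
  tryCatch(validateCohort(coh), error = function(e) {
    # re-map validator row numbers to file line numbers (header is line 1)
    msg <- sub("^row (\\d+)", "", conditionMessage(e))
    row <- suppressWarnings(as.integer(sub("^row (\\d+).*$", "\\1",
                                           conditionMessage(e))))
    if (!is.na(row)) stop(path, " line ", row + 1L, ":", msg, call. = FALSE)
    stop(conditionMessage(e), call. = FALSE)
  })
  coh
}

#' @rdname readCohortCsv
#' @export
writeCohortCsv <- function(cohort, path) {
  validateCohort(cohort)
  utils::write.csv(cohort[.cohortColumns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
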