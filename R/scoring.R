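# Feature scoring: the five-feature rule applied to patient profiles.

#' Band a nonenhanced HU measurement into an attenuation degree
#'
#' Low attenuation is `hu < lowHuCutoff`, high is `hu > highHuCutoff`,
#' everything in between (inclusive) is isoattenuation — so a measurement of
#' exactly 100 HU is iso, not low.
#'
#' @param hu numeric vector of mean parenchymal HU on nonenhanced CT.
#' @param config a [classifierConfig()].
#' @return factor with levels `iso`, `low`, `high`.
#' @export
#' @examples
#' classifyAttenuationDegree(c(94.5, 100, 114.3, 181))
classifyAttenuationDegree <- function(hu, config = classifierConfig()) {
  .stopIf(any(!is.finite(hu)), "HU values must be finite")
  out <- ifelse(hu < config@lowHuCutoff, "low",
                ifelse(hu > config@highHuCutoff, "high", "iso"))
  factor(out, levels = cohortLevels$attenuation_degree)
}

#' Degree of parenchymal enhancement
#'
#' The contrast-enhanced minus the nonenhanced mean parenchymal HU. This
#' quantity is computed and reported but contributes no abnormality flag: no
#' enhancement-degree cut-off separates normal from DTD glands.
#'
#' @param enhancedHu mean HU on contrast-enhanced CT, or a cohort data.frame
#'   with `hu_enhanced` and `hu_nonenhanced` columns.
#' @param nonenhancedHu mean HU on nonenhanced CT (ignored when `enhancedHu`
#'   is a cohort).
#' @return numeric vector of HU differences.
#' @export
#' @examples
#' enhancementDegree(202.5, 114.3)  # 88.2, the normal-thyroid mean
#' enhancementDegree(187.6, 94.5)   # 93.1, the DTD mean
enhancementDegree <- function(enhancedHu, nonenhancedHu) {
  if (is.data.frame(enhancedHu)) {
    .stopIf(!all(c("hu_enhanced", "hu_nonenhanced") %in% names(enhancedHu)),
            "cohort must have hu_enhanced and hu_nonenhanced columns")
    return(enhancedHu$hu_enhanced - enhancedHu$hu_nonenhanced)
  }
  .stopIf(any(!is.finite(enhancedHu)) || any(!is.finite(nonenhancedHu)),
          "HU values must be finite")
  enhancedHu - nonenhancedHu
}

#' Flag the five DTD-suggestive CT features
#'
#' Applies the categorical rules to one or more feature profiles. A feature is
#' abnormal iff: attenuation degree is `low`; attenuation pattern is
#' `inhomogeneous`; size category is `increased`; margin is `lobulated`;
#' enhancement pattern is `inhomogeneous`. Heterogeneous patterns and
#' decreased size are *not* abnormal under this rule (only the five listed
#' categories count), and the enhancement degree raises no flag.
#'
#' If `attenuation_degree` is absent it is derived from `hu_nonenhanced` via
#' [classifyAttenuationDegree()].
#'
#' @param profile a data.frame with the profile columns
#'   (`attenuation_degree` or `hu_nonenhanced`, `attenuation_pattern`,
#'   `size_category`, `margin`, `enhancement_pattern`); typically a cohort.
#' @param config a [classifierConfig()].
#' @return A data.frame with logical columns `low_attenuation`,
#'   `inhomogeneous_attenuation`, `increased_size`, `lobulated_margin`,
#'   `inhomogeneous_enhancement` and an integer `count` column (0-5).
#' @export
#' @examples
#' prof <- data.frame(attenuation_degree = "low", attenuation_pattern = "inhomogeneous",
#'                    size_category = "increased", margin = "smooth",
#'                    enhancement_pattern = "homogeneous")
#' flagAbnormal(prof)$count  # 3
flagAbnormal <- function(profile, config = classifierConfig()) {
  .stopIf(!is.data.frame(profile), "profile must be a data.frame")
  need <- c("attenuation_pattern", "size_category", "margin", "enhancement_pattern")
  .stopIf(!all(need %in% names(profile)),
          "profile is missing columns: ", paste(setdiff(need, names(profile)), collapse = ", "))
  deg <- if ("attenuation_degree" %in% names(profile)) {
    as.character(profile$attenuation_degree)
  } else {
    .stopIf(!"hu_nonenhanced" %in% names(profile),
            "profile needs attenuation_degree or hu_nonenhanced")
    as.character(classifyAttenuationDegree(profile$hu_nonenhanced, config))
  }
  for (col in names(cohortLevels)[-1]) {
    if (col %in% names(profile)) {
      bad <- !as.character(profile[[col]]) %in% cohortLevels[[col]]
      .stopIf(any(bad), "unknown ", col, " value: ",
              paste(unique(profile[[col]][bad]), collapse = ", "))
    }
  }
  flags <- data.frame(
    low_attenuation           = deg == "low",
    inhomogeneous_attenuation = as.character(profile$attenuation_pattern) == "inhomogeneous",
    increased_size            = as.character(profile$size_category) == "increased",
    lobulated_margin          = as.character(profile$margin) == "lobulated",
    inhomogeneous_enhancement = as.character(profile$enhancement_pattern) == "inhomogeneous"
  )
  flags$count <- as.integer(rowSums(flags))
  flags
}

#' Count abnormal CT features per patient
#'
#' @inheritParams flagAbnormal
#' @return integer vector of abnormal-feature counts in 0..5.
#' @export
abnormalCount <- function(profile, config = classifierConfig()) {
  flagAbnormal(profile, config)$count
}

#' Classify DTD from abnormal-feature flags
#'
#' Positive iff the abnormal-feature count reaches the threshold `k` of the
#' configuration ("k or more" rule; the reference operating point is k = 3).
#'
#' @param flags output of [flagAbnormal()], or an integer vector of counts.
#' @param config a [classifierConfig()]; `config@k` is the threshold.
#' @return logical vector, `TRUE` = DTD-positive.
#' @export
#' @examples
#' classifyDtd(c(0, 2, 3, 5))            # k = 3 default
#' classifyDtd(2, classifierConfig(k = 2))
classifyDtd <- function(flags, config = classifierConfig()) {
  count <- if (is.data.frame(flags)) flags$count else flags
  .stopIf(anyNA(count) || any(count < 0 | count > 5),
          "abnormal counts must be integers in 0..5")
  count >= config@k
}
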