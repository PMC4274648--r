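# Deterministic reconstruction of the 209-patient reference cohorts.
#
# Two published summaries of the same study population disagree slightly: the
# per-threshold confusion table ("table4" mode: 46/40/29 DTD and 84/27/7
# normals at >= 1/2/3 abnormal features) and the results narrative
# ("section3" mode: totals 98/50/31/15/5 with per-class breakdowns). Both are
# shipped; table4 matches the headline operating point and is the acceptance
# anchor.

# per-class abnormal-count level distributions (columns = exactly 0..5 features)
.fixtureLevelCounts <- function(mode) {
  if (mode == "table4") {
    # >=k columns fixed for k = 1,2,3 by the threshold table; k >= 4 levels
    # follow the narrative (15 with >=4, of which 1 normal; all 5 fives DTD)
    rbind(
      normal = c(73, 57, 20, 6, 1, 0),
      dtd    = c(6, 6, 11, 15, 9, 5)
    )
  } else {
    # narrative >=k chains per histopathology class:
    # hashimoto 17,16,13,7,3; non-hashimoto 26,20,12,6,2; hyperplasia at 4;
    # normals 54,13,5,1,0 (five-feature split of the 5 cases by largest
    # remainder on the >=4 membership 7:6)
    rbind(
      normal              = c(103, 41, 8, 4, 1, 0),
      hashimoto           = c(0, 1, 3, 6, 4, 3),
      non_hashimoto_lt    = c(8, 6, 8, 6, 4, 2),
      diffuse_hyperplasia = c(0, 0, 0, 0, 1, 0)
    )
  }
}

.featureOrder <- c("low_attenuation", "inhomogeneous_attenuation", "increased_size",
                   "lobulated_margin", "inhomogeneous_enhancement")

# abnormal-feature totals per group from the reference frequency table
.featureQuotas <- function(group) {
  if (group == "normal") {
    c(low_attenuation = 27, inhomogeneous_attenuation = 14, increased_size = 22,
      lobulated_margin = 4, inhomogeneous_enhancement = 5)
  } else {
    c(low_attenuation = 34, inhomogeneous_attenuation = 35, increased_size = 14,
      lobulated_margin = 12, inhomogeneous_enhancement = 30)
  }
}

# greedy integer assignment: patients in descending count order take their c
# features from the largest remaining quotas, ties broken by feature order
.greedyAssignFeatures <- function(counts, quotas) {
  n <- length(counts)
  flags <- matrix(FALSE, n, 5L, dimnames = list(NULL, .featureOrder))
  remaining <- quotas[.featureOrder]
  ord <- order(-counts)          # stable for ties
  for (i in ord) {
    c_i <- counts[i]
    if (c_i == 0L) next
    rank <- order(-remaining, seq_along(remaining))  # quota desc, then order
    pick <- rank[seq_len(c_i)]
    flags[i, pick] <- TRUE
    remaining[pick] <- remaining[pick] - 1L
  }
  flags
}

#' Reconstruct a 209-patient reference cohort
#'
#' Builds, deterministically, a cohort of 209 patient records (157 normal,
#' 17 Hashimoto thyroiditis, 34 non-Hashimoto lymphocytic thyroiditis,
#' 1 diffuse hyperplasia) whose abnormal-feature counts reproduce a published
#' summary of the reference study exactly:
#'
#' * `mode = "table4"`: the number of patients with >= k abnormal features
#'   matches the per-threshold confusion table for k = 1, 2, 3 (DTD:
#'   46/40/29; normals: 84/27/7), so evaluating the "k or more" classifiers
#'   on the fixture returns the printed confusion cells.
#' * `mode = "section3"`: the >= k totals match the results narrative
#'   (98/50/31/15/5 overall, with the stated per-class breakdowns, e.g. 31
#'   cases at >= 3 of which 5 are histopathologically normal).
#'
#' Individual features are then distributed by a deterministic greedy integer
#' assignment that tracks the per-group abnormal-feature totals of the
#' reference frequency table (feature order: attenuation degree, attenuation
#' pattern, size, margin, enhancement pattern). The two summaries are not
#' perfectly consistent with the frequency table, so the achieved L1 residual
#' between assigned and published feature marginals is attached as the
#' `marginalResidual` attribute (see [fixtureResidual()]) rather than failing
#' silently. HU values are filled in deterministically, consistent with each
#' patient's attenuation degree and with the published cut-off sweep (one
#' normal subject sits at exactly 100 HU).
#'
#' @param mode `"table4"` or `"section3"`.
#' @param seed accepted for interface symmetry with the stochastic
#'   generators; the reconstruction is fully deterministic and ignores it.
#' @return A cohort data.frame of 209 rows with attribute `marginalResidual`.
#' @export
#' @examples
#' fix <- reconstructFixtureCohort("table4")
#' table(abnormalCount(fix) >= 3, dtdLabel(fix))
reconstructFixtureCohort <- function(mode = c("table4", "section3"), seed = 0L) {
  mode <- match.arg(mode)
  lev <- .fixtureLevelCounts(mode)
  classes <- character(0)
  counts <- integer(0)
  for (cl in rownames(lev)) {
    classes <- c(classes, rep(cl, sum(lev[cl, ])))
    counts <- c(counts, rep(0:5, times = lev[cl, ]))
  }

  if (mode == "table4") {
    # DTD subclasses are not pinned by the threshold table: assign by
    # descending count (hyperplasia takes the first count-4 patient,
    # Hashimoto the next 17, the rest non-Hashimoto LT)
    isDtd <- classes == "dtd"
    dtdCounts <- counts[isDtd]
    ord <- order(-dtdCounts)
    lab <- rep("non_hashimoto_lt", length(dtdCounts))
    dh <- ord[which(dtdCounts[ord] == 4L)[1]]
    lab[dh] <- "diffuse_hyperplasia"
    lab[setdiff(ord, dh)[1:17]] <- "hashimoto"
    classes[isDtd] <- lab
  }

  group <- ifelse(classes == "normal", "normal", "dtd")
  flags <- matrix(FALSE, length(classes), 5L, dimnames = list(NULL, .featureOrder))
  residual <- list()
  for (g in c("normal", "dtd")) {
    i <- which(group == g)
    quotas <- .featureQuotas(g)
    fl <- .greedyAssignFeatures(counts[i], quotas)
    flags[i, ] <- fl
    achieved <- colSums(fl)
    residual[[g]] <- list(target = quotas, achieved = achieved,
                          l1 = sum(abs(achieved - quotas)))
  }
  residual$totalL1 <- residual$normal$l1 + residual$dtd$l1

  # deterministic HU assignment: low-flagged patients fall in the bands the
  # cut-off sweep implies (<=80, (80,90], (90,100)); iso patients sit well
  # inside the iso band except one normal subject at exactly 100 HU
  hu <- numeric(length(classes))
  for (g in c("normal", "dtd")) {
    i <- which(group == g)
    low <- i[flags[i, "low_attenuation"]]
    bandN <- if (g == "dtd") c(14L, 11L) else c(8L, 11L)
    bandHu <- c(75, 85, 95)
    nl <- length(low)
    take <- c(min(bandN[1], nl), min(bandN[2], max(nl - bandN[1], 0L)))
    hu[low] <- rep(bandHu, times = c(take, nl - sum(take)))
    iso <- setdiff(i, low)
    hu[iso] <- if (g == "dtd") 120 else 115
    if (g == "normal" && length(iso)) hu[iso[1]] <- 100  # the boundary subject
  }
  enh <- hu + ifelse(group == "dtd", 93.1, 88.2)

  attPattern <- ifelse(flags[, "inhomogeneous_attenuation"], "inhomogeneous", "homogeneous")
  sizeCat <- ifelse(flags[, "increased_size"], "increased", "normal")
  margin <- ifelse(flags[, "lobulated_margin"], "lobulated", "smooth")
  enhPattern <- ifelse(flags[, "inhomogeneous_enhancement"], "inhomogeneous", "homogeneous")

  # the frequency table records one normal gland with heterogeneous
  # attenuation and one with decreased size; neither is an abnormal feature,
  # so they are carried by two feature-count-0 normals
  zeros <- which(group == "normal" & counts == 0L)
  if (length(zeros) >= 2L) {
    attPattern[zeros[1]] <- "heterogeneous"
    sizeCat[zeros[2]] <- "decreased"
  }

  coh <- data.frame(
    patient_id = character(length(classes)),
    histopath_class = classes,
    hu_nonenhanced = hu,
    hu_enhanced = enh,
    attenuation_degree = as.character(classifyAttenuationDegree(hu)),
    attenuation_pattern = attPattern,
    size_category = sizeCat,
    margin = margin,
    enhancement_pattern = enhPattern,
    stringsAsFactors = FALSE
  )
  # stable presentation order: normals first, then DTD classes, by count desc
  clOrder <- match(coh$histopath_class, cohortLevels$histopath)
  ord <- order(clOrder, -counts)
  coh <- coh[ord, , drop = FALSE]
  coh$patient_id <- sprintf("F%03d", seq_len(nrow(coh)))
  rownames(coh) <- NULL
  attr(coh, "marginalResidual") <- residual
  validateCohort(coh)
  coh
}

#' Feature-marginal residual of a reconstructed fixture
#'
#' @param cohort a cohort from [reconstructFixtureCohort()].
#' @return The `marginalResidual` attribute: per-group target and achieved
#'   abnormal-feature totals and their L1 distances, plus `totalL1`.
#' @export
fixtureResidual <- function(cohort) {
  res <- attr(cohort, "marginalResidual")
  .stopIf(is.null(res), "cohort carries no marginalResidual attribute")
  res
}

#' Brute-force audit of the sum-of-thresholds identity
#'
#' For any cohort, the total number of abnormal feature instances equals the
#' sum over k >= 1 of the number of patients with >= k abnormal features.
#' This audits the identity by direct enumeration on the flag matrix.
#'
#' @param cohort a cohort data.frame.
#' @param config a [classifierConfig()].
#' @return list with `totalInstances` (sum of all flags), `thresholdCounts`
#'   (patients at >= k for k = 1..5), `thresholdSum` and logical `identityHolds`.
#' @export
abnormalInstanceAudit <- function(cohort, config = classifierConfig()) {
  fl <- flagAbnormal(cohort, config)
  counts <- fl$count
  thr <- vapply(1:5, function(k) sum(counts >= k), integer(1))
  total <- sum(as.matrix(fl[, .featureOrder]))
  list(totalInstances = total,
       thresholdCounts = stats::setNames(thr, paste0("ge", 1:5)),
       thresholdSum = sum(thr),
       identityHolds = total == sum(thr))
}
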