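# Diagnostic-accuracy machinery: confusion counts, indices, two-point ROC
# AUC with Hanley-McNeil CI, cut-off selection, chi-square comparison and a
# univariate logistic fit.

#' Tally confusion counts for a binary rule on a cohort
#'
#' @param cohort a cohort data.frame (the truth is the derived DTD label,
#'   `histopath_class != "normal"`).
#' @param predictor either a logical vector (one call per patient) or a
#'   function taking the cohort and returning one; e.g.
#'   `function(coh) classifyDtd(abnormalCount(coh), config)`.
#' @return A [ConfusionCounts][confusionCounts] object.
#' @export
#' @examples
#' fix <- reconstructFixtureCohort("table4")
#' confusionFromCohort(fix, function(coh) abnormalCount(coh) >= 3)
confusionFromCohort <- function(cohort, predictor) {
  .stopIf(!is.data.frame(cohort) || nrow(cohort) == 0L,
          "cohort must be a non-empty data.frame")
  truth <- dtdLabel(cohort)
  pred <- if (is.function(predictor)) predictor(cohort) else predictor
  .stopIf(!is.logical(pred) || length(pred) != nrow(cohort) || anyNA(pred),
          "predictor must yield one non-missing logical per patient")
  confusionCounts(tp = sum(pred & truth), fp = sum(pred & !truth),
                  fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' Diagnostic indices from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and negative
#' predictive values `tp/(tp+fp)` and `tn/(tn+fn)`, accuracy `(tp+tn)/N`,
#' the two-point ROC AUC `(sensitivity+specificity)/2` and its
#' Hanley-McNeil confidence interval. A zero denominator makes the affected
#' index `NA` ("undefined"), never an error; all-zero counts warn and return
#' everything undefined.
#'
#' @param counts a [ConfusionCounts][confusionCounts] object.
#' @param level confidence level for the AUC interval (default 0.95).
#' @return A `DiagnosticIndices` object; use the accessors
#'   ([sensitivity()], [specificity()], [ppv()], [npv()], [accuracy()],
#'   [auc()], [aucConfint()]) to extract values.
#' @export
#' @examples
#' diagnosticIndices(confusionCounts(29, 7, 23, 150))
diagnosticIndices <- function(counts, level = 0.95) {
  .stopIf(!is(counts, "ConfusionCounts"), "counts must be a ConfusionCounts object")
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  n <- tp + fp + fn + tn
  if (n == 0L) {
    warning("all confusion counts are zero; every index is undefined")
    return(new("DiagnosticIndices", sensitivity = NA_real_, specificity = NA_real_,
               ppv = NA_real_, npv = NA_real_, accuracy = NA_real_, auc = NA_real_,
               aucCi = c(NA_real_, NA_real_), level = level, counts = counts))
  }
  frac <- function(num, den) if (den == 0L) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  a <- if (is.na(sens) || is.na(spec)) NA_real_ else twoPointAuc(sens, spec)
  ci <- if (is.na(a) || tp + fn == 0L || tn + fp == 0L) c(NA_real_, NA_real_)
        else aucCi(a, nPos = tp + fn, nNeg = tn + fp, level = level)
  new("DiagnosticIndices",
      sensitivity = sens, specificity = spec,
      ppv = frac(tp, tp + fp), npv = frac(tn, tn + fn),
      accuracy = frac(tp + tn, n), auc = a, aucCi = ci, level = level,
      counts = counts)
}

#' Two-point ROC AUC of a single binary rule
#'
#' The ROC curve of a single binary rule has one interior operating point;
#' the trapezoidal area through (0,0), (1-specificity, sensitivity), (1,1)
#' is `(sensitivity + specificity) / 2` — i.e. balanced accuracy.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @return The AUC.
#' @export
#' @examples
#' twoPointAuc(29 / 52, 150 / 157)  # 0.7566
twoPointAuc <- function(sensitivity, specificity) {
  .stopIf(any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1,
              na.rm = FALSE) || anyNA(c(sensitivity, specificity)),
          "sensitivity and specificity must be in [0, 1]")
  (sensitivity + specificity) / 2
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Standard-error interval `auc +/- z * SE` with the Hanley-McNeil variance
#' `SE^2 = (A(1-A) + (nPos-1)(Q1-A^2) + (nNeg-1)(Q2-A^2)) / (nPos nNeg)`,
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`, clipped to `[0, 1]`.
#'
#' @param auc the AUC estimate.
#' @param nPos,nNeg numbers of diseased and non-diseased subjects (> 0).
#' @param level confidence level (default 0.95).
#' @return numeric length-2 interval; attribute `"se"` carries the SE.
#' @export
#' @examples
#' aucCi(0.7566, nPos = 52, nNeg = 157)
aucCi <- function(auc, nPos, nNeg, level = 0.95) {
  .stopIf(nPos <= 0 || nNeg <= 0, "nPos and nNeg must be > 0")
  .stopIf(auc < 0 || auc > 1, "auc must be in [0, 1]")
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (nPos - 1) * (q1 - auc^2) +
                (nNeg - 1) * (q2 - auc^2)) / (nPos * nNeg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * se, 0), 1)
  attr(ci, "se") <- se
  ci
}

#' Select the best HU cut-off by two-point AUC
#'
#' Sweeps candidate nonenhanced-HU cut-offs, classifying a patient positive
#' when `hu <= cutoff` (or `< cutoff` under `"strict_less"`), and returns the
#' candidate with maximal two-point AUC. Ties break toward the larger cutoff
#' (the higher-sensitivity operating point); the result is invariant to the
#' order of `candidates`.
#'
#' @param cohort a cohort data.frame with `hu_nonenhanced`.
#' @param candidates numeric vector of candidate cut-offs (>= 1).
#' @param comparison `"less_or_equal"` (default) or `"strict_less"`.
#' @param level confidence level passed to [diagnosticIndices()].
#' @return list with `cutoff` (the winner), `auc`, and `sweep`, a data.frame
#'   of per-candidate confusion counts, indices and AUCs.
#' @export
#' @examples
#' fix <- reconstructFixtureCohort("table4")
#' selectCutoff(fix, c(80, 90, 100))$cutoff
selectCutoff <- function(cohort, candidates,
                         comparison = c("less_or_equal", "strict_less"),
                         level = 0.95) {
  comparison <- match.arg(comparison)
  .stopIf(length(candidates) < 1L || anyNA(candidates),
          "at least one finite candidate cutoff is required")
  candidates <- sort(unique(as.numeric(candidates)))
  rows <- lapply(candidates, function(cut) {
    pred <- if (comparison == "less_or_equal") cohort$hu_nonenhanced <= cut
            else cohort$hu_nonenhanced < cut
    di <- diagnosticIndices(confusionFromCohort(cohort, pred), level = level)
    data.frame(cutoff = cut, tp = di@counts@tp, fp = di@counts@fp,
               fn = di@counts@fn, tn = di@counts@tn,
               sensitivity = di@sensitivity, specificity = di@specificity,
               ppv = di@ppv, npv = di@npv, accuracy = di@accuracy,
               auc = di@auc, ciLow = di@aucCi[1], ciHigh = di@aucCi[2])
  })
  sweep <- do.call(rbind, rows)
  if (all(is.na(sweep$auc))) {
    # degenerate cohort (a single class): no AUC is defined
    return(list(cutoff = NA_real_, auc = NA_real_, sweep = sweep))
  }
  # ties toward the larger cutoff: take the *last* maximum of the sorted sweep
  best <- max(which(sweep$auc == max(sweep$auc, na.rm = TRUE)))
  list(cutoff = sweep$cutoff[best], auc = sweep$auc[best], sweep = sweep)
}

#' Pearson chi-square test on an R x 2 contingency table
#'
#' Compares a categorical CT feature between normal and DTD glands. All-zero
#' rows (unobserved categories) are dropped first; the Pearson statistic is
#' computed without continuity correction on the retained R' x 2 table with
#' `df = R' - 1`.
#'
#' @param table matrix of non-negative counts with 2 columns (groups) and one
#'   row per category.
#' @return list with `statistic`, `df` and `p`.
#' @export
#' @examples
#' chiSquareRx2(matrix(c(153, 4, 40, 12), 2))  # margin: smooth/lobulated
chiSquareRx2 <- function(table) {
  tab <- as.matrix(table)
  .stopIf(ncol(tab) != 2L, "table must have exactly 2 columns")
  .stopIf(anyNA(tab) || any(tab < 0), "counts must be non-negative")
  keep <- rowSums(tab) > 0
  tab <- tab[keep, , drop = FALSE]
  .stopIf(nrow(tab) < 2L, "need at least 2 non-empty categories")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Univariate logistic fit of DTD status on HU
#'
#' Maximum-likelihood logistic regression of the binary DTD label on a single
#' HU covariate, fitted by iteratively reweighted least squares (at most 25
#' iterations, deviance tolerance 1e-8). Complete separation is reported via
#' the `separation` flag — never as an error.
#'
#' @param hu numeric covariate (e.g. nonenhanced parenchymal HU).
#' @param labels logical or 0/1 DTD labels; both classes must be present.
#' @return list with `intercept`, `slope`, their standard errors `se`,
#'   `converged` and `separation` flags, and the `fit` object.
#' @export
#' @examples
#' coh <- sampleCohort(cohortParams(), seed = 1)
#' logisticFit(coh$hu_nonenhanced, dtdLabel(coh))[c("intercept", "slope")]
logisticFit <- function(hu, labels) {
  y <- as.integer(labels)
  .stopIf(length(y) != length(hu) || anyNA(y) || anyNA(hu),
          "hu and labels must be equal-length and complete")
  .stopIf(length(unique(y)) < 2L, "need both classes present")
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ hu, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 25)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) {
        sepWarn <<- TRUE
        invokeRestart("muffleWarning")
      } else if (grepl("did not converge", msg)) {
        # reported through the converged flag instead
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       se = c(intercept = unname(co[1, 2]), slope = unname(co[2, 2])),
       converged = fit$converged && !sepWarn,
       separation = sepWarn, fit = fit)
}
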