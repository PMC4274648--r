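# Image measurements on phantom volumes: ROI HU, AP size, margin, pattern.

# voxel indices of a circular disc on one axial slice
.discIndex <- function(center, radiusMm, dims, spacing) {
  dx <- (seq_len(dims[1]) - center[1]) * spacing[1]
  dy <- (seq_len(dims[2]) - center[2]) * spacing[2]
  which(outer(dx^2, dy^2, "+") <= radiusMm^2, arr.ind = TRUE)
}

#' Measure mean HU inside a circular ROI
#'
#' Arithmetic mean of the HU values over the voxels of a round axial ROI.
#' The ROI must lie strictly inside a single lobe mask: if any ROI voxel —
#' or any voxel of the ROI dilated by one voxel — falls outside the lobe, the
#' contract is violated and an error is raised (edge voxels suffer
#' partial-volume mixing and must never enter the mean).
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param roi an [roiSpec()]; see [defaultRoi()].
#' @param phase `"nonenhanced"` (default) or `"enhanced"`.
#' @return The mean HU over the ROI voxels.
#' @export
#' @examples
#' vol <- generatePhantom(phantomParams(), seed = 1)
#' measureRoiHu(vol, defaultRoi(vol, "left"))
measureRoiHu <- function(volume, roi, phase = c("nonenhanced", "enhanced")) {
  phase <- match.arg(phase)
  validObject(roi)
  dims <- dim(volume@labels)
  z <- roi@center[3]
  .stopIf(z < 1L || z > dims[3], "ROI slice outside the volume")
  slice <- volume@labels[, , z]
  inner <- .discIndex(roi@center, roi@radius, dims, volume@spacing)
  .stopIf(nrow(inner) == 0L, "ROI contains no voxels")
  codes <- unique(slice[inner])
  .stopIf(length(codes) != 1L || !codes %in% 1:2,
          "ROI is not contained in a single lobe mask")
  dilated <- .discIndex(roi@center, roi@radius + max(volume@spacing[1:2]),
                        dims, volume@spacing)
  .stopIf(any(slice[dilated] != codes),
          "ROI touches the lobe mask boundary; shrink it or recentre")
  hu <- huVolume(volume, phase)[, , z]
  mean(hu[inner])
}

#' Average parenchymal HU over both lobes
#'
#' Measures each lobe with its ROI and returns the arithmetic mean of the two
#' per-lobe means — the per-patient attenuation (or enhancement) measurement
#' entering the feature profile.
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param leftRoi,rightRoi [roiSpec()]s; default [defaultRoi()] placements.
#' @param phase `"nonenhanced"` or `"enhanced"`.
#' @return The averaged mean HU.
#' @export
averageLobeHu <- function(volume, leftRoi = NULL, rightRoi = NULL,
                          phase = c("nonenhanced", "enhanced")) {
  phase <- match.arg(phase)
  if (is.null(leftRoi)) leftRoi <- defaultRoi(volume, "left")
  if (is.null(rightRoi)) rightRoi <- defaultRoi(volume, "right")
  (measureRoiHu(volume, leftRoi, phase) + measureRoiHu(volume, rightRoi, phase)) / 2
}

#' Measure and band the anteroposterior gland size
#'
#' The AP extent of each lobe mask on its mid-lobe axial slice (second axis,
#' converted to cm), averaged over the two lobes and banded: within the
#' configured size band (default 1-2 cm, inclusive) is `normal`, above it
#' `increased`, below it `decreased`.
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param config a [classifierConfig()] supplying the size band.
#' @return list with `category` (factor), `diameterCm` (average) and
#'   `perLobeCm` (named numeric).
#' @export
extractSizeCategory <- function(volume, config = classifierConfig()) {
  dims <- dim(volume@labels)
  zMid <- as.integer(ceiling(dims[3] / 2))
  sy <- volume@spacing[2]
  per <- vapply(c(left = 1L, right = 2L), function(code) {
    slice <- volume@labels[, , zMid] == code
    .stopIf(!any(slice), "geometry error: empty lobe mask")
    rows <- range(which(apply(slice, 2, any)))
    (rows[2] - rows[1] + 1L) * sy / 10   # cm
  }, numeric(1))
  avg <- mean(per)
  cat <- if (avg < config@sizeBand[1]) "decreased"
         else if (avg > config@sizeBand[2]) "increased" else "normal"
  list(category = factor(cat, levels = cohortLevels$size_category),
       diameterCm = avg, perLobeCm = per)
}

#' Convexity deficiency of a 2-D mask
#'
#' `1 - area(mask) / area(convex hull)`, with the hull taken over the pixel
#' centres of the mask and the result clamped at 0. For a digitised convex
#' shape the centre hull lies inside the shape, so the ratio exceeds 1 and
#' the deficiency is exactly 0; boundary concavities shrink the mask area
#' relative to the hull and push the statistic up. Used as the lobulation
#' statistic.
#'
#' @param mask logical matrix.
#' @param spacing pixel spacing `c(sx, sy)` in mm.
#' @return The deficiency in `[0, 1)`.
#' @export
convexityDeficiency <- function(mask, spacing = c(1, 1)) {
  .stopIf(!any(mask), "empty mask")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(0)
  cx <- idx[, 1] * spacing[1]
  cy <- idx[, 2] * spacing[2]
  h <- grDevices::chull(cx, cy)
  if (length(h) < 3L) return(0)
  hx <- cx[h]; hy <- cy[h]
  j <- c(seq_along(h)[-1], 1L)
  hullArea <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  maskArea <- nrow(idx) * spacing[1] * spacing[2]
  max(1 - maskArea / hullArea, 0)
}

#' Classify the thyroid margin as smooth or lobulated
#'
#' Lobulated iff the convexity deficiency of either lobe mask on the mid-lobe
#' axial slice exceeds `threshold`. The human classification being visual,
#' the threshold is an explicit, configurable stand-in (default 0.02,
#' calibrated on generated shapes: digitised smooth ellipses score < 0.005,
#' lobulation amplitudes >= 0.15 with >= 3 undulations score well above 0.02).
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param threshold convexity-deficiency threshold (default 0.02); a
#'   threshold of 1 makes every shape smooth.
#' @return list with `margin` (factor smooth/lobulated) and `deficiency`
#'   (named per-lobe numeric).
#' @export
extractMargin <- function(volume, threshold = 0.02) {
  dims <- dim(volume@labels)
  zMid <- as.integer(ceiling(dims[3] / 2))
  def <- vapply(c(left = 1L, right = 2L), function(code) {
    slice <- volume@labels[, , zMid] == code
    .stopIf(!any(slice), "geometry error: empty lobe mask")
    convexityDeficiency(slice, volume@spacing[1:2])
  }, numeric(1))
  cat <- if (max(def) > threshold) "lobulated" else "smooth"
  list(margin = factor(cat, levels = cohortLevels$margin), deficiency = def)
}

#' Classify the parenchymal pattern of a phase
#'
#' Rule, evaluated per lobe and pooled:
#' 1. *heterogeneous* if any connected focal region covering at least
#'    `focalFraction` of the lobe's mid-slice area deviates by at least
#'    `focalDeviationHu` from the lobe median;
#' 2. else *inhomogeneous* if the within-lobe HU standard deviation, after
#'    subtracting the sensor-noise SD in quadrature, exceeds `sdThreshold`;
#' 3. else *homogeneous*.
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param phase `"nonenhanced"` or `"enhanced"`.
#' @param sdThreshold SD threshold in HU (default 15).
#' @param focalFraction minimum focal-region area fraction (default 0.10).
#' @param focalDeviationHu minimum focal deviation from the lobe median in HU
#'   (default 50).
#' @param noiseSd sensor-noise SD to subtract; defaults to the generating
#'   parameters' value.
#' @return list with `pattern` (factor), `residualSd` (noise-corrected
#'   within-lobe SD) and `maxFocalFraction`.
#' @export
extractPattern <- function(volume, phase = c("nonenhanced", "enhanced"),
                           sdThreshold = 15, focalFraction = 0.10,
                           focalDeviationHu = 50, noiseSd = NULL) {
  phase <- match.arg(phase)
  if (is.null(noiseSd)) noiseSd <- volume@params@noiseSd
  hu <- huVolume(volume, phase)
  dims <- dim(volume@labels)
  zMid <- as.integer(ceiling(dims[3] / 2))
  maxFocal <- 0
  ssq <- 0; ntot <- 0L
  for (code in 1:2) {
    m3 <- volume@labels == code
    .stopIf(!any(m3), "geometry error: empty lobe mask")
    med <- stats::median(hu[m3])
    slice <- volume@labels[, , zMid] == code
    dev <- abs(hu[, , zMid] - med) >= focalDeviationHu & slice
    if (any(dev)) {
      lab <- EBImage::bwlabel(dev)
      frac <- max(tabulate(lab[lab > 0])) / sum(slice)
      maxFocal <- max(maxFocal, frac)
    }
    v <- hu[m3]
    ssq <- ssq + sum((v - mean(v))^2)
    ntot <- ntot + length(v)
  }
  residualSd <- sqrt(max(ssq / (ntot - 1L) - noiseSd^2, 0))
  cat <- if (maxFocal >= focalFraction) "heterogeneous"
         else if (residualSd > sdThreshold) "inhomogeneous" else "homogeneous"
  list(pattern = factor(cat, levels = cohortLevels$attenuation_pattern),
       residualSd = residualSd, maxFocalFraction = maxFocal)
}

#' Extract a full CT feature profile from a phantom
#'
#' Runs the complete image-analysis chain (ROI HU on both phases and lobes,
#' AP size, margin, patterns) and returns the profile columns of the cohort
#' contract, so phantom batches can be evaluated exactly like tabular
#' cohorts.
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param config a [classifierConfig()] (HU banding and size band).
#' @param marginThreshold passed to [extractMargin()].
#' @param sdThreshold,focalFraction,focalDeviationHu passed to
#'   [extractPattern()].
#' @return A one-row data.frame with `hu_nonenhanced`, `hu_enhanced`,
#'   `attenuation_degree`, `attenuation_pattern`, `size_category`, `margin`,
#'   `enhancement_pattern`.
#' @export
extractProfile <- function(volume, config = classifierConfig(),
                           marginThreshold = 0.02, sdThreshold = 15,
                           focalFraction = 0.10, focalDeviationHu = 50) {
  huN <- averageLobeHu(volume, phase = "nonenhanced")
  huE <- averageLobeHu(volume, phase = "enhanced")
  data.frame(
    hu_nonenhanced = huN,
    hu_enhanced = huE,
    attenuation_degree = as.character(classifyAttenuationDegree(huN, config)),
    attenuation_pattern = as.character(extractPattern(volume, "nonenhanced",
      sdThreshold, focalFraction, focalDeviationHu)$pattern),
    size_category = as.character(extractSizeCategory(volume, config)$category),
    margin = as.character(extractMargin(volume, marginThreshold)$margin),
    enhancement_pattern = as.character(extractPattern(volume, "enhanced",
      sdThreshold, focalFraction, focalDeviationHu)$pattern),
    stringsAsFactors = FALSE
  )
}
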