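#' @import methods
NULL

# ---- category vocabularies ---------------------------------------------------

#' Category levels used by the cohort column contract
#'
#' Enumerated levels for every categorical cohort column, in the order the
#' reference frequency table lists them. `histopath` holds the four
#' histopathology classes; a patient is DTD-positive iff the class is not
#' `"normal"`.
#'
#' @format A named list of character vectors.
#' @export
cohortLevels <- list(
  histopath           = c("normal", "hashimoto", "non_hashimoto_lt", "diffuse_hyperplasia"),
  attenuation_degree  = c("iso", "low", "high"),
  attenuation_pattern = c("homogeneous", "inhomogeneous", "heterogeneous"),
  size_category       = c("normal", "increased", "decreased"),
  margin              = c("smooth", "lobulated"),
  enhancement_pattern = c("homogeneous", "inhomogeneous", "heterogeneous")
)

# ---- ClassifierConfig --------------------------------------------------------

#' @rdname classifierConfig
#' @export
setClass("ClassifierConfig",
  representation(
    lowHuCutoff  = "numeric",
    highHuCutoff = "numeric",
    sizeBand     = "numeric",
    k            = "integer",
    comparison   = "character"
  )
)

setValidity("ClassifierConfig", function(object) {
  msg <- character()
  if (length(object@lowHuCutoff) != 1L || length(object@highHuCutoff) != 1L ||
      !is.finite(object@lowHuCutoff) || !is.finite(object@highHuCutoff)) {
    msg <- c(msg, "HU cutoffs must be single finite numbers")
  } else if (object@lowHuCutoff >= object@highHuCutoff) {
    msg <- c(msg, "lowHuCutoff must be below highHuCutoff")
  }
  if (length(object@sizeBand) != 2L || any(!is.finite(object@sizeBand)) ||
      object@sizeBand[1] >= object@sizeBand[2] || object@sizeBand[1] <= 0) {
    msg <- c(msg, "sizeBand must be two increasing positive numbers (cm)")
  }
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L || object@k > 5L) {
    msg <- c(msg, "k must be an integer in 1..5")
  }
  if (length(object@comparison) != 1L ||
      !object@comparison %in% c("less_or_equal", "strict_less")) {
    msg <- c(msg, "comparison must be 'less_or_equal' or 'strict_less'")
  }
  if (length(msg)) msg else TRUE
})

#' Classifier configuration
#'
#' Bundles the tunable thresholds of the five-feature CT score: the HU banding
#' cutoffs that define low/iso/high attenuation, the anteroposterior size band
#' regarded as normal, the abnormal-feature count threshold `k`, and the
#' comparison convention used when sweeping HU cut-off candidates.
#'
#' The attenuation *degree* banding is fixed by definition: low iff
#' `hu < lowHuCutoff`, high iff `hu > highHuCutoff`, iso otherwise (both
#' boundary values are iso). The `comparison` switch only affects cut-off
#' sweeps ([selectCutoff()], [evaluateCohort()]), where the reference tables
#' label rows "x or less": `"less_or_equal"` classifies `hu <= cutoff` as
#' positive, `"strict_less"` uses `hu < cutoff`. On continuous HU data the two
#' differ only on exact ties.
#'
#' @param lowHuCutoff HU below which nonenhanced attenuation is "low" (default 100).
#' @param highHuCutoff HU above which attenuation is "high" (default 180).
#' @param sizeBand two-element numeric, the AP-diameter band in cm regarded as
#'   normal (default `c(1, 2)`, inclusive).
#' @param k abnormal-feature count threshold for a positive DTD call (default 3).
#' @param comparison `"less_or_equal"` (default) or `"strict_less"`; see Details.
#' @return A `ClassifierConfig` object.
#' @export
#' @examples
#' classifierConfig()
#' classifierConfig(k = 2, comparison = "strict_less")
classifierConfig <- function(lowHuCutoff = 100, highHuCutoff = 180,
                             sizeBand = c(1, 2), k = 3L,
                             comparison = c("less_or_equal", "strict_less")) {
  comparison <- match.arg(comparison)
  new("ClassifierConfig",
      lowHuCutoff = as.numeric(lowHuCutoff), highHuCutoff = as.numeric(highHuCutoff),
      sizeBand = as.numeric(sizeBand), k = as.integer(k), comparison = comparison)
}

setMethod("show", "ClassifierConfig", function(object) {
  cat("ClassifierConfig\n")
  cat(sprintf("  attenuation banding : low < %g HU, high > %g HU\n",
              object@lowHuCutoff, object@highHuCutoff))
  cat(sprintf("  normal size band    : [%g, %g] cm\n",
              object@sizeBand[1], object@sizeBand[2]))
  cat(sprintf("  positive if count >= %d abnormal features\n", object@k))
  cat(sprintf("  cutoff sweep rule   : %s\n", object@comparison))
})

# ---- ConfusionCounts ---------------------------------------------------------

#' @rdname confusionCounts
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(v) != 4L || anyNA(v) || any(v < 0L)) {
    "tp, fp, fn, tn must be single non-negative integers"
  } else TRUE
})

#' Confusion counts for a binary rule
#'
#' @param tp,fp,fn,tn non-negative integer counts (true/false positives,
#'   false/true negatives) of a binary classifier against the DTD label.
#' @return A `ConfusionCounts` object.
#' @seealso [diagnosticIndices()], [confusionFromCohort()]
#' @export
#' @examples
#' confusionCounts(29, 7, 23, 150)
confusionCounts <- function(tp, fp, fn, tn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

setMethod("show", "ConfusionCounts", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(c("test+", "test-"), c("DTD", "normal")))
  cat("ConfusionCounts (n =", sum(m), ")\n")
  print(m)
})

# ---- DiagnosticIndices -------------------------------------------------------

#' @rdname diagnosticIndices
#' @export
setClass("DiagnosticIndices",
  representation(
    sensitivity = "numeric", specificity = "numeric",
    ppv = "numeric", npv = "numeric", accuracy = "numeric",
    auc = "numeric", aucCi = "numeric", level = "numeric",
    counts = "ConfusionCounts"
  )
)

setValidity("DiagnosticIndices", function(object) {
  ok <- function(x) length(x) == 1L && (is.na(x) || (x >= 0 && x <= 1))
  if (!all(vapply(list(object@sensitivity, object@specificity, object@ppv,
                       object@npv, object@accuracy, object@auc), ok, logical(1)))) {
    return("indices must be single values in [0, 1] or NA (undefined)")
  }
  if (length(object@aucCi) != 2L) return("aucCi must have length 2")
  TRUE
})

setMethod("show", "DiagnosticIndices", function(object) {
  cat("DiagnosticIndices\n")
  cat(sprintf("  sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%  accuracy %s%%\n",
              .fmtPct(object@sensitivity), .fmtPct(object@specificity),
              .fmtPct(object@ppv), .fmtPct(object@npv), .fmtPct(object@accuracy)))
  cat(sprintf("  two-point AUC %s (%d%% CI %s-%s)\n",
              ifelse(is.na(object@auc), "NA", formatC(object@auc, format = "f", digits = 4)),
              round(100 * object@level),
              ifelse(is.na(object@aucCi[1]), "NA", formatC(object@aucCi[1], format = "f", digits = 4)),
              ifelse(is.na(object@aucCi[2]), "NA", formatC(object@aucCi[2], format = "f", digits = 4))))
})

# ---- PhantomParams -----------------------------------------------------------

#' @rdname phantomParams
#' @export
setClass("PhantomParams",
  representation(
    lobeDiameterAP      = "numeric",   # named c(left, right), cm
    lobeHu              = "numeric",   # nonenhanced mean HU per lobe
    lobeHuEnhanced      = "numeric",   # enhanced mean HU per lobe
    noiseSd             = "numeric",   # voxel white-noise SD, HU
    inhomAmplitude      = "numeric",   # low-frequency field SD inside lobes, HU
    inhomScale          = "numeric",   # field correlation scale, mm
    lobulationAmplitude = "numeric",   # radial perturbation, fraction of radius
    lobulationLobes     = "integer",   # number of boundary undulations
    lesions             = "data.frame",# lobe, dx, dy, dz (mm), radius (mm), huOffset
    spacing             = "numeric",   # voxel spacing, mm per axis
    dims                = "integer",   # grid size (0 = auto from geometry)
    lobeWidth           = "numeric",   # left-right semi-axis, mm
    tracheaRadius       = "numeric",   # mm
    lobeGap             = "numeric",   # trachea-to-lobe gap, mm
    backgroundHu        = "numeric",
    airHu               = "numeric"
  )
)

setValidity("PhantomParams", function(object) {
  msg <- character()
  if (length(object@lobeDiameterAP) != 2L || any(object@lobeDiameterAP <= 0)) {
    msg <- c(msg, "lobeDiameterAP must be two positive diameters (cm)")
  }
  if (length(object@lobeHu) != 2L || length(object@lobeHuEnhanced) != 2L) {
    msg <- c(msg, "lobeHu and lobeHuEnhanced must each have length 2")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(object@inhomAmplitude) != 2L || any(object@inhomAmplitude < 0)) {
    msg <- c(msg, "inhomAmplitude must be two non-negative values (per phase)")
  }
  if (object@inhomScale <= 0) msg <- c(msg, "inhomScale must be > 0")
  if (object@lobulationAmplitude < 0 || object@lobulationAmplitude >= 1) {
    msg <- c(msg, "lobulationAmplitude must be in [0, 1)")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0)) {
    msg <- c(msg, "spacing must be three positive numbers (mm)")
  }
  if (object@lobeWidth <= 0 || object@tracheaRadius <= 0 || object@lobeGap < 0) {
    msg <- c(msg, "lobeWidth and tracheaRadius must be > 0, lobeGap >= 0")
  }
  led <- object@lesions
  need <- c("lobe", "dx", "dy", "dz", "radius", "huOffset")
  if (nrow(led) && (!all(need %in% names(led)) || any(led$radius <= 0) ||
                    !all(led$lobe %in% c("left", "right")))) {
    msg <- c(msg, "lesions must have columns lobe/dx/dy/dz/radius/huOffset with radius > 0")
  }
  if (nrow(led) && "phase" %in% names(led) &&
      !all(led$phase %in% c("both", "nonenhanced", "enhanced"))) {
    msg <- c(msg, "lesion phase must be 'both', 'nonenhanced' or 'enhanced'")
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic neck-CT phantom parameters
#'
#' Describes the geometry and texture of a two-lobe thyroid phantom: two
#' elliptical-cylinder lobes flanking an air-filled trachea on a soft-tissue
#' background. The anteroposterior (AP) lobe diameter, mean HU per phase,
#' boundary lobulation, low-frequency parenchymal inhomogeneity, focal lesions
#' and sensor noise are all controllable so that each categorical CT feature
#' of the scoring system has a known ground truth.
#'
#' @param lobeDiameterAP AP diameter of (left, right) lobes in cm (default 1.5).
#' @param lobeHu mean nonenhanced parenchymal HU per lobe (default 114.3, the
#'   normal-thyroid mean).
#' @param lobeHuEnhanced mean contrast-enhanced HU per lobe (default 202.5).
#' @param noiseSd additive white sensor noise SD in HU (default 0).
#' @param inhomAmplitude SD in HU of the smooth low-frequency inhomogeneity
#'   field inside the lobes, per phase (`c(nonenhanced, enhanced)`; a scalar
#'   is recycled; default 0 = perfectly homogeneous parenchyma). Both phases
#'   share the same spatial field, scaled per phase.
#' @param inhomScale correlation scale of that field in mm (default 8).
#' @param lobulationAmplitude radial boundary perturbation as a fraction of the
#'   local lobe radius (default 0 = smooth ellipse).
#' @param lobulationLobes number of sinusoidal undulations around the boundary
#'   (default 4).
#' @param lesions data.frame of focal lesions (`lobe`, `dx`, `dy`, `dz` offsets
#'   from the lobe centre in mm, `radius` in mm, `huOffset` in HU, and an
#'   optional `phase` column — `"both"` (default), `"nonenhanced"` or
#'   `"enhanced"`); default none.
#' @param spacing voxel spacing in mm, default `c(0.5, 0.5, 3)` (3 mm slices).
#' @param dims grid size in voxels; `c(0, 0, 0)` (default) sizes the grid
#'   automatically from the geometry.
#' @param lobeWidth left-right semi-axis of each lobe in mm (default 7).
#' @param tracheaRadius trachea radius in mm (default 8).
#' @param lobeGap gap between trachea wall and lobe in mm (default 2).
#' @param backgroundHu soft-tissue background HU (default 60).
#' @param airHu tracheal air HU (default -1000).
#' @return A `PhantomParams` object.
#' @seealso [generatePhantom()]
#' @export
#' @examples
#' phantomParams(lobeDiameterAP = c(2.4, 2.4), lobulationAmplitude = 0.2)
phantomParams <- function(lobeDiameterAP = c(left = 1.5, right = 1.5),
                          lobeHu = c(left = 114.3, right = 114.3),
                          lobeHuEnhanced = c(left = 202.5, right = 202.5),
                          noiseSd = 0, inhomAmplitude = 0, inhomScale = 8,
                          lobulationAmplitude = 0, lobulationLobes = 4L,
                          lesions = data.frame(),
                          spacing = c(0.5, 0.5, 3), dims = c(0L, 0L, 0L),
                          lobeWidth = 7, tracheaRadius = 8, lobeGap = 2,
                          backgroundHu = 60, airHu = -1000) {
  two <- function(x) {
    x <- rep(as.numeric(x), length.out = 2L)
    names(x) <- c("left", "right")
    x
  }
  amp <- rep(as.numeric(inhomAmplitude), length.out = 2L)
  names(amp) <- c("nonenhanced", "enhanced")
  new("PhantomParams",
      lobeDiameterAP = two(lobeDiameterAP), lobeHu = two(lobeHu),
      lobeHuEnhanced = two(lobeHuEnhanced),
      noiseSd = as.numeric(noiseSd), inhomAmplitude = amp,
      inhomScale = as.numeric(inhomScale),
      lobulationAmplitude = as.numeric(lobulationAmplitude),
      lobulationLobes = as.integer(lobulationLobes),
      lesions = as.data.frame(lesions),
      spacing = as.numeric(spacing), dims = as.integer(dims),
      lobeWidth = as.numeric(lobeWidth), tracheaRadius = as.numeric(tracheaRadius),
      lobeGap = as.numeric(lobeGap), backgroundHu = as.numeric(backgroundHu),
      airHu = as.numeric(airHu))
}

setMethod("show", "PhantomParams", function(object) {
  cat("PhantomParams\n")
  cat(sprintf("  AP diameters (cm)   : left %g, right %g\n",
              object@lobeDiameterAP[1], object@lobeDiameterAP[2]))
  cat(sprintf("  lobe HU (plain/enh) : %g/%g (L), %g/%g (R)\n",
              object@lobeHu[1], object@lobeHuEnhanced[1],
              object@lobeHu[2], object@lobeHuEnhanced[2]))
  cat(sprintf("  noise SD %g HU, inhomogeneity %g/%g HU @ %g mm, lobulation %g x%d\n",
              object@noiseSd, object@inhomAmplitude[1], object@inhomAmplitude[2],
              object@inhomScale, object@lobulationAmplitude, object@lobulationLobes))
  cat(sprintf("  spacing %s mm, %d focal lesion(s)\n",
              paste(object@spacing, collapse = "x"), nrow(object@lesions)))
})

# ---- PhantomVolume -----------------------------------------------------------

#' @rdname generatePhantom
#' @export
setClass("PhantomVolume",
  representation(
    nonenhanced = "array",
    enhanced    = "array",
    labels      = "array",    # 0 background, 1 left lobe, 2 right lobe, 3 trachea
    spacing     = "numeric",
    params      = "PhantomParams",
    seed        = "integer"
  )
)

setValidity("PhantomVolume", function(object) {
  msg <- character()
  d <- dim(object@nonenhanced)
  if (!identical(d, dim(object@enhanced)) || !identical(d, dim(object@labels))) {
    msg <- c(msg, "raster and label arrays must share dimensions")
  }
  if (!all(object@labels %in% 0:3)) msg <- c(msg, "labels must be in 0..3")
  tr <- object@labels == 3L
  if (any(tr)) {
    band <- 250 + 5 * object@params@noiseSd
    if (abs(mean(object@nonenhanced[tr]) - object@params@airHu) > band) {
      msg <- c(msg, "tracheal HU is not in the air band")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@nonenhanced)
  cat(sprintf("PhantomVolume %dx%dx%d voxels @ %s mm (seed %d)\n",
              d[1], d[2], d[3], paste(object@spacing, collapse = "x"), object@seed))
  for (lb in c("left", "right")) {
    n <- sum(object@labels == if (lb == "left") 1L else 2L)
    cat(sprintf("  %s lobe: %d voxels\n", lb, n))
  }
})

# ---- RoiSpec -----------------------------------------------------------------

#' @rdname roiSpec
#' @export
setClass("RoiSpec",
  representation(center = "integer", radius = "numeric"))

setValidity("RoiSpec", function(object) {
  if (length(object@center) != 3L || anyNA(object@center) || any(object@center < 1L)) {
    return("center must be three positive voxel indices")
  }
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0) {
    return("radius must be a single positive number (mm)")
  }
  TRUE
})

#' Region-of-interest specification
#'
#' A circular ROI on one axial slice, mimicking the round PACS ROI used to
#' measure parenchymal HU. The disc must lie strictly inside a single lobe
#' mask (one voxel clear of the boundary), so partial-volume edge voxels never
#' enter the mean.
#'
#' @param center voxel coordinates `c(x, y, z)` of the ROI centre.
#' @param radius ROI radius in mm.
#' @return An `RoiSpec` object.
#' @seealso [defaultRoi()], [measureRoiHu()]
#' @export
roiSpec <- function(center, radius) {
  new("RoiSpec", center = as.integer(center), radius = as.numeric(radius))
}

setMethod("show", "RoiSpec", function(object) {
  cat(sprintf("RoiSpec: centre (%d, %d, %d), radius %g mm\n",
              object@center[1], object@center[2], object@center[3], object@radius))
})
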