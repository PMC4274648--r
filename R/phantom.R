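# Synthetic neck-CT phantom generation with ground-truth geometry.

# trilinear interpolation of a knot array onto voxel centres, axis by axis
.interpAxis <- function(arr, pos, knotSpacing) {
  g <- pos / knotSpacing + 1
  i0 <- pmin(floor(g), dim(arr)[1] - 1L)
  w <- g - i0
  arr[i0, , , drop = FALSE] * (1 - w) + arr[i0 + 1L, , , drop = FALSE] * w
}

.smoothField <- function(dims, spacing, scale) {
  phys <- dims * spacing
  nk <- pmax(ceiling(phys / scale) + 2L, 2L)
  knots <- array(stats::rnorm(prod(nk)), dim = nk)
  pos <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  f <- .interpAxis(knots, pos[[1]], scale)
  f <- aperm(.interpAxis(aperm(f, c(2, 1, 3)), pos[[2]], scale), c(2, 1, 3))
  f <- aperm(.interpAxis(aperm(f, c(3, 2, 1)), pos[[3]], scale), c(3, 2, 1))
  f
}

# physical voxel-centre coordinates, centred on the trachea axis
.gridCoords <- function(dims, spacing) {
  lapply(1:3, function(a) (seq_len(dims[a]) - (dims[a] + 1) / 2) * spacing[a])
}

.lobeCenterX <- function(params, lobe) {
  s <- if (lobe == "left") -1 else 1
  s * (params@tracheaRadius + params@lobeGap + params@lobeWidth)
}

# 2-D axial lobe mask: ellipse with sinusoidal radial boundary perturbation
.lobeMask2d <- function(x, y, params, lobe) {
  a <- params@lobeWidth
  b <- params@lobeDiameterAP[[lobe]] * 10 / 2   # cm -> mm semi-axis
  xc <- .lobeCenterX(params, lobe)
  u <- outer((x - xc) / a, rep(1, length(y)))
  v <- outer(rep(1, length(x)), y / b)
  theta <- atan2(v, u)
  r <- 1 + params@lobulationAmplitude * cos(params@lobulationLobes * theta)
  u^2 + v^2 <= r^2
}

#' Generate a synthetic neck-CT phantom
#'
#' Builds a two-phase (nonenhanced + contrast-enhanced) HU raster containing
#' two elliptical-cylinder thyroid lobes flanking an air trachea on a
#' soft-tissue background, together with ground-truth label masks. Boundary
#' lobulation is a radial sinusoidal perturbation; parenchymal inhomogeneity
#' is a smooth random field (trilinearly interpolated white knots at the
#' configured spatial scale) normalised to the requested SD inside the lobes
#' and re-centred to zero mean over each lobe's default ROI disc, so the
#' ground-truth mean attenuation at the measurement site is preserved at any
#' texture amplitude. Focal lesions add an HU offset inside a sphere; white
#' sensor noise is added last. Identical parameters and seed give identical
#' rasters.
#'
#' @param params a [phantomParams()] object.
#' @param seed integer seed for the texture field and noise.
#' @return A `PhantomVolume` (see [huVolume()], [lobeMask()],
#'   [voxelSpacing()] accessors).
#' @export
#' @examples
#' vol <- generatePhantom(phantomParams(), seed = 1)
#' mean(huVolume(vol)[lobeMask(vol, "left")])
generatePhantom <- function(params = phantomParams(), seed = 1L) {
  validObject(params)
  A <- params@lobulationAmplitude
  .stopIf(A > 0 && A * params@lobeWidth >= params@lobeGap,
          "geometry error: lobulation amplitude pushes a lobe into the trachea ",
          "(amplitude x lobeWidth must stay below lobeGap)")
  sp <- params@spacing
  dims <- params@dims
  if (all(dims == 0L)) {
    bmax <- max(params@lobeDiameterAP) * 10 / 2 * (1 + A)
    halfX <- params@tracheaRadius + params@lobeGap +
      2 * params@lobeWidth * (1 + A) + 5
    dims <- as.integer(c(ceiling(2 * halfX / sp[1]), ceiling(2 * (bmax + 5) / sp[2]), 9L))
  }
  co <- .gridCoords(dims, sp)
  x <- co[[1]]; y <- co[[2]]

  trachea2d <- outer(x^2, y^2, "+") <= params@tracheaRadius^2
  left2d <- .lobeMask2d(x, y, params, "left")
  right2d <- .lobeMask2d(x, y, params, "right")
  .stopIf(any(left2d & trachea2d) || any(right2d & trachea2d) || any(left2d & right2d),
          "geometry error: lobe masks overlap the trachea")

  rep3 <- function(m) array(m, dim = dims)
  labels <- array(0L, dim = dims)
  labels[rep3(left2d)] <- 1L
  labels[rep3(right2d)] <- 2L
  labels[rep3(trachea2d)] <- 3L

  base <- function(lobeHuL, lobeHuR) {
    v <- array(params@backgroundHu, dim = dims)
    v[labels == 1L] <- lobeHuL
    v[labels == 2L] <- lobeHuR
    v[labels == 3L] <- params@airHu
    v
  }
  non <- base(params@lobeHu[["left"]], params@lobeHu[["right"]])
  enh <- base(params@lobeHuEnhanced[["left"]], params@lobeHuEnhanced[["right"]])

  .withSeed(seed, {
    lobeVox <- labels == 1L | labels == 2L
    amp <- params@inhomAmplitude
    if (any(amp > 0)) {
      f <- .smoothField(dims, sp, params@inhomScale)
      s <- stats::sd(f[lobeVox])
      if (s > 0) f <- f / s
      # re-centre so the default-ROI measurement recovers the nominal mean
      for (code in 1:2) {
        m <- labels == code
        roiVox <- .defaultRoiVoxels(labels, params, code, dims)
        f[m] <- f[m] - mean(f[roiVox])
      }
      non[lobeVox] <- non[lobeVox] + amp[1] * f[lobeVox]
      enh[lobeVox] <- enh[lobeVox] + amp[2] * f[lobeVox]
    }
    if (nrow(params@lesions)) {
      z <- co[[3]]
      for (i in seq_len(nrow(params@lesions))) {
        les <- params@lesions[i, ]
        phase <- if ("phase" %in% names(les)) les$phase else "both"
        cx <- .lobeCenterX(params, les$lobe) + les$dx
        d2 <- outer(outer((x - cx)^2, (y - les$dy)^2, "+"), (z - les$dz)^2, "+")
        hit <- d2 <= les$radius^2 & labels == (if (les$lobe == "left") 1L else 2L)
        if (phase %in% c("both", "nonenhanced")) non[hit] <- non[hit] + les$huOffset
        if (phase %in% c("both", "enhanced")) enh[hit] <- enh[hit] + les$huOffset
      }
    }
    if (params@noiseSd > 0) {
      non <- non + array(stats::rnorm(prod(dims), sd = params@noiseSd), dim = dims)
      enh <- enh + array(stats::rnorm(prod(dims), sd = params@noiseSd), dim = dims)
    }
  })

  new("PhantomVolume", nonenhanced = non, enhanced = enh, labels = labels,
      spacing = sp, params = params, seed = as.integer(seed))
}

# linear voxel indices of the default ROI disc for a lobe (used both by the
# generator's re-centring and by defaultRoi())
.defaultRoiVoxels <- function(labels, params, code, dims) {
  zMid <- as.integer(ceiling(dims[3] / 2))
  slice <- labels[, , zMid] == code
  idx <- which(slice, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  lobe <- if (code == 1L) "left" else "right"
  b <- params@lobeDiameterAP[[lobe]] * 10 / 2
  radius <- 0.4 * min(params@lobeWidth, b)
  sp <- params@spacing
  dx <- (seq_len(dims[1]) - ctr[1]) * sp[1]
  dy <- (seq_len(dims[2]) - ctr[2]) * sp[2]
  disc <- outer(dx^2, dy^2, "+") <= radius^2
  which(array(disc & (labels[, , zMid] == code), dim = c(dims[1], dims[2], 1))) +
    prod(dims[1:2]) * (zMid - 1L)
}

#' Default measurement ROI for a lobe
#'
#' A round ROI at the lobe-mask centroid of the mid-lobe axial slice, with
#' radius 40% of the smaller lobe semi-axis — comfortably clear of
#' partial-volume edge voxels, mimicking PACS practice of placing a round ROI
#' centrally in the parenchyma.
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param lobe `"left"` or `"right"`.
#' @return An [roiSpec()].
#' @export
defaultRoi <- function(volume, lobe = c("left", "right")) {
  lobe <- match.arg(lobe)
  dims <- dim(volume@labels)
  zMid <- as.integer(ceiling(dims[3] / 2))
  slice <- volume@labels[, , zMid] == (if (lobe == "left") 1L else 2L)
  .stopIf(!any(slice), "empty ", lobe, " lobe mask on the mid slice")
  idx <- which(slice, arr.ind = TRUE)
  ctr <- round(colMeans(idx))
  p <- volume@params
  b <- p@lobeDiameterAP[[lobe]] * 10 / 2
  roiSpec(center = c(ctr[1], ctr[2], zMid), radius = 0.4 * min(p@lobeWidth, b))
}

#' Write / read a phantom as NIfTI plus JSON sidecar
#'
#' `writePhantom` writes `<prefix>_nonenhanced.nii.gz` and
#' `<prefix>_enhanced.nii.gz` (HU as signed 16-bit, voxel spacing in the
#' header), `<prefix>_labels.nii.gz` (0 background, 1 left lobe, 2 right
#' lobe, 3 trachea) and `<prefix>_params.json`. `readPhantom` reverses it.
#' HU values are quantised to whole HU by the 16-bit encoding.
#'
#' @param volume a [PhantomVolume][generatePhantom].
#' @param prefix path prefix for the output files.
#' @return `writePhantom`: the four file paths, invisibly; `readPhantom`: a
#'   `PhantomVolume`.
#' @export
writePhantom <- function(volume, prefix) {
  wr <- function(arr, path, type) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path, datatype = type)
  }
  paths <- paste0(prefix, c("_nonenhanced.nii.gz", "_enhanced.nii.gz",
                            "_labels.nii.gz", "_params.json"))
  wr(round(volume@nonenhanced), paths[1], "int16")
  wr(round(volume@enhanced), paths[2], "int16")
  wr(volume@labels, paths[3], "uint8")
  p <- volume@params
  meta <- list(
    lobeDiameterAP = p@lobeDiameterAP, lobeHu = p@lobeHu,
    lobeHuEnhanced = p@lobeHuEnhanced, noiseSd = p@noiseSd,
    inhomAmplitude = p@inhomAmplitude, inhomScale = p@inhomScale,
    lobulationAmplitude = p@lobulationAmplitude, lobulationLobes = p@lobulationLobes,
    lesions = p@lesions, spacing = p@spacing, dims = dim(volume@labels),
    lobeWidth = p@lobeWidth, tracheaRadius = p@tracheaRadius, lobeGap = p@lobeGap,
    backgroundHu = p@backgroundHu, airHu = p@airHu, seed = volume@seed,
    package = "thyroCT", version = as.character(utils::packageVersion("thyroCT"))
  )
  jsonlite::write_json(meta, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname writePhantom
#' @export
readPhantom <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_params.json"), simplifyVector = TRUE)
  lesions <- if (length(meta$lesions)) as.data.frame(meta$lesions) else data.frame()
  params <- phantomParams(
    lobeDiameterAP = unlist(meta$lobeDiameterAP), lobeHu = unlist(meta$lobeHu),
    lobeHuEnhanced = unlist(meta$lobeHuEnhanced), noiseSd = meta$noiseSd,
    inhomAmplitude = meta$inhomAmplitude, inhomScale = meta$inhomScale,
    lobulationAmplitude = meta$lobulationAmplitude,
    lobulationLobes = meta$lobulationLobes, lesions = lesions,
    spacing = unlist(meta$spacing), dims = unlist(meta$dims),
    lobeWidth = meta$lobeWidth, tracheaRadius = meta$tracheaRadius,
    lobeGap = meta$lobeGap, backgroundHu = meta$backgroundHu, airHu = meta$airHu)
  rd <- function(suffix) {
    img <- RNifti::readNifti(paste0(prefix, suffix))
    array(as.numeric(img), dim = dim(img))
  }
  labels <- rd("_labels.nii.gz")
  new("PhantomVolume",
      nonenhanced = rd("_nonenhanced.nii.gz"), enhanced = rd("_enhanced.nii.gz"),
      labels = array(as.integer(labels), dim = dim(labels)),
      spacing = unlist(meta$spacing), params = params,
      seed = as.integer(meta$seed))
}
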