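#' Accessors for confusion counts
#'
#' @param object a [ConfusionCounts][confusionCounts] or
#'   [DiagnosticIndices][diagnosticIndices] object.
#' @return A single integer (count accessors) or numeric (index accessors).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("truePositives", function(object) standardGeneric("truePositives"))
#' @rdname accessors
#' @export
setGeneric("falsePositives", function(object) standardGeneric("falsePositives"))
#' @rdname accessors
#' @export
setGeneric("falseNegatives", function(object) standardGeneric("falseNegatives"))
#' @rdname accessors
#' @export
setGeneric("trueNegatives", function(object) standardGeneric("trueNegatives"))

#' @rdname accessors
#' @export
setGeneric("sensitivity", function(object) standardGeneric("sensitivity"))
#' @rdname accessors
#' @export
setGeneric("specificity", function(object) standardGeneric("specificity"))
#' @rdname accessors
#' @export
setGeneric("ppv", function(object) standardGeneric("ppv"))
#' @rdname accessors
#' @export
setGeneric("npv", function(object) standardGeneric("npv"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("aucConfint", function(object) standardGeneric("aucConfint"))

#' Phantom volume accessors
#'
#' @param object a [PhantomVolume][generatePhantom].
#' @param phase `"nonenhanced"` or `"enhanced"`.
#' @param lobe `"left"`, `"right"`, or `"trachea"`.
#' @return `huVolume`: the 3-D HU array for the phase; `lobeMask`: a logical
#'   array; `voxelSpacing`: mm per axis; `phantomParams`: the generating
#'   [PhantomParams][phantomParams].
#' @name phantom-accessors
NULL

#' @rdname phantom-accessors
#' @export
setGeneric("huVolume", function(object, phase = "nonenhanced") standardGeneric("huVolume"))
#' @rdname phantom-accessors
#' @export
setGeneric("lobeMask", function(object, lobe) standardGeneric("lobeMask"))
#' @rdname phantom-accessors
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname phantom-accessors
#' @export
setGeneric("generatingParams", function(object) standardGeneric("generatingParams"))

setMethod("truePositives", "ConfusionCounts", function(object) object@tp)
setMethod("falsePositives", "ConfusionCounts", function(object) object@fp)
setMethod("falseNegatives", "ConfusionCounts", function(object) object@fn)
setMethod("trueNegatives", "ConfusionCounts", function(object) object@tn)

setMethod("truePositives", "DiagnosticIndices", function(object) object@counts@tp)
setMethod("falsePositives", "DiagnosticIndices", function(object) object@counts@fp)
setMethod("falseNegatives", "DiagnosticIndices", function(object) object@counts@fn)
setMethod("trueNegatives", "DiagnosticIndices", function(object) object@counts@tn)

setMethod("sensitivity", "DiagnosticIndices", function(object) object@sensitivity)
setMethod("specificity", "DiagnosticIndices", function(object) object@specificity)
setMethod("ppv", "DiagnosticIndices", function(object) object@ppv)
setMethod("npv", "DiagnosticIndices", function(object) object@npv)
setMethod("accuracy", "DiagnosticIndices", function(object) object@accuracy)
setMethod("auc", "DiagnosticIndices", function(object) object@auc)
setMethod("aucConfint", "DiagnosticIndices", function(object) object@aucCi)

setMethod("huVolume", "PhantomVolume", function(object, phase = "nonenhanced") {
  phase <- match.arg(phase, c("nonenhanced", "enhanced"))
  if (phase == "nonenhanced") object@nonenhanced else object@enhanced
})

setMethod("lobeMask", "PhantomVolume", function(object, lobe) {
  lobe <- match.arg(lobe, c("left", "right", "trachea"))
  code <- c(left = 1L, right = 2L, trachea = 3L)[[lobe]]
  object@labels == code
})

setMethod("voxelSpacing", "PhantomVolume", function(object) object@spacing)
setMethod("generatingParams", "PhantomVolume", function(object) object@params)
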