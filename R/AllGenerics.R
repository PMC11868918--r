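#' Coverage fraction of a scene
#'
#' Pixel-exact fraction of the image covered by the union of cell masks.
#' Overlaps are counted once (union, not sum) because masks are rasterized
#' and OR-ed before counting.
#'
#' @param gt A [SceneGroundTruth-class].
#' @return Fraction in `[0, 1]`.
#' @examples
#' cfg <- sceneConfig(densityPreset = "low", nCellsPerType = 2L)
#' gt <- sampleScene(cfg, seed = 1)
#' coverageFraction(gt)
#' @export
setGeneric("coverageFraction", function(gt) standardGeneric("coverageFraction"))

#' Cell table of a scene
#' @param x A [SceneGroundTruth-class].
#' @return data.frame of cell instances.
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))

#' Probe center of a scene (0-based pixel coordinates)
#' @param x A [SceneGroundTruth-class].
#' @return Length-2 numeric (x, y).
#' @export
setGeneric("probeCenter", function(x) standardGeneric("probeCenter"))

#' Bounding boxes of an annotation set
#' @param x An [AnnotationSet-class].
#' @return data.frame of boxes.
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))

#' Approach / retract segments of a force curve
#' @param x A [ForceCurve-class].
#' @return data.frame with columns `z_um`, `d_nm`.
#' @export
setGeneric("approachSegment", function(x) standardGeneric("approachSegment"))

#' @rdname approachSegment
#' @export
setGeneric("retractSegment", function(x) standardGeneric("retractSegment"))

#' Metadata list of a force curve
#' @param x A [ForceCurve-class].
#' @return Named list.
#' @export
setGeneric("curveMeta", function(x) standardGeneric("curveMeta"))

setMethod("cells", "SceneGroundTruth", function(x) x@cells)
setMethod("probeCenter", "SceneGroundTruth", function(x) x@probeCenterPx)
setMethod("boxes", "AnnotationSet", function(x) x@boxes)
setMethod("approachSegment", "ForceCurve", function(x) x@approach)
setMethod("retractSegment", "ForceCurve", function(x) x@retract)
setMethod("curveMeta", "ForceCurve", function(x) x@meta)

setMethod("show", "SceneGroundTruth", function(object) {
  tab <- table(factor(object@cells$cell_type, levels = CELL_TYPES))
  cat(sprintf(
    "SceneGroundTruth: %dx%d px (%.2f um/px), %d cells (typeA %d, typeB %d)\n",
    object@width, object@height, object@pixelSizeUm, nrow(object@cells),
    tab[["typeA"]], tab[["typeB"]]))
  cat(sprintf("  coverage %.1f%%, probe at (%.1f, %.1f) r=%.1f px\n",
              100 * object@coverage, object@probeCenterPx[1],
              object@probeCenterPx[2], object@probeRadiusPx))
})

setMethod("show", "ImageSet", function(object) {
  d <- dim(object@brightfield)
  cat(sprintf("ImageSet: %dx%d px, channels: brightfield, fluorRed, fluorGreen\n",
              d[2], d[1]))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf("AnnotationSet '%s' (%dx%d px): %d boxes\n", object@imageId,
              object@width, object@height, nrow(object@boxes)))
  if (nrow(object@boxes)) print(table(object@boxes$label))
})

setMethod("show", "DetectionMetrics", function(object) {
  cat(sprintf("DetectionMetrics (IoU >= %.2f): TP %d, FP %d, FN %d\n",
              object@iouThreshold, object@tp, object@fp, object@fn))
  cat(sprintf("  precision %.3f, recall %.3f\n", object@precision, object@recall))
})

setMethod("show", "ForceCurve", function(object) {
  cat(sprintf("ForceCurve [%s]: %d approach + %d retract samples, k=%.3g N/m\n",
              if (is.null(object@meta$kind)) "?" else object@meta$kind,
              nrow(object@approach), nrow(object@retract),
              object@cantilever@springConstant))
})

setMethod("show", "HertzFitResult", function(object) {
  cat(sprintf("HertzFitResult: E = %.1f Pa (z0 = %.4f um, rmse %.3g nN, %d pts, %s)\n",
              object@EPa, object@z0Um, object@rmseNn, object@nPoints,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "AdhesionResult", function(object) {
  cat(sprintf("AdhesionResult: F_adh = %.3f nN, work = %.3f fJ, %d rupture step(s)\n",
              object@FAdhNn, object@workFj, object@nRuptureSteps))
})

setMethod("show", "PopulationSummary", function(object) {
  cat(sprintf("PopulationSummary [%s]: n = %d, mean = %.3g, SD = %.3g\n",
              object@label, object@n, object@mean, object@sd))
})
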