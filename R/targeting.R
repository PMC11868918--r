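#' Center of a bounding box
#'
#' The "central area" of a target cell is operationalized as its box
#' center — the cross drawn inside a detection box.
#'
#' @param box Length-4 numeric `(xmin, ymin, xmax, ymax)` or a single-row
#'   box data.frame.
#' @return Length-2 numeric `(x, y)`, real-valued pixels.
#' @examples
#' boxCenter(c(0, 0, 10, 10))  # (5, 5)
#' @export
boxCenter <- function(box) {
  b <- asBoxVec(box)
  c(x = (b[1] + b[3]) / 2, y = (b[2] + b[4]) / 2)
}

#' Fit the pixel-to-stage affine calibration
#'
#' Least-squares affine fit mapping pixel coordinates to stage microns
#' from at least three non-collinear point pairs. When the pairs are truly
#' affine the residual is zero to machine precision.
#'
#' @param pixelPts n x 2 matrix of pixel points.
#' @param stagePts n x 2 matrix of corresponding stage positions (um).
#' @return A [StageCalibration-class].
#' @section Errors: fewer than 3 pairs or collinear pixel points raise a
#'   `cellAFM_calibration_error`.
#' @examples
#' px <- cbind(c(0, 100, 0), c(0, 0, 100))
#' fitCalibration(px, px * 0.65)
#' @export
fitCalibration <- function(pixelPts, stagePts) {
  pixelPts <- as.matrix(pixelPts); stagePts <- as.matrix(stagePts)
  if (nrow(pixelPts) < 3 || nrow(pixelPts) != nrow(stagePts)) {
    afmStop("calibration needs >= 3 point pairs", "cellAFM_calibration_error")
  }
  X <- cbind(pixelPts, 1)
  if (qr(X)$rank < 3) {
    afmStop("pixel points are collinear; calibration is degenerate",
            "cellAFM_calibration_error")
  }
  fit <- lm.fit(X, stagePts)
  A <- t(fit$coefficients)  # 2 x 3: [linear | offset]
  pred <- X %*% t(A)
  rms <- sqrt(mean((stagePts - pred)^2))
  new("StageCalibration", A = A, residualUm = rms)
}

#' Identity-scale calibration
#'
#' Convenience constructor for the exact calibration of a virtual
#' instrument: stage microns are pixel coordinates times the pixel size.
#'
#' @param pixelSizeUm Microns per pixel.
#' @return A [StageCalibration-class] with zero residual.
#' @export
scaleCalibration <- function(pixelSizeUm) {
  new("StageCalibration",
      A = cbind(diag(c(pixelSizeUm, pixelSizeUm)), c(0, 0)), residualUm = 0)
}

applyAffine <- function(cal, pt) {
  as.numeric(cal@A[, 1:2] %*% pt + cal@A[, 3])
}

#' Plan a stage move placing the probe over a target cell
#'
#' The displacement is the difference of the affine-mapped box centers:
#' `(dx, dy) = affine(center(cell)) - affine(center(probe))`; after an
#' exact move the probe center coincides with the cell's box center.
#'
#' @param probeBox Probe detection box (label `"probe"`).
#' @param cellBox Target cell box (label `"typeA"` or `"typeB"`).
#' @param cal A [StageCalibration-class].
#' @param cellId Integer id recorded in the plan.
#' @return A [MovePlan-class].
#' @export
planMove <- function(probeBox, cellBox, cal, cellId = NA_integer_) {
  pLab <- if (is.data.frame(probeBox)) probeBox$label[1] else "probe"
  cLab <- if (is.data.frame(cellBox)) cellBox$label[1] else NA_character_
  if (is.null(pLab) || is.na(pLab) || pLab != "probe") {
    afmStop("probe box missing or not labeled 'probe'", "cellAFM_targeting_error")
  }
  if (!is.na(cLab) && !cLab %in% CELL_TYPES) {
    afmStop("target box must be a cell (typeA/typeB)", "cellAFM_targeting_error")
  }
  pc <- boxCenter(probeBox); cc <- boxCenter(cellBox)
  d <- applyAffine(cal, cc) - applyAffine(cal, pc)
  new("MovePlan", cellId = as.integer(cellId),
      label = if (is.na(cLab)) "typeA" else cLab,
      dxUm = d[1], dyUm = d[2], predictedProbePx = unname(cc))
}

#' Select target cells from an annotation set
#'
#' Per label, boxes are ordered by descending confidence (ties broken by
#' order of appearance); boxes within `borderMarginPx` of an image edge and
#' boxes whose center lies inside the probe box are excluded; at most
#' `nPerType` boxes per cell type are returned. May return fewer than
#' requested.
#'
#' @param annotations An [AnnotationSet-class].
#' @param nPerType Targets per cell type.
#' @param borderMarginPx Exclusion margin from image edges, px.
#' @return data.frame of selected boxes (columns of `boxes()` plus
#'   `cell_id` running per selection order).
#' @export
selectTargets <- function(annotations, nPerType = 50L, borderMarginPx = 8L) {
  b <- annotations@boxes
  if (!nrow(b)) return(cbind(emptyBoxes(), data.frame(cell_id = integer())))
  probe <- b[b$label == "probe", , drop = FALSE]
  cellsB <- b[b$label %in% CELL_TYPES, , drop = FALSE]
  if (!nrow(cellsB)) return(cbind(emptyBoxes(), data.frame(cell_id = integer())))
  keep <- cellsB$xmin >= borderMarginPx & cellsB$ymin >= borderMarginPx &
    cellsB$xmax <= annotations@width - borderMarginPx &
    cellsB$ymax <= annotations@height - borderMarginPx
  if (nrow(probe) == 1L) {
    ctrs <- t(vapply(seq_len(nrow(cellsB)), function(i) boxCenter(cellsB[i, ]),
                     numeric(2)))
    inProbe <- ctrs[, 1] >= probe$xmin & ctrs[, 1] < probe$xmax &
      ctrs[, 2] >= probe$ymin & ctrs[, 2] < probe$ymax
    keep <- keep & !inProbe
  }
  cellsB <- cellsB[keep, , drop = FALSE]
  sel <- do.call(rbind, lapply(CELL_TYPES, function(lab) {
    sub <- cellsB[cellsB$label == lab, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    sub <- sub[order(-sub$confidence, seq_len(nrow(sub))), , drop = FALSE]
    head(sub, nPerType)
  }))
  if (is.null(sel)) return(cbind(emptyBoxes(), data.frame(cell_id = integer())))
  sel$cell_id <- seq_len(nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Apply a planned move to the scene's probe
#'
#' The stage displacement is mapped back to pixels through the inverse of
#' the calibration's linear part and added to the probe center. With exact
#' calibration the new probe center lands on the target's box center to
#' sub-pixel accuracy.
#'
#' @param gt A [SceneGroundTruth-class].
#' @param plan A [MovePlan-class] produced from this scene.
#' @param cal The [StageCalibration-class] used for planning.
#' @return The updated [SceneGroundTruth-class].
#' @section Errors: a move whose end point leaves the image raises a
#'   `cellAFM_move_error`.
#' @export
applyMove <- function(gt, plan, cal) {
  dPx <- solve(cal@A[, 1:2], c(plan@dxUm, plan@dyUm))
  newCenter <- gt@probeCenterPx + as.numeric(dPx)
  if (newCenter[1] < 0 || newCenter[1] >= gt@width ||
      newCenter[2] < 0 || newCenter[2] >= gt@height) {
    afmStop(sprintf("move to (%.1f, %.1f) px leaves the image bounds",
                    newCenter[1], newCenter[2]), "cellAFM_move_error")
  }
  gt@probeCenterPx <- newCenter
  gt
}
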