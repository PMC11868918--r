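## Central S4 containers. The coordinate convention everywhere:
## image origin top-left, x rightward, y downward, 0-based pixel indices,
## boxes half-open [xmin, xmax) x [ymin, ymax).

CELL_TYPES <- c("typeA", "typeB")
BOX_LABELS <- c("typeA", "typeB", "probe")

#' SceneConfig: parameters of a synthetic co-culture scene
#'
#' Holds image geometry, the density preset, per-type morphology and
#' mechanical-truth distributions, probe geometry and rendering noise.
#' Per-type slots are length-2 named numerics (`typeA`, `typeB`).
#' Young's moduli are drawn log-normally (`modulusLogMean` is the mean of
#' log Pa), matching the right-skew of cell stiffness distributions.
#'
#' @slot width,height Image size, pixels.
#' @slot pixelSizeUm Microns per pixel.
#' @slot densityPreset `"high"` (cells in contact, coverage >= 60%) or
#'   `"low"` (no contact, coverage <= 10%).
#' @slot nCellsPerType Cells of each type to place.
#' @slot radiusMeanUm,radiusSdUm Per-type equivalent-radius distribution, um.
#' @slot modulusLogMean,modulusLogSd Per-type log-normal Young's modulus
#'   parameters (log Pa).
#' @slot adhesionMeanNn,adhesionSdNn Per-type adhesion-force distribution, nN.
#' @slot probeRadiusUm Spherical probe tip radius, um.
#' @slot noiseSd Additive Gaussian image noise (fraction of full scale).
#' @slot illuminationAmplitude Amplitude of the smooth illumination gradient.
#' @slot maxOverlapFraction Maximum pairwise cell-mask overlap (fraction of
#'   the smaller cell's area) tolerated during placement.
#' @slot seed Default seed used when `sampleScene()` is called without one.
#' @export
setClass("SceneConfig", representation(
  width = "integer", height = "integer", pixelSizeUm = "numeric",
  densityPreset = "character", nCellsPerType = "integer",
  radiusMeanUm = "numeric", radiusSdUm = "numeric",
  modulusLogMean = "numeric", modulusLogSd = "numeric",
  adhesionMeanNn = "numeric", adhesionSdNn = "numeric",
  probeRadiusUm = "numeric", noiseSd = "numeric",
  illuminationAmplitude = "numeric", maxOverlapFraction = "numeric",
  seed = "integer"
))

setValidity("SceneConfig", function(object) {
  msgs <- character()
  if (object@width < 16L || object@height < 16L) msgs <- c(msgs, "image must be at least 16x16 px")
  if (object@pixelSizeUm <= 0) msgs <- c(msgs, "pixelSizeUm must be > 0")
  if (!object@densityPreset %in% c("high", "low")) msgs <- c(msgs, "densityPreset must be 'high' or 'low'")
  if (object@nCellsPerType < 0L) msgs <- c(msgs, "nCellsPerType must be >= 0")
  for (s in c("radiusMeanUm", "radiusSdUm", "modulusLogMean", "modulusLogSd",
              "adhesionMeanNn", "adhesionSdNn")) {
    v <- slot(object, s)
    if (length(v) != 2L || !all(CELL_TYPES %in% names(v))) {
      msgs <- c(msgs, sprintf("%s must be a length-2 numeric named typeA/typeB", s))
    }
  }
  if (object@probeRadiusUm <= 0) msgs <- c(msgs, "probeRadiusUm must be > 0")
  if (object@maxOverlapFraction < 0 || object@maxOverlapFraction >= 1) {
    msgs <- c(msgs, "maxOverlapFraction must be in [0, 1)")
  }
  if (object@densityPreset == "high" && object@maxOverlapFraction <= 0) {
    msgs <- c(msgs, "high preset must permit cell-cell contact (maxOverlapFraction > 0)")
  }
  if (object@densityPreset == "low" && object@maxOverlapFraction > 0) {
    msgs <- c(msgs, "low preset forbids cell contact (maxOverlapFraction must be 0)")
  }
  if (length(msgs)) msgs else TRUE
})

#' SceneGroundTruth: the simulation's truth record
#'
#' Cells are rows of a data.frame (id, type, ellipse geometry in px, true
#' Young's modulus in Pa and adhesion force in nN, draw order); the probe
#' appears exactly once. Coverage is the pixel-exact union-mask fraction.
#'
#' @slot cells data.frame with columns `cell_id`, `cell_type`, `cx`, `cy`,
#'   `a`, `b`, `theta`, `E_true`, `F_adh_true`.
#' @slot probeCenterPx Length-2 numeric (x, y), 0-based pixel coordinates.
#' @slot probeRadiusPx Probe tip radius in pixels.
#' @slot pixelSizeUm Microns per pixel.
#' @slot width,height Image size in pixels.
#' @slot coverage Cached union-mask coverage fraction.
#' @export
setClass("SceneGroundTruth", representation(
  cells = "data.frame", probeCenterPx = "numeric", probeRadiusPx = "numeric",
  pixelSizeUm = "numeric", width = "integer", height = "integer",
  coverage = "numeric"
))

setValidity("SceneGroundTruth", function(object) {
  msgs <- character()
  need <- c("cell_id", "cell_type", "cx", "cy", "a", "b", "theta",
            "E_true", "F_adh_true")
  if (!all(need %in% names(object@cells))) {
    msgs <- c(msgs, paste("cells must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(object@cells)) {
    if (any(object@cells$E_true <= 0)) msgs <- c(msgs, "E_true must be > 0")
    if (any(object@cells$F_adh_true < 0)) msgs <- c(msgs, "F_adh_true must be >= 0")
    if (!all(object@cells$cell_type %in% CELL_TYPES)) msgs <- c(msgs, "unknown cell_type")
    inb <- object@cells$cx > -object@cells$a & object@cells$cx < object@width + object@cells$a &
      object@cells$cy > -object@cells$b & object@cells$cy < object@height + object@cells$b
    if (!all(inb)) msgs <- c(msgs, "every cell must intersect the image bounds")
  }
  if (length(object@probeCenterPx) != 2L) msgs <- c(msgs, "probeCenterPx must be length 2")
  if (object@coverage < 0 || object@coverage > 1) msgs <- c(msgs, "coverage must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' ImageSet: paired bright-field and fluorescence rasters
#'
#' Matrices indexed `[y + 1, x + 1]`, intensities in `[0, 1]` (written to
#' disk as 16-bit grayscale). Type A cells fluoresce only in the red
#' channel, type B only in the green channel.
#'
#' @slot brightfield,fluorRed,fluorGreen Numeric matrices, identical shape.
#' @export
setClass("ImageSet", representation(
  brightfield = "matrix", fluorRed = "matrix", fluorGreen = "matrix"
))

setValidity("ImageSet", function(object) {
  d <- dim(object@brightfield)
  if (!identical(d, dim(object@fluorRed)) || !identical(d, dim(object@fluorGreen))) {
    return("all three channels must have identical dimensions")
  }
  rng <- range(object@brightfield, object@fluorRed, object@fluorGreen)
  if (rng[1] < 0 || rng[2] > 1) return("intensities must lie in [0, 1]")
  TRUE
})

#' AnnotationSet: labeled bounding boxes for one image
#'
#' The currency between detection, evaluation and targeting. Boxes follow
#' the half-open 0-based convention; at most one probe box per image.
#'
#' @slot imageId Character image reference.
#' @slot width,height Image dimensions in pixels.
#' @slot boxes data.frame with columns `label` (typeA/typeB/probe),
#'   `xmin`, `ymin`, `xmax`, `ymax`, `confidence`.
#' @export
setClass("AnnotationSet", representation(
  imageId = "character", width = "integer", height = "integer",
  boxes = "data.frame"
))

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  b <- object@boxes
  need <- c("label", "xmin", "ymin", "xmax", "ymax", "confidence")
  if (!all(need %in% names(b))) {
    return(paste("boxes must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(b)) {
    if (!all(b$label %in% BOX_LABELS)) msgs <- c(msgs, "labels must be typeA/typeB/probe")
    if (any(b$xmin >= b$xmax) || any(b$ymin >= b$ymax)) {
      msgs <- c(msgs, "boxes must satisfy xmin < xmax and ymin < ymax")
    }
    if (any(b$confidence < 0 | b$confidence > 1)) msgs <- c(msgs, "confidence must be in [0,1]")
    if (sum(b$label == "probe") > 1L) msgs <- c(msgs, "at most one probe box per image")
    out <- b$xmax <= 0 | b$xmin >= object@width | b$ymax <= 0 | b$ymin >= object@height
    if (any(out)) msgs <- c(msgs, "every box must intersect the image bounds")
  }
  if (length(msgs)) msgs else TRUE
})

#' DetectionMetrics: precision/recall of detections against truth
#'
#' @slot perLabel data.frame with tp/fp/fn/precision/recall per label.
#' @slot tp,fp,fn Overall counts.
#' @slot precision,recall Overall values; 0/0 is defined as 1.
#' @slot iouThreshold IoU threshold used for matching.
#' @export
setClass("DetectionMetrics", representation(
  perLabel = "data.frame", tp = "integer", fp = "integer", fn = "integer",
  precision = "numeric", recall = "numeric", iouThreshold = "numeric"
))

#' StageCalibration: affine map from pixels to stage microns
#'
#' @slot A 2x3 matrix: stage = A[, 1:2] %*% pixel + A[, 3].
#' @slot residualUm RMS reprojection residual in microns.
#' @export
setClass("StageCalibration", representation(A = "matrix", residualUm = "numeric"))

setValidity("StageCalibration", function(object) {
  if (!identical(dim(object@A), c(2L, 3L))) return("A must be 2x3")
  if (abs(det(object@A[, 1:2])) < 1e-12) return("linear part must be invertible")
  if (object@residualUm < 0) return("residual must be >= 0")
  TRUE
})

#' MovePlan: one planned stage displacement onto a target cell
#'
#' @slot cellId Integer id of the target (row index among selected boxes).
#' @slot label Target cell type.
#' @slot dxUm,dyUm Stage displacement in microns.
#' @slot predictedProbePx Predicted probe center after the move (px).
#' @export
setClass("MovePlan", representation(
  cellId = "integer", label = "character", dxUm = "numeric", dyUm = "numeric",
  predictedProbePx = "numeric"
))

#' CantileverSpec: cantilever and probe parameters
#'
#' @slot springConstant N/m.
#' @slot tipRadiusUm Spherical tip (microsphere) radius, um.
#' @slot noiseSdNm Deflection noise standard deviation, nm.
#' @slot driftNmPerUm Linear baseline drift, nm per um of piezo travel.
#' @export
setClass("CantileverSpec", representation(
  springConstant = "numeric", tipRadiusUm = "numeric",
  noiseSdNm = "numeric", driftNmPerUm = "numeric"
))

setValidity("CantileverSpec", function(object) {
  if (object@springConstant <= 0) return("spring constant must be > 0")
  if (object@tipRadiusUm <= 0) return("tip radius must be > 0")
  if (object@noiseSdNm < 0) return("noise sd must be >= 0")
  TRUE
})

#' RampConfig: piezo ramp acquisition settings
#'
#' @slot zStartUm,zEndUm Piezo travel range, um (end > start).
#' @slot samples Samples per segment (>= 50).
#' @slot setpointNn Approach force setpoint, nN.
#' @export
setClass("RampConfig", representation(
  zStartUm = "numeric", zEndUm = "numeric", samples = "integer",
  setpointNn = "numeric"
))

setValidity("RampConfig", function(object) {
  if (object@zEndUm <= object@zStartUm) return("z range must be > 0")
  if (object@samples < 50L) return("samples must be >= 50")
  if (object@setpointNn <= 0) return("setpoint must be > 0")
  TRUE
})

#' ForceCurve: one approach-retract cycle
#'
#' Segments are data.frames of piezo height `z_um` (increasing toward the
#' sample on approach, reversed on retract) and deflection `d_nm`. Force in
#' nN is `springConstant * d_nm`.
#'
#' @slot meta Named list: cell_id, label, kind ("indentation"/"scfs"),
#'   seed, and acquisition truth where simulated.
#' @slot cantilever A [CantileverSpec-class].
#' @slot approach,retract data.frames with columns `z_um`, `d_nm`.
#' @export
setClass("ForceCurve", representation(
  meta = "list", cantilever = "CantileverSpec",
  approach = "data.frame", retract = "data.frame"
))

setValidity("ForceCurve", function(object) {
  for (segname in c("approach", "retract")) {
    seg <- slot(object, segname)
    if (!all(c("z_um", "d_nm") %in% names(seg))) {
      return(sprintf("%s needs columns z_um, d_nm", segname))
    }
    if (nrow(seg) && any(!is.finite(seg$z_um) | !is.finite(seg$d_nm))) {
      return(sprintf("%s contains non-finite values", segname))
    }
    if (nrow(seg) > 1) {
      dz <- diff(seg$z_um)
      ok <- if (segname == "approach") all(dz > 0) else all(dz < 0)
      if (!ok) return(sprintf("z must be strictly monotone in %s", segname))
    }
  }
  TRUE
})

#' HertzFitResult: per-curve Young's modulus read-out
#'
#' @slot EPa Fitted Young's modulus, Pa.
#' @slot z0Um,d0Nm Fitted contact point (piezo position, deflection offset).
#' @slot rmseNn RMS force residual over the fitted range, nN.
#' @slot nPoints Number of post-contact samples fitted.
#' @slot deltaRangeNm Indentation range used for the fit, nm.
#' @slot converged Logical convergence flag.
#' @export
setClass("HertzFitResult", representation(
  EPa = "numeric", z0Um = "numeric", d0Nm = "numeric", rmseNn = "numeric",
  nPoints = "integer", deltaRangeNm = "numeric", converged = "logical"
))

#' AdhesionResult: per-curve adhesion read-out
#'
#' @slot FAdhNn Peak adhesion force (magnitude of retract minimum), nN.
#' @slot workFj Work of adhesion over the adhesive well, fJ.
#' @slot pullOffZUm Piezo position of the force minimum, um.
#' @slot nRuptureSteps Count of detected rupture jumps.
#' @export
setClass("AdhesionResult", representation(
  FAdhNn = "numeric", workFj = "numeric", pullOffZUm = "numeric",
  nRuptureSteps = "integer"
))

#' CellMeasurement: aggregated per-cell mechanical value
#'
#' @slot cellId,label Identity of the measured cell.
#' @slot values Per-curve values (converged curves only).
#' @slot nExcluded Non-converged curves excluded from the aggregate.
#' @slot aggregate,sdValue Aggregate (mean or median) and SD.
#' @slot method Aggregation method used.
#' @export
setClass("CellMeasurement", representation(
  cellId = "integer", label = "character", values = "numeric",
  nExcluded = "integer", aggregate = "numeric", sdValue = "numeric",
  method = "character"
))

setValidity("CellMeasurement", function(object) {
  if (length(object@values) < 1L) return("at least one converged curve required")
  if (object@aggregate < min(object@values) - 1e-12 ||
      object@aggregate > max(object@values) + 1e-12) {
    return("aggregate must lie within [min, max] of per-curve values")
  }
  TRUE
})

#' PopulationSummary: per-cell-type distribution summary
#'
#' Gaussian parameters are maximum-likelihood on the raw values (mu =
#' sample mean, sigma = sample SD), independent of the histogram binning.
#'
#' @slot label Cell type.
#' @slot n Number of cells.
#' @slot mean,sd Sample mean and (unbiased) SD.
#' @slot mu,sigma Gaussian fit parameters.
#' @slot degenerate TRUE when all values coincide (sigma 0).
#' @slot breaks,counts Equal-width histogram over [min, max].
#' @export
setClass("PopulationSummary", representation(
  label = "character", n = "integer", mean = "numeric", sd = "numeric",
  mu = "numeric", sigma = "numeric", degenerate = "logical",
  breaks = "numeric", counts = "integer"
))

setValidity("PopulationSummary", function(object) {
  if (object@n != sum(object@counts)) return("histogram counts must sum to n")
  if (object@n >= 2L && !object@degenerate && object@sigma <= 0) {
    return("sigma must be > 0 for non-degenerate n >= 2")
  }
  TRUE
})
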