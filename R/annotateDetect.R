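#' Intersection-over-union of two boxes
#'
#' Boxes follow the half-open convention, so the area of `[xmin, xmax) x
#' [ymin, ymax)` is `(xmax - xmin) * (ymax - ymin)`. Disjoint boxes give 0.
#'
#' @param a,b Length-4 numerics `(xmin, ymin, xmax, ymax)`, or single-row
#'   box data.frames.
#' @return IoU in `[0, 1]`.
#' @examples
#' boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3))  # 1/7
#' @export
boxIoU <- function(a, b) {
  a <- asBoxVec(a); b <- asBoxVec(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  inter / union
}

asBoxVec <- function(x) {
  if (is.data.frame(x)) x <- c(x$xmin[1], x$ymin[1], x$xmax[1], x$ymax[1])
  x <- as.numeric(x)
  if (length(x) != 4 || x[1] >= x[3] || x[2] >= x[4]) {
    afmStop("a box is (xmin, ymin, xmax, ymax) with xmin < xmax, ymin < ymax",
            "cellAFM_format_error")
  }
  x
}

emptyBoxes <- function() {
  data.frame(label = character(), xmin = numeric(), ymin = numeric(),
             xmax = numeric(), ymax = numeric(), confidence = numeric())
}

## Threshold + label + watershed-split one fluorescence channel.
channelComponents <- function(channel, minAreaPx, thresholdMethod, fixedThreshold) {
  thr <- if (thresholdMethod == "fixed") fixedThreshold else {
    if (max(channel) < 0.2) Inf else EBImage::otsu(EBImage::Image(channel), range = c(0, 1))
  }
  mask <- channel > thr
  if (!any(mask)) return(NULL)
  seg <- splitTouching(mask)
  boxesFromLabels(seg, minAreaPx)
}

## Watershed on the distance map separates touching same-label cells while
## leaving isolated convex components intact.
splitTouching <- function(mask) {
  img <- EBImage::Image(mask * 1)
  dm <- EBImage::distmap(img)
  EBImage::watershed(dm, tolerance = 0.5, ext = 1)
}

boxesFromLabels <- function(seg, minAreaPx) {
  labs <- as.matrix(EBImage::imageData(seg))
  ids <- sort(unique(as.vector(labs)))
  ids <- ids[ids > 0]
  out <- list()
  for (id in ids) {
    idx <- which(labs == id, arr.ind = TRUE)
    if (nrow(idx) < minAreaPx) next
    ## EBImage images are [x, y]; convert to 0-based half-open box coords
    out[[length(out) + 1]] <- data.frame(
      xmin = min(idx[, 1]) - 1, ymin = min(idx[, 2]) - 1,
      xmax = max(idx[, 1]), ymax = max(idx[, 2]), area = nrow(idx))
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Annotate cells from fluorescence channels
#'
#' The dataset-preparation step: each fluorescence channel is thresholded
#' (Otsu by default), touching components are split on the distance-map
#' watershed, and components of at least `minAreaPx` pixels become boxes
#' labeled typeA (red channel) or typeB (green channel) with confidence 1.
#' A component whose footprint is super-threshold in both channels is
#' resolved to the channel with the larger overlap area.
#'
#' @param images An [ImageSet-class].
#' @param minAreaPx Minimum component area in pixels.
#' @param thresholdMethod `"otsu"` or `"fixed"`.
#' @param fixedThreshold Threshold used when `thresholdMethod = "fixed"`.
#' @param imageId Image reference string.
#' @return An [AnnotationSet-class] (no probe box; blank channels give an
#'   empty set).
#' @export
autoAnnotateFluorescence <- function(images, minAreaPx = 60L,
                                     thresholdMethod = c("otsu", "fixed"),
                                     fixedThreshold = 0.3, imageId = "scene") {
  thresholdMethod <- match.arg(thresholdMethod)
  H <- nrow(images@fluorRed); W <- ncol(images@fluorRed)
  ## EBImage convention is [x, y]: transpose the [y, x] rasters
  chans <- list(typeA = t(images@fluorRed), typeB = t(images@fluorGreen))
  masks <- lapply(chans, function(ch) {
    thr <- if (thresholdMethod == "fixed") fixedThreshold else {
      if (max(ch) < 0.2) Inf else EBImage::otsu(EBImage::Image(ch), range = c(0, 1))
    }
    ch > thr
  })
  allBoxes <- list()
  for (lab in names(chans)) {
    if (!any(masks[[lab]])) next
    comp <- channelComponents(chans[[lab]], minAreaPx, thresholdMethod, fixedThreshold)
    if (is.null(comp)) next
    other <- setdiff(names(chans), lab)
    for (i in seq_len(nrow(comp))) {
      xs <- (comp$xmin[i] + 1):comp$xmax[i]; ys <- (comp$ymin[i] + 1):comp$ymax[i]
      ovSelf <- sum(masks[[lab]][xs, ys])
      ovOther <- sum(masks[[other]][xs, ys])
      finalLab <- if (ovOther > ovSelf) other else lab
      allBoxes[[length(allBoxes) + 1]] <- data.frame(
        label = finalLab, xmin = comp$xmin[i], ymin = comp$ymin[i],
        xmax = comp$xmax[i], ymax = comp$ymax[i], confidence = 1)
    }
  }
  b <- if (length(allBoxes)) do.call(rbind, allBoxes) else emptyBoxes()
  new("AnnotationSet", imageId = imageId, width = W, height = H, boxes = b)
}

#' Default bright-field detector configuration
#'
#' Fixed decision constants of the classical reference detector. The size
#' threshold sits midway between the two types' mean radii; the texture
#' threshold separates fine (type A) from coarse (type B) interior texture
#' in band-pass energy ratio. These constants were calibrated once against
#' the simulator's default rendering.
#'
#' @param pixelSizeUm Microns per pixel of the input image.
#' @param probeRadiusUm Expected probe tip radius (known to the operator).
#' @param minAreaPx Minimum interior-component area.
#' @param darkThreshold Interior threshold on the background-flattened image.
#' @param sizeThresholdUm Radius (um) separating typeA from typeB.
#' @param textureLogRatioThreshold Log band-energy ratio separating fine
#'   from coarse texture.
#' @param nmsIoU Non-maximum-suppression IoU threshold.
#' @return Named list of detector constants.
#' @export
detectorConfig <- function(pixelSizeUm = 0.65, probeRadiusUm = 7,
                           minAreaPx = 80L, darkThreshold = -0.02,
                           sizeThresholdUm = 14.4,
                           textureLogRatioThreshold = 0.33,
                           nmsIoU = 0.5) {
  list(pixelSizeUm = pixelSizeUm, probeRadiusUm = probeRadiusUm,
       minAreaPx = as.integer(minAreaPx), darkThreshold = darkThreshold,
       sizeThresholdUm = sizeThresholdUm,
       textureLogRatioThreshold = textureLogRatioThreshold, nmsIoU = nmsIoU)
}

#' Detect cells and the probe from a bright-field image alone
#'
#' Classical reference detector (deterministic for a fixed input): the
#' image is flattened by subtracting a heavy Gaussian blur (removing the
#' illumination gradient), cell interiors are segmented as dark regions —
#' the bright halo rings between touching cells act as natural separators —
#' and remaining merged interiors are split on the distance-map watershed.
#' Each candidate is classified by equivalent radius and by the ratio of
#' coarse- to fine-band texture energy through fixed linear decision rules;
#' the decision margin maps monotonically onto confidence in (0.5, 1]. The
#' probe is found as a bright disc of the expected radius. Greedy
#' non-maximum suppression removes duplicate boxes.
#'
#' @param brightfield 2-D numeric matrix in `[0, 1]` (rows = y).
#' @param config Constants from [detectorConfig()].
#' @param imageId Image reference string.
#' @return An [AnnotationSet-class].
#' @export
detectBrightfield <- function(brightfield, config = detectorConfig(),
                              imageId = "scene") {
  if (!is.matrix(brightfield) || !is.numeric(brightfield)) {
    afmStop("brightfield must be a 2-D numeric matrix", "cellAFM_format_error")
  }
  H <- nrow(brightfield); W <- ncol(brightfield)
  img <- EBImage::Image(t(brightfield))  # EBImage [x, y]
  ## background sigma capped so the blur kernel fits small images
  bgSigma <- min(50, (min(W, H) - 1) / 7)
  flat <- img - EBImage::gblur(img, sigma = bgSigma)  # illumination + local bg
  sm <- EBImage::gblur(flat, sigma = 2.5)
  smM <- as.matrix(EBImage::imageData(sm))
  ## band-pass fields for the texture-coarseness feature
  fine <- as.matrix(EBImage::imageData(flat - EBImage::gblur(flat, 1.2)))
  coarse <- as.matrix(EBImage::imageData(
    EBImage::gblur(flat, 2) - EBImage::gblur(flat, 5)))

  out <- list()
  probeBox <- NULL
  ## --- probe: bright compact disc of the expected radius ---
  prPx <- config$probeRadiusUm / config$pixelSizeUm
  bmask <- smM > 0.2
  if (any(bmask)) {
    blab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(bmask * 1))))
    ids <- setdiff(unique(as.vector(blab)), 0)
    best <- NULL; bestScore <- Inf
    for (id in ids) {
      idx <- which(blab == id, arr.ind = TRUE)
      rel <- abs(log(nrow(idx) / (pi * prPx^2)))
      if (rel < bestScore) { bestScore <- rel; best <- idx }
    }
    if (!is.null(best) && bestScore < log(3)) {
      pad <- 3  # rim + smoothing loss around the bright interior
      probeBox <- data.frame(
        label = "probe",
        xmin = max(0, min(best[, 1]) - 1 - pad), ymin = max(0, min(best[, 2]) - 1 - pad),
        xmax = min(W, max(best[, 1]) + pad), ymax = min(H, max(best[, 2]) + pad),
        confidence = max(0.5, min(1, 1 - 0.3 * bestScore)))
      out[[length(out) + 1]] <- probeBox
    }
  }

  ## --- cells: dark textured interiors; halo rings separate neighbours ---
  cmask <- smM < config$darkThreshold
  if (any(cmask)) {
    cmask <- as.matrix(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(cmask * 1)))) > 0
    seg <- EBImage::watershed(EBImage::distmap(EBImage::Image(cmask * 1)),
                              tolerance = 3, ext = 1)
    labs <- as.matrix(EBImage::imageData(seg))
    ids <- setdiff(unique(as.vector(labs)), 0)
    ringW <- 2.5
    for (id in ids) {
      idx <- which(labs == id, arr.ind = TRUE)
      if (nrow(idx) < config$minAreaPx) next
      box <- c(max(0, min(idx[, 1]) - 1 - ringW), max(0, min(idx[, 2]) - 1 - ringW),
               min(W, max(idx[, 1]) + ringW), min(H, max(idx[, 2]) + ringW))
      ## the probe's dark rim also segments as a "dark" component: drop
      ## candidates that mostly live inside the probe box
      if (!is.null(probeBox)) {
        pb <- asBoxVec(probeBox)
        iw <- min(box[3], pb[3]) - max(box[1], pb[1])
        ih <- min(box[4], pb[4]) - max(box[2], pb[2])
        inter <- max(0, iw) * max(0, ih)
        if (inter > 0.5 * (box[3] - box[1]) * (box[4] - box[2])) next
      }
      rEstUm <- (sqrt(nrow(idx) / pi) + ringW) * config$pixelSizeUm
      sdFine <- sd(fine[idx]); sdCoarse <- sd(coarse[idx])
      texRatio <- log((sdCoarse + 1e-6) / (sdFine + 1e-6))
      sizeScore <- (rEstUm - config$sizeThresholdUm) / 1.5
      texScore <- (texRatio - config$textureLogRatioThreshold) / 0.15
      s <- 0.35 * sizeScore + 0.65 * texScore
      lab <- if (s > 0) "typeB" else "typeA"
      conf <- 1 / (1 + exp(-abs(s)))
      out[[length(out) + 1]] <- data.frame(
        label = lab, xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4],
        confidence = conf)
    }
  }
  b <- if (length(out)) do.call(rbind, out) else emptyBoxes()
  b <- nmsBoxes(b, config$nmsIoU)
  rownames(b) <- NULL
  new("AnnotationSet", imageId = imageId, width = W, height = H, boxes = b)
}

## Greedy NMS by descending confidence (ties: smaller index first).
nmsBoxes <- function(b, iouThr) {
  if (nrow(b) < 2) return(b)
  ord <- order(-b$confidence, seq_len(nrow(b)))
  keep <- logical(nrow(b))
  for (i in ord) {
    ok <- TRUE
    for (j in which(keep)) {
      if (boxIoU(b[i, ], b[j, ]) >= iouThr) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  b[keep, , drop = FALSE]
}

#' Evaluate detections against ground truth
#'
#' Greedy one-to-one matching in descending prediction confidence
#' (confidence ties broken by box order): a prediction is a true positive
#' iff it matches a not-yet-matched truth box of the same label with IoU at
#' or above the threshold. Remaining predictions are false positives,
#' remaining truths false negatives. Empty-over-empty precision/recall is
#' defined as 1.
#'
#' @param pred,truth [AnnotationSet-class] objects for the same image.
#' @param iouThreshold Matching IoU threshold (default 0.5).
#' @return A [DetectionMetrics-class].
#' @export
matchDetections <- function(pred, truth, iouThreshold = 0.5) {
  if (pred@imageId != truth@imageId) {
    afmStop("prediction and truth refer to different images", "cellAFM_format_error")
  }
  pb <- pred@boxes; tb <- truth@boxes
  matchedT <- rep(FALSE, nrow(tb))
  isTP <- rep(FALSE, nrow(pb))
  ord <- if (nrow(pb)) order(-pb$confidence, seq_len(nrow(pb))) else integer()
  for (i in ord) {
    cand <- which(!matchedT & tb$label == pb$label[i])
    if (!length(cand)) next
    ious <- vapply(cand, function(j) boxIoU(pb[i, ], tb[j, ]), numeric(1))
    jbest <- cand[which.max(ious)]
    if (max(ious) >= iouThreshold) { matchedT[jbest] <- TRUE; isTP[i] <- TRUE }
  }
  safeDiv <- function(num, den) if (den == 0) 1 else num / den
  per <- do.call(rbind, lapply(BOX_LABELS, function(lab) {
    tp <- sum(isTP & pb$label == lab)
    fp <- sum(!isTP & pb$label == lab)
    fn <- sum(!matchedT & tb$label == lab)
    data.frame(label = lab, tp = tp, fp = fp, fn = fn,
               precision = safeDiv(tp, tp + fp), recall = safeDiv(tp, tp + fn))
  }))
  tp <- sum(isTP); fp <- sum(!isTP); fn <- sum(!matchedT)
  new("DetectionMetrics", perLabel = per, tp = as.integer(tp),
      fp = as.integer(fp), fn = as.integer(fn),
      precision = safeDiv(tp, tp + fp), recall = safeDiv(tp, tp + fn),
      iouThreshold = iouThreshold)
}

YOLO_CLASSES <- c(typeA = 0L, typeB = 1L, probe = 2L)

#' Read and write annotation files
#'
#' Two interchange dialects so externally produced detections (e.g. from a
#' trained network) can enter the pipeline:
#' \itemize{
#'   \item `yolo_txt`: one line per box, `class cx cy w h [confidence]`,
#'     all coordinates normalized to image size; classes 0 = typeA,
#'     1 = typeB, 2 = probe.
#'   \item `coco_json`: COCO-style JSON with absolute `[x, y, w, h]` bboxes
#'     and optional `score`.
#' }
#' Round-trips are exact to float precision. Malformed records raise a
#' parse error naming the offending line/record.
#'
#' @param ann An [AnnotationSet-class] (for writing).
#' @param path File path.
#' @param format `"yolo_txt"` or `"coco_json"`.
#' @param width,height Image dimensions in px (required to denormalize
#'   YOLO boxes on read).
#' @param imageId Image reference for the returned set.
#' @return `readBoxes`: an [AnnotationSet-class]. `writeBoxes`: `path`,
#'   invisibly.
#' @export
writeBoxes <- function(ann, path, format = c("yolo_txt", "coco_json")) {
  format <- match.arg(format)
  b <- ann@boxes
  if (format == "yolo_txt") {
    lines <- character(nrow(b))
    for (i in seq_len(nrow(b))) {
      cx <- (b$xmin[i] + b$xmax[i]) / 2 / ann@width
      cy <- (b$ymin[i] + b$ymax[i]) / 2 / ann@height
      w <- (b$xmax[i] - b$xmin[i]) / ann@width
      h <- (b$ymax[i] - b$ymin[i]) / ann@height
      lines[i] <- sprintf("%d %.9f %.9f %.9f %.9f %.9f",
                          YOLO_CLASSES[[b$label[i]]], cx, cy, w, h, b$confidence[i])
    }
    writeLines(lines, path)
  } else {
    cats <- lapply(seq_along(YOLO_CLASSES), function(i) {
      list(id = unname(YOLO_CLASSES[i]) + 1L, name = names(YOLO_CLASSES)[i])
    })
    anns <- lapply(seq_len(nrow(b)), function(i) {
      list(id = i, image_id = 1L,
           category_id = YOLO_CLASSES[[b$label[i]]] + 1L,
           bbox = c(b$xmin[i], b$ymin[i], b$xmax[i] - b$xmin[i], b$ymax[i] - b$ymin[i]),
           score = b$confidence[i])
    })
    obj <- list(images = list(list(id = 1L, width = ann@width, height = ann@height,
                                   file_name = ann@imageId)),
                annotations = anns, categories = cats)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeBoxes
#' @export
readBoxes <- function(path, format = c("yolo_txt", "coco_json"),
                      width = NULL, height = NULL, imageId = "scene") {
  format <- match.arg(format)
  if (format == "yolo_txt") {
    if (is.null(width) || is.null(height)) {
      afmStop("width and height are required to read YOLO-txt boxes",
              "cellAFM_format_error")
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- list()
    for (ln in seq_along(lines)) {
      parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (!(length(parts) %in% c(5L, 6L)) || anyNA(vals)) {
        afmStop(sprintf("malformed YOLO line %d: '%s'", ln, lines[ln]),
                "cellAFM_parse_error")
      }
      cls <- as.integer(vals[1])
      if (!cls %in% YOLO_CLASSES) {
        afmStop(sprintf("unknown class index %d on YOLO line %d", cls, ln),
                "cellAFM_parse_error")
      }
      cx <- vals[2] * width; cy <- vals[3] * height
      w <- vals[4] * width; h <- vals[5] * height
      rows[[ln]] <- data.frame(
        label = names(YOLO_CLASSES)[match(cls, YOLO_CLASSES)],
        xmin = cx - w / 2, ymin = cy - h / 2, xmax = cx + w / 2, ymax = cy + h / 2,
        confidence = if (length(parts) == 6L) vals[6] else 1)
    }
    b <- if (length(rows)) do.call(rbind, rows) else emptyBoxes()
    new("AnnotationSet", imageId = imageId, width = as.integer(width),
        height = as.integer(height), boxes = b)
  } else {
    obj <- tryCatch(jsonlite::read_json(path),
                    error = function(e) afmStop(paste("COCO JSON parse failure:",
                                                      conditionMessage(e)),
                                                "cellAFM_parse_error"))
    if (is.null(obj$images) || !length(obj$images)) {
      afmStop("COCO JSON has no images entry", "cellAFM_parse_error")
    }
    imgInfo <- obj$images[[1]]
    catMap <- vapply(obj$categories, function(ct) ct$name, character(1))
    names(catMap) <- vapply(obj$categories, function(ct) as.character(ct$id), character(1))
    rows <- list()
    for (i in seq_along(obj$annotations)) {
      a <- obj$annotations[[i]]
      if (is.null(a$bbox) || length(a$bbox) != 4) {
        afmStop(sprintf("malformed COCO annotation record %d (bad bbox)", i),
                "cellAFM_parse_error")
      }
      bb <- as.numeric(a$bbox)
      lab <- catMap[[as.character(a$category_id)]]
      rows[[i]] <- data.frame(
        label = lab, xmin = bb[1], ymin = bb[2], xmax = bb[1] + bb[3],
        ymax = bb[2] + bb[4],
        confidence = if (is.null(a$score)) 1 else a$score)
    }
    b <- if (length(rows)) do.call(rbind, rows) else emptyBoxes()
    new("AnnotationSet", imageId = imgInfo$file_name,
        width = as.integer(imgInfo$width), height = as.integer(imgInfo$height),
        boxes = b)
  }
}
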