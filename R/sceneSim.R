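#' Construct a scene configuration
#'
#' Defaults describe a 512x512 px field of view at 0.65 um/px containing a
#' two-type adherent co-culture. The `"high"` preset places enough cells,
#' with bounded pairwise overlap, that different cell types are in physical
#' contact and the union of cell masks covers at least 60% of the surface;
#' the `"low"` preset keeps cells separated and coverage at or below 10%.
#' Type B cells are rendered ~30% larger with coarser interior texture than
#' type A — a simulator convention that makes the two types separable by a
#' classical detector, not a biological claim. Type B also carries higher
#' true Young's modulus and adhesion force, mirroring the qualitative
#' ordering between an undifferentiated and a differentiated gastric cancer
#' line in co-culture.
#'
#' @param width,height Image size, px.
#' @param pixelSizeUm Microns per pixel.
#' @param densityPreset `"high"` or `"low"`.
#' @param nCellsPerType Cells of each type.
#' @param radiusMeanUm,radiusSdUm Per-type equivalent radius distribution, um.
#' @param modulusLogMean,modulusLogSd Per-type log-normal modulus parameters
#'   (log Pa).
#' @param adhesionMeanNn,adhesionSdNn Per-type adhesion force distribution, nN.
#' @param probeRadiusUm Probe tip radius, um.
#' @param noiseSd Image noise SD (fraction of full scale).
#' @param illuminationAmplitude Amplitude of the smooth illumination field.
#' @param maxOverlapFraction Maximum pairwise mask overlap during placement.
#' @param seed Default seed.
#' @return A validated [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(densityPreset = "low", nCellsPerType = 3L)
#' gt <- sampleScene(cfg, seed = 7)
#' @export
sceneConfig <- function(width = 512L, height = 512L, pixelSizeUm = 0.65,
                        densityPreset = c("high", "low"),
                        nCellsPerType = NULL,
                        radiusMeanUm = c(typeA = 12.5, typeB = 16.25),
                        radiusSdUm = c(typeA = 1.2, typeB = 1.6),
                        modulusLogMean = c(typeA = log(3000), typeB = log(6000)),
                        modulusLogSd = c(typeA = 0.35, typeB = 0.35),
                        adhesionMeanNn = c(typeA = 1.2, typeB = 2.4),
                        adhesionSdNn = c(typeA = 0.25, typeB = 0.4),
                        probeRadiusUm = 7, noiseSd = 0.01,
                        illuminationAmplitude = 0.04,
                        maxOverlapFraction = NULL, seed = 1L) {
  densityPreset <- match.arg(densityPreset)
  if (is.null(nCellsPerType)) {
    nCellsPerType <- if (densityPreset == "high") 80L else 6L
  }
  if (is.null(maxOverlapFraction)) {
    maxOverlapFraction <- if (densityPreset == "high") 0.25 else 0
  }
  new("SceneConfig",
      width = as.integer(width), height = as.integer(height),
      pixelSizeUm = pixelSizeUm, densityPreset = densityPreset,
      nCellsPerType = as.integer(nCellsPerType),
      radiusMeanUm = radiusMeanUm, radiusSdUm = radiusSdUm,
      modulusLogMean = modulusLogMean, modulusLogSd = modulusLogSd,
      adhesionMeanNn = adhesionMeanNn, adhesionSdNn = adhesionSdNn,
      probeRadiusUm = probeRadiusUm, noiseSd = noiseSd,
      illuminationAmplitude = illuminationAmplitude,
      maxOverlapFraction = maxOverlapFraction, seed = as.integer(seed))
}

## Lens (intersection) area of two circles at center distance d.
circleOverlapArea <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  a1 + a2 - a3
}

## Logical ellipse mask over a pixel window; pixel (x, y) is covered when
## its center (x + 0.5, y + 0.5) lies inside the ellipse.
ellipseWindow <- function(cx, cy, a, b, theta, width, height) {
  x0 <- max(0L, floor(cx - a)); x1 <- min(width - 1L, ceiling(cx + a))
  y0 <- max(0L, floor(cy - a)); y1 <- min(height - 1L, ceiling(cy + a))
  if (x0 > x1 || y0 > y1) return(NULL)
  xs <- (x0:x1) + 0.5; ys <- (y0:y1) + 0.5
  dx <- outer(ys - cy, xs - cx, function(yy, xx) xx)  # [row=y, col=x]
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  list(x0 = x0, y0 = y0, mask = (u^2 + v^2) <= 1, u2v2 = u^2 + v^2)
}

unionCellMask <- function(cellsDf, width, height) {
  m <- matrix(FALSE, nrow = height, ncol = width)
  for (i in seq_len(nrow(cellsDf))) {
    w <- ellipseWindow(cellsDf$cx[i], cellsDf$cy[i], cellsDf$a[i], cellsDf$b[i],
                       cellsDf$theta[i], width, height)
    if (is.null(w)) next
    ri <- (w$y0 + 1):(w$y0 + nrow(w$mask)); ci <- (w$x0 + 1):(w$x0 + ncol(w$mask))
    m[ri, ci] <- m[ri, ci] | w$mask
  }
  m
}

#' @describeIn coverageFraction Pixel-exact union-mask coverage.
#' @export
setMethod("coverageFraction", "SceneGroundTruth", function(gt) {
  sum(unionCellMask(gt@cells, gt@width, gt@height)) / (as.numeric(gt@width) * gt@height)
})

#' Sample a co-culture scene with ground truth
#'
#' Dart-throwing placement: cell candidates (ellipse geometry drawn from the
#' per-type distributions) are accepted when their pairwise overlap with
#' every placed cell stays at or below `maxOverlapFraction` (low preset
#' additionally requires a clear gap) and they avoid the probe's clear zone.
#' Radii are resampled after repeated rejection. The probe is placed first
#' in what remains a cell-free region. True Young's modulus (log-normal)
#' and adhesion force (normal, truncated at 0) are drawn per cell.
#'
#' @param config A [SceneConfig-class].
#' @param seed Integer seed; identical `(config, seed)` reproduce the
#'   identical scene.
#' @return A [SceneGroundTruth-class].
#' @section Errors: when the requested density is geometrically unreachable
#'   (placement fails after bounded retries, or a high-preset scene cannot
#'   reach 60% coverage), an error of class `cellAFM_density_error` is
#'   raised.
#' @export
sampleScene <- function(config, seed = config@seed) {
  validObject(config)
  withSeed(seed, {
    W <- config@width; H <- config@height
    probeRpx <- config@probeRadiusUm / config@pixelSizeUm
    marginP <- probeRpx + 4
    probe <- c(runif(1, marginP, W - marginP), runif(1, marginP, H - marginP))

    nTot <- 2L * config@nCellsPerType
    ## place the larger type first: packing is tightest for big cells
    types <- rep(c("typeB", "typeA"), each = config@nCellsPerType)

    placed <- data.frame(cell_id = integer(), cell_type = character(),
                         cx = numeric(), cy = numeric(), a = numeric(),
                         b = numeric(), theta = numeric(), E_true = numeric(),
                         F_adh_true = numeric(), r_eff = numeric())
    maxTries <- 12000L
    for (i in seq_len(nTot)) {
      ty <- types[i]
      ok <- FALSE
      rUm <- max(2 * config@pixelSizeUm,
                 rnorm(1, config@radiusMeanUm[[ty]], config@radiusSdUm[[ty]]))
      for (tryi in seq_len(maxTries)) {
        if (tryi %% 50L == 0L) {  # resample radius after repeated rejection
          rUm <- max(2 * config@pixelSizeUm,
                     rnorm(1, config@radiusMeanUm[[ty]], config@radiusSdUm[[ty]]))
        }
        r <- rUm / config@pixelSizeUm
        q <- runif(1, 0.78, 1)
        a <- r / sqrt(q); b <- r * sqrt(q)
        theta <- runif(1, 0, pi)
        cx <- runif(1, 0.6 * a, W - 0.6 * a)
        cy <- runif(1, 0.6 * a, H - 0.6 * a)
        dp <- sqrt((cx - probe[1])^2 + (cy - probe[2])^2)
        if (dp < r + probeRpx + 3) next
        accept <- TRUE
        if (nrow(placed)) {
          dd <- sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2)
          if (config@maxOverlapFraction == 0) {
            if (any(dd <= placed$r_eff + r + 2)) accept <- FALSE
          } else {
            ## co-culture mixing convention: substantial overlap is allowed
            ## only across cell types (that is what "in contact" means for a
            ## high-density co-culture); same-type neighbours may barely touch
            near <- which(dd < placed$r_eff + r)
            for (j in near) {
              cap <- if (placed$cell_type[j] == ty) {
                min(0.1, config@maxOverlapFraction)
              } else config@maxOverlapFraction
              ov <- circleOverlapArea(placed$r_eff[j], r, dd[j]) /
                (pi * min(placed$r_eff[j], r)^2)
              if (ov > cap) { accept <- FALSE; break }
            }
          }
        }
        if (accept) { ok <- TRUE; break }
      }
      if (!ok) {
        afmStop(sprintf(
          "could not place cell %d of %d: requested %s-density unsatisfiable for this geometry",
          i, nTot, config@densityPreset), "cellAFM_density_error")
      }
      E <- rlnorm(1, config@modulusLogMean[[ty]], config@modulusLogSd[[ty]])
      Fa <- max(0, rnorm(1, config@adhesionMeanNn[[ty]], config@adhesionSdNn[[ty]]))
      placed <- rbind(placed, data.frame(
        cell_id = i, cell_type = ty, cx = cx, cy = cy, a = a, b = b,
        theta = theta, E_true = E, F_adh_true = Fa, r_eff = r))
    }
    cellsDf <- placed[, setdiff(names(placed), "r_eff")]
    cov <- sum(unionCellMask(cellsDf, W, H)) / (as.numeric(W) * H)
    if (config@densityPreset == "high" && cov < 0.60) {
      afmStop(sprintf(
        "high-density preset reached only %.1f%% coverage (needs >= 60%%); too few/small cells for this image",
        100 * cov), "cellAFM_density_error")
    }
    if (config@densityPreset == "low" && cov > 0.10) {
      afmStop(sprintf(
        "low-density preset reached %.1f%% coverage (must stay <= 10%%); too many/large cells",
        100 * cov), "cellAFM_density_error")
    }
    new("SceneGroundTruth", cells = cellsDf, probeCenterPx = probe,
        probeRadiusPx = probeRpx, pixelSizeUm = config@pixelSizeUm,
        width = W, height = H, coverage = cov)
  })
}

## Smooth illumination field: tilted plane plus one low-frequency mode.
illuminationField <- function(width, height, amplitude) {
  xs <- seq(0, 1, length.out = width); ys <- seq(0, 1, length.out = height)
  plane <- outer(ys, xs, function(y, x) 0.5 * (x - 0.5) + 0.35 * (y - 0.5))
  wave <- outer(ys, xs, function(y, x) sin(2 * pi * (0.7 * x + 0.4 * y)))
  amplitude * (plane + 0.5 * wave)
}

## Per-cell interior texture: white noise smoothed at a type-specific scale.
textureField <- function(nr, nc, sigma, amplitude) {
  raw <- matrix(rnorm(nr * nc), nr, nc)
  pad <- ceiling(3 * sigma)
  big <- matrix(rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad, nc + 2 * pad)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(big), sigma = sigma))
  sm <- sm[(pad + 1):(pad + nr), (pad + 1):(pad + nc), drop = FALSE]
  s <- sd(as.vector(sm)); if (s == 0) s <- 1
  amplitude * sm / s
}

#' Render bright-field and fluorescence images of a scene
#'
#' Bright-field: each cell appears as a bright halo ring at its boundary
#' with a darker, textured interior; type A interiors carry fine texture,
#' type B coarse texture (and type B cells are larger) — the cues the
#' default detector uses. Cells are drawn in placement order, so later
#' cells occlude earlier ones where they overlap, and the ring of the cell
#' on top separates the two interiors. The probe is a bright disc with a
#' dark rim. A smooth illumination gradient and additive Gaussian noise are
#' applied last. Fluorescence channels are noisy indicator masks: type A
#' cells appear only in the red channel, type B only in the green channel.
#'
#' @param gt A [SceneGroundTruth-class].
#' @param config The [SceneConfig-class] the scene was sampled from.
#' @param seed Seed for the rendering noise (default: `config@seed`);
#'   identical inputs render bit-identical images.
#' @return An [ImageSet-class].
#' @export
renderImages <- function(gt, config, seed = config@seed) {
  if (gt@width != config@width || gt@height != config@height) {
    afmStop("scene dimensions do not match config", "cellAFM_format_error")
  }
  withSeed(seed, {
    W <- gt@width; H <- gt@height
    bf <- matrix(0.55, H, W)
    red <- matrix(0.02, H, W)
    green <- matrix(0.02, H, W)
    ringW <- 2.5
    texSigma <- c(typeA = 1.0, typeB = 3.0)
    texAmp <- c(typeA = 0.04, typeB = 0.05)
    ringLevel <- c(typeA = 0.74, typeB = 0.84)
    for (i in seq_len(nrow(gt@cells))) {
      ci <- gt@cells[i, ]
      w <- ellipseWindow(ci$cx, ci$cy, ci$a, ci$b, ci$theta, W, H)
      if (is.null(w)) next
      nr <- nrow(w$mask); nc <- ncol(w$mask)
      ri <- (w$y0 + 1):(w$y0 + nr); cc <- (w$x0 + 1):(w$x0 + nc)
      innerScale <- 1 - ringW / sqrt(ci$a * ci$b)
      inner <- w$u2v2 <= innerScale^2
      ring <- w$mask & !inner
      tex <- textureField(nr, nc, texSigma[[ci$cell_type]], texAmp[[ci$cell_type]])
      sub <- bf[ri, cc]
      sub[inner] <- 0.40 + tex[inner]
      sub[ring] <- ringLevel[[ci$cell_type]]
      bf[ri, cc] <- sub
      fl <- if (ci$cell_type == "typeA") red else green
      flsub <- fl[ri, cc]
      flsub[w$mask] <- 0.6
      if (ci$cell_type == "typeA") red[ri, cc] <- flsub else green[ri, cc] <- flsub
    }
    ## probe: bright disc, dark rim, drawn on top
    pr <- gt@probeRadiusPx
    w <- ellipseWindow(gt@probeCenterPx[1], gt@probeCenterPx[2], pr, pr, 0, W, H)
    if (!is.null(w)) {
      nr <- nrow(w$mask); nc <- ncol(w$mask)
      ri <- (w$y0 + 1):(w$y0 + nr); cc <- (w$x0 + 1):(w$x0 + nc)
      inner <- w$u2v2 <= (1 - 2 / pr)^2
      rim <- w$mask & !inner
      sub <- bf[ri, cc]
      sub[inner] <- 0.88
      sub[rim] <- 0.12
      bf[ri, cc] <- sub
    }
    bf <- bf + illuminationField(W, H, config@illuminationAmplitude)
    bf <- bf + matrix(rnorm(W * H, 0, config@noiseSd), H, W)
    red <- red + matrix(rnorm(W * H, 0, 0.005), H, W)
    green <- green + matrix(rnorm(W * H, 0, 0.005), H, W)
    clamp <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
    new("ImageSet", brightfield = clamp(bf), fluorRed = clamp(red),
        fluorGreen = clamp(green))
  })
}

## Axis-aligned bounding box of a rotated ellipse, half-open pixel coords.
ellipseBBox <- function(cx, cy, a, b, theta) {
  ex <- sqrt((a * cos(theta))^2 + (b * sin(theta))^2)
  ey <- sqrt((a * sin(theta))^2 + (b * cos(theta))^2)
  c(xmin = cx - ex, ymin = cy - ey, xmax = cx + ex, ymax = cy + ey)
}

#' Ground-truth annotations of a scene
#'
#' Bounding boxes of every cell ellipse (clipped to the image) plus the
#' probe box, confidence 1 — the reference the detector is evaluated
#' against.
#'
#' @param gt A [SceneGroundTruth-class].
#' @param imageId Image reference string.
#' @return An [AnnotationSet-class].
#' @export
truthAnnotations <- function(gt, imageId = "scene") {
  rows <- lapply(seq_len(nrow(gt@cells)), function(i) {
    ci <- gt@cells[i, ]
    bb <- ellipseBBox(ci$cx, ci$cy, ci$a, ci$b, ci$theta)
    data.frame(label = ci$cell_type,
               xmin = max(0, bb["xmin"]), ymin = max(0, bb["ymin"]),
               xmax = min(gt@width, bb["xmax"]), ymax = min(gt@height, bb["ymax"]),
               confidence = 1, cell_id = ci$cell_id)
  })
  pr <- gt@probeRadiusPx
  probeRow <- data.frame(
    label = "probe",
    xmin = max(0, gt@probeCenterPx[1] - pr), ymin = max(0, gt@probeCenterPx[2] - pr),
    xmax = min(gt@width, gt@probeCenterPx[1] + pr),
    ymax = min(gt@height, gt@probeCenterPx[2] + pr),
    confidence = 1, cell_id = NA_integer_)
  b <- do.call(rbind, c(rows, list(probeRow)))
  b <- b[b$xmax > b$xmin & b$ymax > b$ymin, , drop = FALSE]
  rownames(b) <- NULL
  new("AnnotationSet", imageId = imageId, width = gt@width, height = gt@height,
      boxes = b)
}

#' Write / read an image set as 16-bit grayscale TIFF
#'
#' One file per channel: `<prefix>_brightfield.tif`, `<prefix>_fluor_red.tif`,
#' `<prefix>_fluor_green.tif`.
#'
#' @param images An [ImageSet-class].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return `writeImageSet`: the three paths, invisibly. `readImageSet`: an
#'   [ImageSet-class].
#' @export
writeImageSet <- function(images, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_brightfield.tif", "_fluor_red.tif",
                                           "_fluor_green.tif")))
  tiff::writeTIFF(images@brightfield, paths[1], bits.per.sample = 16)
  tiff::writeTIFF(images@fluorRed, paths[2], bits.per.sample = 16)
  tiff::writeTIFF(images@fluorGreen, paths[3], bits.per.sample = 16)
  invisible(paths)
}

#' @rdname writeImageSet
#' @export
readImageSet <- function(dir, prefix = "scene") {
  paths <- file.path(dir, paste0(prefix, c("_brightfield.tif", "_fluor_red.tif",
                                           "_fluor_green.tif")))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    afmStop(paste("missing image file(s):", paste(missing, collapse = ", ")),
            "cellAFM_format_error")
  }
  rd <- function(p) { m <- tiff::readTIFF(p); if (length(dim(m)) == 3) m[, , 1] else m }
  new("ImageSet", brightfield = rd(paths[1]), fluorRed = rd(paths[2]),
      fluorGreen = rd(paths[3]))
}

#' Serialize / deserialize scene ground truth as JSON
#'
#' The JSON carries a `schema_version` field; `readScene` refuses unknown
#' versions.
#'
#' @param gt A [SceneGroundTruth-class].
#' @param path File path.
#' @return `writeScene`: `path`, invisibly. `readScene`: a
#'   [SceneGroundTruth-class].
#' @export
writeScene <- function(gt, path) {
  obj <- list(
    schema_version = 1L,
    width = gt@width, height = gt@height, pixel_size_um = gt@pixelSizeUm,
    probe_center_px = gt@probeCenterPx, probe_radius_px = gt@probeRadiusPx,
    coverage_fraction = gt@coverage, cells = gt@cells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    afmStop("unsupported scene schema version", "cellAFM_format_error")
  }
  cellsDf <- as.data.frame(obj$cells)
  if (!nrow(cellsDf)) {
    cellsDf <- data.frame(cell_id = integer(), cell_type = character(),
                          cx = numeric(), cy = numeric(), a = numeric(),
                          b = numeric(), theta = numeric(), E_true = numeric(),
                          F_adh_true = numeric())
  }
  new("SceneGroundTruth", cells = cellsDf,
      probeCenterPx = as.numeric(obj$probe_center_px),
      probeRadiusPx = obj$probe_radius_px, pixelSizeUm = obj$pixel_size_um,
      width = as.integer(obj$width), height = as.integer(obj$height),
      coverage = obj$coverage_fraction)
}
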