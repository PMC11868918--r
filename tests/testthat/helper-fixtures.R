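# Shared fixtures. Heavy objects (a rendered default high-density scene)
# are built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

defaultHighScene <- function(seed = 1L) {
  key <- paste0("high_", seed)
  if (is.null(.fixtureCache[[key]])) {
    cfg <- sceneConfig(densityPreset = "high")
    gt <- sampleScene(cfg, seed = seed)
    img <- renderImages(gt, cfg, seed = seed)
    .fixtureCache[[key]] <- list(cfg = cfg, gt = gt, img = img)
  }
  .fixtureCache[[key]]
}

quietCantilever <- function(...) {
  cantileverSpec(noiseSdNm = 0, driftNmPerUm = 0, ...)
}

## noise level expressed as a fraction of the 5 nN setpoint force,
## converted to deflection nm through the default spring constant
noiseNmForForceFraction <- function(fraction, setpointNn = 5, k = 0.05) {
  fraction * setpointNn / k
}

## Manually assembled ground truth: circular cells at given centers/radii.
manualScene <- function(centers, radii, types, width = 100L, height = 100L,
                        probe = c(width - 8, height - 8), probeRadiusPx = 5) {
  n <- length(radii)
  cellsDf <- if (n == 0L) {
    data.frame(cell_id = integer(), cell_type = character(),
               cx = numeric(), cy = numeric(), a = numeric(),
               b = numeric(), theta = numeric(), E_true = numeric(),
               F_adh_true = numeric())
  } else {
    data.frame(
      cell_id = seq_len(n), cell_type = types,
      cx = vapply(centers, `[`, numeric(1), 1),
      cy = vapply(centers, `[`, numeric(1), 2),
      a = radii, b = radii, theta = 0,
      E_true = 1000, F_adh_true = 1)
  }
  methods::new("SceneGroundTruth", cells = cellsDf,
               probeCenterPx = probe, probeRadiusPx = probeRadiusPx,
               pixelSizeUm = 0.65, width = as.integer(width),
               height = as.integer(height), coverage = 0)
}

## Independent pixel-counting coverage oracle: brute-force loop over all
## pixel centers, no shared code with the package's mask machinery.
coverageOracle <- function(gt) {
  cl <- cells(gt)
  covered <- 0L
  for (py in seq_len(gt@height) - 1L) {
    for (px in seq_len(gt@width) - 1L) {
      x <- px + 0.5; y <- py + 0.5
      inside <- FALSE
      for (i in seq_len(nrow(cl))) {
        dx <- x - cl$cx[i]; dy <- y - cl$cy[i]
        u <- (dx * cos(cl$theta[i]) + dy * sin(cl$theta[i])) / cl$a[i]
        v <- (-dx * sin(cl$theta[i]) + dy * cos(cl$theta[i])) / cl$b[i]
        if (u^2 + v^2 <= 1) { inside <- TRUE; break }
      }
      if (inside) covered <- covered + 1L
    }
  }
  covered / (as.numeric(gt@width) * gt@height)
}

annotationFromDf <- function(df, width = 100L, height = 100L, id = "scene") {
  methods::new("AnnotationSet", imageId = id, width = as.integer(width),
               height = as.integer(height), boxes = df)
}

boxDf <- function(label, xmin, ymin, xmax, ymax, confidence = 1) {
  data.frame(label = label, xmin = xmin, ymin = ymin, xmax = xmax,
             ymax = ymax, confidence = confidence)
}
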