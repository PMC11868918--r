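#' Configuration of a full virtual experiment
#'
#' Defaults mirror the reference experimental design: 50 cells measured
#' per type with 10 force curves recorded at the same location on each
#' cell, on a high-density co-culture scene.
#'
#' @param scene A [SceneConfig-class].
#' @param detector Constants from [detectorConfig()] (pixel size and probe
#'   radius default to the scene's).
#' @param cantilever A [CantileverSpec-class].
#' @param ramp A [RampConfig-class].
#' @param nCellsPerType Cells to measure per type.
#' @param curvesPerCell Force curves per cell.
#' @param assay `"indentation"` (Young's modulus) or `"scfs"` (adhesion).
#' @param seed Master seed; all stage seeds derive from it.
#' @param outputDir Run directory (a fresh temporary directory by default).
#' @param borderMarginPx Edge-exclusion margin for target selection.
#' @param writeCurves Write one TSV per force curve.
#' @return A classed list (`afmRunConfig`).
#' @export
runConfig <- function(scene = sceneConfig(densityPreset = "high"),
                      detector = NULL, cantilever = cantileverSpec(),
                      ramp = rampConfig(), nCellsPerType = 50L,
                      curvesPerCell = 10L,
                      assay = c("indentation", "scfs"), seed = 1L,
                      outputDir = NULL, borderMarginPx = 8L,
                      writeCurves = TRUE) {
  assay <- match.arg(assay)
  if (is.null(detector)) {
    detector <- detectorConfig(pixelSizeUm = scene@pixelSizeUm,
                               probeRadiusUm = scene@probeRadiusUm)
  }
  structure(list(scene = scene, detector = detector, cantilever = cantilever,
                 ramp = ramp, nCellsPerType = as.integer(nCellsPerType),
                 curvesPerCell = as.integer(curvesPerCell), assay = assay,
                 seed = as.integer(seed), outputDir = outputDir,
                 borderMarginPx = as.integer(borderMarginPx),
                 writeCurves = isTRUE(writeCurves)),
            class = "afmRunConfig")
}

## Topmost (last-drawn) ground-truth cell containing a pixel point, or NULL.
cellAtPoint <- function(gt, pt) {
  cl <- gt@cells
  hit <- NULL
  for (i in seq_len(nrow(cl))) {
    dx <- pt[1] - cl$cx[i]; dy <- pt[2] - cl$cy[i]
    ct <- cos(cl$theta[i]); st <- sin(cl$theta[i])
    u <- (dx * ct + dy * st) / cl$a[i]
    v <- (-dx * st + dy * ct) / cl$b[i]
    if (u^2 + v^2 <= 1) hit <- i  # later-placed cells are drawn on top
  }
  if (is.null(hit)) NULL else cl[hit, ]
}

#' Run the end-to-end virtual experiment
#'
#' Executes scene sampling, rendering, bright-field detection, target
#' selection, and then per target: move planning, the (virtual) stage
#' move, simulation of `curvesPerCell` force curves from that cell's true
#' mechanical parameters at the probe's post-move position, per-curve
#' analysis, and per-cell aggregation; finally per-type population
#' summaries and the group comparison. Every artifact (scene JSON, images,
#' annotations, move plans, curve TSVs, per-curve and per-cell CSVs,
#' summary JSON, log) is written into the run directory with the seed and
#' a config snapshot. A rerun with identical config reproduces all
#' CSV/JSON outputs byte-identically. A probe that lands off every cell
#' mask is logged as a miss and contributes a baseline-only curve, which
#' the analysis rejects through its no-contact error path.
#'
#' @param config An `afmRunConfig` from [runConfig()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the run directory, scene, annotations,
#'   selected targets, per-cell measurements, population summaries and the
#'   comparison.
#' @export
runExperiment <- function(config, quiet = TRUE) {
  if (!inherits(config, "afmRunConfig")) {
    afmStop("config must come from runConfig()", "cellAFM_format_error")
  }
  dir <- config$outputDir
  if (is.null(dir)) dir <- tempfile("afm_run_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character()
  logIt <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    logLines <<- c(logLines, line)
    if (!quiet) message(line)
  }
  stageFail <- function(stage, targetId, e) {
    logIt(stage, sprintf("ABORT target=%s: %s", targetId, conditionMessage(e)))
    writeLines(logLines, file.path(dir, "run_log.txt"))
    stop(e)
  }
  logIt("init", sprintf("master seed %d, assay %s", config$seed, config$assay))

  ## scene + images
  gt <- tryCatch(sampleScene(config$scene, deriveSeed(config$seed, 1L)),
                 error = function(e) stageFail("scene", NA, e))
  img <- renderImages(gt, config$scene, deriveSeed(config$seed, 2L))
  writeScene(gt, file.path(dir, "scene.json"))
  writeImageSet(img, dir)
  logIt("scene", sprintf("%d cells, coverage %.1f%%", nrow(gt@cells),
                         100 * gt@coverage))

  ## annotation + detection
  truth <- truthAnnotations(gt)
  writeBoxes(truth, file.path(dir, "truth_boxes.json"), "coco_json")
  det <- tryCatch(detectBrightfield(img@brightfield, config$detector, "scene"),
                  error = function(e) stageFail("detect", NA, e))
  writeBoxes(det, file.path(dir, "detected_boxes.json"), "coco_json")
  metrics <- matchDetections(det, truth)
  logIt("detect", sprintf("%d boxes; precision %.3f recall %.3f",
                          nrow(boxes(det)), metrics@precision, metrics@recall))
  probeBox <- boxes(det)[boxes(det)$label == "probe", , drop = FALSE]
  if (nrow(probeBox) != 1L) {
    stageFail("detect", NA, errorCondition("probe not detected",
                                           class = c("cellAFM_targeting_error",
                                                     "error", "condition")))
  }

  ## targets + calibration
  targets <- selectTargets(det, config$nCellsPerType, config$borderMarginPx)
  logIt("select", sprintf("%d targets (%s)", nrow(targets),
                          paste(names(table(targets$label)),
                                table(targets$label), collapse = ", ",
                                sep = ":")))
  cal <- scaleCalibration(config$scene@pixelSizeUm)

  curveDir <- file.path(dir, "curves")
  if (config$writeCurves) dir.create(curveDir, showWarnings = FALSE)
  moveRows <- list(); curveRows <- list(); cellRows <- list()
  measurements <- list()
  curProbeBox <- probeBox
  for (i in seq_len(nrow(targets))) {
    tgt <- targets[i, ]
    plan <- tryCatch(planMove(curProbeBox, tgt, cal, cellId = tgt$cell_id),
                     error = function(e) stageFail("plan", tgt$cell_id, e))
    gt <- tryCatch(applyMove(gt, plan, cal),
                   error = function(e) stageFail("move", tgt$cell_id, e))
    ## probe box travels with the probe
    pw <- (curProbeBox$xmax - curProbeBox$xmin) / 2
    ph <- (curProbeBox$ymax - curProbeBox$ymin) / 2
    curProbeBox <- data.frame(label = "probe",
                              xmin = plan@predictedProbePx[1] - pw,
                              ymin = plan@predictedProbePx[2] - ph,
                              xmax = plan@predictedProbePx[1] + pw,
                              ymax = plan@predictedProbePx[2] + ph,
                              confidence = 1)
    moveRows[[i]] <- data.frame(cell_id = tgt$cell_id, label = tgt$label,
                                dx_um = plan@dxUm, dy_um = plan@dyUm)
    cell <- cellAtPoint(gt, gt@probeCenterPx)
    miss <- is.null(cell)
    if (miss) logIt("move", sprintf("target %d: probe landed off-cell (miss)",
                                    tgt$cell_id))
    vals <- numeric(0); conv <- logical(0)
    for (j in seq_len(config$curvesPerCell)) {
      sj <- deriveSeed(config$seed, 1000L + tgt$cell_id * 100L + j)
      curve <- if (config$assay == "indentation") {
        simulateIndentation(
          E_true = if (miss) 1 else cell$E_true, nu = 0.5,
          cant = config$cantilever, ramp = config$ramp,
          z0_true = if (miss) config$ramp@zEndUm + 10 else 3,
          seed = sj, cellId = tgt$cell_id, label = tgt$label)
      } else {
        if (miss) {
          simulateIndentation(1, 0.5, config$cantilever, config$ramp,
                              z0_true = config$ramp@zEndUm + 10, seed = sj,
                              cellId = tgt$cell_id, label = tgt$label)
        } else {
          simulateSCFS(F_adh_true = cell$F_adh_true, cant = config$cantilever,
                       ramp = config$ramp, z0_true = 3, seed = sj,
                       cellId = tgt$cell_id, label = tgt$label)
        }
      }
      if (config$writeCurves) {
        writeForceCurve(curve, file.path(curveDir,
                                         sprintf("cell_%03d_curve_%02d.tsv",
                                                 tgt$cell_id, j)))
      }
      bc <- baselineCorrect(curve)
      if (config$assay == "indentation") {
        fit <- tryCatch(fitHertz(bc), error = function(e) NULL)
        ok <- !is.null(fit) && fit@converged
        v <- if (ok) fit@EPa else NA_real_
        curveRows[[length(curveRows) + 1]] <- data.frame(
          cell_id = tgt$cell_id, label = tgt$label, curve_index = j,
          value = v, metric = "E_Pa",
          rmse = if (ok) fit@rmseNn else NA_real_, converged = ok)
      } else {
        ad <- tryCatch(extractAdhesion(bc), error = function(e) NULL)
        ok <- !is.null(ad)
        v <- if (ok) ad@FAdhNn else NA_real_
        curveRows[[length(curveRows) + 1]] <- data.frame(
          cell_id = tgt$cell_id, label = tgt$label, curve_index = j,
          value = v, metric = "F_adh_nN",
          rmse = NA_real_, converged = ok)
      }
      vals <- c(vals, v); conv <- c(conv, ok)
    }
    meas <- tryCatch(aggregateCell(vals, conv, cellId = tgt$cell_id,
                                   label = tgt$label),
                     error = function(e) NULL)
    if (is.null(meas)) {
      logIt("analyze", sprintf("target %d: excluded (no converged curves)",
                               tgt$cell_id))
    } else {
      measurements[[length(measurements) + 1]] <- meas
      cellRows[[length(cellRows) + 1]] <- data.frame(
        cell_id = tgt$cell_id, label = tgt$label, n_curves = length(meas@values),
        n_excluded = meas@nExcluded, aggregate = meas@aggregate,
        sd = meas@sdValue)
    }
  }

  movesDf <- do.call(rbind, moveRows)
  curvesDf <- do.call(rbind, curveRows)
  cellsDf <- do.call(rbind, cellRows)
  write.csv(movesDf, file.path(dir, "moves.csv"), row.names = FALSE)
  write.csv(curvesDf, file.path(dir, "results_curves.csv"), row.names = FALSE)
  write.csv(cellsDf, file.path(dir, "results_cells.csv"), row.names = FALSE)

  ## population summaries + comparison
  summaries <- list(); comparison <- NULL
  valsA <- cellsDf$aggregate[cellsDf$label == "typeA"]
  valsB <- cellsDf$aggregate[cellsDf$label == "typeB"]
  if (length(valsA) >= 2 && length(valsB) >= 2) {
    summaries$typeA <- summarizePopulation(valsA, label = "typeA")
    summaries$typeB <- summarizePopulation(valsB, label = "typeB")
    comparison <- compareGroups(summaries$typeA, summaries$typeB, valsA, valsB)
    logIt("stats", sprintf("typeA mean %.3g (n=%d), typeB mean %.3g (n=%d), ordering %s",
                           summaries$typeA@mean, summaries$typeA@n,
                           summaries$typeB@mean, summaries$typeB@n,
                           comparison$ordering))
  } else {
    logIt("stats", "too few measured cells for population summaries")
  }
  summaryObj <- list(
    schema_version = 1L, assay = config$assay, master_seed = config$seed,
    n_cells_per_type = config$nCellsPerType,
    curves_per_cell = config$curvesPerCell,
    coverage_fraction = gt@coverage,
    detection = list(precision = metrics@precision, recall = metrics@recall,
                     iou_threshold = metrics@iouThreshold),
    populations = lapply(summaries, function(s) {
      list(label = s@label, n = s@n, mean = s@mean, sd = s@sd,
           mu = s@mu, sigma = s@sigma)
    }),
    comparison = comparison,
    config = list(scene_density = config$scene@densityPreset,
                  pixel_size_um = config$scene@pixelSizeUm,
                  spring_constant = config$cantilever@springConstant,
                  tip_radius_um = config$cantilever@tipRadiusUm,
                  setpoint_nN = config$ramp@setpointNn))
  jsonlite::write_json(summaryObj, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(logLines, file.path(dir, "run_log.txt"))
  invisible(list(dir = dir, scene = gt, images = img, truth = truth,
                 detected = det, metrics = metrics, targets = targets,
                 moves = movesDf, curves = curvesDf, cells = cellsDf,
                 measurements = measurements, summaries = summaries,
                 comparison = comparison))
}

#' Render a human-readable report of a completed run
#'
#' Writes `report.md` (detection metrics, move-plan table, population
#' tables and the group comparison) plus PNG panels: a detection overlay
#' on the bright-field image, one example force curve, and per-type
#' population histograms with their Gaussian overlays. Rerunning on the
#' same directory reproduces the tables byte-identically.
#'
#' @param runDir A directory produced by [runExperiment()].
#' @return Invisibly, the path to `report.md`.
#' @section Errors: an incomplete run raises a `cellAFM_report_error`
#'   listing the missing artifacts.
#' @export
reportRun <- function(runDir) {
  need <- c("scene.json", "summary.json", "results_cells.csv", "moves.csv",
            "results_curves.csv", "scene_brightfield.tif")
  missing <- need[!file.exists(file.path(runDir, need))]
  if (length(missing)) {
    afmStop(paste("incomplete run; missing artifacts:",
                  paste(missing, collapse = ", ")), "cellAFM_report_error")
  }
  summ <- jsonlite::read_json(file.path(runDir, "summary.json"),
                              simplifyVector = TRUE)
  cellsDf <- read.csv(file.path(runDir, "results_cells.csv"))
  movesDf <- read.csv(file.path(runDir, "moves.csv"))

  md <- c(sprintf("# Virtual AFM run report: %s assay", summ$assay),
          "",
          sprintf("Master seed: %d. Scene coverage: %.1f%%.",
                  summ$master_seed, 100 * summ$coverage_fraction),
          sprintf("Detection precision %.3f, recall %.3f (IoU >= %.2f).",
                  summ$detection$precision, summ$detection$recall,
                  summ$detection$iou_threshold),
          "", "## Move plan (first 10)", "",
          "| cell_id | label | dx_um | dy_um |", "|---|---|---|---|")
  for (i in seq_len(min(10L, nrow(movesDf)))) {
    md <- c(md, sprintf("| %d | %s | %.2f | %.2f |", movesDf$cell_id[i],
                        movesDf$label[i], movesDf$dx_um[i], movesDf$dy_um[i]))
  }
  md <- c(md, "", "## Populations", "",
          "| label | n | mean | SD |", "|---|---|---|---|")
  for (lab in names(summ$populations)) {
    p <- summ$populations[[lab]]
    md <- c(md, sprintf("| %s | %d | %.4g | %.4g |", p$label, p$n, p$mean, p$sd))
  }
  if (!is.null(summ$comparison)) {
    md <- c(md, "", sprintf(
      "Ordering: **%s** (mean difference %.4g, rank-based p = %.3g).",
      summ$comparison$ordering, summ$comparison$meanDifference,
      summ$comparison$pValue))
  }
  ## figures
  bf <- tiff::readTIFF(file.path(runDir, "scene_brightfield.tif"))
  if (length(dim(bf)) == 3) bf <- bf[, , 1]
  det <- readBoxes(file.path(runDir, "detected_boxes.json"), "coco_json")
  grDevices::png(file.path(runDir, "report_detection.png"), 700, 700)
  op <- graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(c(0, ncol(bf)), c(nrow(bf), 0), type = "n", axes = FALSE,
                 xlab = "", ylab = "", main = "Detections on bright-field",
                 asp = 1)
  graphics::rasterImage(bf, 0, nrow(bf), ncol(bf), 0)
  cols <- c(typeA = "red", typeB = "green3", probe = "white")
  bxs <- boxes(det)
  for (i in seq_len(nrow(bxs))) {
    graphics::rect(bxs$xmin[i], bxs$ymax[i], bxs$xmax[i], bxs$ymin[i],
                   border = cols[[bxs$label[i]]], lwd = 1.5)
  }
  graphics::par(op); grDevices::dev.off()

  curveFiles <- list.files(file.path(runDir, "curves"), full.names = TRUE)
  if (length(curveFiles)) {
    cur <- readForceCurve(curveFiles[1])
    grDevices::png(file.path(runDir, "report_curve.png"), 700, 500)
    Fap <- segmentForce(cur, "approach"); Fre <- segmentForce(cur, "retract")
    graphics::plot(cur@approach$z_um, Fap, type = "l", col = "blue",
                   xlab = "piezo z (um)", ylab = "force (nN)",
                   main = "Example force curve",
                   ylim = range(c(Fap, Fre)))
    graphics::lines(cur@retract$z_um, Fre, col = "red")
    graphics::legend("topleft", c("approach", "retract"), lwd = 1,
                     col = c("blue", "red"))
    grDevices::dev.off()
  }
  for (lab in unique(cellsDf$label)) {
    v <- cellsDf$aggregate[cellsDf$label == lab]
    if (length(v) >= 2) {
      s <- summarizePopulation(v, label = lab)
      grDevices::png(file.path(runDir, sprintf("report_hist_%s.png", lab)),
                     600, 450)
      plotPopulation(s, xlab = if (summ$assay == "indentation") {
        "Young's modulus (Pa)"
      } else "adhesion force (nN)")
      grDevices::dev.off()
    }
  }
  writeLines(md, file.path(runDir, "report.md"))
  invisible(file.path(runDir, "report.md"))
}
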