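test_that("box IoU follows the half-open convention, against a pixel oracle", {
  expect_identical(boxIoU(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_identical(boxIoU(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0)
  expect_equal(boxIoU(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)

  ## pixel-counting oracle on random integer boxes
  set.seed(7)
  for (rep in 1:20) {
    a <- sort(sample(0:20, 2)); b <- sort(sample(0:20, 2))
    c2 <- sort(sample(0:20, 2)); d2 <- sort(sample(0:20, 2))
    if (a[1] == a[2] || b[1] == b[2] || c2[1] == c2[2] || d2[1] == d2[2]) next
    boxA <- c(a[1], b[1], a[2], b[2]); boxB <- c(c2[1], d2[1], c2[2], d2[2])
    grid <- expand.grid(x = 0:19, y = 0:19)
    inA <- grid$x >= boxA[1] & grid$x < boxA[3] & grid$y >= boxA[2] & grid$y < boxA[4]
    inB <- grid$x >= boxB[1] & grid$x < boxB[3] & grid$y >= boxB[2] & grid$y < boxB[4]
    oracle <- if (sum(inA | inB) == 0) 0 else sum(inA & inB) / sum(inA | inB)
    expect_equal(boxIoU(boxA, boxB), oracle)
  }
})

test_that("greedy matching yields the hand-enumerated metrics", {
  truth <- annotationFromDf(rbind(
    boxDf("typeA", 0, 0, 10, 10), boxDf("typeA", 20, 20, 30, 30),
    boxDf("typeB", 40, 40, 50, 50)))
  ## identical predictions: perfect
  m <- matchDetections(truth, truth)
  expect_identical(m@precision, 1)
  expect_identical(m@recall, 1)

  ## empty predictions: precision 1 by the 0/0 convention, recall 0
  empty <- annotationFromDf(boxDf(character(0), numeric(0), numeric(0),
                                  numeric(0), numeric(0), numeric(0)))
  m0 <- matchDetections(empty, truth)
  expect_identical(m0@precision, 1)
  expect_identical(m0@recall, 0)

  ## two correct + one mislabeled -> precision 2/3, recall 2/3
  pred <- annotationFromDf(rbind(
    boxDf("typeA", 0, 0, 10, 10, 0.9), boxDf("typeA", 20, 20, 30, 30, 0.8),
    boxDf("typeA", 40, 40, 50, 50, 0.7)))  # truth there is typeB
  m1 <- matchDetections(pred, truth)
  expect_equal(m1@precision, 2 / 3)
  expect_equal(m1@recall, 2 / 3)

  ## mismatched image references refuse to compare
  other <- annotationFromDf(boxDf("typeA", 0, 0, 10, 10), id = "other")
  expect_error(matchDetections(other, truth), class = "cellAFM_format_error")
})

test_that("spurious predictions cannot raise precision; correct ones keep recall", {
  truth <- annotationFromDf(rbind(
    boxDf("typeA", 0, 0, 10, 10), boxDf("typeB", 30, 30, 42, 42)))
  pred <- annotationFromDf(boxDf("typeA", 1, 1, 11, 11, 0.9))
  base <- matchDetections(pred, truth)
  withSpurious <- annotationFromDf(rbind(
    boxDf("typeA", 1, 1, 11, 11, 0.9), boxDf("typeA", 60, 60, 70, 70, 0.8)))
  m2 <- matchDetections(withSpurious, truth)
  expect_lte(m2@precision, base@precision)
  withCorrect <- annotationFromDf(rbind(
    boxDf("typeA", 1, 1, 11, 11, 0.9), boxDf("typeB", 30, 30, 42, 42, 0.8)))
  m3 <- matchDetections(withCorrect, truth)
  expect_gte(m3@recall, base@recall)
  expect_true(all(c(m2@precision, m2@recall, m3@precision, m3@recall) >= 0))
  expect_true(all(c(m2@precision, m2@recall, m3@precision, m3@recall) <= 1))
})

test_that("fluorescence auto-annotation labels blank and single-cell scenes", {
  blank <- methods::new("ImageSet", brightfield = matrix(0.5, 64, 64),
                        fluorRed = matrix(0.02, 64, 64),
                        fluorGreen = matrix(0.02, 64, 64))
  expect_identical(nrow(boxes(autoAnnotateFluorescence(blank))), 0L)

  cfg <- sceneConfig(width = 128L, height = 128L, densityPreset = "low",
                     nCellsPerType = 1L)
  gtA <- manualScene(list(c(60, 60)), 14, "typeA", 128, 128, probe = c(110, 110))
  img <- renderImages(gtA, cfg, seed = 5)
  ann <- autoAnnotateFluorescence(img)
  b <- boxes(ann)
  expect_identical(nrow(b), 1L)
  expect_identical(b$label, "typeA")
  expect_true(b$xmin <= 60 && b$xmax >= 60 && b$ymin <= 60 && b$ymax >= 60)
})

test_that("auto-annotation never contradicts the dominant fluorescence channel", {
  sc <- defaultHighScene(1L)
  ann <- autoAnnotateFluorescence(sc$img)
  b <- boxes(ann)
  red <- sc$img@fluorRed > 0.3; green <- sc$img@fluorGreen > 0.3
  for (i in seq_len(nrow(b))) {
    xs <- max(1, floor(b$xmin[i]) + 1):min(ncol(red), ceiling(b$xmax[i]))
    ys <- max(1, floor(b$ymin[i]) + 1):min(nrow(red), ceiling(b$ymax[i]))
    ovRed <- sum(red[ys, xs]); ovGreen <- sum(green[ys, xs])
    if (b$label[i] == "typeA") expect_gte(ovRed, ovGreen)
  }
})

test_that("annotation files round-trip in both dialects", {
  ann <- annotationFromDf(rbind(
    boxDf("typeA", 3.25, 4.5, 17.75, 22.125, 0.75),
    boxDf("typeB", 40, 41, 59, 60, 0.5),
    boxDf("probe", 80, 80, 90, 90, 1)))
  for (fmt in c("yolo_txt", "coco_json")) {
    p <- tempfile()
    writeBoxes(ann, p, fmt)
    back <- readBoxes(p, fmt, width = 100, height = 100)
    expect_identical(back@boxes$label, ann@boxes$label)
    for (col in c("xmin", "ymin", "xmax", "ymax", "confidence")) {
      expect_equal(back@boxes[[col]], ann@boxes[[col]], tolerance = 1e-6)
    }
  }
})

test_that("YOLO arithmetic, empty files, and malformed lines behave as specified", {
  p <- tempfile()
  writeLines("0 0.5 0.5 0.2 0.2", p)
  ann <- readBoxes(p, "yolo_txt", width = 100, height = 100)
  expect_equal(as.numeric(ann@boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(40, 40, 60, 60))

  writeLines(character(0), p)
  expect_identical(nrow(boxes(readBoxes(p, "yolo_txt", width = 10, height = 10))), 0L)

  writeLines(c("0 0.5 0.5 0.2 0.2", "junk line here"), p)
  err <- tryCatch(readBoxes(p, "yolo_txt", width = 10, height = 10),
                  error = function(e) e)
  expect_s3_class(err, "cellAFM_parse_error")
  expect_match(conditionMessage(err), "line 2")
})

test_that("the bright-field detector is deterministic and handles edge inputs", {
  expect_error(detectBrightfield(array(0, c(4, 4, 2))),
               class = "cellAFM_format_error")
  blank <- matrix(0.55, 128, 128)
  expect_identical(nrow(boxes(detectBrightfield(blank))), 0L)

  sc <- defaultHighScene(1L)
  d1 <- detectBrightfield(sc$img@brightfield)
  d2 <- detectBrightfield(sc$img@brightfield)
  expect_identical(boxes(d1), boxes(d2))
})

test_that("one well-separated cell of each type is detected with correct labels", {
  cfg <- sceneConfig(width = 192L, height = 192L, densityPreset = "low",
                     nCellsPerType = 1L)
  gt <- manualScene(list(c(50, 50), c(135, 135)), c(19, 25),
                    c("typeA", "typeB"), 192, 192, probe = c(170, 40),
                    probeRadiusPx = 7 / 0.65)
  gt@width <- 192L; gt@height <- 192L
  img <- renderImages(gt, cfg, seed = 2)
  det <- detectBrightfield(img@brightfield)
  truth <- truthAnnotations(gt)
  tb <- boxes(truth)
  for (lab in c("typeA", "typeB")) {
    tBox <- tb[tb$label == lab, ]
    dBox <- boxes(det)[boxes(det)$label == lab, ]
    expect_gte(nrow(dBox), 1L)
    best <- max(vapply(seq_len(nrow(dBox)),
                       function(i) boxIoU(dBox[i, ], tBox[1, ]), numeric(1)))
    expect_gte(best, 0.5)
  }
})
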