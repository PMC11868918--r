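test_that("coverage is a pixel-exact union, matching a brute-force oracle", {
  ## two disjoint circles r = 5 px in a 100x100 image
  gt <- manualScene(list(c(25, 25), c(70, 70)), c(5, 5), c("typeA", "typeB"))
  expect_equal(coverageFraction(gt), coverageOracle(gt))
  expect_equal(coverageFraction(gt), 2 * pi * 25 / 1e4, tolerance = 0.05)

  ## two fully overlapping identical cells count once (union, not sum)
  gt2 <- manualScene(list(c(40, 40), c(40, 40)), c(8, 8), c("typeA", "typeA"))
  gt1 <- manualScene(list(c(40, 40)), 8, "typeA")
  expect_identical(coverageFraction(gt2), coverageFraction(gt1))

  ## no cells -> 0
  expect_identical(coverageFraction(manualScene(list(), numeric(0), character(0))), 0)
})

test_that("a single r = 10 px cell in a 100 px image covers ~ pi r^2 / area", {
  gt <- manualScene(list(c(50, 50)), 10, "typeA")
  expect_equal(coverageFraction(gt), pi * 100 / 1e4, tolerance = 0.03)
})

test_that("adding a cell never decreases coverage", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:4, 1)
    ctrs <- lapply(seq_len(n), function(i) runif(2, 10, 90))
    gt <- manualScene(ctrs, runif(n, 4, 12), sample(c("typeA", "typeB"), n, TRUE))
    before <- coverageFraction(gt)
    extra <- gt@cells[1, ]
    extra$cell_id <- n + 1L
    extra$cx <- runif(1, 10, 90); extra$cy <- runif(1, 10, 90)
    gt@cells <- rbind(gt@cells, extra)
    expect_gte(coverageFraction(gt), before)
  }
})

test_that("scene sampling is deterministic and respects both presets", {
  cfg <- sceneConfig(densityPreset = "low")
  a <- sampleScene(cfg, seed = 11)
  b <- sampleScene(cfg, seed = 11)
  expect_identical(cells(a), cells(b))
  expect_identical(probeCenter(a), probeCenter(b))
  expect_lte(coverageFraction(a), 0.10)

  sc <- defaultHighScene(1L)
  expect_gte(coverageFraction(sc$gt), 0.60)
  ## different cell types actually touch (center distance below radius sum)
  cl <- cells(sc$gt)
  touching <- FALSE
  for (i in seq_len(nrow(cl) - 1)) {
    j <- which(cl$cell_type[-seq_len(i)] != cl$cell_type[i]) + i
    if (!length(j)) next
    d <- sqrt((cl$cx[j] - cl$cx[i])^2 + (cl$cy[j] - cl$cy[i])^2)
    rsum <- sqrt(cl$a[j] * cl$b[j]) + sqrt(cl$a[i] * cl$b[i])
    if (any(d < rsum)) { touching <- TRUE; break }
  }
  expect_true(touching)
})

test_that("unreachable densities raise the density error", {
  cfgEmpty <- sceneConfig(densityPreset = "high", nCellsPerType = 0L)
  expect_error(sampleScene(cfgEmpty, seed = 1), class = "cellAFM_density_error")
  ## far too few cells for 60% coverage
  cfgFew <- sceneConfig(densityPreset = "high", nCellsPerType = 2L)
  expect_error(sampleScene(cfgFew, seed = 1), class = "cellAFM_density_error")
  ## too many cells for the low preset ceiling
  cfgMany <- sceneConfig(densityPreset = "low", nCellsPerType = 40L)
  expect_error(sampleScene(cfgMany, seed = 1), class = "cellAFM_density_error")
})

test_that("rendering is deterministic and fluorescence tracks cell types", {
  cfg <- sceneConfig(width = 224L, height = 224L, densityPreset = "low",
                     nCellsPerType = 1L)
  gt <- sampleScene(cfg, seed = 3)
  img1 <- renderImages(gt, cfg, seed = 3)
  img2 <- renderImages(gt, cfg, seed = 3)
  expect_identical(img1@brightfield, img2@brightfield)
  expect_identical(img1@fluorRed, img2@fluorRed)

  ## empty scene: only background + noise, both channels sub-threshold
  gt0 <- manualScene(list(), numeric(0), character(0), 224, 224,
                     probe = c(180, 180))
  img0 <- renderImages(gt0, cfg, seed = 3)
  expect_lt(max(img0@fluorRed), 0.2)
  expect_lt(max(img0@fluorGreen), 0.2)

  ## one typeA cell: one red component, no green
  gtA <- manualScene(list(c(60, 60)), 12, "typeA", 224, 224, probe = c(190, 190))
  imgA <- renderImages(gtA, cfg, seed = 3)
  redMask <- imgA@fluorRed > 0.3
  comp <- EBImage::bwlabel(EBImage::Image(t(redMask) * 1))
  expect_equal(max(EBImage::imageData(comp)), 1)
  expect_lt(max(imgA@fluorGreen), 0.2)
})

test_that("scene JSON and 16-bit image round-trips preserve the data", {
  cfg <- sceneConfig(width = 256L, height = 256L, densityPreset = "low",
                     nCellsPerType = 1L)
  gt <- sampleScene(cfg, seed = 9)
  tmp <- tempfile(fileext = ".json")
  writeScene(gt, tmp)
  gt2 <- readScene(tmp)
  expect_equal(cells(gt2)$cx, cells(gt)$cx, tolerance = 1e-12)
  expect_equal(probeCenter(gt2), probeCenter(gt), tolerance = 1e-12)
  expect_identical(gt2@width, gt@width)

  img <- renderImages(gt, cfg, seed = 9)
  d <- tempfile()
  writeImageSet(img, d)
  img2 <- readImageSet(d)
  ## 16-bit quantization: max error half a gray level
  expect_lt(max(abs(img2@brightfield - img@brightfield)), 1 / 65535)
  expect_error(readImageSet(tempfile()), class = "cellAFM_format_error")
})
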