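test_that("baseline correction removes exactly the injected drift line", {
  cant0 <- quietCantilever()
  clean <- simulateIndentation(1000, 0.5, cant0, rampConfig(), 3, seed = 1)
  corrected <- baselineCorrect(clean)
  expect_lt(max(abs(approachSegment(corrected)$d_nm -
                      approachSegment(clean)$d_nm)), 1e-9)

  drift <- 25
  drifty <- simulateIndentation(1000, 0.5,
                                cantileverSpec(noiseSdNm = 0,
                                               driftNmPerUm = drift),
                                rampConfig(), 3, seed = 1)
  fixed <- baselineCorrect(drifty)
  app <- approachSegment(fixed)
  base <- app$z_um < 1.5
  slope <- coef(lm(d_nm ~ z_um, data = app[base, ]))[2]
  expect_lt(abs(slope), 1e-6 * drift)

  ## probe never contacts: whole curve collapses to ~0
  flat <- simulateIndentation(1000, 0.5,
                              cantileverSpec(noiseSdNm = 0, driftNmPerUm = 3),
                              rampConfig(), z0_true = 100, seed = 1)
  flatFixed <- baselineCorrect(flat)
  expect_lt(max(abs(approachSegment(flatFixed)$d_nm)), 1e-9)

  short <- flat
  short@approach <- short@approach[1:20, ]
  expect_error(baselineCorrect(short), class = "cellAFM_baseline_error")
})

test_that("contact-point search hits the true contact and flags pure noise", {
  cant0 <- quietCantilever()
  ramp <- rampConfig()
  dz <- (ramp@zEndUm - ramp@zStartUm) / (ramp@samples - 1)
  for (z0 in c(2.2, 3.0, 3.7)) {
    cur <- baselineCorrect(simulateIndentation(2000, 0.5, cant0, ramp,
                                               z0_true = z0, seed = 1))
    cp <- findContactPoint(cur)
    expect_lt(abs(cp$z0Um - z0), dz)
  }

  noise <- simulateIndentation(1000, 0.5, cantileverSpec(noiseSdNm = 2),
                               rampConfig(), z0_true = 1e3, seed = 5)
  expect_error(findContactPoint(baselineCorrect(noise)),
               class = "cellAFM_no_contact")
})

test_that("the Hertz fit recovers the modulus and is linear in E", {
  cant0 <- quietCantilever()
  cur <- baselineCorrect(simulateIndentation(1000, 0.5, cant0, rampConfig(),
                                             3, seed = 1))
  fit <- fitHertz(cur)
  expect_true(fit@converged)
  expect_lt(abs(fit@EPa - 1000) / 1000, 1e-3)

  cur2 <- baselineCorrect(simulateIndentation(2000, 0.5, cant0, rampConfig(),
                                              3, seed = 1))
  fit2 <- fitHertz(cur2)
  expect_lt(abs(fit2@EPa - 2000) / 2000, 1e-3)
})

test_that("fitted moduli stay within 5% median error at 2% force noise", {
  cant <- cantileverSpec(noiseSdNm = noiseNmForForceFraction(0.02),
                         driftNmPerUm = 0.5)
  errs <- vapply(1:40, function(s) {
    set.seed(s + 5000L)
    E <- exp(runif(1, log(500), log(50000)))
    cur <- simulateIndentation(E, 0.5, cant, rampConfig(), 3, seed = s)
    fit <- fitHertz(baselineCorrect(cur))
    if (!fit@converged) return(NA_real_)
    abs(fit@EPa - E) / E
  }, numeric(1))
  expect_lte(median(errs, na.rm = TRUE), 0.05)
})

test_that("fitted modulus is independent of the cantilever used to measure it", {
  ## a stiffer cantilever records smaller deflections for the same sample;
  ## the recovered modulus must not depend on that instrument choice
  fits <- vapply(c(0.02, 0.05, 0.2), function(k) {
    cant <- cantileverSpec(springConstant = k, noiseSdNm = 0, driftNmPerUm = 0)
    fitHertz(baselineCorrect(
      simulateIndentation(3000, 0.5, cant, rampConfig(), 3, seed = 2)))@EPa
  }, numeric(1))
  expect_true(all(abs(fits - 3000) / 3000 < 1e-3))
  expect_lt(diff(range(fits)) / 3000, 1e-3)
})

test_that("adhesion extraction matches construction and a trapezoid oracle", {
  cant0 <- quietCantilever()
  indent <- baselineCorrect(simulateIndentation(1000, 0.5, cant0, rampConfig(),
                                                3, seed = 1))
  expect_identical(extractAdhesion(indent)@FAdhNn, 0)

  scfs <- baselineCorrect(simulateSCFS(2, cant = cant0, ramp = rampConfig(),
                                       seed = 1))
  ad <- extractAdhesion(scfs)
  expect_equal(ad@FAdhNn, 2, tolerance = 1e-12)
  expect_identical(ad@nRuptureSteps, 3L)

  ## hand-built triangular well: depth 1 nN, base 1 um -> work 0.5 fJ
  z <- seq(5, 0, length.out = 501)
  F <- numeric(501)
  well <- z <= 3 & z >= 2
  F[well] <- -(1 - 2 * abs(z[well] - 2.5))
  tri <- methods::new("ForceCurve", meta = list(kind = "scfs"),
                      cantilever = cantileverSpec(springConstant = 1),
                      approach = data.frame(z_um = rev(z), d_nm = 0),
                      retract = data.frame(z_um = z, d_nm = F))
  adTri <- extractAdhesion(tri)
  expect_equal(adTri@FAdhNn, 1, tolerance = 1e-9)
  expect_equal(adTri@workFj, 0.5, tolerance = 1e-3)

  ## deepening the well strictly increases the recovered force
  rec <- vapply(c(0.5, 1, 2, 4), function(Fa) {
    extractAdhesion(baselineCorrect(
      simulateSCFS(Fa, cant = cant0, ramp = rampConfig(), seed = 1)))@FAdhNn
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("per-cell aggregation excludes non-converged curves", {
  m <- aggregateCell(rep(5, 10))
  expect_identical(m@aggregate, 5)
  expect_identical(m@sdValue, 0)

  m2 <- aggregateCell(c(1, 2, 3))
  expect_identical(m2@aggregate, 2)

  m3 <- aggregateCell(c(1, 2, 100), converged = c(TRUE, TRUE, FALSE))
  expect_identical(m3@aggregate, 1.5)
  expect_identical(m3@nExcluded, 1L)

  expect_error(aggregateCell(c(1, 2), converged = c(FALSE, FALSE)),
               class = "cellAFM_aggregation_error")
})

test_that("averaging 10 noisy curves beats the worst single curve", {
  cant <- cantileverSpec(noiseSdNm = noiseNmForForceFraction(0.02),
                         driftNmPerUm = 0)
  wins <- vapply(1:25, function(trial) {
    Es <- vapply(1:10, function(j) {
      cur <- simulateIndentation(2000, 0.5, cant, rampConfig(), 3,
                                 seed = trial * 100 + j)
      fitHertz(baselineCorrect(cur))@EPa
    }, numeric(1))
    abs(mean(Es) - 2000) <= max(abs(Es - 2000))
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
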