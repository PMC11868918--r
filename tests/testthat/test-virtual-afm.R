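# Independent bisection oracle for the cantilever-sample balance
# k d = C ((z - z0) 1000 - d)^{3/2}; shares no code with the package solver.
bisectBalance <- function(t_nm, k, C, iter = 200L) {
  lo <- 0; hi <- t_nm
  for (i in seq_len(iter)) {
    mid <- 0.5 * (lo + hi)
    if (k * mid - C * (t_nm - mid)^1.5 > 0) hi <- mid else lo <- mid
  }
  0.5 * (lo + hi)
}

hertzC <- function(E, nu, R) {
  (4 / 3) * (E / (1 - nu^2)) * sqrt(R * 1e-6) * (1e-9)^1.5 * 1e9
}

test_that("noise-free indentation satisfies the implicit balance everywhere", {
  cant <- quietCantilever()
  curve <- simulateIndentation(1000, 0.5, cant, rampConfig(), z0_true = 3,
                               seed = 1)
  app <- approachSegment(curve)
  C <- hertzC(1000, 0.5, 5); k <- 0.05
  post <- app$z_um > 3
  resid <- k * app$d_nm[post] -
    C * pmax((app$z_um[post] - 3) * 1000 - app$d_nm[post], 0)^1.5
  expect_lt(max(abs(resid)) / max(k * app$d_nm), 1e-9)

  ## force is exactly zero at and before contact
  expect_identical(max(abs(app$d_nm[app$z_um <= 3])), 0)
})

test_that("the Newton solver agrees with an independent bisection oracle", {
  C <- hertzC(1000, 0.5, 5); k <- 0.05
  curve <- simulateIndentation(1000, 0.5, quietCantilever(), rampConfig(),
                               z0_true = 3, seed = 1)
  app <- approachSegment(curve)
  iDeep <- nrow(app)
  t_nm <- (app$z_um[iDeep] - 3) * 1000
  dOracle <- bisectBalance(t_nm, k, C)
  expect_lt(abs(app$d_nm[iDeep] - dOracle) / dOracle, 1e-8)
})

test_that("post-contact force grows with z and with the modulus", {
  cant <- quietCantilever()
  ramp <- rampConfig()
  c1 <- simulateIndentation(1000, 0.5, cant, ramp, z0_true = 3, seed = 1)
  F1 <- 0.05 * approachSegment(c1)$d_nm
  post <- which(approachSegment(c1)$z_um > 3.02)
  expect_true(all(diff(F1[post]) > 0))

  c2 <- simulateIndentation(2000, 0.5, cant, ramp, z0_true = 3, seed = 1)
  app1 <- approachSegment(c1); app2 <- approachSegment(c2)
  n <- min(nrow(app1), nrow(app2))
  ## at any common z past contact the stiffer sample pushes back harder
  zs <- app1$z_um[post[post <= n]]
  expect_true(all(app2$d_nm[match(zs, app2$z_um)] > app1$d_nm[match(zs, app1$z_um)]))
})

test_that("the noise-free Hertz force scales as delta^{3/2}", {
  curve <- simulateIndentation(5000, 0.5, quietCantilever(), rampConfig(),
                               z0_true = 2, seed = 1)
  app <- approachSegment(curve)
  delta <- (app$z_um - 2) * 1000 - app$d_nm
  F <- 0.05 * app$d_nm
  use <- delta > 5 & F > 1e-4
  slope <- coef(lm(log(F[use]) ~ log(delta[use])))[2]
  expect_equal(unname(slope), 1.5, tolerance = 0.01)
})

test_that("identical arguments and seed reproduce bit-identical curves", {
  cant <- cantileverSpec(noiseSdNm = 1, driftNmPerUm = 0.5)
  a <- simulateIndentation(1500, 0.5, cant, rampConfig(), 3, seed = 42)
  b <- simulateIndentation(1500, 0.5, cant, rampConfig(), 3, seed = 42)
  expect_identical(approachSegment(a), approachSegment(b))
  expect_identical(retractSegment(a), retractSegment(b))
  s1 <- simulateSCFS(2, cant = cant, ramp = rampConfig(), seed = 7)
  s2 <- simulateSCFS(2, cant = cant, ramp = rampConfig(), seed = 7)
  expect_identical(retractSegment(s1), retractSegment(s2))
})

test_that("SCFS retract reaches exactly -F_adh and detaches in n steps", {
  cant <- quietCantilever()
  s0 <- simulateSCFS(0, cant = cant, ramp = rampConfig(), seed = 1)
  expect_gte(min(0.05 * retractSegment(s0)$d_nm), 0)

  s2 <- simulateSCFS(2, cant = cant, ramp = rampConfig(), seed = 1)
  expect_equal(min(0.05 * retractSegment(s2)$d_nm), -2, tolerance = 1e-12)

  expect_error(simulateSCFS(2, detachSeparationUm = 50, cant = cant,
                            ramp = rampConfig(), z0_true = 3),
               class = "cellAFM_simulation_error")
})

test_that("adhesion recovery is unbiased under measurement noise", {
  cant <- cantileverSpec(noiseSdNm = 0.05 / 0.05, driftNmPerUm = 0)  # 0.05 nN
  rec <- vapply(1:30, function(s) {
    cur <- simulateSCFS(2, cant = cant, ramp = rampConfig(), seed = s)
    extractAdhesion(baselineCorrect(cur))@FAdhNn
  }, numeric(1))
  se <- sd(rec) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - 2), 3 * se + 1e-6)
})

test_that("the force-curve TSV dialect round-trips", {
  cant <- cantileverSpec(noiseSdNm = 1, driftNmPerUm = 0.5)
  cur <- simulateIndentation(1234.5, 0.5, cant, rampConfig(), 3, seed = 9,
                             cellId = 7L, label = "typeB")
  p <- tempfile(fileext = ".tsv")
  writeForceCurve(cur, p)
  back <- readForceCurve(p)
  expect_equal(approachSegment(back)$z_um, approachSegment(cur)$z_um,
               tolerance = 1e-12)
  expect_equal(approachSegment(back)$d_nm, approachSegment(cur)$d_nm,
               tolerance = 1e-12)
  expect_identical(back@cantilever@springConstant, 0.05)
  expect_identical(curveMeta(back)$kind, "indentation")
  expect_identical(curveMeta(back)$cell_id, 7L)
  expect_equal(curveMeta(back)$E_true, 1234.5, tolerance = 1e-12)

  bad <- tempfile()
  writeLines(c("# broken header no equals sign", "segment\tz_um\td_nm\tF_nN"), bad)
  expect_error(readForceCurve(bad), class = "cellAFM_parse_error")
})
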