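#' Cantilever and ramp constructors
#'
#' Defaults describe a soft cantilever carrying a glued microsphere, the
#' usual choice for gentle cell indentation: spring constant 0.05 N/m, tip
#' radius 5 um, 1 nm deflection noise and a mild linear baseline drift.
#'
#' @param springConstant Cantilever spring constant, N/m.
#' @param tipRadiusUm Microsphere radius, um.
#' @param noiseSdNm Deflection noise SD, nm.
#' @param driftNmPerUm Baseline drift, nm per um of piezo travel.
#' @return A [CantileverSpec-class].
#' @export
cantileverSpec <- function(springConstant = 0.05, tipRadiusUm = 5,
                           noiseSdNm = 1, driftNmPerUm = 0.5) {
  new("CantileverSpec", springConstant = springConstant,
      tipRadiusUm = tipRadiusUm, noiseSdNm = noiseSdNm,
      driftNmPerUm = driftNmPerUm)
}

#' @param zStartUm,zEndUm Piezo travel range, um.
#' @param samples Samples per segment.
#' @param setpointNn Approach force setpoint, nN (approach stops there).
#' @return A [RampConfig-class].
#' @rdname cantileverSpec
#' @export
rampConfig <- function(zStartUm = 0, zEndUm = 6, samples = 600L,
                       setpointNn = 5) {
  new("RampConfig", zStartUm = zStartUm, zEndUm = zEndUm,
      samples = as.integer(samples), setpointNn = setpointNn)
}

## Solve the implicit cantilever-sample balance k*d = Hertz((z - z0)*1000 - d)
## for deflection d (nm) at one piezo position. Safeguarded Newton iteration
## bracketed on [0, t]; monotone g so the root is unique.
solveBalance <- function(t_nm, k, C, d0 = NULL, tol = 1e-10, maxIter = 100L) {
  if (t_nm <= 0) return(0)
  lo <- 0; hi <- t_nm
  d <- if (!is.null(d0) && d0 > lo && d0 < hi) d0 else 0.5 * t_nm
  for (it in seq_len(maxIter)) {
    delta <- t_nm - d
    g <- k * d - C * delta^1.5
    if (g > 0) hi <- d else lo <- d
    gp <- k + 1.5 * C * sqrt(max(delta, 0))
    step <- g / gp
    dNew <- d - step
    if (dNew <= lo || dNew >= hi) dNew <- 0.5 * (lo + hi)  # bisection safeguard
    if (abs(dNew - d) <= tol * max(1, abs(d))) {
      return(dNew)
    }
    d <- dNew
  }
  afmStop(sprintf("balance solve did not converge (t = %.3g nm)", t_nm),
          "cellAFM_simulation_error")
}

## Hertz prefactor C such that F_nN = C * delta_nm^1.5.
hertzPrefactor <- function(E_pa, nu, R_um) {
  (4 / 3) * (E_pa / (1 - nu^2)) * sqrt(R_um * 1e-6) * (1e-9)^1.5 * 1e9
}

#' Simulate an indentation force curve
#'
#' Physics: below contact the deflection is a drift line plus Gaussian
#' noise; past contact the deflection solves the implicit cantilever-sample
#' balance `k d = (4/3) E/(1-nu^2) sqrt(R) delta^{3/2}` with indentation
#' `delta = (z - z0) - d` (piezo travel past contact minus deflection; z in
#' um, d in nm, force in nN for k in N/m), solved per sample by safeguarded
#' Newton iteration to relative tolerance 1e-10. The approach is truncated
#' once the setpoint force is reached; the retract retraces the elastic
#' curve (no adhesion in indentation mode). Noise and drift are applied
#' after the physics.
#'
#' @param E_true True Young's modulus, Pa.
#' @param nu Poisson ratio (0.5 = incompressible cell).
#' @param cant A [CantileverSpec-class].
#' @param ramp A [RampConfig-class].
#' @param z0_true True contact position, um.
#' @param seed Integer seed; identical arguments give bit-identical curves.
#' @param cellId,label Metadata passed through to the curve.
#' @return A [ForceCurve-class] of kind `"indentation"`.
#' @export
simulateIndentation <- function(E_true, nu = 0.5, cant = cantileverSpec(),
                                ramp = rampConfig(), z0_true = 3, seed = 1L,
                                cellId = NA_integer_, label = NA_character_) {
  stopifnotScalarNum(E_true, "E_true", positive = TRUE)
  if (nu < 0 || nu > 0.5) afmStop("nu must lie in [0, 0.5]", "cellAFM_format_error")
  validObject(cant); validObject(ramp)
  C <- hertzPrefactor(E_true, nu, cant@tipRadiusUm)
  k <- cant@springConstant
  z <- seq(ramp@zStartUm, ramp@zEndUm, length.out = ramp@samples)
  d <- numeric(length(z))
  prev <- NULL
  for (i in seq_along(z)) {
    t_nm <- (z[i] - z0_true) * 1000
    d[i] <- if (t_nm <= 0) 0 else solveBalance(t_nm, k, C, d0 = prev)
    prev <- if (d[i] > 0) d[i] else NULL
  }
  F <- k * d
  keep <- which(F <= ramp@setpointNn)
  ## include the first sample at/above the setpoint so the curve reaches it
  if (length(keep) < length(z)) keep <- c(keep, max(keep) + 1L)
  z <- z[keep]; d <- d[keep]
  withSeed(seed, {
    drift <- cant@driftNmPerUm * (z - ramp@zStartUm)
    dApp <- d + drift + rnorm(length(z), 0, cant@noiseSdNm)
    dRet <- d + drift + rnorm(length(z), 0, cant@noiseSdNm)
    meta <- list(cell_id = cellId, label = label, kind = "indentation",
                 seed = as.integer(seed), E_true = E_true, nu = nu,
                 z0_true = z0_true)
    new("ForceCurve", meta = meta, cantilever = cant,
        approach = data.frame(z_um = z, d_nm = dApp),
        retract = data.frame(z_um = rev(z), d_nm = rev(dRet)))
  })
}

#' Simulate a single-cell force spectroscopy (SCFS) curve
#'
#' The approach is a soft elastic contact. The retract shows an adhesive
#' well: past the contact point the force ramps down to exactly
#' `-F_adh_true` (noise-free) at a quarter of the detachment separation,
#' then returns to baseline through `nRuptureSteps` successive force drops,
#' reaching zero at `detachSeparationUm`. The well is phenomenological
#' (piecewise elastic + rupture staircase); the peak adhesion force is the
#' quantity reproduced exactly by construction.
#'
#' @param F_adh_true True peak adhesion force, nN (>= 0).
#' @param detachSeparationUm Separation at which the cell fully detaches, um.
#' @param nRuptureSteps Number of rupture steps (>= 1).
#' @param E_contact Young's modulus governing the elastic contact, Pa.
#' @param nu Poisson ratio of the contact.
#' @param cant A [CantileverSpec-class].
#' @param ramp A [RampConfig-class].
#' @param z0_true Contact position, um.
#' @param seed Integer seed.
#' @param cellId,label Metadata passed through.
#' @return A [ForceCurve-class] of kind `"scfs"`.
#' @export
simulateSCFS <- function(F_adh_true, detachSeparationUm = 1.5,
                         nRuptureSteps = 3L, E_contact = 400, nu = 0.5,
                         cant = cantileverSpec(), ramp = rampConfig(),
                         z0_true = 3, seed = 1L, cellId = NA_integer_,
                         label = NA_character_) {
  if (F_adh_true < 0) afmStop("F_adh_true must be >= 0", "cellAFM_format_error")
  if (nRuptureSteps < 1L) afmStop("nRuptureSteps must be >= 1", "cellAFM_format_error")
  validObject(cant); validObject(ramp)
  if (z0_true - detachSeparationUm <= ramp@zStartUm) {
    afmStop("detach separation outside the ramp range", "cellAFM_simulation_error")
  }
  C <- hertzPrefactor(E_contact, nu, cant@tipRadiusUm)
  k <- cant@springConstant
  z <- seq(ramp@zStartUm, ramp@zEndUm, length.out = ramp@samples)
  dEl <- numeric(length(z))
  prev <- NULL
  for (i in seq_along(z)) {
    t_nm <- (z[i] - z0_true) * 1000
    dEl[i] <- if (t_nm <= 0) 0 else solveBalance(t_nm, k, C, d0 = prev)
    prev <- if (dEl[i] > 0) dEl[i] else NULL
  }
  Fel <- k * dEl
  keep <- which(Fel <= ramp@setpointNn)
  if (length(keep) < length(z)) keep <- c(keep, max(keep) + 1L)
  zApp <- z[keep]
  dApp <- dEl[keep]

  ## retract: elastic unload above contact, adhesive well below
  zRet <- rev(zApp)
  Fret <- k * rev(dApp)
  sep <- pmax(0, z0_true - zRet)                # separation, um
  below <- which(zRet < z0_true)
  if (length(below) && F_adh_true > 0) {
    ## snap the well apex to the nearest sampled separation so the
    ## noise-free minimum equals -F_adh_true exactly
    sPeakTarget <- 0.25 * detachSeparationUm
    iPeak <- below[which.min(abs(sep[below] - sPeakTarget))]
    sPeak <- sep[iPeak]
    ramping <- below[sep[below] <= sPeak]
    Fret[ramping] <- -F_adh_true * sep[ramping] / sPeak
    after <- below[sep[below] > sPeak]
    if (length(after)) {
      ## plateau i of n covers (sPeak + (i-1)*D, sPeak + i*D] at level
      ## -F_adh*(n-i)/n: n upward jumps from the apex back to baseline
      n <- nRuptureSteps
      sEdges <- sPeak + (detachSeparationUm - sPeak) * seq_len(n) / n
      i <- findInterval(sep[after], sEdges, left.open = TRUE) + 1L
      Fret[after] <- -F_adh_true * pmax(0, n - i) / n
    }
  }
  dRet <- Fret / k
  withSeed(seed, {
    driftA <- cant@driftNmPerUm * (zApp - ramp@zStartUm)
    driftR <- cant@driftNmPerUm * (zRet - ramp@zStartUm)
    dA <- dApp + driftA + rnorm(length(zApp), 0, cant@noiseSdNm)
    dR <- dRet + driftR + rnorm(length(zRet), 0, cant@noiseSdNm)
    meta <- list(cell_id = cellId, label = label, kind = "scfs",
                 seed = as.integer(seed), F_adh_true = F_adh_true,
                 detach_separation_um = detachSeparationUm,
                 n_rupture_steps = as.integer(nRuptureSteps),
                 z0_true = z0_true)
    new("ForceCurve", meta = meta, cantilever = cant,
        approach = data.frame(z_um = zApp, d_nm = dA),
        retract = data.frame(z_um = zRet, d_nm = dR))
  })
}

#' Write / read a force curve in the TSV dialect
#'
#' `#`-prefixed `key=value` metadata header lines (spring constant, tip
#' radius, kind, seed, ...), then tab-separated columns `segment`, `z_um`,
#' `d_nm`, `F_nN`. Round-trips are exact to numerical print precision
#' (better than 1e-9 relative).
#'
#' @param curve A [ForceCurve-class].
#' @param path File path.
#' @return `writeForceCurve`: `path`, invisibly. `readForceCurve`: a
#'   [ForceCurve-class].
#' @export
writeForceCurve <- function(curve, path) {
  cant <- curve@cantilever
  hdr <- c(
    sprintf("# k_N_per_m=%.17g", cant@springConstant),
    sprintf("# R_um=%.17g", cant@tipRadiusUm),
    sprintf("# noise_sd_nm=%.17g", cant@noiseSdNm),
    sprintf("# drift_nm_per_um=%.17g", cant@driftNmPerUm))
  for (key in names(curve@meta)) {
    v <- curve@meta[[key]]
    if (is.null(v) || length(v) != 1L) next
    hdr <- c(hdr, sprintf("# %s=%s", key,
                          if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)))
  }
  seg <- rbind(
    data.frame(segment = "approach", curve@approach),
    data.frame(segment = "retract", curve@retract))
  seg$F_nN <- cant@springConstant * seg$d_nm
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("segment\tz_um\td_nm\tF_nN", con)
  writeLines(sprintf("%s\t%.17g\t%.17g\t%.17g", seg$segment, seg$z_um,
                     seg$d_nm, seg$F_nN), con)
  invisible(path)
}

#' @rdname writeForceCurve
#' @export
readForceCurve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) afmStop(sprintf("malformed header line: '%s'", h), "cellAFM_parse_error")
    key <- substr(kv, 1, eq - 1); val <- substr(kv, eq + 1, nchar(kv))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num)) val else num
  }
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("segment", "z_um", "d_nm")
  if (!all(need %in% names(df))) {
    afmStop("force-curve TSV must have columns segment, z_um, d_nm, F_nN",
            "cellAFM_parse_error")
  }
  cant <- cantileverSpec(
    springConstant = if (is.null(meta$k_N_per_m)) 0.05 else meta$k_N_per_m,
    tipRadiusUm = if (is.null(meta$R_um)) 5 else meta$R_um,
    noiseSdNm = if (is.null(meta$noise_sd_nm)) 0 else meta$noise_sd_nm,
    driftNmPerUm = if (is.null(meta$drift_nm_per_um)) 0 else meta$drift_nm_per_um)
  meta <- meta[setdiff(names(meta), c("k_N_per_m", "R_um", "noise_sd_nm",
                                      "drift_nm_per_um"))]
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  if (!is.null(meta$cell_id) && !is.na(suppressWarnings(as.integer(meta$cell_id)))) {
    meta$cell_id <- as.integer(meta$cell_id)
  }
  new("ForceCurve", meta = meta, cantilever = cant,
      approach = df[df$segment == "approach", c("z_um", "d_nm")],
      retract = df[df$segment == "retract", c("z_um", "d_nm")])
}
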