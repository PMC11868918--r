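#' Baseline-correct a force curve
#'
#' A straight line is fitted to the first `baselineFraction` of the
#' approach segment (far from contact) and subtracted from both segments,
#' removing offset and linear drift so the pre-contact force averages zero.
#'
#' @param curve A [ForceCurve-class].
#' @param baselineFraction Fraction of the approach used as baseline window.
#' @return The corrected [ForceCurve-class].
#' @section Errors: a baseline window of fewer than 10 samples raises a
#'   `cellAFM_baseline_error`.
#' @export
baselineCorrect <- function(curve, baselineFraction = 0.3) {
  app <- curve@approach
  nb <- floor(nrow(app) * baselineFraction)
  if (nb < 10L) {
    afmStop(sprintf("baseline window has %d samples (need >= 10)", nb),
            "cellAFM_baseline_error")
  }
  fit <- lm(d_nm ~ z_um, data = app[seq_len(nb), ])
  pred <- function(z) coef(fit)[1] + coef(fit)[2] * z
  curve@approach$d_nm <- app$d_nm - pred(app$z_um)
  curve@retract$d_nm <- curve@retract$d_nm - pred(curve@retract$z_um)
  curve@meta$baseline_corrected <- TRUE
  curve
}

## Force in nN along one segment.
segmentForce <- function(curve, segment = c("approach", "retract")) {
  seg <- slot(curve, match.arg(segment))
  curve@cantilever@springConstant * seg$d_nm
}

#' Locate the contact point of a baseline-corrected curve
#'
#' Grid search over candidate contact samples: for each candidate the curve
#' is modeled as flat baseline before and Hertz `B delta^{3/2}` after (with
#' `delta = (z - z0)*1000 - d` from the measured deflection and `B`
#' profiled out in closed form), scored by total residual sum of squares.
#' The minimizing candidate is refined by local parabolic interpolation of
#' the RSS profile, giving sub-sample resolution. Deterministic.
#'
#' @param curve A baseline-corrected [ForceCurve-class].
#' @param minPostContact Minimum post-contact samples for a valid candidate.
#' @return List with `z0Um`, `d0Nm` (0 after baseline correction), `index`
#'   (contact sample index) and `rssRatio` (best RSS over the all-baseline
#'   RSS).
#' @section Errors: when no candidate clearly improves on the all-baseline
#'   model (pure-noise curve), a `cellAFM_no_contact` error is raised.
#' @export
findContactPoint <- function(curve, minPostContact = 5L) {
  app <- curve@approach
  z <- app$z_um; d <- app$d_nm
  k <- curve@cantilever@springConstant
  F <- k * d
  n <- length(z)
  if (n < 30L) afmStop("approach segment too short", "cellAFM_format_error")
  nb <- max(10L, floor(0.2 * n))
  sdBase <- sd(F[seq_len(nb)])
  rss0 <- sum(F^2)
  cand <- seq(nb, n - minPostContact)
  score <- function(j) {
    delta <- pmax((z - z[j]) * 1000 - d, 0)
    x <- delta^1.5
    post <- seq(j + 1L, n)
    B <- max(0, sum(F[post] * x[post]) / sum(x[post]^2))
    sum(F[seq_len(j)]^2) + sum((F[post] - B * x[post])^2)
  }
  coarse <- cand[seq(1, length(cand), by = 4L)]
  rssC <- vapply(coarse, score, numeric(1))
  jBest <- coarse[which.min(rssC)]
  fine <- seq(max(cand[1], jBest - 5L), min(cand[length(cand)], jBest + 5L))
  rssF <- vapply(fine, score, numeric(1))
  j <- fine[which.min(rssF)]
  rssBest <- min(rssF)
  noContact <- rssBest > 0.9 * rss0 || max(F) < 6 * sdBase
  if (noContact) {
    afmStop("no contact found: curve is indistinguishable from baseline",
            "cellAFM_no_contact")
  }
  ## parabolic refinement of the RSS valley around j
  z0 <- z[j]
  if (j > fine[1] && j < fine[length(fine)]) {
    r <- c(score(j - 1L), rssBest, score(j + 1L))
    denom <- r[1] - 2 * r[2] + r[3]
    if (is.finite(denom) && denom > 0) {
      shift <- 0.5 * (r[1] - r[3]) / denom
      shift <- max(-1, min(1, shift))
      z0 <- z[j] + shift * mean(diff(z))
    }
  }
  list(z0Um = z0, d0Nm = 0, index = j, rssRatio = rssBest / rss0)
}

#' Fit the Hertz model to an indentation curve
#'
#' Young's modulus is obtained by minimizing the squared force residuals of
#' the spherical-indenter Hertz model `F = (4/3) E/(1-nu^2) sqrt(R)
#' delta^{3/2}` over post-contact approach samples with `delta` at most
#' `deltaMaxFraction` of the maximum indentation. A closed-form profiled
#' estimate at the located contact point initializes a joint nonlinear
#' refinement of `(E, z0)`; convergence requires a finite positive modulus
#' and optimizer success at gradient tolerance 1e-10.
#'
#' @param curve A baseline-corrected [ForceCurve-class].
#' @param R Probe radius, um (default: the curve's cantilever tip radius).
#' @param nu Poisson ratio.
#' @param deltaMaxFraction Fitted indentation range as a fraction of the
#'   maximum indentation.
#' @param contact Optional list with `z0Um`, `d0Nm` (from
#'   [findContactPoint()]); located automatically when missing.
#' @return A [HertzFitResult-class].
#' @export
fitHertz <- function(curve, R = curve@cantilever@tipRadiusUm, nu = 0.5,
                     deltaMaxFraction = 0.8, contact = NULL) {
  if (is.null(contact)) contact <- findContactPoint(curve)
  app <- curve@approach
  k <- curve@cantilever@springConstant
  z <- app$z_um; d <- app$d_nm - contact$d0Nm
  F <- k * d
  unitC <- hertzPrefactor(1, nu, R)  # B = unitC * E

  subsetFor <- function(z0) {
    delta <- (z - z0) * 1000 - d
    pos <- which(delta > 0)
    if (length(pos) < 2L) return(integer())
    dmax <- max(delta[pos])
    pos[delta[pos] <= deltaMaxFraction * dmax]
  }
  rssFor <- function(par, idx) {
    B <- par[1]; z0 <- par[2]
    delta <- pmax((z[idx] - z0) * 1000 - d[idx], 0)
    sum((F[idx] - B * delta^1.5)^2)
  }
  fail <- function() new("HertzFitResult", EPa = NA_real_, z0Um = contact$z0Um,
                         d0Nm = contact$d0Nm, rmseNn = NA_real_, nPoints = 0L,
                         deltaRangeNm = c(0, 0), converged = FALSE)

  idx <- subsetFor(contact$z0Um)
  if (length(idx) < 10L) return(fail())
  delta0 <- pmax((z[idx] - contact$z0Um) * 1000 - d[idx], 0)
  B0 <- sum(F[idx] * delta0^1.5) / sum(delta0^3)
  if (!is.finite(B0) || B0 <= 0) return(fail())

  opt <- optim(c(B0, contact$z0Um), function(p) rssFor(p, idx),
               method = "BFGS",
               control = list(reltol = 1e-14, abstol = 1e-14, maxit = 500))
  B <- opt$par[1]; z0 <- opt$par[2]
  if (!is.finite(B) || B <= 0) return(fail())
  idx2 <- subsetFor(z0)
  if (length(idx2) >= 10L) {
    opt2 <- optim(c(B, z0), function(p) rssFor(p, idx2), method = "BFGS",
                  control = list(reltol = 1e-14, abstol = 1e-14, maxit = 500))
    if (opt2$value <= opt$value) { opt <- opt2; B <- opt$par[1]; z0 <- opt$par[2] }
    idx <- idx2
  }
  if (!is.finite(B) || B <= 0) return(fail())
  deltaF <- pmax((z[idx] - z0) * 1000 - d[idx], 0)
  rmse <- sqrt(opt$value / length(idx))
  new("HertzFitResult", EPa = B / unitC, z0Um = z0, d0Nm = contact$d0Nm,
      rmseNn = rmse, nPoints = length(idx),
      deltaRangeNm = range(deltaF), converged = opt$convergence == 0)
}

#' Extract the adhesion force and work from a retract curve
#'
#' The adhesion force is the magnitude of the most negative baseline-
#' corrected retract force (zero when the retract never dips below
#' baseline). Because a raw per-sample minimum is biased upward by noise
#' (an extreme-value effect), the peak is refined whenever a clear rupture
#' edge borders the minimum: a line is fitted to the loading ramp up to the
#' rupture and evaluated at the rupture position — the usual way rupture
#' forces are read off force-spectroscopy curves. Noise-free curves are
#' reproduced exactly either way. The work of adhesion is the area between
#' the force curve and zero over the contiguous negative-force region
#' containing the minimum (trapezoid rule; nN x um = fJ). Rupture steps are
#' counted as upward force jumps between adjacent samples exceeding 5x the
#' baseline noise SD inside the adhesive well.
#'
#' @param curve A baseline-corrected [ForceCurve-class].
#' @return An [AdhesionResult-class].
#' @export
extractAdhesion <- function(curve) {
  F <- segmentForce(curve, "retract")
  zr <- curve@retract$z_um
  iMin <- which.min(F)
  FAdh <- max(0, -F[iMin])
  if (FAdh == 0) {
    return(new("AdhesionResult", FAdhNn = 0, workFj = 0,
               pullOffZUm = zr[iMin], nRuptureSteps = 0L))
  }
  neg <- F < 0
  lo <- iMin; while (lo > 1L && neg[lo - 1L]) lo <- lo - 1L
  hi <- iMin; while (hi < length(F) && neg[hi + 1L]) hi <- hi + 1L
  idx <- lo:hi
  work <- if (length(idx) > 1L) {
    ## trapezoid over piezo distance (z decreases along retract); nN*um = fJ
    Fw <- F[idx]
    abs(sum(0.5 * (Fw[-1] + Fw[-length(Fw)]) * diff(zr[idx])))
  } else 0
  ## noise estimate from the far (fully detached) end of the retract
  nTail <- max(10L, floor(0.15 * length(F)))
  sdNoise <- sd(F[seq(length(F) - nTail + 1L, length(F))])
  thr <- max(5 * sdNoise, 1e-9)
  dF <- diff(F[idx])
  nSteps <- sum(dF > thr)
  ## the final return to baseline (edge of the well) is a rupture too
  if (hi < length(F) && (F[hi + 1L] - F[hi]) > thr) nSteps <- nSteps + 1L

  ## rupture-edge peak refinement: fit the loading ramp up to the first
  ## rupture at/after the minimum and read the force at the rupture
  jumpThr <- max(6 * sdNoise, 1e-9)
  dAll <- diff(F)
  jumps <- which(dAll > jumpThr)
  j <- jumps[jumps >= iMin - 2L & jumps <= hi][1]
  if (!is.na(j) && j - lo >= 2L) {
    fitIdx <- max(lo, j - 5L):j
    lf <- lm(F[fitIdx] ~ zr[fitIdx])
    FAtEdge <- unname(coef(lf)[1] + coef(lf)[2] * zr[j])
    if (is.finite(FAtEdge) && FAtEdge < 0) FAdh <- -FAtEdge
  }
  new("AdhesionResult", FAdhNn = FAdh, workFj = work, pullOffZUm = zr[iMin],
      nRuptureSteps = as.integer(nSteps))
}

#' Aggregate per-curve values into a per-cell measurement
#'
#' Non-converged curves are excluded (never imputed) and counted; the
#' aggregate is the arithmetic mean by default (median optional) with the
#' unbiased SD.
#'
#' @param values Per-curve values (e.g. fitted moduli).
#' @param converged Logical vector marking valid curves (default all).
#' @param method `"mean"` or `"median"`.
#' @param cellId,label Cell identity recorded in the result.
#' @return A [CellMeasurement-class].
#' @section Errors: all curves non-converged raises a
#'   `cellAFM_aggregation_error`.
#' @export
aggregateCell <- function(values, converged = rep(TRUE, length(values)),
                          method = c("mean", "median"),
                          cellId = NA_integer_, label = NA_character_) {
  method <- match.arg(method)
  ok <- converged & is.finite(values)
  if (!any(ok)) {
    afmStop("no converged curves to aggregate for this cell",
            "cellAFM_aggregation_error")
  }
  v <- values[ok]
  agg <- if (method == "mean") mean(v) else median(v)
  new("CellMeasurement", cellId = as.integer(cellId), label = label,
      values = v, nExcluded = as.integer(sum(!ok)), aggregate = agg,
      sdValue = if (length(v) > 1L) sd(v) else 0, method = method)
}
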