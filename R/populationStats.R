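#' Summarize per-cell aggregates for one cell type
#'
#' The Gaussian "fit" is maximum likelihood on the raw values (mu = sample
#' mean, sigma = sample SD), making it independent of the histogram
#' binning; the histogram uses equal-width bins over `[min, max]`. All
#' values equal is reported as a degenerate fit rather than an error.
#'
#' @param values Per-cell aggregate values (n >= 2).
#' @param bins Number of histogram bins.
#' @param label Cell-type label recorded in the summary.
#' @return A [PopulationSummary-class].
#' @export
summarizePopulation <- function(values, bins = 10L, label = NA_character_) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) afmStop("population summary needs at least 2 values",
                      "cellAFM_format_error")
  mu <- mean(values); sig <- sd(values)
  degenerate <- sig == 0
  if (degenerate) {
    breaks <- c(values[1] - 0.5, values[1] + 0.5)
    counts <- n
  } else {
    breaks <- seq(min(values), max(values), length.out = bins + 1L)
    h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    counts <- h$counts
  }
  new("PopulationSummary", label = label, n = as.integer(n), mean = mu,
      sd = sig, mu = mu, sigma = sig, degenerate = degenerate,
      breaks = breaks, counts = as.integer(counts))
}

#' Compare two cell-type populations
#'
#' Descriptive comparison: difference of means, direction of the ordering,
#' and a rank-based (Wilcoxon) p-value. No decision threshold is applied —
#' the read-out is the ordering itself.
#'
#' @param a,b [PopulationSummary-class] objects.
#' @param valuesA,valuesB Optional raw values backing the summaries (used
#'   for the rank test; the test is skipped when absent).
#' @return List with `meanDifference` (b - a), `ordering` (one of
#'   `"b_greater"`, `"a_greater"`, `"none"`), and `pValue` (rank-based,
#'   NA without raw values).
#' @export
compareGroups <- function(a, b, valuesA = NULL, valuesB = NULL) {
  dm <- b@mean - a@mean
  ordering <- if (dm > 0) "b_greater" else if (dm < 0) "a_greater" else "none"
  p <- NA_real_
  if (!is.null(valuesA) && !is.null(valuesB) &&
      length(valuesA) >= 2 && length(valuesB) >= 2) {
    p <- suppressWarnings(wilcox.test(valuesB, valuesA)$p.value)
  }
  list(labelA = a@label, labelB = b@label, meanA = a@mean, meanB = b@mean,
       meanDifference = dm, ordering = ordering, pValue = p)
}

#' Plot a population histogram with its Gaussian overlay
#'
#' The overlay renders the maximum-likelihood Gaussian scaled by
#' `n * binwidth`, the usual count-scale convention.
#'
#' @param summary A [PopulationSummary-class].
#' @param xlab X-axis label.
#' @param main Title.
#' @return Invisibly, the summary.
#' @export
plotPopulation <- function(summary, xlab = "value", main = summary@label) {
  mids <- (summary@breaks[-1] + summary@breaks[-length(summary@breaks)]) / 2
  bw <- diff(summary@breaks)[1]
  graphics::barplot(summary@counts, names.arg = signif(mids, 3), space = 0,
                    xlab = xlab, ylab = "cells", main = main, col = "grey85")
  if (!summary@degenerate) {
    xs <- seq(summary@breaks[1], summary@breaks[length(summary@breaks)],
              length.out = 200)
    ys <- summary@n * bw * dnorm(xs, summary@mu, summary@sigma)
    xPlot <- (xs - summary@breaks[1]) / bw
    graphics::lines(xPlot, ys, lwd = 2)
  }
  invisible(summary)
}
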