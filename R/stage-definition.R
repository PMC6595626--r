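#' Fit water-uptake phase breakpoints to a fresh-weight series
#'
#' Continuous piecewise-linear least squares with breakpoints restricted
#' to the observed time grid, found by exhaustive search over all
#' admissible breakpoint combinations, so the fit is globally optimal
#' over the grid and fully deterministic. Formalizes how the rapid and
#' slow water-absorption phases of a triphasic imbibition curve delimit
#' germination stages 2 and 3.
#'
#' The mean is a linear spline: `w(t) = a + s1*t + (s2-s1)*(t-b1)+ +
#' (s3-s2)*(t-b2)+ ...`, continuous at every breakpoint. Each candidate
#' segment must contain at least two observations so all slopes are
#' identifiable. Among fits with equal (within 1e-10 relative) residual
#' sum of squares the lexicographically smallest breakpoint combination
#' is returned.
#'
#' @param series data.frame with columns `time_min`, `weight_g` (as
#'   produced by [generateImbibitionSeries()]), or a numeric time vector
#'   if `weight` is given.
#' @param weight numeric weights, when `series` is a time vector.
#' @param nSegments number of linear segments (default 3, the triphasic
#'   model).
#' @return A [PhaseFit-class] with breakpoints (minutes), per-segment
#'   slopes (g/min), intercept, residual sum of squares, and fitted
#'   values.
#' @examples
#' s <- generateImbibitionSeries(noiseSd = 0, seed = 1)
#' fit <- fitPhaseBreakpoints(s)
#' fit@breakpoints   # c(120, 600)
#' @export
fitPhaseBreakpoints <- function(series, weight = NULL, nSegments = 3) {
  if (is.data.frame(series)) {
    tm <- series$time_min; wt <- series$weight_g
  } else {
    tm <- series; wt <- weight
  }
  if (length(tm) != length(wt))
    stop(germError("time and weight must have equal length",
                   "germDataError"))
  n <- length(tm)
  if (is.unsorted(tm, strictly = TRUE))
    stop(germError("time must be strictly increasing", "germDataError"))
  if (n < 3 * nSegments)
    stop(germError(sprintf("need at least %d points for %d segments",
                           3 * nSegments, nSegments), "germDataError"))
  nb <- nSegments - 1L
  if (nb == 0L) {
    f <- stats::lm.fit(cbind(1, tm), wt)
    return(methods::new("PhaseFit", breakpoints = numeric(0),
                        slopes = f$coefficients[2], intercept = f$coefficients[1],
                        rss = sum(f$residuals^2),
                        fitted = as.numeric(cbind(1, tm) %*% f$coefficients),
                        time = tm, weight = wt))
  }
  # candidate breakpoints: interior grid points with >= 2 points per
  # segment (index gaps >= 2)
  candIdx <- 3:(n - 2)
  combos <- utils::combn(candIdx, nb)
  keep <- if (nb > 1) apply(combos, 2, function(ix) all(diff(ix) >= 2))
          else rep(TRUE, ncol(combos))
  combos <- combos[, keep, drop = FALSE]
  best <- NULL; bestRSS <- Inf
  for (j in seq_len(ncol(combos))) {
    bp <- tm[combos[, j]]
    X <- cbind(1, tm,
               vapply(bp, function(b) pmax(0, tm - b), numeric(n)))
    f <- stats::lm.fit(X, wt)
    rss <- sum(f$residuals^2)
    if (rss < bestRSS * (1 - 1e-10) ||
        (is.null(best) && is.finite(rss))) {
      bestRSS <- rss
      best <- list(bp = bp, coef = f$coefficients,
                   fitted = as.numeric(X %*% f$coefficients))
    }
  }
  co <- best$coef
  slopes <- cumsum(co[-1])
  methods::new("PhaseFit", breakpoints = as.numeric(best$bp),
               slopes = as.numeric(slopes), intercept = as.numeric(co[1]),
               rss = bestRSS, fitted = best$fitted, time = tm, weight = wt)
}

setMethod("show", "PhaseFit", function(object) {
  cat("PhaseFit:", length(object@slopes), "segments\n")
  cat("  breakpoints (min):",
      paste(signif(object@breakpoints, 6), collapse = ", "), "\n")
  cat("  slopes (g/min):  ",
      paste(signif(object@slopes, 4), collapse = ", "), "\n")
  cat("  rss:", signif(object@rss, 4), "\n")
})

#' Export a PhaseFit as JSON
#'
#' @param fit a [PhaseFit-class].
#' @param path output file.
#' @export
writePhaseFit <- function(fit, path) {
  jsonlite::write_json(list(breakpoints = fit@breakpoints,
                            slopes = fit@slopes,
                            intercept = fit@intercept, rss = fit@rss),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
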