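#' Signal-enhancement curve of a region unit
#'
#' Fractional enhancement relative to the pre-contrast frame:
#' `E(t) = (mean(t) - mean(0)) / mean(0)` over the unit's voxels, so
#' `E(0) = 0` by construction.  With `percent = TRUE` the curve is
#' expressed in percent.
#'
#' @param stack A `region_stack` (frame 0 must be pre-contrast).
#' @param times Frame times in minutes; defaults to equally spaced
#'   frames if the stack does not carry a geometry.
#' @param percent Report percent instead of a ratio.
#' @return Object of class `enhancement_curve`: numeric vector `E` with
#'   attribute `times` (minutes).
#' @export
enhancement_curve <- function(stack, times = NULL, percent = FALSE) {
  m <- colMeans(stack$values)
  if (m[1L] <= 0)
    stop("degenerate baseline: pre-contrast mean must be positive",
         call. = FALSE)
  e <- (m - m[1L]) / m[1L]
  if (percent) e <- 100 * e
  if (is.null(times)) times <- seq_along(e) - 1
  structure(e, times = times, class = "enhancement_curve")
}

#' Area under the enhancement curve
#'
#' Trapezoidal integral of `E(t)` over the frame times (minutes), a
#' semi-quantitative surrogate of contrast accumulation.
#'
#' @param curve An `enhancement_curve` (or plain numeric vector).
#' @param times Frame times in minutes (taken from the curve attribute
#'   when present).
#' @return Scalar (dimensionless x min).
#' @export
auec <- function(curve, times = attr(curve, "times")) {
  e <- as.numeric(curve)
  if (length(e) < 2L) stop("need at least two frames", call. = FALSE)
  sum(diff(times) * (e[-1L] + e[-length(e)]) / 2)
}

#' Post-peak enhancement slope
#'
#' Ordinary least-squares slope of `E` against time over the frames
#' strictly after the bolus peak, assuming the curve is roughly linear
#' there.  The peak frame is the argmax of `E` restricted to the first
#' third of frames (bolus arrival is early in a ~24 min protocol, and
#' restricting the search stops late leakage maxima from truncating the
#' fit window).
#'
#' @inheritParams auec
#' @return Scalar slope in 1/min.
#' @export
enhancement_slope <- function(curve, times = attr(curve, "times")) {
  e <- as.numeric(curve)
  n <- length(e)
  peak <- which.max(e[seq_len(max(1L, ceiling(n / 3)))])
  if (n - peak < 3L)
    stop("need at least three frames after the peak", call. = FALSE)
  post <- seq.int(peak + 1L, n)
  unname(stats::coef(stats::lm(e[post] ~ times[post]))[2L])
}

#' @export
print.enhancement_curve <- function(x, ...) {
  cat(sprintf("Enhancement curve: %d frames, peak %.3f, final %.3f\n",
              length(x), max(x), x[length(x)]))
  invisible(x)
}
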