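#' Baseline knot specification
#'
#' Knot x-positions (cm-1) placed in peak-free spectral windows, plus the
#' half-width (in points) of the neighborhood whose average defines each
#' knot's y-value. The default half-width of 2 gives the 5-point
#' neighborhood average; `half_width = 0` anchors the spline at the exact
#' intensity values (useful when the baseline itself must be reproduced
#' exactly).
#'
#' @param positions knot x-positions, cm-1 (>= 4 required for a cubic
#'   spline).
#' @param half_width neighborhood half-width in axis points (>= 0).
#' @return a `baseline_knots` object.
#' @export
baseline_knots <- function(positions, half_width = 2) {
  if (length(positions) < 4L)
    stop_input("at least 4 knots are required for a cubic spline baseline")
  if (any(diff(sort(positions)) <= 0))
    stop_input("knot positions must be distinct")
  check_scalar(half_width, "half_width")
  if (half_width < 0 || half_width != round(half_width))
    stop_input("half_width must be a non-negative integer")
  structure(list(positions = sort(as.numeric(positions)),
                 half_width = as.integer(half_width)),
            class = "baseline_knots")
}

#' Default knot positions for cytochrome c SERS spectra
#'
#' Twelve knots distributed over the band-free windows of the 600-1800 cm-1
#' region (below 640, 800-1100, 1200-1290, 1420-1520 and above 1660 cm-1),
#' i.e. between the heme marker bands. The exact choice is a package
#' default, intended to be adjusted per instrument; the same positions
#' should be reused across all spectra of a study.
#'
#' @param half_width neighborhood half-width in points (default 2 = 5-point
#'   averages).
#' @return a [baseline_knots()] object.
#' @export
default_baseline_knots <- function(half_width = 2) {
  baseline_knots(c(610, 635, 820, 920, 1020, 1095, 1215, 1280,
                   1435, 1505, 1675, 1780), half_width = half_width)
}

#' Subtract a spline-knot baseline from a spectrum
#'
#' The baseline is a cubic spline through knots whose x-positions are fixed
#' (shared across all spectra of a study) and whose y-values are the
#' neighborhood averages of the spectrum around each knot (5-point windows
#' by default). The spline uses the Forsythe-Malcolm-Moler end conditions,
#' which reproduce any cubic polynomial exactly; a constant offset added to
#' a trace is therefore absorbed entirely into the baseline.
#'
#' @param trace a [sers_spectrum()].
#' @param knots a [baseline_knots()] object; all positions must lie within
#'   the trace axis.
#' @return the baseline-subtracted [sers_spectrum()]; the fitted baseline is
#'   attached as `metadata$baseline` and the knots used as
#'   `metadata$knots`.
#' @export
subtract_baseline <- function(trace, knots = default_baseline_knots()) {
  stopifnot(inherits(trace, "sers_spectrum"), inherits(knots, "baseline_knots"))
  x <- trace$wavenumber
  if (any(knots$positions < min(x)) || any(knots$positions > max(x)))
    stop_input("baseline knot(s) outside the spectrum axis")
  hw <- knots$half_width
  n <- length(x)
  ky <- vapply(knots$positions, function(p) {
    i <- which.min(abs(x - p))
    win <- max(1L, i - hw):min(n, i + hw)
    mean(trace$intensity[win])
  }, numeric(1))
  kx <- x[vapply(knots$positions, function(p) which.min(abs(x - p)), integer(1))]
  bl <- splinefun(kx, ky, method = "fmm")(x)
  out <- sers_spectrum(x, trace$intensity - bl, metadata = trace$metadata)
  out$metadata$baseline <- bl
  out$metadata$knots <- knots
  out
}
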