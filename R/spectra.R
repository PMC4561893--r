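#' Wavenumber-indexed spectrum container
#'
#' @param wavenumber strictly increasing, uniformly spaced axis (cm-1).
#' @param intensity intensity values (a.u.); negative values are allowed
#'   (e.g. after baseline subtraction).
#' @param metadata named list recording generation parameters or file
#'   origin.
#' @return a `sers_spectrum` object.
#' @export
sers_spectrum <- function(wavenumber, intensity, metadata = list()) {
  if (length(wavenumber) != length(intensity))
    stop_input("wavenumber and intensity must have the same length")
  if (length(wavenumber) < 2L) stop_input("a spectrum needs >= 2 points")
  d <- diff(wavenumber)
  if (any(d <= 0)) stop_input("wavenumber axis must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop_input("wavenumber axis must be uniformly spaced")
  structure(list(wavenumber = as.numeric(wavenumber),
                 intensity = as.numeric(intensity),
                 metadata = metadata),
            class = "sers_spectrum")
}

#' @export
print.sers_spectrum <- function(x, ...) {
  cat("<sers_spectrum>", length(x$wavenumber), "points,",
      min(x$wavenumber), "-", max(x$wavenumber), "cm-1\n")
  invisible(x)
}

#' @export
plot.sers_spectrum <- function(x, ...,
                               xlab = expression(paste("wavenumber (", cm^-1, ")")),
                               ylab = "intensity (a.u.)", type = "l") {
  graphics::plot(x$wavenumber, x$intensity, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

# sum of Lorentzian bands on an axis; peak height = rel_amplitude,
# half-width gamma = fwhm/2, area = amplitude * fwhm * pi / 2
.band_profile <- function(axis, bands) {
  y <- numeric(length(axis))
  for (i in seq_len(nrow(bands))) {
    g <- bands$fwhm[i] / 2
    y <- y + bands$rel_amplitude[i] * g^2 /
      ((axis - bands$center[i])^2 + g^2)
  }
  y
}

.make_axis <- function(axis) {
  if (length(axis) != 3L || axis[3] <= 0 || axis[2] <= axis[1])
    stop_input("axis must be c(min, max, step) with max > min, step > 0")
  seq(axis[1], axis[2], by = axis[3])
}

# smooth additive baseline: cubic spline through (x, y) knot pairs
.baseline_curve <- function(axis, knot_x, knot_y) {
  if (is.null(knot_x) || length(knot_x) == 0L) return(numeric(length(axis)))
  if (length(knot_x) != length(knot_y))
    stop_input("baseline knot x and y must have the same length")
  splinefun(knot_x, knot_y, method = "fmm")(axis)
}

#' Synthesize a SERS spectrum from parametric bands
#'
#' Sum of Lorentzian bands plus a smooth cubic-spline baseline through the
#' stated knot values plus i.i.d. Gaussian noise. Identical seeds give
#' identical traces.
#'
#' @param bands data frame with `center`, `fwhm`, `rel_amplitude` columns
#'   (one set of a [band_library()]); may have zero rows.
#' @param axis `c(min, max, step)` in cm-1; must cover all band centers.
#' @param baseline_knots,baseline_values x-positions (cm-1) and y-values of
#'   the baseline spline knots; both `NULL` for a flat zero baseline.
#' @param noise_sd Gaussian noise standard deviation (a.u., >= 0).
#' @param seed integer RNG seed (used only when `noise_sd > 0`).
#' @return a [sers_spectrum()].
#' @export
synthesize_spectrum <- function(bands, axis = c(600, 1800, 1),
                                baseline_knots = NULL, baseline_values = NULL,
                                noise_sd = 0, seed = NULL) {
  x <- .make_axis(axis)
  if (nrow(bands) > 0 &&
      (any(bands$center < min(x)) || any(bands$center > max(x))))
    stop_input("band center(s) outside the requested axis")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  y <- .band_profile(x, bands) + .baseline_curve(x, baseline_knots, baseline_values)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    y <- y + rnorm(length(x), sd = noise_sd)
  }
  sers_spectrum(x, y, metadata = list(
    kind = "synthetic", noise_sd = noise_sd, seed = seed,
    baseline_knots = baseline_knots, baseline_values = baseline_values))
}

#' Two-state redox mixture spectrum
#'
#' Linear mixture `f_red * S_reduced + (1 - f_red) * S_oxidized` of the
#' noiseless band profiles of a library, with baseline and noise added after
#' mixing. Emulates the partially reduced cytochrome pool of respiring
#' mitochondria, whose reduced fraction falls under uncoupling (FCCP) and
#' rises under ATP-synthase inhibition (oligomycin).
#'
#' @param f_red reduced fraction in `[0, 1]`.
#' @param library a [band_library()].
#' @param which `"mitochondria"` or `"isolated"` band sets.
#' @inheritParams synthesize_spectrum
#' @return a [sers_spectrum()] whose metadata records `f_red`.
#' @export
mixture_spectrum <- function(f_red, library = band_library(),
                             which = c("mitochondria", "isolated"),
                             axis = c(600, 1800, 1),
                             baseline_knots = NULL, baseline_values = NULL,
                             noise_sd = 0, seed = NULL) {
  which <- match.arg(which)
  if (!is.numeric(f_red) || length(f_red) != 1L || f_red < 0 || f_red > 1)
    stop_input("f_red must be a single value in [0, 1]")
  sets <- if (which == "mitochondria")
    list(ox = library$mito_oxidized, red = library$mito_reduced)
  else
    list(ox = library$cyt_oxidized, red = library$cyt_reduced)
  x <- .make_axis(axis)
  y <- (1 - f_red) * .band_profile(x, sets$ox) +
    f_red * .band_profile(x, sets$red) +
    .baseline_curve(x, baseline_knots, baseline_values)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    y <- y + rnorm(length(x), sd = noise_sd)
  }
  sers_spectrum(x, y, metadata = list(
    kind = "synthetic-mixture", f_red = f_red, which = which,
    noise_sd = noise_sd, seed = seed,
    baseline_knots = baseline_knots, baseline_values = baseline_values))
}

#' Read/write two-column ASCII spectra
#'
#' Plain delimited text: wavenumber (cm-1) and intensity (a.u.), one pair
#' per line, `#`-prefixed comment lines ignored (and used by
#' `write_spectrum()` for a small provenance header).
#'
#' @param path file path.
#' @param trace a [sers_spectrum()].
#' @return `read_spectrum()` returns a `sers_spectrum`; `write_spectrum()`
#'   returns `path` invisibly.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop_input("spectrum file not found: ", path)
  d <- read.table(path, comment.char = "#", col.names = c("wavenumber", "intensity"))
  sers_spectrum(d$wavenumber, d$intensity, metadata = list(origin = path))
}

#' @rdname read_spectrum
#' @export
write_spectrum <- function(trace, path) {
  stopifnot(inherits(trace, "sers_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# sersim spectrum", "# wavenumber_cm-1  intensity_au"), con)
  write.table(data.frame(trace$wavenumber, trace$intensity), con,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
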