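#' Maximum of a peak within a window
#'
#' Position and value of the intensity maximum inside
#' `[center - half_window, center + half_window]`. Ties are broken towards
#' the lower wavenumber. No profile fitting is attempted: the pipeline works
#' on maxima in windows throughout.
#'
#' @param trace a [sers_spectrum()] (baseline already subtracted for ratio
#'   work).
#' @param center window center, cm-1.
#' @param half_window half-width, cm-1.
#' @return list with `position` (cm-1) and `intensity` (a.u.).
#' @export
peak_maximum <- function(trace, center, half_window = 15) {
  stopifnot(inherits(trace, "sers_spectrum"))
  check_scalar(center, "center")
  check_scalar(half_window, "half_window", positive = TRUE)
  idx <- which(trace$wavenumber >= center - half_window &
                 trace$wavenumber <= center + half_window)
  if (length(idx) == 0L)
    stop_input("peak window [", center - half_window, ", ",
               center + half_window, "] contains no axis points")
  i <- idx[which.max(trace$intensity[idx])]
  list(position = trace$wavenumber[i], intensity = trace$intensity[i])
}

# window centers per redox state; the reduced-state nu4 and nu10 markers
# shift (1371 -> 1356, 1638 -> 1605), so reduced-state ratios are computed
# at the shifted centers to avoid marker cross-talk
.ratio_centers <- function(state) {
  if (state == "reduced")
    c(r748 = 748, r1170 = 1170, r1371 = 1356, denom = 1605)
  else
    c(r748 = 748, r1170 = 1170, r1371 = 1371, denom = 1638)
}

#' Band-intensity ratios of a baseline-subtracted spectrum
#'
#' The three diagnostic ratios I748/I1638, I1170/I1638 and I1371/I1638: peak
#' maxima in 15 cm-1 half-windows around the marker positions, each
#' normalized by the 1638 cm-1 peak maximum. For spectra of the reduced
#' state the shifted marker centers are used (1356 for ν4 and 1605 for the
#' normalization peak); the centers actually used are recorded in the
#' report. Ratios are invariant under positive rescaling of the intensity.
#'
#' @param trace baseline-subtracted [sers_spectrum()].
#' @param state `"oxidized"` (default) or `"reduced"` window centers.
#' @param half_window half-width of every peak window, cm-1.
#' @return a `ratio_report`: list with `r748`, `r1170`, `r1371`, the
#'   `centers` used and the measured `positions`.
#' @export
peak_ratios <- function(trace, state = c("oxidized", "reduced"),
                        half_window = 15) {
  state <- match.arg(state)
  ctr <- .ratio_centers(state)
  pk <- lapply(ctr, function(c0) peak_maximum(trace, c0, half_window))
  denom <- pk$denom$intensity
  if (!is.finite(denom) || denom <= 0)
    stop_input("normalization peak intensity at ", ctr["denom"],
               " cm-1 is not positive; undefined ratios")
  structure(list(r748 = pk$r748$intensity / denom,
                 r1170 = pk$r1170$intensity / denom,
                 r1371 = pk$r1371$intensity / denom,
                 centers = ctr,
                 positions = vapply(pk, `[[`, numeric(1), "position"),
                 state = state),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf("<ratio_report> I748/I%d = %.3f  I1170/I%d = %.3f  I%d/I%d = %.3f\n",
              x$centers["denom"], x$r748, x$centers["denom"], x$r1170,
              x$centers["r1371"], x$centers["denom"], x$r1371))
  invisible(x)
}

#' Express treated ratios as a percentage of control
#'
#' @param treated,control [peak_ratios()] reports (control ratios must be
#'   positive).
#' @return named numeric vector (`r748`, `r1170`, `r1371`) of percentages;
#'   control = 100.
#' @export
percent_of_control <- function(treated, control) {
  stopifnot(inherits(treated, "ratio_report"), inherits(control, "ratio_report"))
  ctrl <- c(r748 = control$r748, r1170 = control$r1170, r1371 = control$r1371)
  if (any(ctrl <= 0)) stop_input("control ratios must be positive")
  trt <- c(r748 = treated$r748, r1170 = treated$r1170, r1371 = treated$r1371)
  100 * trt / ctrl
}

#' Redox-state call from a baseline-subtracted spectrum
#'
#' Combines the marker-band evidence (ν4 position 1371 vs 1356 cm-1;
#' high-frequency marker 1638 vs 1605 cm-1; relative 748 cm-1 intensity)
#' with a non-negative least-squares projection of the spectrum onto the two
#' noiseless library end members to estimate the reduced fraction. The call
#' is `"oxidized"` for estimates below 0.3, `"reduced"` above 0.7 and
#' `"mixed"` in between; when the signal is indistinguishable from the noise
#' floor the call is `"mixed"` with `low_confidence = TRUE`.
#'
#' @param trace baseline-subtracted [sers_spectrum()] covering at least
#'   650-1700 cm-1.
#' @param library a [band_library()].
#' @param which `"mitochondria"` or `"isolated"` end members.
#' @return a `redox_call`: `state`, `reduced_fraction_estimate` in `[0,
#'   1]`, `low_confidence`, and `evidence` (marker positions and the r748
#'   level).
#' @export
classify_redox <- function(trace, library = band_library(),
                           which = c("mitochondria", "isolated")) {
  which <- match.arg(which)
  stopifnot(inherits(trace, "sers_spectrum"))
  x <- trace$wavenumber
  if (min(x) > 650 || max(x) < 1700)
    stop_input("classify_redox needs coverage of 650-1700 cm-1")
  sets <- if (which == "mitochondria")
    list(ox = library$mito_oxidized, red = library$mito_reduced)
  else
    list(ox = library$cyt_oxidized, red = library$cyt_reduced)
  S <- cbind(.band_profile(x, sets$ox), .band_profile(x, sets$red))
  fit <- pracma::lsqnonneg(S, trace$intensity)
  coefs <- fit$x
  f_hat <- if (sum(coefs) > 0) coefs[2] / sum(coefs) else NA_real_

  # marker evidence
  nu4 <- peak_maximum(trace, 1363.5, 22.5)      # window spans 1341-1386
  hf <- peak_maximum(trace, 1621.5, 31.5)       # window spans 1590-1653
  r748_level <- tryCatch(peak_ratios(trace)$r748, error = function(e) NA_real_)
  # noise floor: compare peak signal to the scatter in a band-free window
  quiet <- trace$intensity[x >= 820 & x <= 1090]
  noise <- if (length(quiet) > 2) sd(quiet) else 0
  signal <- max(nu4$intensity, hf$intensity)
  low_conf <- is.na(f_hat) || signal < 5 * noise
  state <- if (low_conf || is.na(f_hat)) "mixed"
  else if (f_hat <= 0.3) "oxidized"
  else if (f_hat >= 0.7) "reduced"
  else "mixed"
  structure(list(state = state,
                 reduced_fraction_estimate = f_hat,
                 low_confidence = low_conf,
                 evidence = list(nu4_position = nu4$position,
                                 hf_marker_position = hf$position,
                                 r748 = r748_level)),
            class = "redox_call")
}

#' @export
print.redox_call <- function(x, ...) {
  cat(sprintf("<redox_call> %s (reduced fraction %.3f%s)\n", x$state,
              x$reduced_fraction_estimate,
              if (x$low_confidence) ", low confidence" else ""))
  invisible(x)
}

#' Emulated treatment experiment (FCCP / oligomycin)
#'
#' Generates paired control and treated replicate spectra with the mixture
#' generator (control reduced fraction `f_red_control`, treated fraction
#' shifted by `delta_f`: negative for FCCP-like uncoupling, positive for
#' oligomycin-like ATP-synthase inhibition), runs the full pipeline
#' (baseline subtraction, peak ratios) on every replicate and reports
#' percent-of-control values against the mean control ratios.
#'
#' @param f_red_control control reduced fraction.
#' @param delta_f treatment-induced change; treated fractions are clipped to
#'   `[0, 1]` with a warning.
#' @param n_replicates replicate spectra per arm.
#' @param noise_sd Gaussian noise sd (a.u.).
#' @param seed integer seed; replicate seeds are derived deterministically.
#' @param library band library used for synthesis.
#' @param baseline_knots,baseline_values knots of the synthetic additive
#'   baseline (defaults emulate a gently curved fluorescence background).
#' @param knots [baseline_knots()] used by the subtraction step.
#' @return a `treatment_series`: data frame `ratios` (one row per
#'   replicate and arm), `percent_of_control` matrix (replicates x 3), and
#'   the mean control/treated reports.
#' @export
treatment_series <- function(f_red_control = 0.6, delta_f = -0.3,
                             n_replicates = 10, noise_sd = 0.03, seed = 1,
                             library = band_library(),
                             baseline_knots = c(600, 900, 1200, 1500, 1800),
                             baseline_values = c(1.2, 0.9, 0.75, 0.55, 0.5),
                             knots = default_baseline_knots()) {
  f_trt <- f_red_control + delta_f
  if (f_trt < 0 || f_trt > 1) {
    warning("treated fraction clipped to [0, 1]", call. = FALSE)
    f_trt <- min(max(f_trt, 0), 1)
  }
  one_arm <- function(f, arm, offset) {
    lapply(seq_len(n_replicates), function(i) {
      tr <- mixture_spectrum(f, library = library,
                             baseline_knots = baseline_knots,
                             baseline_values = baseline_values,
                             noise_sd = noise_sd,
                             seed = derive_seed(seed, offset + i))
      peak_ratios(subtract_baseline(tr, knots))
    })
  }
  ctrl <- one_arm(f_red_control, "control", 0L)
  trt <- one_arm(f_trt, "treated", 10000L)
  as_row <- function(r) c(r748 = r$r748, r1170 = r$r1170, r1371 = r$r1371)
  ctrl_m <- t(vapply(ctrl, as_row, numeric(3)))
  trt_m <- t(vapply(trt, as_row, numeric(3)))
  ctrl_mean <- colMeans(ctrl_m)
  poc <- sweep(trt_m, 2, ctrl_mean, "/") * 100
  ratios <- data.frame(arm = rep(c("control", "treated"), each = n_replicates),
                       replicate = rep(seq_len(n_replicates), 2),
                       rbind(ctrl_m, trt_m))
  structure(list(ratios = ratios, percent_of_control = poc,
                 mean_percent = colMeans(poc),
                 f_red_control = f_red_control, f_red_treated = f_trt,
                 seed = seed),
            class = "treatment_series")
}

#' @export
print.treatment_series <- function(x, ...) {
  cat(sprintf("<treatment_series> f_red %.2f -> %.2f, %d replicates\n",
              x$f_red_control, x$f_red_treated, nrow(x$percent_of_control)))
  cat("  mean percent of control:",
      paste(sprintf("%s = %.1f%%", names(x$mean_percent), x$mean_percent),
            collapse = ", "), "\n")
  invisible(x)
}
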