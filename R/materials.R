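#' Analytic dielectric model (Drude-Lorentz)
#'
#' A causal, passive model of a complex relative permittivity,
#' \deqn{\varepsilon(\omega) = \varepsilon_\infty
#'   - \frac{\omega_p^2}{\omega^2 + i\gamma\omega}
#'   + \sum_j \frac{f_j \omega_j^2}{\omega_j^2 - \omega^2 - i\Gamma_j\omega},}
#' under the `exp(-i w t)` time convention (so `Im(eps) >= 0` for passive
#' media). Setting `plasma_frequency = 0` and no Lorentz terms gives a
#' constant (non-dispersive) medium with `eps = eps_inf`.
#'
#' @param eps_inf dimensionless high-frequency limit (may be complex for a
#'   constant lossy medium).
#' @param plasma_frequency Drude plasma frequency, rad/s.
#' @param drude_damping Drude collision rate, rad/s.
#' @param lorentz_terms list of `c(strength, resonance, width)` triples; the
#'   strength is dimensionless, resonance and width are rad/s. Negative
#'   strengths are accepted as correction terms of fitted models provided the
#'   total model stays passive on its validity window.
#' @param name label used in printing and serialization.
#' @param validity_nm wavelength window (nm) over which the parameterization
#'   is trusted; [permittivity()] warns outside it.
#' @return an object of class `dielectric_model`.
#' @seealso [silver_drude_lorentz()], [permittivity()]
#' @export
dielectric_model <- function(eps_inf = 1, plasma_frequency = 0,
                             drude_damping = 0, lorentz_terms = list(),
                             name = "custom", validity_nm = c(300, 1100)) {
  check_scalar(Re(eps_inf), "Re(eps_inf)")
  check_scalar(plasma_frequency, "plasma_frequency")
  check_scalar(drude_damping, "drude_damping")
  lorentz_terms <- lapply(lorentz_terms, function(t) {
    if (length(t) != 3L) stop_input("each Lorentz term needs (strength, resonance, width)")
    as.numeric(t)
  })
  structure(list(eps_inf = as.complex(eps_inf),
                 plasma_frequency = plasma_frequency,
                 drude_damping = drude_damping,
                 lorentz_terms = lorentz_terms,
                 name = name, validity_nm = validity_nm),
            class = "dielectric_model")
}

#' @export
print.dielectric_model <- function(x, ...) {
  cat("<dielectric_model>", x$name, "\n")
  cat("  eps_inf:", format(x$eps_inf), "  plasma:",
      format(x$plasma_frequency, digits = 4), "rad/s  damping:",
      format(x$drude_damping, digits = 4), "rad/s\n")
  cat("  Lorentz terms:", length(x$lorentz_terms),
      "  validity:", paste(x$validity_nm, collapse = "-"), "nm\n")
  invisible(x)
}

#' Drude-Lorentz parameterization of silver
#'
#' Analytic fit of the silver permittivity over 300-1100 nm to the embedded
#' Johnson-Christy tabulation (see [johnson_christy_silver()]). The fit uses a
#' Drude term plus three Lorentz-type correction oscillators; one correction
#' term carries a negative strength (a fit artifact that improves the
#' mid-visible imaginary part while the total model remains passive on the
#' validity window).
#'
#' @return a `dielectric_model` for silver.
#' @export
silver_drude_lorentz <- function() {
  # oscillator parameters fitted in eV, stored in rad/s
  eV <- .rads_per_eV
  dielectric_model(
    eps_inf = 1,
    plasma_frequency = 9.232889577 * eV,
    drude_damping = 0.02326681526 * eV,
    lorentz_terms = list(
      c(2.569742842, 5.705112164 * eV, 0.4823177805 * eV),
      c(-1.667058874, 2.053515014 * eV, 4.074898588 * eV),
      c(0.7917703237, 2.146758759 * eV, 1.860254173 * eV)),
    name = "silver (Drude-Lorentz fit)")
}

#' Constant (non-dispersive) media
#'
#' @param eps relative permittivity (complex allowed).
#' @param name label.
#' @return a `dielectric_model` with no dispersion.
#' @export
constant_medium <- function(eps = 1, name = "constant") {
  dielectric_model(eps_inf = eps, name = name, validity_nm = c(0, Inf))
}

#' @rdname constant_medium
#' @export
vacuum_medium <- function() constant_medium(1, "vacuum")

#' @rdname constant_medium
#' @export
water_medium <- function() constant_medium(1.77, "water")

#' Embedded Johnson-Christy optical constants of silver
#'
#' The classic reflectivity-derived (n, k) tabulation for evaporated silver
#' films, restricted to 0.64-3.74 eV (approximately 332-1937 nm). Used as the
#' interpolation oracle that the analytic fit of [silver_drude_lorentz()] is
#' validated against.
#'
#' @return data frame with columns `wavelength` (nm), `n`, `k`, `eps_re`,
#'   `eps_im`.
#' @export
johnson_christy_silver <- function() {
  eV <- c(0.64, 0.77, 0.89, 1.02, 1.14, 1.26, 1.39, 1.51, 1.64, 1.76, 1.88,
          2.01, 2.13, 2.26, 2.38, 2.50, 2.63, 2.75, 2.88, 3.00, 3.12, 3.25,
          3.37, 3.50, 3.62, 3.74)
  n <- c(0.24, 0.15, 0.13, 0.09, 0.04, 0.04, 0.04, 0.04, 0.03, 0.04, 0.05,
         0.06, 0.05, 0.06, 0.05, 0.05, 0.05, 0.04, 0.04, 0.05, 0.05, 0.05,
         0.07, 0.10, 0.14, 0.17)
  k <- c(14.08, 11.85, 10.10, 8.828, 7.795, 6.992, 6.312, 5.727, 5.242,
         4.838, 4.483, 4.152, 3.858, 3.586, 3.324, 3.093, 2.869, 2.657,
         2.462, 2.275, 2.070, 1.864, 1.657, 1.419, 1.142, 0.829)
  out <- data.frame(wavelength = .hc_eVnm / eV, n = n, k = k,
                    eps_re = n^2 - k^2, eps_im = 2 * n * k)
  out[order(out$wavelength), , drop = FALSE]
}

#' Silver permittivity by table interpolation
#'
#' Linear interpolation (separately on real and imaginary parts) of the
#' embedded Johnson-Christy tabulation. Primarily an independent cross-check
#' for the analytic model.
#'
#' @param wavelength nm, within the tabulated range.
#' @return complex permittivity.
#' @export
silver_permittivity_table <- function(wavelength) {
  check_scalar(wavelength, "wavelength", positive = TRUE)
  tab <- johnson_christy_silver()
  if (wavelength < min(tab$wavelength) || wavelength > max(tab$wavelength))
    stop_input("wavelength outside the tabulated range")
  complex(real = approx(tab$wavelength, tab$eps_re, wavelength)$y,
          imaginary = approx(tab$wavelength, tab$eps_im, wavelength)$y)
}

#' Evaluate a dielectric model at a wavelength
#'
#' @param model a [dielectric_model()].
#' @param wavelength vacuum wavelength, nm (> 0). Warns (once per call)
#'   outside the model's validity window.
#' @return complex relative permittivity with `Im >= 0` on the validity
#'   window (passivity under the `exp(-i w t)` convention).
#' @export
permittivity <- function(model, wavelength) {
  stopifnot(inherits(model, "dielectric_model"))
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop_input("wavelength must be finite and > 0 (nm)")
  v <- model$validity_nm
  if (any(wavelength < v[1] | wavelength > v[2]))
    warning("wavelength outside the ", v[1], "-", v[2],
            " nm validity window of the '", model$name, "' model",
            call. = FALSE)
  w <- 2 * pi * 2.99792458e8 / (wavelength * 1e-9)  # rad/s
  eps <- rep(model$eps_inf, length(w))
  if (model$plasma_frequency > 0)
    eps <- eps - model$plasma_frequency^2 / (w^2 + 1i * model$drude_damping * w)
  for (t in model$lorentz_terms)
    eps <- eps + t[1] * t[2]^2 / (t[2]^2 - w^2 - 1i * t[3] * w)
  eps
}

#' Bundle the optical constants of a simulation
#'
#' @param wavelength vacuum wavelength, nm.
#' @param ambient,substrate [dielectric_model()]s; `substrate = NULL` removes
#'   the interface entirely (free-standing ensemble, no reflected wave, no
#'   image coupling).
#' @return an `optical_constants` object carrying `wavelength`, the vacuum
#'   wavenumber `k0` (rad/nm), the ambient wavenumber `k` (rad/nm), and the
#'   complex ambient/substrate permittivities at `wavelength`.
#' @export
optical_constants <- function(wavelength = 532, ambient = vacuum_medium(),
                              substrate = silver_drude_lorentz()) {
  check_scalar(wavelength, "wavelength", positive = TRUE)
  eps_a <- permittivity(ambient, wavelength)
  if (abs(Im(eps_a)) > 1e-12)
    stop_input("ambient medium must be lossless")
  eps_a <- Re(eps_a)
  if (eps_a < 1) stop_input("ambient permittivity must be >= 1")
  eps_s <- if (is.null(substrate)) NULL else permittivity(substrate, wavelength)
  k0 <- 2 * pi / wavelength
  structure(list(wavelength = wavelength, k0 = k0, k = k0 * sqrt(eps_a),
                 eps_ambient = eps_a, eps_substrate = eps_s,
                 ambient = ambient, substrate = substrate),
            class = "optical_constants")
}

#' Fresnel amplitude reflection coefficient of the substrate
#'
#' Reflection of a plane wave incident from the ambient half-space onto the
#' substrate, for either polarization, under the `exp(-i w t)` convention.
#' Sign conventions are chosen so that in the perfect-conductor limit the
#' total tangential electric field vanishes on the surface for both
#' polarizations (`r_TE -> -1`, `r_TM -> +1` with the TM field vectors used
#' by [external_field()]).
#'
#' @param theta angle of incidence, degrees from the surface normal,
#'   `0 <= theta < 90`.
#' @param polarization `"TM"` (p) or `"TE"` (s).
#' @param eps_ambient real ambient permittivity.
#' @param eps_substrate complex substrate permittivity.
#' @return complex amplitude reflection coefficient, `|r| <= 1` for passive
#'   substrates.
#' @export
fresnel_reflection <- function(theta, polarization = c("TM", "TE"),
                               eps_ambient = 1, eps_substrate) {
  polarization <- match.arg(polarization)
  check_scalar(theta, "theta")
  if (theta < 0 || theta >= 90)
    stop_input("theta must satisfy 0 <= theta < 90 degrees")
  th <- theta * pi / 180
  # with k0 = 1: tangential wavenumber and normal components in both media
  kx <- sqrt(eps_ambient) * sin(th)
  kz1 <- complex_sqrt_upper(eps_ambient - kx^2)
  kz2 <- complex_sqrt_upper(eps_substrate - kx^2)
  if (polarization == "TE") {
    (kz1 - kz2) / (kz1 + kz2)
  } else {
    (eps_substrate * kz1 - eps_ambient * kz2) /
      (eps_substrate * kz1 + eps_ambient * kz2)
  }
}

# Riccati-Bessel functions of order 1 for complex argument
.psi1 <- function(z) sin(z) / z - cos(z)
.psi1p <- function(z) cos(z) / z - sin(z) / z^2 + sin(z)
.xi1 <- function(z) -exp(1i * z) * (1 + 1i / z)
.xi1p <- function(z) exp(1i * z) * (-1i + 1 / z + 1i / z^2)

#' Mie electric-dipole coefficient a1 of a sphere
#'
#' @param radius sphere radius, nm.
#' @param wavelength vacuum wavelength, nm.
#' @param eps_particle,eps_ambient complex/real relative permittivities.
#' @return complex Mie coefficient `a1`.
#' @export
mie_a1 <- function(radius, wavelength, eps_particle, eps_ambient = 1) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(wavelength, "wavelength", positive = TRUE)
  k <- 2 * pi * sqrt(eps_ambient) / wavelength
  x <- k * radius
  m <- complex_sqrt_upper(as.complex(eps_particle) / eps_ambient)
  mx <- m * x
  (m * .psi1(mx) * .psi1p(x) - .psi1(x) * .psi1p(mx)) /
    (m * .psi1(mx) * .xi1p(x) - .xi1(x) * .psi1p(mx))
}

#' Electric-dipole polarizability from Mie theory
#'
#' The sphere's dipole response including retardation and radiative damping,
#' obtained from the Mie coefficient `a1` as
#' \deqn{\alpha = \frac{6\pi i\,\varepsilon_0\varepsilon_{amb}}{k^3} a_1,}
#' with `k` the ambient wavenumber. Units are F nm^2 (SI with lengths in nm),
#' so the induced moment is `p = alpha * E` with `E` in V/nm. A warning is
#' issued once the size parameter `k a` exceeds 1.5, where higher multipoles
#' start to matter.
#'
#' @inheritParams mie_a1
#' @return complex polarizability (F nm^2).
#' @seealso [quasistatic_polarizability()] for the small-particle limit.
#' @export
mie_dipole_polarizability <- function(radius, wavelength, eps_particle,
                                      eps_ambient = 1) {
  check_scalar(radius, "radius", positive = TRUE)
  k <- 2 * pi * sqrt(eps_ambient) / wavelength
  if (k * radius > 1.5)
    warning("size parameter k*a = ", format(k * radius, digits = 3),
            " > 1.5: dipole term alone may be inaccurate", call. = FALSE)
  a1 <- mie_a1(radius, wavelength, eps_particle, eps_ambient)
  6i * pi * .eps0_nm * eps_ambient * a1 / k^3
}

#' Quasi-static (Clausius-Mossotti) polarizability of a sphere
#'
#' \deqn{\alpha = 4\pi\varepsilon_0\varepsilon_{amb} a^3
#'   \frac{\varepsilon_p - \varepsilon_{amb}}
#'        {\varepsilon_p + 2\varepsilon_{amb}}.}
#' No radiative correction; serves as the small-radius limit check of
#' [mie_dipole_polarizability()].
#'
#' @param radius sphere radius, nm.
#' @param eps_particle,eps_ambient relative permittivities.
#' @return complex polarizability (F nm^2).
#' @export
quasistatic_polarizability <- function(radius, eps_particle, eps_ambient = 1) {
  check_scalar(radius, "radius", positive = TRUE)
  denom <- as.complex(eps_particle) + 2 * eps_ambient
  if (abs(denom) < 1e-9)
    stop_input("eps_particle + 2*eps_ambient ~ 0: quasi-static (Frohlich) resonance singularity")
  4 * pi * .eps0_nm * eps_ambient * radius^3 *
    (as.complex(eps_particle) - eps_ambient) / denom
}

#' Read or write material definitions as a config file
#'
#' Materials are stored as a YAML mapping: `name`, `type`
#' (`"drude_lorentz"` or `"constant"`), and numeric parameters. Frequencies
#' are stored in rad/s, matching [dielectric_model()].
#'
#' @param model a `dielectric_model`.
#' @param path file path.
#' @return `read_material()` returns a `dielectric_model`;
#'   `write_material()` returns `path` invisibly.
#' @export
write_material <- function(model, path) {
  stopifnot(inherits(model, "dielectric_model"))
  x <- list(name = model$name,
            type = if (model$plasma_frequency > 0 || length(model$lorentz_terms))
              "drude_lorentz" else "constant",
            eps_inf_re = Re(model$eps_inf), eps_inf_im = Im(model$eps_inf),
            plasma_frequency = model$plasma_frequency,
            drude_damping = model$drude_damping,
            lorentz_terms = lapply(model$lorentz_terms, as.list),
            validity_nm = as.list(model$validity_nm))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_material
#' @export
read_material <- function(path) {
  x <- yaml::read_yaml(path)
  dielectric_model(
    eps_inf = complex(real = x$eps_inf_re, imaginary = x$eps_inf_im %||% 0),
    plasma_frequency = x$plasma_frequency %||% 0,
    drude_damping = x$drude_damping %||% 0,
    lorentz_terms = lapply(x$lorentz_terms, unlist),
    name = x$name %||% "custom",
    validity_nm = unlist(x$validity_nm %||% list(300, 1100)))
}
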