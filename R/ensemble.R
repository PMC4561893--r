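#' Plane-wave illumination
#'
#' @param wavelength vacuum wavelength, nm.
#' @param angle angle of incidence, degrees from the surface normal
#'   (`0 <= angle < 90`). The plane of incidence is the x-z plane; the wave
#'   travels towards the substrate (negative z).
#' @param polarization `"TM"` (p; E in the plane of incidence, has a normal
#'   component at oblique incidence) or `"TE"` (s; E along y).
#' @param amplitude incident field amplitude; kept at 1 since all reported
#'   intensities are relative.
#' @return a `plane_wave` object.
#' @export
plane_wave <- function(wavelength = 532, angle = 0,
                       polarization = c("TM", "TE"), amplitude = 1) {
  polarization <- match.arg(polarization)
  check_scalar(wavelength, "wavelength", positive = TRUE)
  check_scalar(angle, "angle")
  if (angle < 0 || angle >= 90)
    stop_input("angle must satisfy 0 <= angle < 90 degrees")
  structure(list(wavelength = wavelength, angle = angle,
                 polarization = polarization, amplitude = amplitude),
            class = "plane_wave")
}

#' Construct a particle ensemble from explicit positions
#'
#' @param centers n x 3 matrix of centers (nm); substrate surface is z = 0.
#' @param radii vector of radii (nm), recycled.
#' @param optics an [optical_constants()] bundle (wavelength + materials).
#' @param particle_material [dielectric_model()] of the spheres.
#' @param rng_seed integer recorded for provenance (may be NA for manual
#'   configurations).
#' @return an `ensemble` object. Particles must not interpenetrate each
#'   other or the substrate.
#' @export
ensemble <- function(centers, radii, optics = optical_constants(),
                     particle_material = silver_drude_lorentz(),
                     rng_seed = NA_integer_) {
  centers <- as_points(centers)
  radii <- rep_len(as.numeric(radii), nrow(centers))
  if (any(radii <= 0)) stop_input("all radii must be > 0")
  if (any(centers[, 3] < radii - 1e-9))
    stop_input("particles must not interpenetrate the substrate (z >= radius)")
  n <- nrow(centers)
  if (n > 1) {
    dm <- as.matrix(stats::dist(centers))
    rsum <- outer(radii, radii, "+")
    diag(dm) <- Inf
    if (any(dm < rsum - 1e-9))
      stop_input("particles overlap")
  }
  structure(list(centers = centers, radii = radii, optics = optics,
                 particle_material = particle_material, rng_seed = rng_seed),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("<ensemble>", nrow(x$centers), "particles, radii",
      format(min(x$radii), digits = 3), "-", format(max(x$radii), digits = 3),
      "nm, wavelength", x$optics$wavelength, "nm\n")
  invisible(x)
}

#' Generate a random non-overlapping nanoparticle layer on the substrate
#'
#' Seeded rejection sampling: radii uniform in `radius_range`, centers
#' uniform in the `region` rectangle, each sphere resting on the substrate
#' (`z = radius`). A candidate is rejected when any pairwise surface-to-
#' surface gap would fall below `min_gap`. Identical seeds give identical
#' ensembles.
#'
#' @param n number of particles (>= 1).
#' @param radius_range `c(min, max)` radii, nm.
#' @param region `c(Lx, Ly)` dimensions of the placement rectangle, nm
#'   (centered on the origin).
#' @param min_gap minimum surface separation between spheres, nm.
#' @param seed integer RNG seed.
#' @param optics,particle_material as in [ensemble()].
#' @param max_attempts total rejection-sampling budget before a packing
#'   error is raised.
#' @return an `ensemble`.
#' @export
generate_ensemble <- function(n, radius_range = c(20, 25),
                              region = c(600, 600), min_gap = 2, seed = 1,
                              optics = optical_constants(),
                              particle_material = silver_drude_lorentz(),
                              max_attempts = 1e5) {
  check_scalar(n, "n", positive = TRUE)
  if (n != round(n)) stop_input("n must be an integer")
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    stop_input("radius_range must be c(min, max) with 0 < min <= max")
  if (length(region) != 2L || any(region <= 0))
    stop_input("region must be c(Lx, Ly) with positive extents")
  rmax <- radius_range[2]
  # conservative area feasibility check for random (non-lattice) packing
  if (n * pi * (rmax + min_gap / 2)^2 > 0.45 * prod(region))
    stop_input("packing infeasible: requested particles exceed ~45% area coverage")
  set.seed(as.integer(seed))
  centers <- matrix(NA_real_, n, 3)
  radii <- numeric(n)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_input("packing failed after ", max_attempts, " attempts")
    r <- runif(1, radius_range[1], radius_range[2])
    xy <- c(runif(1, -region[1] / 2, region[1] / 2),
            runif(1, -region[2] / 2, region[2] / 2))
    cand <- c(xy, r)
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE], 2, cand)^2))
      ok <- all(d >= radii[seq_len(placed)] + r + min_gap - 1e-12)
    }
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      radii[placed] <- r
    }
  }
  ensemble(centers, radii, optics = optics,
           particle_material = particle_material, rng_seed = as.integer(seed))
}
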