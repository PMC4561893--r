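#' External driving field above the substrate
#'
#' Superposition of the incident plane wave and its Fresnel reflection from
#' the bare substrate (no particles), evaluated with the correct propagation
#' phase at each point. With `eps_substrate = NULL` in `optics` only the
#' incident wave is returned. TE fields are purely in-plane (along y); TM
#' fields have in-plane (x) and, at oblique incidence, normal (z)
#' components.
#'
#' @param points a length-3 position or an n x 3 matrix (nm), `z >= 0`.
#' @param wave a [plane_wave()].
#' @param optics an [optical_constants()] bundle; its wavelength must match
#'   the wave's.
#' @return complex n x 3 matrix of field values (incident amplitude = 1).
#' @export
external_field <- function(points, wave, optics = optical_constants()) {
  stopifnot(inherits(wave, "plane_wave"), inherits(optics, "optical_constants"))
  if (abs(wave$wavelength - optics$wavelength) > 1e-9)
    stop_input("wave and optics wavelengths differ")
  points <- as_points(points)
  if (any(points[, 3] < 0)) stop_input("external_field requires z >= 0")
  th <- wave$angle * pi / 180
  k <- optics$k                      # ambient wavenumber, rad/nm
  kx <- k * sin(th)
  kz <- k * cos(th)
  r <- if (is.null(optics$eps_substrate)) 0i else
    fresnel_reflection(wave$angle, wave$polarization,
                       optics$eps_ambient, optics$eps_substrate)
  phase_in <- exp(1i * (kx * points[, 1] - kz * points[, 3]))
  phase_re <- exp(1i * (kx * points[, 1] + kz * points[, 3]))
  if (wave$polarization == "TE") {
    e_in <- c(0, 1, 0); e_re <- c(0, 1, 0)
  } else {
    e_in <- c(cos(th), 0, sin(th))
    e_re <- c(-cos(th), 0, sin(th))
  }
  wave$amplitude * (outer(phase_in, e_in) + r * outer(phase_re, e_re))
}

# reduced polarizabilities alpha/eps0 (nm^3) of every particle at the
# ensemble's wavelength
.reduced_alphas <- function(ens) {
  eps_p <- permittivity(ens$particle_material, ens$optics$wavelength)
  vapply(ens$radii, function(a)
    mie_dipole_polarizability(a, ens$optics$wavelength, eps_p,
                              ens$optics$eps_ambient) / .eps0_nm,
    complex(1))
}

#' Solve the coupled-dipole equations for an ensemble
#'
#' Assembles and solves the dense 3N x 3N linear system
#' \deqn{p_i = \alpha_i\Big[E_{in}(r_i)
#'   + \tfrac{k_0^2}{\varepsilon_0}\sum_{j\ne i} \hat G(r_i, r_j)\,p_j
#'   + \tfrac{k_0^2}{\varepsilon_0}\hat G_s(r_i, r_i)\,p_i\Big],}
#' where `G = G0 + Gs` couples distinct particles through free space and
#' through the substrate-reflected (image) field, and the self-term `Gs(ri,
#' ri)` is the particle's interaction with its own image. The free-space
#' self-term is excluded: its radiative part is already contained in the Mie
#' polarizability. Direct dense solve; intended for N up to a few hundred.
#'
#' @param ens an [ensemble()].
#' @param wave a [plane_wave()] at the ensemble's wavelength.
#' @return a `dipole_solution` with `moments` (N x 3 complex, SI units
#'   C nm), `moments_reduced` (`p/eps0`, used internally for field
#'   evaluation), the relative `residual_norm` of the linear solve and a
#'   reciprocal-condition estimate `rcond`.
#' @export
solve_dipoles <- function(ens, wave) {
  stopifnot(inherits(ens, "ensemble"))
  n <- nrow(ens$centers)
  opt <- ens$optics
  k0sq <- opt$k0^2
  alph <- .reduced_alphas(ens)
  E_in <- external_field(ens$centers, wave, opt)
  A <- diag(3 * n) + 0i
  b <- complex(3 * n)
  for (i in seq_len(n)) {
    ri <- ens$centers[i, ]
    ii <- (3 * i - 2):(3 * i)
    b[ii] <- alph[i] * E_in[i, ]
    if (!is.null(opt$eps_substrate)) {
      gs <- surface_self_term(ri, opt$k, opt$eps_ambient, opt$eps_substrate)
      A[ii, ii] <- A[ii, ii] - alph[i] * k0sq * gs
    }
    for (j in seq_len(n)) {
      if (j == i) next
      g <- total_green(ri, ens$centers[j, ], opt$k,
                       opt$eps_ambient, opt$eps_substrate)
      jj <- (3 * j - 2):(3 * j)
      A[ii, jj] <- A[ii, jj] - alph[i] * k0sq * g
    }
  }
  rc <- tryCatch(1 / kappa(A, exact = FALSE), error = function(e) NA_real_)
  p_bar <- tryCatch(solve(A, b), error = function(e)
    stop_input("coupled-dipole system is singular (rcond ~ ",
               format(rc, digits = 3),
               "); resonant polarizability/geometry combination"))
  resid <- sqrt(sum(Mod(A %*% p_bar - b)^2)) / max(sqrt(sum(Mod(b)^2)), 1e-300)
  structure(list(moments = matrix(p_bar, n, 3, byrow = TRUE) * .eps0_nm,
                 moments_reduced = matrix(p_bar, n, 3, byrow = TRUE),
                 residual_norm = resid, rcond = rc, wave = wave),
            class = "dipole_solution")
}

#' @export
print.dipole_solution <- function(x, ...) {
  cat("<dipole_solution>", nrow(x$moments), "dipoles, residual",
      format(x$residual_norm, digits = 3), "\n")
  invisible(x)
}

#' Total electric field on a set of points
#'
#' `E(r) = E_in(r) + (k0^2/eps0) sum_i [G0(r, ri) + Gs(r, ri)] p_i`. Points
#' lying inside any particle are masked (`NA`) with a warning: the
#' point-dipole field is not valid there.
#'
#' @param ens the [ensemble()] that was solved.
#' @param solution the matching [solve_dipoles()] result.
#' @param points n x 3 matrix of evaluation points (nm, `z >= 0`).
#' @return a `field_grid`: `points`, complex `field` (n x 3), and
#'   `intensity = |E|^2` per point (relative to the incident intensity).
#' @export
total_field <- function(ens, solution, points) {
  stopifnot(inherits(ens, "ensemble"), inherits(solution, "dipole_solution"))
  points <- as_points(points)
  opt <- ens$optics
  inside <- rep(FALSE, nrow(points))
  for (i in seq_len(nrow(ens$centers))) {
    d <- sqrt(rowSums(sweep(points, 2, ens$centers[i, ])^2))
    inside <- inside | d < ens$radii[i]
  }
  if (any(inside))
    warning(sum(inside), " evaluation point(s) inside particles masked",
            call. = FALSE)
  E <- external_field(points, solution$wave, opt)
  k0sq <- opt$k0^2
  for (i in seq_len(nrow(ens$centers))) {
    p_bar <- solution$moments_reduced[i, ]
    src <- ens$centers[i, ]
    E <- E + .dipole_field(points, src, p_bar, opt$k, k0sq)
    if (!is.null(opt$eps_substrate)) {
      beta <- image_reflection_factor(opt$eps_ambient, opt$eps_substrate)
      p_img <- beta * c(-p_bar[1], -p_bar[2], p_bar[3])
      E <- E + .dipole_field(points, c(src[1], src[2], -src[3]), p_img,
                             opt$k, k0sq)
    }
  }
  E[inside, ] <- NA_complex_
  structure(list(points = points, field = E,
                 intensity = rowSums(Mod(E)^2)),
            class = "field_grid")
}

#' Background field grid (no particles)
#'
#' Convenience wrapper: external field and its intensity on the same points,
#' for use as the denominator of enhancement maps.
#'
#' @inheritParams total_field
#' @param wave a [plane_wave()].
#' @param optics an [optical_constants()].
#' @return a `field_grid`.
#' @export
background_field <- function(points, wave, optics = optical_constants()) {
  points <- as_points(points)
  E <- external_field(points, wave, optics)
  structure(list(points = points, field = E,
                 intensity = rowSums(Mod(E)^2)),
            class = "field_grid")
}

#' Rectangular evaluation grid at fixed height
#'
#' @param z plane height above the substrate, nm.
#' @param region `c(Lx, Ly)` lateral extents, nm (centered on the origin).
#' @param nx,ny number of grid points per axis.
#' @return n x 3 matrix of points.
#' @export
plane_grid <- function(z, region = c(600, 600), nx = 41, ny = 41) {
  x <- seq(-region[1] / 2, region[1] / 2, length.out = nx)
  y <- seq(-region[2] / 2, region[2] / 2, length.out = ny)
  cbind(rep(x, times = ny), rep(y, each = nx), z)
}

#' Intensity-enhancement statistics of a field map
#'
#' Pointwise ratio `|E_total|^2 / |E_background|^2` summarized by its mean
#' and maximum. Points where the background intensity vanishes (TM null
#' planes) or where the total field is masked are excluded with a warning.
#'
#' @param grid,background matching [total_field()] / [background_field()]
#'   results on identical point sets.
#' @return list with `mean_enhancement`, `max_enhancement`, `n_used`.
#' @export
enhancement_summary <- function(grid, background) {
  stopifnot(inherits(grid, "field_grid"), inherits(background, "field_grid"))
  if (!isTRUE(all.equal(grid$points, background$points)))
    stop_input("grid and background must share the same points")
  ratio <- grid$intensity / background$intensity
  bad <- !is.finite(ratio) | background$intensity < 1e-12
  if (any(bad))
    warning(sum(bad), " point(s) with vanishing background or masked field excluded",
            call. = FALSE)
  ratio <- ratio[!bad]
  list(mean_enhancement = mean(ratio), max_enhancement = max(ratio),
       n_used = length(ratio))
}

#' Laterally averaged intensity versus height above the particle layer
#'
#' Probes how the near-field intensity decays with distance from the top of
#' the nanoparticle layer -- e.g. across the 7-17 nm band where cytochrome c
#' resides between the outer mitochondrial membrane and the intermembrane
#' space.
#'
#' The total intensity contains the incident/reflected standing wave, which
#' oscillates with height; the scattered-field intensity
#' (`mean_scattered`) isolates the particle contribution and decays
#' monotonically far above the layer.
#'
#' @param ens solved [ensemble()].
#' @param solution matching [solve_dipoles()] result.
#' @param heights heights above the top of the particle layer, nm (>= 0).
#' @param region lateral extents of the averaging plane, nm.
#' @param nx,ny lateral grid resolution.
#' @return data frame with columns `height`, `z` (absolute),
#'   `mean_intensity` (total), `mean_scattered` (`|E - E_in|^2`) and
#'   `mean_enhancement` (ratio to the particle-free background).
#' @export
field_vs_height <- function(ens, solution, heights, region = c(600, 600),
                            nx = 31, ny = 31) {
  if (any(heights < 0)) stop_input("heights must be >= 0")
  top <- max(ens$centers[, 3] + ens$radii)
  rows <- lapply(heights, function(h) {
    pts <- plane_grid(top + h, region, nx, ny)
    g <- total_field(ens, solution, pts)
    E_bg <- external_field(pts, solution$wave, ens$optics)
    i_bg <- rowSums(Mod(E_bg)^2)
    data.frame(height = h, z = top + h,
               mean_intensity = mean(g$intensity, na.rm = TRUE),
               mean_scattered = mean(rowSums(Mod(g$field - E_bg)^2),
                                     na.rm = TRUE),
               mean_enhancement = mean((g$intensity / i_bg)[i_bg > 1e-12],
                                       na.rm = TRUE))
  })
  do.call(rbind, rows)
}
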