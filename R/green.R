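#' Free-space electric dyadic Green tensor
#'
#' The homogeneous-medium tensor (units 1/nm) in the convention
#' `E(r) = (k0^2/eps0) G(r, r') p`, containing the near- (1/R^3),
#' intermediate- (1/R^2) and far-field (1/R) terms:
#' \deqn{G = \frac{e^{ikR}}{4\pi R}\Big[(1 + \tfrac{i}{kR} - \tfrac{1}{(kR)^2}) I
#'   + (-1 - \tfrac{3i}{kR} + \tfrac{3}{(kR)^2})\,\hat n \hat n^T\Big].}
#' Satisfies reciprocity `G(r, r') = t(G(r', r))` and reduces to the static
#' dyadic `(3 n n^T - I) / (4 pi k^2 R^3)` for `kR << 1`.
#'
#' @param r,r_prime field and source points, nm (length-3).
#' @param k ambient wavenumber, rad/nm.
#' @return complex 3x3 matrix (1/nm).
#' @export
free_space_green <- function(r, r_prime, k) {
  r <- check_point(r); r_prime <- check_point(r_prime, "r_prime")
  check_scalar(k, "k", positive = TRUE)
  d <- r - r_prime
  R <- sqrt(sum(d^2))
  if (R < 1e-9) stop_input("free_space_green is singular at coincident points")
  n <- d / R
  kR <- k * R
  A <- 1 + 1i / kR - 1 / kR^2
  B <- -1 - 3i / kR + 3 / kR^2
  (exp(1i * kR) / (4 * pi * R)) * (A * diag(3) + B * tcrossprod(n))
}

#' Quasi-static image reflection factor of the interface
#'
#' `beta = (eps_sub - eps_amb) / (eps_sub + eps_amb)`; 1 in the
#' perfect-conductor limit, 0 when there is no dielectric contrast.
#'
#' @param eps_ambient,eps_substrate relative permittivities.
#' @return complex scalar.
#' @export
image_reflection_factor <- function(eps_ambient, eps_substrate) {
  (as.complex(eps_substrate) - eps_ambient) /
    (as.complex(eps_substrate) + eps_ambient)
}

# mirror matrix applied to a source dipole to form its image:
# in-plane components flip sign, the normal component is preserved
.image_mirror <- function(beta) diag(c(-beta, -beta, beta))

#' Substrate-reflected dyadic Green tensor (image approximation)
#'
#' Field reflected by the substrate, modelled by an image dipole below the
#' interface: the source at `(x', y', z')` is mirrored to `(x', y', -z')`
#' and its moment mapped to `beta * (-p_x, -p_y, +p_z)` with the
#' quasi-static reflection factor `beta` of [image_reflection_factor()].
#' In the perfect-conductor limit an in-plane dipole and its image are
#' antiparallel while a normal dipole and its image are parallel. The image
#' field then propagates with the free-space tensor. This approximation is
#' accurate for sub-wavelength heights; the interface is defined so an exact
#' Sommerfeld-integral backend could replace it without touching callers.
#'
#' @param r,r_prime field and source points, both with `z > 0` (the substrate
#'   occupies `z <= 0`).
#' @param k ambient wavenumber, rad/nm.
#' @param eps_ambient,eps_substrate relative permittivities of the two
#'   half-spaces.
#' @return complex 3x3 matrix (1/nm).
#' @export
reflected_green <- function(r, r_prime, k, eps_ambient = 1, eps_substrate) {
  r <- check_point(r); r_prime <- check_point(r_prime, "r_prime")
  if (r[3] <= 0 || r_prime[3] <= 0)
    stop_input("reflected_green requires both points above the substrate (z > 0)")
  beta <- image_reflection_factor(eps_ambient, eps_substrate)
  if (abs(beta) == 0) return(matrix(0i, 3, 3))
  image <- c(r_prime[1], r_prime[2], -r_prime[3])
  free_space_green(r, image, k) %*% .image_mirror(beta)
}

#' Particle-substrate self-interaction tensor
#'
#' The reflected tensor evaluated with the field point at the source point:
#' the particle's own image, at distance `2 z`, acts back on it. Finite for
#' any `z > 0`, diagonal in the surface frame, and scaling as `1/z^3` in the
#' quasi-static regime, with the normal (zz) element twice the in-plane one.
#'
#' @param r_i particle position, `z > 0`.
#' @inheritParams reflected_green
#' @return complex 3x3 matrix (1/nm).
#' @export
surface_self_term <- function(r_i, k, eps_ambient = 1, eps_substrate) {
  r_i <- check_point(r_i, "r_i")
  if (r_i[3] <= 0)
    stop_input("surface_self_term requires z > 0")
  reflected_green(r_i, r_i, k, eps_ambient, eps_substrate)
}

#' Total propagation tensor used by the coupled-dipole solver
#'
#' Sum of the free-space and substrate-reflected tensors; with
#' `eps_substrate = NULL` only the free-space part is returned.
#'
#' @inheritParams reflected_green
#' @return complex 3x3 matrix (1/nm).
#' @export
total_green <- function(r, r_prime, k, eps_ambient = 1, eps_substrate = NULL) {
  g <- free_space_green(r, r_prime, k)
  if (!is.null(eps_substrate))
    g <- g + reflected_green(r, r_prime, k, eps_ambient, eps_substrate)
  g
}

# Vectorized field of one point dipole (reduced moment p_bar = p/eps0, in
# E-units * nm^3) at many field points: E = k0^2 * G0(r, src) p_bar.
# Used by the field evaluator; kept separate from the 3x3 tensor API.
.dipole_field <- function(points, src, p_bar, k, k0sq) {
  d <- sweep(points, 2, src)
  R <- sqrt(rowSums(d^2))
  bad <- R < 1e-9
  R[bad] <- NA_real_
  n <- d / R
  kR <- k * R
  A <- 1 + 1i / kR - 1 / kR^2
  B <- -1 - 3i / kR + 3 / kR^2
  ndotp <- as.vector(n %*% p_bar)
  pref <- k0sq * exp(1i * kR) / (4 * pi * R)
  E <- pref * (A * matrix(p_bar, nrow(points), 3, byrow = TRUE) + B * ndotp * n)
  E[bad, ] <- NA_complex_
  E
}
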