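# Independent oracles used across the suite. These deliberately re-derive
# quantities through different code paths than the package implementation.

# --- spherical Bessel functions by power series (independent of the
# closed trigonometric forms used in the package) ---------------------------
.ddfact <- function(n) prod(seq(n, 1, by = -2))

j0_series <- function(z, terms = 40) {
  s <- 0:terms
  sum((-z^2 / 2)^s / (factorial(s) * vapply(2 * s + 1, .ddfact, numeric(1))))
}

j1_series <- function(z, terms = 40) {
  s <- 0:terms
  z / 3 * sum((-z^2 / 2)^s * 3 / (factorial(s) * vapply(2 * s + 3, .ddfact, numeric(1))))
}

psi1_series <- function(z) z * j1_series(z)
psi1p_series <- function(z) z * j0_series(z) - j1_series(z)
chi1_trig <- function(z) cos(z) / z + sin(z)
chi1p_trig <- function(z) -sin(z) / z - cos(z) / z^2 + cos(z)

# Mie electric-dipole coefficient via the series path
mie_a1_oracle <- function(radius, wavelength, eps_particle, eps_ambient = 1) {
  k <- 2 * pi * sqrt(eps_ambient) / wavelength
  x <- k * radius
  m <- sqrt(as.complex(eps_particle) / eps_ambient)
  if (Im(m) < 0) m <- -m
  mx <- m * x
  num <- m * psi1_series(mx) * psi1p_series(x) -
    psi1_series(x) * psi1p_series(mx)
  den <- m * psi1_series(mx) *
    (psi1p_series(x) - 1i * chi1p_trig(x)) -
    (psi1_series(x) - 1i * chi1_trig(x)) * psi1p_series(mx)
  num / den
}

# --- free-space dyadic Green tensor assembled element-by-element -----------
green0_oracle <- function(r, rp, k) {
  d <- r - rp
  R <- sqrt(sum(d^2))
  n <- d / R
  kR <- k * R
  g <- matrix(0i, 3, 3)
  for (a in 1:3) for (b in 1:3) {
    del <- as.numeric(a == b)
    g[a, b] <- exp(1i * kR) / (4 * pi * R) *
      (del * (1 + 1i / kR - 1 / kR^2) +
         n[a] * n[b] * (-1 - 3i / kR + 3 / kR^2))
  }
  g
}

# image tensor from first principles: mirror the source, flip in-plane
# moment components, scale by the quasi-static reflection factor
green_image_oracle <- function(r, rp, k, eps_amb, eps_sub) {
  beta <- (eps_sub - eps_amb) / (eps_sub + eps_amb)
  g0 <- green0_oracle(r, c(rp[1], rp[2], -rp[3]), k)
  g0 %*% diag(c(-beta, -beta, beta))
}

# --- two-term Born (order-of-scattering) series, free space ----------------
born_two_term <- function(centers, alphas_reduced, E_in, k0, k) {
  n <- nrow(centers)
  p0 <- lapply(seq_len(n), function(i) alphas_reduced[i] * E_in[i, ])
  lapply(seq_len(n), function(i) {
    scat <- c(0i, 0i, 0i)
    for (j in seq_len(n)[-i])
      scat <- scat + k0^2 * green0_oracle(centers[i, ], centers[j, ], k) %*% p0[[j]]
    alphas_reduced[i] * (E_in[i, ] + as.vector(scat))
  })
}

# --- direct inversion of the coupled-dipole equations with the unknowns
# grouped by Cartesian component (different assembly path), solved by QR ----
cdm_direct_oracle <- function(centers, alphas_reduced, E_in, k0, k,
                              eps_amb = NULL, eps_sub = NULL) {
  n <- nrow(centers)
  M <- diag(3 * n) + 0i
  rhs <- complex(3 * n)
  idx <- function(a, i) (a - 1) * n + i   # component-major ordering
  for (i in seq_len(n)) {
    gs <- if (!is.null(eps_sub))
      green_image_oracle(centers[i, ], centers[i, ], k, eps_amb, eps_sub)
    else matrix(0i, 3, 3)
    for (a in 1:3) {
      rhs[idx(a, i)] <- alphas_reduced[i] * E_in[i, a]
      for (b in 1:3)
        M[idx(a, i), idx(b, i)] <- M[idx(a, i), idx(b, i)] -
          alphas_reduced[i] * k0^2 * gs[a, b]
    }
    for (j in seq_len(n)[-i]) {
      g <- green0_oracle(centers[i, ], centers[j, ], k)
      if (!is.null(eps_sub))
        g <- g + green_image_oracle(centers[i, ], centers[j, ], k, eps_amb, eps_sub)
      for (a in 1:3) for (b in 1:3)
        M[idx(a, i), idx(b, j)] <- M[idx(a, i), idx(b, j)] -
          alphas_reduced[i] * k0^2 * g[a, b]
    }
  }
  u <- qr.solve(M, rhs)
  t(vapply(seq_len(n), function(i) u[c(idx(1, i), idx(2, i), idx(3, i))],
           complex(3)))
}

# --- standalone incident + reflected plane-wave sum ------------------------
two_wave_oracle <- function(point, wavelength, angle_deg, polarization,
                            eps_amb = 1, eps_sub) {
  th <- angle_deg * pi / 180
  n1 <- sqrt(eps_amb)
  n2 <- sqrt(as.complex(eps_sub))
  if (Im(n2) < 0) n2 <- -n2
  cos_t <- sqrt(1 - (n1 / n2)^2 * sin(th)^2)
  if (polarization == "TM") {
    r <- (n2 * cos(th) - n1 * cos_t) / (n2 * cos(th) + n1 * cos_t)
    e_in <- c(cos(th), 0, sin(th)); e_re <- c(-cos(th), 0, sin(th))
  } else {
    r <- (n1 * cos(th) - n2 * cos_t) / (n1 * cos(th) + n2 * cos_t)
    e_in <- c(0, 1, 0); e_re <- c(0, 1, 0)
  }
  k <- 2 * pi * n1 / wavelength
  kx <- k * sin(th); kz <- k * cos(th)
  e_in * exp(1i * (kx * point[1] - kz * point[3])) +
    r * e_re * exp(1i * (kx * point[1] + kz * point[3]))
}

# on-axis field of a vertical dipole (closed form): only the z-component
# survives on the axis, with the longitudinal near/intermediate terms
onaxis_vertical_dipole_Ez <- function(dz, p_bar_z, k0, k) {
  kR <- k * abs(dz)
  k0^2 * exp(1i * kR) / (4 * pi * abs(dz)) * (2 / kR^2 - 2i / kR) * p_bar_z
}
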