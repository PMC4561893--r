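`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(name, " must be a single finite number")
  if (positive && x <= 0)
    stop_input(name, " must be > 0")
  invisible(x)
}

check_point <- function(r, name = "r") {
  if (!is.numeric(r) || length(r) != 3L || any(!is.finite(r)))
    stop_input(name, " must be a numeric (x, y, z) triple")
  as.numeric(r)
}

# coerce a point or an n x 3 matrix of points to matrix form
as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  if (ncol(points) != 3L) stop_input("points must have 3 columns (x, y, z)")
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  points
}

complex_sqrt_upper <- function(z) {
  # principal square root, then flip to the Im >= 0 branch (decaying waves
  # under the exp(-i w t) convention)
  s <- sqrt(as.complex(z))
  flip <- Im(s) < 0
  s[flip] <- -s[flip]
  s
}

# deterministic seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}
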