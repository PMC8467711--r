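# Shared fixtures built in code.

# random symmetric positive-definite 3x3 matrix
rand_spd <- function() {
  a <- matrix(stats::rnorm(9), 3L)
  crossprod(a) + diag(3) * 0.1
}

# tensor field holding arbitrary 6-component rows on a tiny grid
tf_from_rows <- function(rows, quantity = "diffusion_mm2_per_s",
                         grid = NULL) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  if (is.null(grid)) grid <- c(nrow(rows), 1L, 1L)
  tensor_field(rows, quantity = quantity, grid = grid)
}

# 6-component row of a symmetric matrix
row_of <- function(m) c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])

# full matrix from a 6-component row
sym_of <- function(v) matrix(c(v[1], v[2], v[3],
                               v[2], v[4], v[5],
                               v[3], v[5], v[6]), 3L, 3L)

# random 3-D rotation matrix
rand_rotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3L))) * sample(c(-1, 1), 1L)
}

# eigenvalues by the characteristic-polynomial root oracle (independent of
# the eigen() path used by the package)
eig_cubic_oracle <- function(m) {
  tr <- sum(diag(m))
  m2 <- sum(diag(m)^2 * 0) +  # second invariant: sum of principal 2x2 minors
    (m[1, 1] * m[2, 2] - m[1, 2]^2) +
    (m[1, 1] * m[3, 3] - m[1, 3]^2) +
    (m[2, 2] * m[3, 3] - m[2, 3]^2)
  dt <- det(m)
  r <- polyroot(c(-dt, m2, -tr, 1))
  sort(Re(r), decreasing = TRUE)
}

# small phantom truth used by several files (kept tiny for speed)
small_phantom <- function(preset = "phantom1", grid = c(20, 20, 6)) {
  make_phantom(phantom_presets(preset), grid = grid)
}
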