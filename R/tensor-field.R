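# Symmetric 3x3 tensor fields -------------------------------------------------
#
# A tensor field stores one symmetric 3x3 matrix per voxel as its 6 unique
# components.  The component order is fixed throughout the package:
#
#     1 = xx, 2 = xy, 3 = xz, 4 = yy, 5 = yz, 6 = zz
#
# Unit convention ("units ledger"):
#   * diffusivities are always mm^2/s, b-values s/mm^2,
#   * conductivities are always S/m,
#   * scale factors eta that multiply a diffusion tensor into a conductivity
#     tensor therefore carry units S.s/(m.mm^2).

#' Component order of stored tensors
#'
#' The fixed order of the six unique components of a symmetric 3x3 tensor as
#' stored in a [tensor_field()].
#' @return Character vector `c("xx","xy","xz","yy","yz","zz")`.
#' @export
tensor_component_order <- function() c("xx", "xy", "xz", "yy", "yz", "zz")

# row/column index of each stored component in the full 3x3 matrix
.tf_comp_idx <- cbind(i = c(1L, 1L, 1L, 2L, 2L, 3L),
                      j = c(1L, 2L, 3L, 2L, 3L, 3L))

#' Quantity tags understood by tensor fields
#' @return Character vector of valid `quantity` values.
#' @export
tensor_quantities <- function() c("diffusion_mm2_per_s", "conductivity_S_per_m")

#' Create a per-voxel symmetric 3x3 tensor field
#'
#' @param values Numeric array of dimension `c(grid, 6)` where `grid` is the
#'   3-D voxel grid, with the six unique tensor components in the order
#'   given by [tensor_component_order()].  A matrix of dimension `n x 6`
#'   with an explicit `grid` argument is also accepted.
#' @param quantity One of [tensor_quantities()]; arithmetic never mixes
#'   quantities (a diffusion field cannot be scaled into place of a
#'   conductivity field without an explicit model).
#' @param mask Logical array of the grid dimensions flagging valid voxels;
#'   defaults to all `TRUE`.
#' @param voxel_size_mm Numeric length-3 voxel edge lengths in mm.
#' @param grid Optional integer length-3 grid dimensions when `values` is a
#'   plain matrix.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(values, quantity, mask = NULL,
                         voxel_size_mm = c(1, 1, 1), grid = NULL) {
  quantity <- match.arg(quantity, tensor_quantities())
  if (is.matrix(values)) {
    if (is.null(grid)) stop("`grid` is required when `values` is a matrix")
    stopifnot(ncol(values) == 6L, nrow(values) == prod(grid))
    dim(values) <- c(grid, 6L)
  }
  d <- dim(values)
  if (length(d) != 4L || d[4] != 6L)
    stop("`values` must be a 4-D array with 6 tensor components last")
  grid <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  stopifnot(identical(dim(mask), as.integer(grid)) ||
              identical(dim(mask), grid))
  values <- array(as.double(values), d)   # drop stray attributes
  structure(list(values = values,
                 grid = as.integer(grid),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 quantity = quantity,
                 mask = array(as.logical(mask), grid)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s, grid %s, %d/%d voxels in mask\n",
              x$quantity, paste(x$grid, collapse = "x"),
              sum(x$mask), prod(x$grid)))
  invisible(x)
}

#' Tensor components as a voxels-by-6 matrix
#'
#' @param field A [tensor_field()].
#' @return Numeric matrix `n_voxels x 6` in the order of
#'   [tensor_component_order()] (voxels in array order).
#' @export
tensor_values <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  tf_mat(field)
}

# flatten values to an n-voxel x 6 matrix
tf_mat <- function(field) {
  v <- field$values
  dim(v) <- c(prod(field$grid), 6L)
  v
}

# replace values of `field` with an n x 6 matrix, preserving metadata
tf_with_values <- function(field, m, quantity = field$quantity,
                           mask = field$mask) {
  dim(m) <- c(field$grid, 6L)
  tensor_field(m, quantity = quantity, mask = mask,
               voxel_size_mm = field$voxel_size_mm)
}

# expand one 3x3 symmetric matrix to its 6-component row
sym_to_comp <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

# rebuild the full 3x3 matrix of one voxel from a 6-component row
comp_to_sym <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3L, 3L)
}

stop_quantity_mismatch <- function(a, b) {
  if (!identical(a$quantity, b$quantity))
    stop(sprintf("quantity mismatch: %s vs %s", a$quantity, b$quantity))
}

stop_grid_mismatch <- function(a, b) {
  ga <- if (inherits(a, "tensor_field")) a$grid else dim(a)
  gb <- if (inherits(b, "tensor_field")) b$grid else dim(b)
  if (!identical(as.integer(ga), as.integer(gb)))
    stop("inputs are not on the same voxel grid")
}

#' Per-voxel eigendecomposition of a tensor field
#'
#' Factorises every masked-in tensor as `S diag(l1,l2,l3) S^T` with
#' eigenvalues sorted in descending order (longitudinal first) and an
#' orthonormal eigenvector triad.  Masked-out voxels carry `NA` sentinels.
#'
#' Eigenvalues in `[-tol * lmax, 0)` are clamped to zero (numerical noise on
#' positive semidefinite input); more negative eigenvalues raise an error
#' unless `clamp` is set large enough by the caller.
#'
#' @param field A [tensor_field()].
#' @param clamp Relative tolerance below which negative eigenvalues are
#'   clamped to zero (default `1e-12` of the largest eigenvalue magnitude).
#' @return An object of class `eigen_field` with elements `values`
#'   (`grid x 3` descending eigenvalues), `vectors` (`grid x 3 x 3`; last
#'   index enumerates eigenvectors, second-to-last their components),
#'   `quantity`, `mask`, `grid`.
#' @export
eig_decompose <- function(field, clamp = 1e-12) {
  stopifnot(inherits(field, "tensor_field"))
  m <- tf_mat(field)
  n <- nrow(m)
  idx <- which(as.vector(field$mask))
  bad <- idx[!is.finite(rowSums(m[idx, , drop = FALSE]))]
  if (length(bad))
    stop(sprintf("non-finite tensor entries at masked-in voxel(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  vals <- matrix(NA_real_, n, 3L)
  vecs <- array(NA_real_, c(n, 3L, 3L))
  for (k in idx) {
    e <- eigen(comp_to_sym(m[k, ]), symmetric = TRUE)  # descending order
    lam <- e$values
    lmax <- max(abs(lam), .Machine$double.xmin)
    neg <- lam < 0
    if (any(lam < -clamp * lmax))
      stop(sprintf("tensor at voxel %d is not positive semidefinite (min eigenvalue %.3e)",
                   k, min(lam)))
    lam[neg] <- 0
    vals[k, ] <- lam
    vecs[k, , ] <- e$vectors
  }
  structure(list(values = array(vals, c(field$grid, 3L)),
                 vectors = array(vecs, c(field$grid, 3L, 3L)),
                 grid = field$grid,
                 voxel_size_mm = field$voxel_size_mm,
                 quantity = field$quantity,
                 mask = field$mask),
            class = "eigen_field")
}

#' @export
print.eigen_field <- function(x, ...) {
  cat(sprintf("<eigen_field> %s, grid %s\n", x$quantity,
              paste(x$grid, collapse = "x")))
  invisible(x)
}

#' Recompose a tensor field from its eigendecomposition
#'
#' Inverse of [eig_decompose()] up to eigenvalue ordering and eigenvector
#' sign: rebuilds `S diag(lambda) S^T` per voxel.
#'
#' @param eig An `eigen_field`.
#' @param tol Orthonormality tolerance on the eigenvector triad.
#' @return A [tensor_field()].
#' @export
compose_tensor <- function(eig, tol = 1e-8) {
  stopifnot(inherits(eig, "eigen_field"))
  n <- prod(eig$grid)
  vals <- eig$values; dim(vals) <- c(n, 3L)
  vecs <- eig$vectors; dim(vecs) <- c(n, 3L, 3L)
  out <- matrix(NA_real_, n, 6L)
  for (k in which(as.vector(eig$mask))) {
    s <- matrix(vecs[k, , ], 3L, 3L)
    if (max(abs(crossprod(s) - diag(3))) > tol)
      stop(sprintf("eigenvector triad at voxel %d is not orthonormal", k))
    out[k, ] <- sym_to_comp(s %*% (vals[k, ] * t(s)))
  }
  tensor_field(out, quantity = eig$quantity, mask = eig$mask,
               voxel_size_mm = eig$voxel_size_mm, grid = eig$grid)
}

#' Mean scalar (trace/3) of a tensor field
#'
#' The rotation-invariant mean of the three eigenvalues,
#' `(l1 + l2 + l3)/3 = trace/3`.  For a conductivity tensor this is the
#' mean conductivity `sigma_L`; for a diffusion tensor the mean diffusivity.
#'
#' @param field A [tensor_field()].
#' @return Numeric 3-D array on the field grid; `NA` outside the mask.
#' @export
mean_scalar <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  m <- tf_mat(field)
  out <- (m[, 1L] + m[, 4L] + m[, 6L]) / 3
  out[!as.vector(field$mask)] <- NA_real_
  array(out, field$grid)
}

#' Per-voxel trace of a tensor field
#' @param field A [tensor_field()].
#' @return Numeric 3-D array of `xx + yy + zz`; `NA` outside the mask.
#' @export
tensor_trace <- function(field) 3 * mean_scalar(field)

#' Anisotropy ratio of a tensor field
#'
#' `AR = 2 l1 / (l2 + l3)` with descending eigenvalues: the longitudinal
#' eigenvalue over the mean transversal one.  Equals 1 for isotropic
#' tensors and is invariant to rotation and to scalar rescaling, so a
#' conductivity tensor built as `eta * D` with per-voxel scalar `eta` has
#' exactly the anisotropy ratio of `D`.
#'
#' @param field A [tensor_field()] or an `eigen_field`.
#' @return Numeric 3-D array; voxels whose transversal eigenvalue sum is
#'   zero receive `NA` with a warning.
#' @export
anisotropy_ratio <- function(field) {
  eig <- if (inherits(field, "eigen_field")) field else eig_decompose(field)
  vals <- eig$values
  dim(vals) <- c(prod(eig$grid), 3L)
  tsum <- vals[, 2L] + vals[, 3L]
  zero <- as.vector(eig$mask) & !is.na(tsum) & tsum == 0
  if (any(zero)) {
    warning(sprintf("%d voxel(s) with zero transversal eigenvalue sum set to NA",
                    sum(zero)))
    tsum[zero] <- NA_real_
  }
  array(2 * vals[, 1L] / tsum, eig$grid)
}

#' Quadratic form u' T u of a tensor field along a direction
#'
#' @param field A [tensor_field()].
#' @param u Numeric length-3 direction (unit norm not required).
#' @return Numeric 3-D array of the per-voxel quadratic form.
#' @export
tensor_quadform <- function(field, u) {
  m <- tf_mat(field)
  q <- u[1]^2 * m[, 1L] + 2 * u[1] * u[2] * m[, 2L] + 2 * u[1] * u[3] * m[, 3L] +
    u[2]^2 * m[, 4L] + 2 * u[2] * u[3] * m[, 5L] + u[3]^2 * m[, 6L]
  array(q, field$grid)
}

#' Scale a tensor field voxelwise into another physical quantity
#'
#' Multiplies every tensor by a scalar (global or per voxel) and re-tags the
#' quantity.  This is the shared primitive behind the linear cross-property
#' models `C = eta * D`.
#'
#' @param field Input [tensor_field()].
#' @param eta Scalar or 3-D array of per-voxel scale factors.
#' @param quantity Quantity tag of the result.
#' @return A [tensor_field()] of the requested quantity.
#' @export
tensor_scale <- function(field, eta, quantity = field$quantity) {
  m <- tf_mat(field)
  if (length(eta) == 1L) {
    m <- m * as.numeric(eta)
  } else {
    stopifnot(identical(dim(eta), as.integer(field$grid)) ||
                identical(dim(eta), field$grid))
    m <- m * as.vector(eta)
  }
  tf_with_values(field, m, quantity = quantity)
}

# Clamp slightly negative eigenvalues of fitted tensors to zero (PSD policy).
# Voxels violating PSD beyond `hard` relative tolerance raise an error.
psd_clamp <- function(field, soft = 1e-12, hard = Inf) {
  m <- tf_mat(field)
  out <- m
  for (k in which(as.vector(field$mask))) {
    e <- eigen(comp_to_sym(m[k, ]), symmetric = TRUE)
    lam <- e$values
    lmax <- max(abs(lam), .Machine$double.xmin)
    if (min(lam) < -hard * lmax)
      stop(sprintf("fitted tensor at voxel %d is strongly non-PSD", k))
    if (any(lam < 0)) {
      lam[lam < 0] <- 0
      out[k, ] <- sym_to_comp(e$vectors %*% (lam * t(e$vectors)))
    }
  }
  tf_with_values(field, out)
}
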