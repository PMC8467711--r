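# Conductivity tensor reconstruction models -----------------------------------
#
# All five models share the premise that the conductivity tensor C and the
# water diffusion tensor D have the same eigenvectors, and all but the
# volume fraction model are per-voxel scalar scalings C = eta * D:
#
#   LEM  eta global: empirical constant, or matched to two reference
#        tissues by least squares,
#   FEM  eta global: microscopic force-equilibrium constant applied to the
#        fast (extracellular) diffusion tensor,
#   VCM  eta per voxel: trace-constrained so trace(C) = 3 sigma_iso,
#   VFM  no eta: eigenvalues as volume-fraction-weighted sums of
#        literature compartment conductivities (WM only),
#   CTI  eta per voxel from the high-frequency conductivity and the
#        bi-exponential water compartment estimates.

# S.s/mm^3 -> S.s/(m.mm^2): conductivities are kept in S/m while
# diffusivities stay in mm^2/s, so published "per mm" scale factors gain a
# factor 1000 on ingestion.
.eta_mm3_to_internal <- 1000

#' Literature constants used by the reconstruction models
#'
#' Bundles every tunable constant consumed by the five models.  Tissue
#' conductivities and the force-equilibrium microscopic constants are
#' published values; the volume-fraction-model compartment constants are
#' configurable stand-ins for values cited to prior work (documented as
#' such), with a single transversal WM conductivity (`vfm_sigma_tW`)
#' reflecting the enforced transversal symmetry.
#'
#' @param sigma_wm,sigma_gm,sigma_csf Isotropic tissue conductivities, S/m
#'   (defaults 0.14, 0.27, 1.79).
#' @param eta_empirical Empirical global scale factor of the linear
#'   eigenvalue model, in S.s/mm^3 (default 0.844); converted internally to
#'   S.s/(m.mm^2) by a factor 1000.
#' @param q Elementary charge, C (1.6e-19).
#' @param N Charge carrier number density, 1/m^3 (2e25).
#' @param kBT Thermal energy, J (4.1e-21).
#' @param fem_prefactor Dimensionless prefactor of the force-equilibrium
#'   relation (0.76).
#' @param beta Intracellular-to-extracellular ion concentration ratio
#'   (default 0.41).
#' @param vfm_sigma_lW,vfm_sigma_tW,vfm_sigma_iso WM longitudinal/
#'   transversal and isotropic-compartment conductivities, S/m.
#' @param vfm_d_lW,vfm_d_tW,vfm_d_iso Matching literature diffusivities,
#'   mm^2/s.
#' @param vfm_b b-value at which the volume-fraction system is evaluated,
#'   s/mm^2 (default 700, the tensor shell).
#' @return Object of class `literature_constants` (a validated list).
#' @export
literature_constants <- function(sigma_wm = 0.14, sigma_gm = 0.27,
                                 sigma_csf = 1.79,
                                 eta_empirical = 0.844,
                                 q = 1.6e-19, N = 2e25, kBT = 4.1e-21,
                                 fem_prefactor = 0.76,
                                 beta = 0.41,
                                 vfm_sigma_lW = 0.65, vfm_sigma_tW = 0.13,
                                 vfm_sigma_iso = 0.27,
                                 vfm_d_lW = 1.7e-3, vfm_d_tW = 0.3e-3,
                                 vfm_d_iso = 0.8e-3,
                                 vfm_b = 700) {
  consts <- list(sigma_wm = sigma_wm, sigma_gm = sigma_gm,
                 sigma_csf = sigma_csf, eta_empirical = eta_empirical,
                 q = q, N = N, kBT = kBT, fem_prefactor = fem_prefactor,
                 beta = beta,
                 vfm_sigma_lW = vfm_sigma_lW, vfm_sigma_tW = vfm_sigma_tW,
                 vfm_sigma_iso = vfm_sigma_iso,
                 vfm_d_lW = vfm_d_lW, vfm_d_tW = vfm_d_tW,
                 vfm_d_iso = vfm_d_iso, vfm_b = vfm_b)
  pos <- c("sigma_wm", "sigma_gm", "sigma_csf", "eta_empirical", "q", "N",
           "kBT", "fem_prefactor", "vfm_sigma_lW", "vfm_sigma_tW",
           "vfm_sigma_iso", "vfm_d_lW", "vfm_d_tW", "vfm_d_iso", "vfm_b")
  for (nm in pos) if (consts[[nm]] <= 0) stop(nm, " must be positive")
  if (!(beta > 0 && beta <= 1)) stop("beta must be in (0, 1]")
  structure(consts, class = "literature_constants")
}

#' Matched global scale factor of the linear eigenvalue model
#'
#' Least-squares scale matching the conductivity ellipsoid to two reference
#' tissues: `eta = (dWM sWM + dGM sGM) / (dWM^2 + dGM^2)` with `dWM`, `dGM`
#' the ROI means of mean diffusivity (mm^2/s).  For phantoms the two tissue
#' conductivities are replaced by measured compartment conductivities via
#' `sigma_a`/`sigma_b`.
#'
#' @param dWM,dGM Mean diffusivities of the two reference regions (mm^2/s).
#' @param consts [literature_constants()].
#' @param sigma_a,sigma_b Reference conductivities (S/m); default the WM and
#'   GM literature values.
#' @return Scalar `eta` in S.s/(m.mm^2).
#' @export
lem_scale_factor <- function(dWM, dGM, consts = literature_constants(),
                             sigma_a = consts$sigma_wm,
                             sigma_b = consts$sigma_gm) {
  if (!is.finite(dWM) || !is.finite(dGM) || dWM <= 0 || dGM <= 0)
    stop("dWM and dGM must be positive (empty tissue mask?)")
  (dWM * sigma_a + dGM * sigma_b) / (dWM^2 + dGM^2)
}

#' Linear eigenvalue model reconstruction
#'
#' `C = eta * D` with a global scale factor: either the empirical constant
#' (0.844 S.s/mm^3, converted to internal units), or a subject-matched
#' factor computed by [lem_scale_factor()] from two reference-region mean
#' diffusivities.
#'
#' @param D Diffusion [tensor_field()].
#' @param mode `"empirical"` or `"matched"`.
#' @param masks For matched mode: list of two logical arrays (reference
#'   regions, e.g. WM and GM).
#' @param consts [literature_constants()].
#' @param sigma_refs For matched mode: conductivities of the two reference
#'   regions (default literature WM/GM).
#' @return Conductivity [tensor_field()] with attribute `eta` (the global
#'   factor, S.s/(m.mm^2)).
#' @export
reconstruct_lem <- function(D, mode = c("empirical", "matched"),
                            masks = NULL, consts = literature_constants(),
                            sigma_refs = c(consts$sigma_wm, consts$sigma_gm)) {
  mode <- match.arg(mode)
  stopifnot(inherits(D, "tensor_field"),
            identical(D$quantity, "diffusion_mm2_per_s"))
  if (mode == "empirical") {
    eta <- consts$eta_empirical * .eta_mm3_to_internal
  } else {
    if (is.null(masks) || length(masks) != 2L)
      stop("matched mode requires a list of two reference-region masks")
    md <- mean_scalar(D)
    d1 <- mean(md[masks[[1]] & D$mask])
    d2 <- mean(md[masks[[2]] & D$mask])
    eta <- unname(lem_scale_factor(d1, d2, consts,
                                   sigma_a = sigma_refs[1],
                                   sigma_b = sigma_refs[2]))
  }
  out <- tensor_scale(D, eta, quantity = "conductivity_S_per_m")
  attr(out, "eta") <- eta
  attr(out, "model") <- "LEM"
  out
}

#' Global scale factor of the force equilibrium model
#'
#' `eta = 0.76 q^2 N / (kB T)` from the Stokes-Einstein relation and the
#' balance of electric and viscous forces on a charge carrier; independent
#' of the data.  In SI this is S.s/m^3 (about 9.49e7 with the default
#' constants); multiplied by 1e-6 it scales diffusivities in mm^2/s to S/m.
#'
#' @param consts [literature_constants()].
#' @param units `"internal"` (S.s/(m.mm^2), default) or `"SI"` (S.s/m^3).
#' @return Scalar `eta`.
#' @export
fem_scale_factor <- function(consts = literature_constants(),
                             units = c("internal", "SI")) {
  units <- match.arg(units)
  eta_si <- consts$fem_prefactor * consts$q^2 * consts$N / consts$kBT
  if (units == "SI") eta_si else eta_si * 1e-6
}

#' Force equilibrium model reconstruction
#'
#' `C = eta_FEM * Df` with the global microscopic constant of
#' [fem_scale_factor()] applied to the fast (extracellular) diffusion
#' tensor from the bi-exponential fit.
#'
#' @param Df Fast diffusion [tensor_field()] (e.g. `fit$Df` from
#'   [assemble_fast_slow()]).
#' @param consts [literature_constants()].
#' @return Conductivity [tensor_field()] with attribute `eta`.
#' @export
reconstruct_fem <- function(Df, consts = literature_constants()) {
  stopifnot(inherits(Df, "tensor_field"),
            identical(Df$quantity, "diffusion_mm2_per_s"))
  eta <- fem_scale_factor(consts)
  out <- tensor_scale(Df, eta, quantity = "conductivity_S_per_m")
  attr(out, "eta") <- eta
  attr(out, "model") <- "FEM"
  out
}

#' Volume constraint model reconstruction
#'
#' `C = (3 sigma_iso / trace(D)) * D` per voxel, so that
#' `trace(C) = 3 sigma_iso` exactly: the mean conductivity is pinned to the
#' assigned isotropic value while the anisotropy comes from `D`.
#'
#' @param D Diffusion [tensor_field()].
#' @param sigma_iso A single value, a 3-D array of per-voxel values, or a
#'   named numeric vector of per-region values combined with `masks`.
#' @param masks Named list of logical region masks matching the names of
#'   `sigma_iso` when per-region values are given.
#' @return Conductivity [tensor_field()] with attribute `eta` (per-voxel
#'   array); zero-trace voxels are masked out with a warning.
#' @export
reconstruct_vcm <- function(D, sigma_iso, masks = NULL) {
  stopifnot(inherits(D, "tensor_field"),
            identical(D$quantity, "diffusion_mm2_per_s"))
  grid <- D$grid
  if (!is.null(masks)) {
    stopifnot(!is.null(names(sigma_iso)),
              all(names(masks) %in% names(sigma_iso)))
    smap <- array(NA_real_, grid)
    for (nm in names(masks)) smap[masks[[nm]]] <- sigma_iso[[nm]]
  } else if (length(sigma_iso) == 1L) {
    smap <- array(as.numeric(sigma_iso), grid)
  } else {
    stopifnot(identical(dim(sigma_iso), as.integer(grid)) ||
                identical(dim(sigma_iso), grid))
    smap <- sigma_iso
  }
  tr <- tensor_trace(D)
  mask <- D$mask & !is.na(smap)
  zero <- mask & (is.na(tr) | tr <= 0)
  if (any(zero)) {
    warning(sprintf("%d zero-trace voxel(s) masked out", sum(zero)))
    mask <- mask & !zero
  }
  eta <- array(NA_real_, grid)
  eta[mask] <- 3 * smap[mask] / tr[mask]
  etav <- eta
  etav[!mask] <- 0
  out <- tensor_scale(D, etav, quantity = "conductivity_S_per_m")
  out$mask <- mask
  attr(out, "eta") <- eta
  attr(out, "model") <- "VCM"
  out
}

#' Solve the volume-fraction system for one or many eigenvalue triples
#'
#' The measured mono-exponential decays along the three eigen-directions
#' are matched to a four-compartment mixture (three orthogonal WM fiber
#' groups plus isotropic tissue).  Fixing the literature diffusivities
#' makes the system linear in the three fiber fractions:
#' the exponentials of the literature rates form a constant 3x3 matrix and
#' `exp(-b d_m) - exp(-b d_iso)` the right-hand side.  Solutions are
#' clipped to the simplex; voxels needing clipping beyond `flag_tol` are
#' flagged ill-posed.
#'
#' @param d_eigs Numeric length-3 vector `(dl, dt1, dt2)` or an `n x 3`
#'   matrix of descending diffusion eigenvalues (mm^2/s).
#' @param consts [literature_constants()] (uses `vfm_d_lW`, `vfm_d_tW`,
#'   `vfm_d_iso`, `vfm_b`).
#' @param flag_tol Simplex violation beyond which a voxel is flagged.
#' @return Matrix with columns `al`, `at1`, `at2`, `aiso` and logical
#'   attribute `flagged`.
#' @export
solve_vfm_fractions <- function(d_eigs, consts = literature_constants(),
                                flag_tol = 1e-6) {
  if (is.null(dim(d_eigs))) d_eigs <- matrix(d_eigs, nrow = 1L)
  stopifnot(ncol(d_eigs) == 3L)
  b <- consts$vfm_b
  el <- exp(-b * consts$vfm_d_lW)
  et <- exp(-b * consts$vfm_d_tW)
  e0 <- exp(-b * consts$vfm_d_iso)
  M <- matrix(c(el - e0, et - e0, et - e0,
                et - e0, el - e0, et - e0,
                et - e0, et - e0, el - e0), 3L, 3L, byrow = TRUE)
  if (abs(det(M)) < .Machine$double.eps * 10)
    stop("volume-fraction coefficient matrix is singular; adjust literature diffusivities")
  rhs <- exp(-b * d_eigs) - e0        # n x 3
  a <- t(solve(M, t(rhs)))            # n x 3 fractions
  aiso <- 1 - rowSums(a)
  raw <- cbind(a, aiso)
  flagged <- apply(raw, 1L, function(r) any(r < -flag_tol | r > 1 + flag_tol)) |
    !is.finite(rowSums(raw))
  a <- pmin(pmax(a, 0), 1)
  s <- rowSums(a)
  over <- s > 1
  if (any(over)) a[over, ] <- a[over, , drop = FALSE] / s[over]
  aiso <- pmax(0, 1 - rowSums(a))
  out <- cbind(al = a[, 1L], at1 = a[, 2L], at2 = a[, 3L], aiso = aiso)
  attr(out, "flagged") <- flagged
  out
}

#' Volume fraction model reconstruction
#'
#' WM voxels: the diffusion eigenvalues are decomposed into fractions of
#' three orthogonal fiber groups plus isotropic tissue
#' ([solve_vfm_fractions()]); conductivity eigenvalues are the matching
#' weighted sums of the literature compartment conductivities, with the
#' two transversal conductivities constrained equal (their Eq.-style
#' weighted sums are averaged), and the eigenvectors are copied from `D`.
#' GM and CSF voxels get isotropic literature values.  This is the one
#' model that is not a scalar scaling of `D`, and the transversal
#' constraint lowers the anisotropy ratio wherever the diffusion
#' transversal eigenvalues differ.
#'
#' @param D Diffusion [tensor_field()].
#' @param masks Named list with logical arrays `WM`, `GM`, `CSF`.
#' @param consts [literature_constants()].
#' @return Conductivity [tensor_field()] with attributes `fractions`
#'   (per-WM-voxel matrix) and `flagged` (ill-posed voxel count).
#' @export
reconstruct_vfm <- function(D, masks, consts = literature_constants()) {
  stopifnot(inherits(D, "tensor_field"),
            identical(D$quantity, "diffusion_mm2_per_s"))
  if (is.null(masks$WM) || is.null(masks$GM) || is.null(masks$CSF))
    stop("masks must contain WM, GM and CSF")
  grid <- D$grid
  n <- prod(grid)
  eig <- eig_decompose(D)
  vals <- eig$values; dim(vals) <- c(n, 3L)
  vecs <- eig$vectors; dim(vecs) <- c(n, 3L, 3L)
  out <- matrix(0, n, 6L)
  mask <- D$mask & (masks$WM | masks$GM | masks$CSF)

  widx <- which(as.vector(masks$WM & mask))
  frac <- NULL
  nflag <- 0L
  if (length(widx)) {
    frac <- solve_vfm_fractions(vals[widx, , drop = FALSE], consts)
    nflag <- sum(attr(frac, "flagged"))
    sl <- frac[, "al"] * consts$vfm_sigma_lW +
      (frac[, "at1"] + frac[, "at2"]) * consts$vfm_sigma_tW +
      frac[, "aiso"] * consts$vfm_sigma_iso
    # transversal weighted sums under sigma_t1W = sigma_t2W, then averaged
    # to enforce the transversal-equality constraint exactly
    st1 <- frac[, "al"] * consts$vfm_sigma_tW +
      frac[, "at1"] * consts$vfm_sigma_lW +
      frac[, "at2"] * consts$vfm_sigma_tW +
      frac[, "aiso"] * consts$vfm_sigma_iso
    st2 <- frac[, "al"] * consts$vfm_sigma_tW +
      frac[, "at1"] * consts$vfm_sigma_tW +
      frac[, "at2"] * consts$vfm_sigma_lW +
      frac[, "aiso"] * consts$vfm_sigma_iso
    st <- (st1 + st2) / 2
    for (k in seq_along(widx)) {
      v <- matrix(vecs[widx[k], , ], 3L, 3L)
      out[widx[k], ] <- sym_to_comp(v %*% (c(sl[k], st[k], st[k]) * t(v)))
    }
  }
  for (tis in c("GM", "CSF")) {
    sidx <- which(as.vector(masks[[tis]] & mask))
    sig <- if (tis == "GM") consts$sigma_gm else consts$sigma_csf
    out[sidx, c(1L, 4L, 6L)] <- sig
  }
  res <- tensor_field(out, quantity = "conductivity_S_per_m", mask = mask,
                      voxel_size_mm = D$voxel_size_mm, grid = grid)
  attr(res, "fractions") <- frac
  attr(res, "flagged") <- nflag
  attr(res, "model") <- "VFM"
  res
}

#' Apparent extracellular ion concentration from the high-frequency map
#'
#' Inverts the high-frequency forward relation:
#' `ce = sigma_H / (alpha*dew + (1-alpha)*diw*beta)` per voxel.
#'
#' @param sigmaH 3-D array of high-frequency conductivity (S/m).
#' @param alpha,dew,diw 3-D arrays (or scalars) of the extracellular volume
#'   fraction and fast/slow diffusivities (mm^2/s).
#' @param beta Ion concentration ratio (> 0), default 0.41.
#' @return 3-D array of `ce` (concentration-like units); zero-denominator
#'   voxels are `NA` with a warning.
#' @export
estimate_ce <- function(sigmaH, alpha, dew, diw, beta = 0.41) {
  if (beta <= 0) stop("beta must be positive")
  den <- alpha * dew + (1 - alpha) * diw * beta
  zero <- !is.na(den) & den == 0
  if (any(zero)) {
    warning(sprintf("%d voxel(s) with zero denominator masked", sum(zero)))
    den[zero] <- NA_real_
  }
  sigmaH / den
}

#' Conductivity tensor imaging reconstruction
#'
#' Per voxel, `eta = alpha * sigma_H / (alpha*dew + (1-alpha)*diw*beta)`
#' and `C = eta * De`, with `De` the fast diffusion tensor and `alpha`,
#' `dew`, `diw` the bi-exponential compartment estimates.  Unlike the
#' global-scale models, `eta` varies with the measured high-frequency
#' conductivity, so compartments with equal diffusion but different ion
#' concentration are distinguished.
#'
#' @param sigmaH 3-D array of high-frequency conductivity (S/m).
#' @param fit A `biexp_fit` from [assemble_fast_slow()] (fields `Df`,
#'   `alpha`, `dew`, `diw`).
#' @param beta Ion concentration ratio, default 0.41.
#' @return Conductivity [tensor_field()] with attribute `eta` (per-voxel
#'   array) and `ce` (the apparent ion concentration map).
#' @export
reconstruct_cti <- function(sigmaH, fit, beta = 0.41) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (!identical(dim(sigmaH), as.integer(fit$grid)) &&
      !identical(dim(sigmaH), fit$grid))
    stop("sigmaH is not on the fit grid")
  ce <- estimate_ce(sigmaH, fit$alpha, fit$dew, fit$diw, beta)
  eta <- fit$alpha * ce
  etav <- eta
  etav[is.na(etav)] <- 0
  out <- tensor_scale(fit$Df, etav, quantity = "conductivity_S_per_m")
  out$mask <- out$mask & !is.na(eta)
  attr(out, "eta") <- eta
  attr(out, "ce") <- ce
  attr(out, "model") <- "CTI"
  out
}
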