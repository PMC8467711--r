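# Synthetic phantoms, brain-like objects and forward simulation ---------------
#
# The generator states a known world: per-voxel extracellular diffusion
# tensor De, intracellular diffusivity diw, extracellular volume fraction
# alpha and apparent extracellular ion concentration ce.  From these it
# derives, in forward form, the quantities every reconstruction consumes:
#
#   C_true  = alpha * ce * De                      (low-frequency tensor)
#   sigma_H = ce * (alpha*dew + (1-alpha)*diw*beta) (high-frequency scalar)
#
# with dew = trace(De)/3.  ce carries arbitrary concentration units fixed by
# anchoring mean(C_true) to each compartment's reference conductivity.

#' Default multi-b protocol b-values
#'
#' The fifteen diffusion-weighting strengths of the simulated protocol,
#' spanning 50 to 5000 s/mm^2.
#' @return Numeric vector of b-values (s/mm^2).
#' @export
default_bvalues <- function() {
  c(50, 150, 300, 500, 700, 1000, 1400, 1800, 2200, 2600,
    3000, 3600, 4000, 4500, 5000)
}

#' Deterministic well-spread gradient directions
#'
#' Fibonacci-hemisphere construction: unit vectors spread over the upper
#' hemisphere, adequate for tensor fitting for any `n >= 6`.
#'
#' @param n Number of directions (default 15, the in vivo protocol size).
#' @return `n x 3` matrix of unit vectors.
#' @export
default_directions <- function(n = 15L) {
  stopifnot(n >= 1L)
  k <- seq_len(n) - 1L
  z <- (k + 0.5) / n
  golden <- pi * (3 - sqrt(5))
  phi <- k * golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Specify one phantom compartment
#'
#' A compartment is an electrolyte or a giant-vesicle suspension (an
#' electrolyte crowded with thin insulating membranes) with a known
#' composition and a reference low-frequency conductivity measured at 10 Hz.
#'
#' @param name Compartment label.
#' @param nacl_g_per_L NaCl concentration (g/L); sets the ion concentration.
#' @param extracellular_volume_fraction Fraction `alpha` in (0, 1]; pure
#'   electrolytes have `alpha = 1`.
#' @param mobility_class `"high"` or `"low"`; selects the default
#'   extracellular diffusivity unless `dew_mm2_per_s` is given.
#' @param sigma_ref_S_per_m Reference conductivity at 10 Hz (S/m).
#' @param cuso4_g_per_L CuSO4 dopant concentration (g/L); recorded only.
#' @param dew_mm2_per_s Extracellular (fast) water diffusivity; defaults to
#'   2.0e-3 for high and 1.1e-3 mm^2/s for low mobility.
#' @param diw_mm2_per_s Intracellular (slow) water diffusivity
#'   (default 0.4e-3 mm^2/s; irrelevant when `alpha = 1`).
#' @param shape Optional geometry, a list
#'   `list(center = c(x, y) [fractions of the grid], radius = r [fraction])`;
#'   assigned automatically by [make_phantom()] when `NULL`.
#' @return Object of class `compartment_spec`.
#' @export
compartment_spec <- function(name, nacl_g_per_L,
                             extracellular_volume_fraction,
                             mobility_class = c("high", "low"),
                             sigma_ref_S_per_m,
                             cuso4_g_per_L = 0,
                             dew_mm2_per_s = NULL,
                             diw_mm2_per_s = 0.4e-3,
                             shape = NULL) {
  mobility_class <- match.arg(mobility_class)
  if (is.null(dew_mm2_per_s))
    dew_mm2_per_s <- if (mobility_class == "high") 2.0e-3 else 1.1e-3
  a <- extracellular_volume_fraction
  if (!(a > 0 && a <= 1)) stop("extracellular_volume_fraction must be in (0, 1]")
  if (!(dew_mm2_per_s >= diw_mm2_per_s && diw_mm2_per_s >= 0))
    stop("need dew >= diw >= 0")
  if (sigma_ref_S_per_m <= 0) stop("sigma_ref_S_per_m must be positive")
  structure(list(name = name,
                 nacl_g_per_L = nacl_g_per_L,
                 cuso4_g_per_L = cuso4_g_per_L,
                 extracellular_volume_fraction = a,
                 mobility_class = mobility_class,
                 sigma_ref_S_per_m = sigma_ref_S_per_m,
                 dew_mm2_per_s = dew_mm2_per_s,
                 diw_mm2_per_s = diw_mm2_per_s,
                 shape = shape),
            class = "compartment_spec")
}

#' Built-in phantom compartment presets
#'
#' Two three-compartment phantoms: phantom 1 varies NaCl concentration at
#' fixed (high) mobility, phantom 2 varies mobility at fixed concentration;
#' each includes one giant-vesicle suspension with reduced extracellular
#' volume fraction.
#'
#' @param preset `"phantom1"` (EL1, EL2, GVS1) or `"phantom2"`
#'   (EL3, EL4, GVS2).
#' @return List of [compartment_spec()] objects.
#' @export
phantom_presets <- function(preset = c("phantom1", "phantom2")) {
  preset <- match.arg(preset)
  if (preset == "phantom1") {
    list(
      compartment_spec("EL1", nacl_g_per_L = 7.5,
                       extracellular_volume_fraction = 1,
                       mobility_class = "high", sigma_ref_S_per_m = 1.56),
      compartment_spec("EL2", nacl_g_per_L = 3.5, cuso4_g_per_L = 1,
                       extracellular_volume_fraction = 1,
                       mobility_class = "high", sigma_ref_S_per_m = 0.83),
      compartment_spec("GVS1", nacl_g_per_L = 7.5,
                       extracellular_volume_fraction = 0.10,
                       mobility_class = "high", sigma_ref_S_per_m = 0.29))
  } else {
    list(
      compartment_spec("EL3", nacl_g_per_L = 3,
                       extracellular_volume_fraction = 1,
                       mobility_class = "low", sigma_ref_S_per_m = 0.55),
      compartment_spec("EL4", nacl_g_per_L = 3,
                       extracellular_volume_fraction = 1,
                       mobility_class = "high", sigma_ref_S_per_m = 0.70),
      compartment_spec("GVS2", nacl_g_per_L = 3,
                       extracellular_volume_fraction = 0.50,
                       mobility_class = "low", sigma_ref_S_per_m = 0.45))
  }
}

# assemble a ground_truth object from per-voxel primitive maps
.ground_truth <- function(De, diw_map, alpha_map, ce_map, labels,
                          label_names, beta, spec_sheet = NULL) {
  dew_map <- mean_scalar(De)
  mask <- De$mask
  n <- prod(De$grid)
  scale <- as.vector(alpha_map) * as.vector(ce_map)
  C <- tf_mat(De) * scale
  C_true <- tensor_field(C, quantity = "conductivity_S_per_m", mask = mask,
                         voxel_size_mm = De$voxel_size_mm, grid = De$grid)
  sigmaH <- as.vector(ce_map) *
    (as.vector(alpha_map) * as.vector(dew_map) +
       (1 - as.vector(alpha_map)) * as.vector(diw_map) * beta)
  structure(list(D_true = De,           # extracellular diffusion tensor De
                 C_true = C_true,
                 alpha_map = alpha_map,
                 diw_map = diw_map,
                 dew_map = dew_map,
                 ce_map = ce_map,
                 sigmaH_map = array(sigmaH, De$grid),
                 labels = labels,
                 label_names = label_names,
                 beta = beta,
                 mask = mask,
                 grid = De$grid,
                 voxel_size_mm = De$voxel_size_mm,
                 spec_sheet = spec_sheet),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> grid %s, %d region(s): %s\n",
              paste(x$grid, collapse = "x"), length(x$label_names),
              paste(x$label_names, collapse = ", ")))
  invisible(x)
}

#' Masks of each labelled region of a ground-truth object
#' @param truth A `ground_truth`.
#' @return Named list of logical arrays, one per region label.
#' @export
truth_masks <- function(truth) {
  out <- lapply(seq_along(truth$label_names),
                function(i) array(truth$labels == i, truth$grid))
  names(out) <- truth$label_names
  out
}

#' Build a synthetic multi-compartment conductivity phantom
#'
#' Places the compartments as parallel cylinders (axis along z) in an
#' otherwise masked-out grid and derives every ground-truth map.  The
#' apparent extracellular ion concentration of each compartment is
#' back-solved so that the mean of its true conductivity tensor equals the
#' compartment's reference conductivity, which anchors the arbitrary
#' concentration units to the 10 Hz reference measurements.
#'
#' @param specs List of [compartment_spec()]s (e.g. [phantom_presets()]).
#' @param grid Integer length-3 grid dimensions.
#' @param beta Intracellular-to-extracellular ion concentration ratio used
#'   in the high-frequency forward relation (default 0.41).
#' @param voxel_size_mm Voxel edge lengths.
#' @param seed Accepted for interface symmetry; the phantom construction is
#'   deterministic and does not consume randomness.
#' @return A `ground_truth` object; its `spec_sheet` element is a data frame
#'   restating every compartment parameter actually used.
#' @export
make_phantom <- function(specs, grid = c(64, 64, 16), beta = 0.41,
                         voxel_size_mm = c(1, 1, 1), seed = NULL) {
  stopifnot(length(grid) == 3L, all(grid[1:2] >= 8L), grid[3] >= 3L)
  grid <- as.integer(grid)
  default_centers <- list(c(0.28, 0.30), c(0.72, 0.30), c(0.50, 0.72))
  if (length(specs) > 3L && any(vapply(specs, function(s) is.null(s$shape),
                                       logical(1))))
    stop("more than 3 compartments requires explicit shapes")
  n <- prod(grid)
  labels <- array(0L, grid)
  alpha_map <- array(NA_real_, grid)
  diw_map <- array(NA_real_, grid)
  ce_map <- array(NA_real_, grid)
  Dm <- matrix(NA_real_, n, 6L)
  ix <- (slice.index(labels, 1L) - 0.5) / grid[1]
  iy <- (slice.index(labels, 2L) - 0.5) / grid[2]
  iz <- slice.index(labels, 3L)
  zmargin <- max(1L, round(0.08 * grid[3]))
  sheet <- list()
  for (s in seq_along(specs)) {
    sp <- specs[[s]]
    stopifnot(inherits(sp, "compartment_spec"))
    shape <- sp$shape
    if (is.null(shape))
      shape <- list(center = default_centers[[s]], radius = 0.16)
    aspect <- grid / max(grid[1:2])
    inside <- ((ix - shape$center[1]) * aspect[1])^2 +
      ((iy - shape$center[2]) * aspect[2])^2 <= shape$radius^2
    inside <- inside & iz > zmargin & iz <= grid[3] - zmargin
    if (any(labels[inside] != 0L)) stop("compartment shapes overlap")
    labels[inside] <- s
    idx <- which(as.vector(inside))
    alpha_map[idx] <- sp$extracellular_volume_fraction
    diw_map[idx] <- sp$diw_mm2_per_s
    # isotropic extracellular diffusion set by the mobility class
    Dm[idx, ] <- rep(c(sp$dew_mm2_per_s, 0, 0, sp$dew_mm2_per_s, 0,
                       sp$dew_mm2_per_s), each = length(idx))
    # anchor ce so that mean(C_true) = alpha * ce * dew equals sigma_ref
    ce <- sp$sigma_ref_S_per_m /
      (sp$extracellular_volume_fraction * sp$dew_mm2_per_s)
    ce_map[idx] <- ce
    sheet[[s]] <- data.frame(
      name = sp$name, nacl_g_per_L = sp$nacl_g_per_L,
      cuso4_g_per_L = sp$cuso4_g_per_L,
      extracellular_volume_fraction = sp$extracellular_volume_fraction,
      mobility_class = sp$mobility_class,
      sigma_ref_S_per_m = sp$sigma_ref_S_per_m,
      dew_mm2_per_s = sp$dew_mm2_per_s, diw_mm2_per_s = sp$diw_mm2_per_s,
      ce = ce, n_voxels = length(idx))
  }
  mask <- labels > 0L
  Dm[!as.vector(mask), ] <- 0
  De <- tensor_field(Dm, quantity = "diffusion_mm2_per_s", mask = mask,
                     voxel_size_mm = voxel_size_mm, grid = grid)
  .ground_truth(De, diw_map, alpha_map, ce_map, labels,
                vapply(specs, `[[`, character(1), "name"), beta,
                spec_sheet = do.call(rbind, sheet))
}

#' Build a brain-like synthetic object
#'
#' Nested regions inside an ellipsoidal head: a CSF rim plus a central
#' ventricle (isotropic, high conductivity), a GM shell (isotropic), and a
#' WM core whose fibers circle the ventricle in-plane, giving a spatially
#' varying anisotropic extracellular diffusion tensor.  Ground-truth
#' conductivity follows the same forward relations as the phantoms, with
#' per-tissue ion concentration anchored to literature isotropic
#' conductivities (WM 0.14, GM 0.27, CSF 1.79 S/m).  An optional smooth
#' in-plane concentration gradient inside WM and GM makes the true
#' conductivity depart from any global scaling of diffusion.
#'
#' @param grid Integer length-3 grid dimensions (all at least 16).
#' @param wm_eigenvalues Descending WM extracellular diffusion eigenvalues
#'   (mm^2/s).
#' @param consts [literature_constants()] supplying the three tissue
#'   conductivity anchors and `beta`.
#' @param ce_gradient Fractional peak-to-centre amplitude of the linear
#'   concentration gradient in WM and GM (default 0.1; 0 disables it).
#' @param seed Accepted for interface symmetry; construction is
#'   deterministic.
#' @return A `ground_truth` object with regions `WM`, `GM`, `CSF` (use
#'   [truth_masks()] for the masks).
#' @export
make_brain <- function(grid = c(48, 48, 12),
                       wm_eigenvalues = c(1.7e-3, 0.4e-3, 0.3e-3),
                       consts = literature_constants(),
                       ce_gradient = 0.1, seed = NULL) {
  stopifnot(length(grid) == 3L)
  grid <- as.integer(grid)
  if (any(grid[1:2] < 16L) || grid[3] < 4L)
    stop("grid too small for three nested regions")
  stopifnot(length(wm_eigenvalues) == 3L, all(diff(wm_eigenvalues) <= 0),
            all(wm_eigenvalues > 0))
  n <- prod(grid)
  x <- (slice.index(array(0, grid), 1L) - 0.5) / grid[1] - 0.5
  y <- (slice.index(array(0, grid), 2L) - 0.5) / grid[2] - 0.5
  z <- (slice.index(array(0, grid), 3L) - 0.5) / grid[3] - 0.5
  rin <- sqrt((x / 0.46)^2 + (y / 0.46)^2 + (z / 0.46)^2)  # head ellipsoid
  vent <- sqrt(x^2 + y^2 + (z * grid[3] / grid[1])^2) <= 0.07
  labels <- array(0L, grid)
  labels[rin <= 1] <- 3L                 # CSF rim by default
  labels[rin <= 0.82] <- 2L              # GM shell
  labels[rin <= 0.58] <- 1L              # WM core
  labels[vent & rin <= 1] <- 3L          # central ventricle is CSF
  if (!any(labels == 1L) || !any(labels == 2L) || !any(labels == 3L))
    stop("degenerate grid: some tissue region is empty")
  mask <- labels > 0L

  # tissue parameters of the stated world
  tis <- data.frame(
    name = c("WM", "GM", "CSF"),
    alpha = c(0.30, 0.45, 1.00),
    diw = c(0.3e-3, 0.3e-3, 0.3e-3),
    sigma_iso = c(consts$sigma_wm, consts$sigma_gm, consts$sigma_csf))
  dmean <- c(mean(wm_eigenvalues), 0.8e-3, 3.0e-3)

  Dm <- matrix(0, n, 6L)
  lab <- as.vector(labels)
  # isotropic GM / CSF
  for (t in 2:3) {
    idx <- which(lab == t)
    Dm[idx, c(1L, 4L, 6L)] <- dmean[t]
  }
  # WM: fibers tangential around the ventricle, in-plane
  widx <- which(lab == 1L)
  theta <- atan2(y[widx], x[widx])
  ct <- cos(theta); st <- sin(theta)
  l <- wm_eigenvalues
  # eigenvectors: e1 = (-st, ct, 0), e2 = (ct, st, 0), e3 = (0, 0, 1)
  Dm[widx, 1L] <- l[1] * st^2 + l[2] * ct^2            # xx
  Dm[widx, 2L] <- (l[2] - l[1]) * st * ct              # xy
  Dm[widx, 4L] <- l[1] * ct^2 + l[2] * st^2            # yy
  Dm[widx, 6L] <- l[3]                                 # zz
  De <- tensor_field(Dm, quantity = "diffusion_mm2_per_s", mask = mask,
                     grid = grid)

  alpha_map <- array(NA_real_, grid)
  diw_map <- array(NA_real_, grid)
  ce_map <- array(NA_real_, grid)
  for (t in 1:3) {
    idx <- which(lab == t)
    alpha_map[idx] <- tis$alpha[t]
    diw_map[idx] <- tis$diw[t]
    ce0 <- tis$sigma_iso[t] / (tis$alpha[t] * dmean[t])
    g <- if (t <= 2L) ce_gradient else 0   # keep CSF anchored exactly
    ce_map[idx] <- ce0 * (1 + g * 2 * as.vector(x)[idx])
  }
  .ground_truth(De, diw_map, alpha_map, ce_map, labels,
                c("WM", "GM", "CSF"), consts$beta,
                spec_sheet = cbind(tis, dmean_mm2_per_s = dmean))
}

#' A 4-D multi-b diffusion-weighted stack
#'
#' @param signals Array `c(grid, n_acq)` of diffusion-weighted signals, one
#'   volume per (b-value, direction) pair.
#' @param b_values Numeric vector of b-values (s/mm^2), one per acquisition,
#'   all positive (the unweighted image lives in `s0`).
#' @param directions `n_acq x 3` matrix of gradient directions; renormalised
#'   to unit length with a warning if needed.
#' @param s0 3-D array of the unweighted (b = 0) signal.
#' @param mask Optional logical array of valid voxels.
#' @return Object of class `multib_stack`.
#' @export
multib_stack <- function(signals, b_values, directions, s0, mask = NULL) {
  d <- dim(signals)
  stopifnot(length(d) == 4L, length(b_values) == d[4],
            nrow(directions) == d[4], ncol(directions) == 3L,
            identical(dim(s0), d[1:3]) || identical(dim(s0), as.integer(d[1:3])))
  if (any(b_values <= 0)) stop("b_values must be strictly positive")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  if (min(signals, na.rm = TRUE) < 0) stop("signals must be non-negative")
  if (any(s0[mask] <= 0)) stop("s0 must be positive on masked-in voxels")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8)) {
    warning("non-unit gradient directions renormalised")
    directions <- directions / nrm
  }
  structure(list(signals = signals, b_values = as.numeric(b_values),
                 directions = directions, s0 = s0,
                 mask = array(as.logical(mask), d[1:3]),
                 grid = as.integer(d[1:3])),
            class = "multib_stack")
}

#' @export
print.multib_stack <- function(x, ...) {
  cat(sprintf("<multib_stack> grid %s, %d acquisitions, %d shells, %d directions\n",
              paste(x$grid, collapse = "x"), length(x$b_values),
              length(unique(x$b_values)), nrow(unique(x$directions))))
  invisible(x)
}

#' Forward-simulate a multi-b diffusion-weighted stack
#'
#' Per voxel and gradient direction `u`, the signal follows the
#' two-compartment bi-exponential decay
#' `S(b)/S0 = alpha * exp(-b u'De u) + (1 - alpha) * exp(-b diw)`:
#' the fast component is the extracellular tensor seen along `u`, the slow
#' component the isotropic intracellular diffusivity.
#'
#' @param truth A `ground_truth`.
#' @param b_values Shell b-values (default the built-in 15-shell protocol).
#' @param directions Matrix of unit gradient directions (default 15
#'   Fibonacci directions); every shell is acquired along every direction.
#' @param noise_sd Additive Gaussian noise SD on the signal (default 0,
#'   giving the exact bi-exponential; use [add_rician_noise()] for a
#'   magnitude-MRI noise model).
#' @param s0 Unweighted signal level (scalar or 3-D array).
#' @param seed RNG seed consumed only when `noise_sd > 0`.
#' @return A [multib_stack()].
#' @export
simulate_dwi <- function(truth, b_values = default_bvalues(),
                         directions = default_directions(15L),
                         noise_sd = 0, s0 = 1, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            length(b_values) >= 1L, nrow(directions) >= 1L)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  grid <- truth$grid
  nvox <- prod(grid)
  nb <- length(b_values); nd <- nrow(directions)
  if (length(s0) == 1L) s0 <- array(s0, grid)
  alpha <- as.vector(truth$alpha_map)
  diw <- as.vector(truth$diw_map)
  msk <- as.vector(truth$mask)
  alpha[!msk] <- 1; diw[!msk] <- 0
  signals <- array(0, c(grid, nb * nd))
  b_out <- numeric(nb * nd)
  dir_out <- matrix(0, nb * nd, 3L)
  a <- 0L
  s0v <- as.vector(s0)
  for (j in seq_len(nd)) {
    de_j <- as.vector(tensor_quadform(truth$D_true, directions[j, ]))
    de_j[!msk] <- 0
    for (i in seq_len(nb)) {
      a <- a + 1L
      ratio <- alpha * exp(-b_values[i] * de_j) +
        (1 - alpha) * exp(-b_values[i] * diw)
      signals[, , , a] <- s0v * ratio
      b_out[a] <- b_values[i]
      dir_out[a, ] <- directions[j, ]
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    signals <- signals + stats::rnorm(length(signals), sd = noise_sd)
    signals[signals < 0] <- 0
  }
  multib_stack(signals, b_out, dir_out, s0, mask = truth$mask)
}

#' Forward-simulate the high-frequency conductivity map
#'
#' `sigma_H = ce * (alpha*dew + (1-alpha)*diw*beta)` per voxel, optionally
#' with additive Gaussian noise.  This is the map an MR electrical
#' properties tomography step would measure at the Larmor frequency; the
#' measurement itself is out of scope and the map is produced directly.
#'
#' @param truth A `ground_truth`.
#' @param noise_sd Additive Gaussian noise SD in S/m (default 0).
#' @param seed RNG seed consumed only when `noise_sd > 0`.
#' @return 3-D numeric array (S/m), `NA` outside the mask.
#' @export
simulate_sigma_h <- function(truth, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  if (truth$beta <= 0) stop("beta must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  out <- truth$sigmaH_map
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    out <- out + stats::rnorm(length(out), sd = noise_sd)
  }
  out[!truth$mask] <- NA_real_
  out
}

#' Add Rician noise to a multi-b stack
#'
#' Magnitude-MRI noise: every signal `s` (including the unweighted image) is
#' replaced by `sqrt((s + n1)^2 + n2^2)` with independent zero-mean Gaussian
#' `n1, n2` of standard deviation `mean(s0 in mask)/snr`.
#'
#' @param stack A [multib_stack()].
#' @param snr Signal-to-noise ratio (> 0); `Inf` returns the input.
#' @param seed RNG seed for reproducibility.
#' @return A [multib_stack()] with noisy signals and `s0`.
#' @export
add_rician_noise <- function(stack, snr, seed = NULL) {
  stopifnot(inherits(stack, "multib_stack"), snr > 0)
  if (!is.finite(snr)) return(stack)
  if (!is.null(seed)) set.seed(seed)
  sd <- mean(stack$s0[stack$mask]) / snr
  rice <- function(s) {
    n1 <- stats::rnorm(length(s), sd = sd)
    n2 <- stats::rnorm(length(s), sd = sd)
    array(sqrt((as.vector(s) + n1)^2 + n2^2), dim(s))
  }
  s0 <- rice(stack$s0)
  signals <- rice(stack$signals)
  multib_stack(signals, stack$b_values, stack$directions, s0,
               mask = stack$mask)
}
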