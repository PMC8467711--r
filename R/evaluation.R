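# Evaluation statistics -------------------------------------------------------
#
# ROI erosion, relative errors against reference conductivities,
# relative-difference maps against a reference reconstruction, pooled
# conductivity-vs-diffusion regressions, and ROI summaries.  SD is the
# sample (n-1) convention throughout.

#' Erode ROI masks in-plane
#'
#' Morphological erosion of each label by `width` voxels using a 3x3 cross
#' (4-neighbour) structuring element applied per z-slice, the conventional
#' way to peel partial-volume layers off slice-defined ROIs.
#'
#' @param mask Logical array (single ROI) or integer label array.
#' @param width Erosion width in voxels (default 2; 0 is the identity).
#' @return Same type as `mask`.
#' @export
roi_erode <- function(mask, width = 2L) {
  stopifnot(width >= 0L, length(dim(mask)) == 3L)
  if (width == 0L) return(mask)
  labels <- if (is.logical(mask)) 1L else sort(unique(mask[mask != 0L]))
  out <- if (is.logical(mask)) array(FALSE, dim(mask)) else array(0L, dim(mask))
  erode_slice <- function(m) {
    up <- rbind(m[-1L, , drop = FALSE], FALSE)
    down <- rbind(FALSE, m[-nrow(m), , drop = FALSE])
    left <- cbind(m[, -1L, drop = FALSE], FALSE)
    right <- cbind(FALSE, m[, -ncol(m), drop = FALSE])
    m & up & down & left & right
  }
  for (lab in labels) {
    m <- if (is.logical(mask)) mask else mask == lab
    for (z in seq_len(dim(mask)[3])) {
      sl <- m[, , z]
      for (i in seq_len(width)) sl <- erode_slice(sl)
      m[, , z] <- sl
    }
    if (!any(m))
      stop(sprintf("ROI label %s erodes to empty at width %d", lab, width))
    if (is.logical(mask)) out <- out | m else out[m] <- lab
  }
  out
}

#' Relative error of reconstructed mean conductivity per compartment
#'
#' `100 * |mean(sigma_L in ROI) - sigma_ref| / sigma_ref` with
#' `sigma_L = (sigma_l + sigma_t1 + sigma_t2)/3` the mean conductivity,
#' reported as absolute percentages.
#'
#' @param recon Conductivity [tensor_field()].
#' @param reference Named numeric vector of reference conductivities (S/m),
#'   one per compartment.
#' @param masks Named list of logical ROI masks (erode first with
#'   [roi_erode()]); names must match `reference`.
#' @return Data frame with `roi`, `n`, `mean_S_per_m`, `sd_S_per_m`,
#'   `reference_S_per_m`, `rel_error_pct`.
#' @export
relative_error <- function(recon, reference, masks) {
  stopifnot(inherits(recon, "tensor_field"),
            identical(recon$quantity, "conductivity_S_per_m"),
            !is.null(names(reference)), all(names(masks) %in% names(reference)))
  sL <- mean_scalar(recon)
  rows <- lapply(names(masks), function(nm) {
    sel <- masks[[nm]] & recon$mask
    if (!any(sel)) stop(sprintf("ROI %s is empty", nm))
    v <- sL[sel]
    ref <- reference[[nm]]
    data.frame(roi = nm, n = length(v), mean_S_per_m = mean(v),
               sd_S_per_m = stats::sd(v), reference_S_per_m = ref,
               rel_error_pct = 100 * abs(mean(v) - ref) / ref)
  })
  do.call(rbind, rows)
}

#' Relative-difference maps against a reference reconstruction
#'
#' Per voxel and tensor direction DIR in (l, t1, t2):
#' `rd_DIR = (sigma_DIR,ref - sigma_DIR,method) / sigma_DIR,ref * 100 (%)`,
#' signed (a method exceeding the reference gives negative values).
#'
#' @param c_method Conductivity [tensor_field()] of the method under test.
#' @param c_ref Reference conductivity [tensor_field()] (conventionally the
#'   high-frequency-informed reconstruction).
#' @return List with 3-D arrays `l`, `t1`, `t2` (percent, `NA` outside the
#'   common mask), and `n_excluded` (voxels dropped for zero reference
#'   eigenvalues, logged with a message).
#' @export
relative_difference_map <- function(c_method, c_ref) {
  stop_grid_mismatch(c_method, c_ref)
  stop_quantity_mismatch(c_method, c_ref)
  e_m <- eig_decompose(c_method)
  e_r <- eig_decompose(c_ref)
  n <- prod(c_ref$grid)
  vm <- e_m$values; dim(vm) <- c(n, 3L)
  vr <- e_r$values; dim(vr) <- c(n, 3L)
  mask <- as.vector(c_method$mask & c_ref$mask)
  zero <- mask & (rowSums(vr == 0) > 0)
  n_excluded <- sum(zero)
  if (n_excluded)
    message(sprintf("relative_difference_map: %d voxel(s) with zero reference eigenvalue excluded",
                    n_excluded))
  use <- mask & !zero
  rd <- matrix(NA_real_, n, 3L)
  rd[use, ] <- (vr[use, , drop = FALSE] - vm[use, , drop = FALSE]) /
    vr[use, , drop = FALSE] * 100
  g <- c_ref$grid
  list(l = array(rd[, 1L], g), t1 = array(rd[, 2L], g),
       t2 = array(rd[, 3L], g), n_excluded = n_excluded)
}

#' Summarise absolute relative differences per ROI
#'
#' @param rd Result of [relative_difference_map()].
#' @param masks Named list of logical ROI masks.
#' @return Data frame with the mean of `|rd|` pooled over the three
#'   directions and per direction, for each ROI.
#' @export
rd_summary <- function(rd, masks) {
  rows <- lapply(names(masks), function(nm) {
    sel <- masks[[nm]]
    vals <- cbind(rd$l[sel], rd$t1[sel], rd$t2[sel])
    vals <- vals[stats::complete.cases(vals), , drop = FALSE]
    data.frame(roi = nm, n = nrow(vals),
               abs_rd_pct = mean(abs(vals)),
               abs_rd_l_pct = mean(abs(vals[, 1L])),
               abs_rd_t1_pct = mean(abs(vals[, 2L])),
               abs_rd_t2_pct = mean(abs(vals[, 3L])))
  })
  do.call(rbind, rows)
}

#' Pooled regression between conductivity and diffusion tensor components
#'
#' Ordinary least squares between matched eigen-components of the two
#' fields, pooled over all ROI voxels: the longitudinal pair
#' `(sigma_l, d_l)` and the averaged transversal pair
#' `(sigma_t, d_t)` with `sigma_t = (sigma_t1 + sigma_t2)/2` (likewise for
#' `d_t`), plus both pairs pooled into one regression.  A coefficient of
#' determination of 1 means the conductivity field carries no information
#' beyond a linear rescaling of diffusion.
#'
#' @param c_field Conductivity [tensor_field()].
#' @param d_field Diffusion [tensor_field()] on the same grid.
#' @param masks Named list of logical ROI masks (pooled together).
#' @return List with `r2_l`, `r2_t`, `r2_pooled`, slopes/intercepts of the
#'   pooled fit, and `n` voxels used.  Constant regressors give `NA` R^2.
#' @export
regression_r2 <- function(c_field, d_field, masks) {
  stop_grid_mismatch(c_field, d_field)
  sel <- Reduce(`|`, masks) & c_field$mask & d_field$mask
  if (!any(sel)) stop("pooled ROI selection is empty")
  e_c <- eig_decompose(c_field)
  e_d <- eig_decompose(d_field)
  n <- prod(c_field$grid)
  vc <- e_c$values; dim(vc) <- c(n, 3L)
  vd <- e_d$values; dim(vd) <- c(n, 3L)
  idx <- which(as.vector(sel))
  sl <- vc[idx, 1L]; dl <- vd[idx, 1L]
  st <- (vc[idx, 2L] + vc[idx, 3L]) / 2
  dt <- (vd[idx, 2L] + vd[idx, 3L]) / 2
  r2 <- function(y, x) {
    if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
    f <- stats::lm.fit(cbind(1, x), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  xp <- c(dl, dt); yp <- c(sl, st)
  fit <- stats::lm.fit(cbind(1, xp), yp)
  list(r2_l = r2(sl, dl), r2_t = r2(st, dt), r2_pooled = r2(yp, xp),
       slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       n = length(idx))
}

#' Mean and SD of a scalar volume per ROI
#'
#' @param field 3-D numeric array (e.g. [mean_scalar()] or
#'   [anisotropy_ratio()] output).
#' @param masks Named list of logical ROI masks.
#' @return Data frame with `roi`, `n`, `mean`, `sd` (sample SD).
#' @export
roi_stats <- function(field, masks) {
  rows <- lapply(names(masks), function(nm) {
    v <- field[masks[[nm]]]
    v <- v[!is.na(v)]
    if (!length(v)) stop(sprintf("ROI %s is empty", nm))
    data.frame(roi = nm, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0)
  })
  do.call(rbind, rows)
}
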