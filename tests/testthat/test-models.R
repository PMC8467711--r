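# The five conductivity reconstructions.

test_that("lem_scale_factor follows the least-squares matching formula", {
  cst <- literature_constants()
  # equal diffusivities collapse to the mean-conductivity limit
  expect_equal(lem_scale_factor(1e-3, 1e-3, cst),
               (0.14 + 0.27) / (2 * 1e-3))
  # direct arithmetic with the literature conductivities
  expect_equal(lem_scale_factor(0.7e-3, 0.9e-3, cst),
               (0.7e-3 * 0.14 + 0.9e-3 * 0.27) / ((0.7e-3)^2 + (0.9e-3)^2))
  expect_error(lem_scale_factor(0, 1e-3), "positive")
})

test_that("reconstruct_lem: empirical constant, zero map, AR preservation", {
  f <- tf_from_rows(rbind(c(2e-3, 1e-4, 0, 1e-3, 0, 0.8e-3),
                          rep(0, 6)))
  out <- reconstruct_lem(f)
  # 0.844 S.s/mm^3 converts to 844 S.s/(m.mm^2) internally
  expect_equal(attr(out, "eta"), 844)
  expect_equal(tensor_values(out), 844 * tensor_values(f))
  expect_equal(tensor_values(out)[2, ], rep(0, 6))
  expect_equal(suppressWarnings(anisotropy_ratio(out))[1],
               suppressWarnings(anisotropy_ratio(f))[1],
               tolerance = 1e-12)   # warning comes from the all-zero voxel
  expect_error(reconstruct_lem(f, mode = "matched"), "masks")
})

test_that("matched LEM uses ROI mean diffusivities", {
  tr <- small_phantom("phantom1")
  st <- simulate_dwi(tr)
  D <- fit_dti(st, 700)
  masks <- truth_masks(tr)
  refs <- c(EL1 = 1.56, EL2 = 0.83)
  out <- reconstruct_lem(D, mode = "matched", masks = masks[c("EL1", "EL2")],
                         sigma_refs = refs)
  md <- mean_scalar(D)
  d1 <- mean(md[masks$EL1 & D$mask]); d2 <- mean(md[masks$EL2 & D$mask])
  expect_equal(attr(out, "eta"),
               (d1 * 1.56 + d2 * 0.83) / (d1^2 + d2^2))
})

test_that("fem_scale_factor is the printed microscopic constant", {
  cst <- literature_constants()
  oracle_si <- 0.76 * (1.6e-19)^2 * 2e25 / 4.1e-21
  expect_equal(fem_scale_factor(cst, units = "SI"), oracle_si)
  expect_equal(fem_scale_factor(cst), oracle_si * 1e-6)
  # linear in the carrier density, independent of any data
  half <- literature_constants(N = 1e25)
  expect_equal(fem_scale_factor(half), fem_scale_factor(cst) / 2)
})

test_that("FEM is blind to concentration but carries the anisotropy", {
  f <- tf_from_rows(rbind(c(2e-3, 0, 0, 1e-3, 0, 1e-3),
                          c(2e-3, 0, 0, 1e-3, 0, 1e-3)))
  out <- reconstruct_fem(f)
  # identical Df -> identical C, whatever the underlying concentration
  expect_identical(tensor_values(out)[1, ], tensor_values(out)[2, ])
  expect_equal(anisotropy_ratio(out)[1], anisotropy_ratio(f)[1],
               tolerance = 1e-12)
})

test_that("VCM pins the mean conductivity and preserves anisotropy", {
  set.seed(13)
  rows <- t(vapply(1:20, function(i) row_of(rand_spd() * 1e-3), numeric(6)))
  f <- tf_from_rows(rows)
  out <- reconstruct_vcm(f, 1.79)
  expect_equal(as.vector(mean_scalar(out)), rep(1.79, 20), tolerance = 1e-12)
  expect_equal(anisotropy_ratio(out), anisotropy_ratio(f), tolerance = 1e-10)
  # isotropic D becomes sigma_iso * I
  iso <- reconstruct_vcm(tf_from_rows(c(1e-3, 0, 0, 1e-3, 0, 1e-3)), 0.5)
  expect_equal(as.vector(tensor_values(iso)), c(0.5, 0, 0, 0.5, 0, 0.5))
  # zero trace voxels are masked out with a warning
  z <- tf_from_rows(rbind(c(1e-3, 0, 0, 1e-3, 0, 1e-3), rep(0, 6)))
  expect_warning(outz <- reconstruct_vcm(z, 0.5), "zero-trace")
  expect_false(outz$mask[2, 1, 1])
})

test_that("solve_vfm_fractions: limits and forward/inverse round trip", {
  cst <- literature_constants()
  iso <- solve_vfm_fractions(rep(cst$vfm_d_iso, 3), cst)
  expect_equal(as.vector(iso), c(0, 0, 0, 1), tolerance = 1e-12,
               ignore_attr = TRUE)
  pure <- solve_vfm_fractions(c(cst$vfm_d_lW, cst$vfm_d_tW, cst$vfm_d_tW), cst)
  expect_equal(as.vector(pure), c(1, 0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)

  # random simplex fractions pushed through the forward mixture model and
  # solved back (oracle: the forward map written out longhand)
  set.seed(31)
  b <- cst$vfm_b
  eW <- exp(-b * c(cst$vfm_d_lW, cst$vfm_d_tW, cst$vfm_d_tW))
  e0 <- exp(-b * cst$vfm_d_iso)
  for (i in 1:50) {
    a <- stats::runif(4); a <- a / sum(a)
    rhs <- c(a[1] * eW[1] + a[2] * eW[2] + a[3] * eW[3] + a[4] * e0,
             a[1] * eW[2] + a[2] * eW[1] + a[3] * eW[3] + a[4] * e0,
             a[1] * eW[3] + a[2] * eW[2] + a[3] * eW[1] + a[4] * e0)
    d <- -log(rhs) / b
    got <- solve_vfm_fractions(d, cst)
    expect_equal(as.vector(got), a, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("reconstruct_vfm eigenvalue limits and transversal symmetry", {
  cst <- literature_constants()
  grid <- c(2, 1, 1)
  rows <- rbind(
    c(cst$vfm_d_iso, 0, 0, cst$vfm_d_iso, 0, cst$vfm_d_iso),  # aiso = 1
    c(cst$vfm_d_lW, 0, 0, cst$vfm_d_tW, 0, cst$vfm_d_tW))     # al = 1
  D <- tf_from_rows(rows, grid = grid)
  masks <- list(WM = array(TRUE, grid), GM = array(FALSE, grid),
                CSF = array(FALSE, grid))
  out <- reconstruct_vfm(D, masks, cst)
  e <- eig_decompose(out)
  expect_equal(as.vector(e$values[1, 1, 1, ]), rep(cst$vfm_sigma_iso, 3),
               tolerance = 1e-9)
  expect_equal(as.vector(e$values[2, 1, 1, ]),
               c(cst$vfm_sigma_lW, cst$vfm_sigma_tW, cst$vfm_sigma_tW),
               tolerance = 1e-9)
  # GM / CSF voxels take isotropic literature values
  masks2 <- list(WM = array(c(TRUE, FALSE), grid),
                 GM = array(c(FALSE, TRUE), grid),
                 CSF = array(FALSE, grid))
  out2 <- reconstruct_vfm(D, masks2, cst)
  expect_equal(tensor_values(out2)[2, ],
               c(cst$sigma_gm, 0, 0, cst$sigma_gm, 0, cst$sigma_gm))
})

test_that("VFM lowers the anisotropy ratio on unequal-transversal voxels", {
  cst <- literature_constants()
  tr <- make_brain(grid = c(32, 32, 8))
  masks <- truth_masks(tr)
  out <- reconstruct_vfm(tr$D_true, masks, cst)
  wm <- masks$WM & out$mask
  arc <- anisotropy_ratio(out)[wm]
  ard <- anisotropy_ratio(tr$D_true)[wm]
  expect_true(mean(arc) < mean(ard))
  # voxelwise: wherever dt1 != dt2 strictly, ARC < ARD
  e <- eig_decompose(tr$D_true)
  n <- prod(tr$grid); vals <- e$values; dim(vals) <- c(n, 3)
  uneq <- which(wm)[abs(vals[which(wm), 2] - vals[which(wm), 3]) > 1e-6]
  expect_true(all(arc[match(uneq, which(wm))] <
                    ard[match(uneq, which(wm))] + 1e-10))
})

test_that("estimate_ce arithmetic and degenerate denominator", {
  expect_equal(estimate_ce(1, alpha = 1, dew = 2e-3, diw = 0, beta = 0.41),
               1 / 2e-3)
  expect_equal(estimate_ce(1.0, 0.5, 2e-3, 0.5e-3, 0.41),
               1.0 / (0.5 * 2e-3 + 0.5 * 0.5e-3 * 0.41))
  expect_warning(out <- estimate_ce(c(1, 1), c(0.5, 0), c(2e-3, 1e-3),
                                    c(0, 0), 0.41), "zero denominator")
  expect_true(is.na(out[2]))
  expect_error(estimate_ce(1, 1, 2e-3, 0, beta = 0), "positive")
})

test_that("CTI separates concentration where LEM/FEM cannot", {
  tr <- small_phantom("phantom1")
  st <- simulate_dwi(tr)
  fit <- assemble_fast_slow(st)
  sh <- simulate_sigma_h(tr)
  cti <- reconstruct_cti(sh, fit, beta = tr$beta)
  masks <- truth_masks(tr)
  v1 <- which(masks$EL1)[1]; v2 <- which(masks$EL2)[1]
  # equal De, different sigmaH -> different C for CTI ...
  expect_false(isTRUE(all.equal(tensor_values(cti)[v1, ],
                                tensor_values(cti)[v2, ])))
  # ... but identical C for FEM (and LEM)
  fem <- reconstruct_fem(fit$Df)
  expect_identical(tensor_values(fem)[v1, ], tensor_values(fem)[v2, ])
  # electrolyte limit: C isotropic with value sigmaH
  expect_equal(tensor_values(cti)[v1, c(1, 4, 6)], rep(sh[v1], 3),
               tolerance = 1e-10)
  expect_error(reconstruct_cti(sh[1:3, , 1], fit), "grid")
})

test_that("CTI at noise 0 recovers C_true per voxel on every preset", {
  for (preset in c("phantom1", "phantom2")) {
    tr <- small_phantom(preset)
    fit <- assemble_fast_slow(simulate_dwi(tr))
    cti <- reconstruct_cti(simulate_sigma_h(tr), fit, beta = tr$beta)
    sel <- which(tr$mask)
    cv <- tensor_values(cti)[sel, , drop = FALSE]
    tv <- tensor_values(tr$C_true)[sel, , drop = FALSE]
    expect_lt(max(abs(cv - tv)) / max(tv), 0.001)  # < 0.1 %
  }
})
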