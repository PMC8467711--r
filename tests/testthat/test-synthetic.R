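# Phantom/brain generators and the forward simulator.

test_that("phantom presets reproduce the published compartment sheet", {
  sheet <- rbind(make_phantom(phantom_presets("phantom1"),
                              grid = c(16, 16, 6))$spec_sheet,
                 make_phantom(phantom_presets("phantom2"),
                              grid = c(16, 16, 6))$spec_sheet)
  expect_equal(sheet$name, c("EL1", "EL2", "GVS1", "EL3", "EL4", "GVS2"))
  expect_equal(sheet$nacl_g_per_L, c(7.5, 3.5, 7.5, 3, 3, 3))
  expect_equal(sheet$cuso4_g_per_L, c(0, 1, 0, 0, 0, 0))
  expect_equal(sheet$extracellular_volume_fraction,
               c(1, 1, 0.10, 1, 1, 0.50))
  expect_equal(sheet$mobility_class,
               c("high", "high", "high", "low", "high", "low"))
  expect_equal(sheet$sigma_ref_S_per_m, c(1.56, 0.83, 0.29, 0.55, 0.70, 0.45))
})

test_that("ground-truth invariants hold per voxel to machine precision", {
  for (preset in c("phantom1", "phantom2")) {
    tr <- small_phantom(preset)
    sel <- which(tr$mask)
    a <- tr$alpha_map[sel]; ce <- tr$ce_map[sel]
    Dv <- tensor_values(tr$D_true)[sel, , drop = FALSE]
    Cv <- tensor_values(tr$C_true)[sel, , drop = FALSE]
    # C = alpha * ce * De componentwise (same eigenvectors for free)
    expect_equal(Cv, Dv * (a * ce), tolerance = 1e-14)
    # high-frequency forward relation
    dew <- tr$dew_map[sel]; diw <- tr$diw_map[sel]
    expect_equal(tr$sigmaH_map[sel],
                 ce * (a * dew + (1 - a) * diw * tr$beta), tolerance = 1e-14)
    # mean conductivity anchored to each reference
    err <- relative_error(tr$C_true,
                          stats::setNames(tr$spec_sheet$sigma_ref_S_per_m,
                                          tr$spec_sheet$name),
                          truth_masks(tr))
    expect_lt(max(err$rel_error_pct), 1e-10)
  }
})

test_that("single alpha=1 compartment gives C = ce * De; presets differ as built", {
  tr <- small_phantom("phantom1")
  masks <- truth_masks(tr)
  el1 <- which(masks$EL1); el2 <- which(masks$EL2)
  # same mobility class -> identical diffusion; different NaCl -> different C
  expect_identical(tensor_values(tr$D_true)[el1[1], ],
                   tensor_values(tr$D_true)[el2[1], ])
  expect_false(isTRUE(all.equal(tensor_values(tr$C_true)[el1[1], ],
                                tensor_values(tr$C_true)[el2[1], ])))
  expect_equal(tensor_values(tr$C_true)[el1, , drop = FALSE],
               tensor_values(tr$D_true)[el1, , drop = FALSE] *
                 tr$ce_map[el1], tolerance = 1e-14)
})

test_that("make_phantom validates shapes and volume fractions", {
  sp <- phantom_presets("phantom1")
  sp[[2]]$shape <- list(center = c(0.28, 0.30), radius = 0.16)  # on top of 1
  expect_error(make_phantom(sp, grid = c(20, 20, 6)), "overlap")
  expect_error(compartment_spec("bad", 1, extracellular_volume_fraction = 0,
                                sigma_ref_S_per_m = 1), "\\(0, 1\\]")
  expect_error(compartment_spec("bad", 1, extracellular_volume_fraction = 1.2,
                                sigma_ref_S_per_m = 1), "\\(0, 1\\]")
})

test_that("make_brain anchors CSF, shares eigenvectors, bounds sigmaH", {
  tr <- make_brain(grid = c(32, 32, 8))
  masks <- truth_masks(tr)
  expect_named(masks, c("WM", "GM", "CSF"))
  csf <- mean_scalar(tr$C_true)[masks$CSF]
  expect_equal(mean(csf), 1.79, tolerance = 1e-12)
  # anisotropy ratio of C equals that of D in WM (scalar per-voxel scale)
  arc <- anisotropy_ratio(tr$C_true)[masks$WM]
  ard <- anisotropy_ratio(tr$D_true)[masks$WM]
  expect_equal(arc, ard, tolerance = 1e-10)
  # sigmaH >= mean(C) wherever beta <= 1 and diw <= dew
  sel <- which(tr$mask)
  expect_true(all(tr$sigmaH_map[sel] >=
                    mean_scalar(tr$C_true)[sel] - 1e-12))
  expect_error(make_brain(grid = c(8, 8, 2)), "too small|degenerate")
})

test_that("simulate_dwi matches the bi-exponential forward model", {
  # alpha = 1: pure mono-exponential along any direction
  tr <- make_phantom(list(
    compartment_spec("EL", 5, extracellular_volume_fraction = 1,
                     sigma_ref_S_per_m = 1)), grid = c(12, 12, 6))
  b <- c(500, 1000, 2000)
  u <- rbind(c(1, 0, 0), c(0, 0, 1))
  st <- simulate_dwi(tr, b, u, s0 = 2)
  v <- which(tr$mask)[1]
  for (i in seq_along(st$b_values))
    expect_equal(st$signals[, , , i][v] / st$s0[v],
                 exp(-st$b_values[i] * 2e-3), tolerance = 1e-14)

  # mixed voxel: the worked two-compartment ratio at b = 1000
  trm <- make_phantom(list(
    compartment_spec("MIX", 5, extracellular_volume_fraction = 0.5,
                     sigma_ref_S_per_m = 1, dew_mm2_per_s = 2e-3,
                     diw_mm2_per_s = 0.5e-3)), grid = c(12, 12, 6))
  stm <- simulate_dwi(trm, 1000, rbind(c(0, 0, 1)))
  v <- which(trm$mask)[1]
  expect_equal(stm$signals[, , , 1][v],
               0.5 * exp(-2) + 0.5 * exp(-0.5), tolerance = 1e-14)
  expect_error(simulate_dwi(tr, b, u, noise_sd = -1), "non-negative")
})

test_that("simulate_sigma_h inverts exactly and is linear in ce", {
  tr <- small_phantom("phantom2")
  sh <- simulate_sigma_h(tr)
  sel <- which(tr$mask)
  ce <- estimate_ce(sh, tr$alpha_map, tr$dew_map, tr$diw_map, tr$beta)
  expect_equal(ce[sel], tr$ce_map[sel], tolerance = 1e-12)
  # doubling every reference conductivity doubles ce, hence sigmaH
  sp2 <- lapply(phantom_presets("phantom2"), function(s) {
    s$sigma_ref_S_per_m <- 2 * s$sigma_ref_S_per_m; s
  })
  tr2 <- make_phantom(sp2, grid = c(20, 20, 6))
  expect_equal(simulate_sigma_h(tr2)[sel], 2 * sh[sel], tolerance = 1e-12)
  # alpha = 1 voxels: sigmaH = ce * dew
  a1 <- sel[tr$alpha_map[sel] == 1]
  expect_equal(sh[a1], tr$ce_map[a1] * tr$dew_map[a1], tolerance = 1e-14)
})

test_that("add_rician_noise: identity at snr=Inf, seeded, biased upward", {
  tr <- small_phantom("phantom1")
  st <- simulate_dwi(tr, c(500, 1500, 3000), default_directions(3))
  expect_identical(add_rician_noise(st, Inf), st)
  n1 <- add_rician_noise(st, 20, seed = 9)
  n2 <- add_rician_noise(st, 20, seed = 9)
  expect_identical(n1$signals, n2$signals)
  # Rician bias: at very low signal the magnitude mean exceeds the input
  low <- multib_stack(array(0.02, c(50, 50, 40, 1)), 1000,
                      rbind(c(0, 0, 1)), array(1, c(50, 50, 40)))
  nz <- add_rician_noise(low, 10, seed = 1)   # sd = 0.1 >> signal
  expect_gt(mean(nz$signals), 0.02)
})

test_that("stack validation catches shape and sign errors", {
  s <- array(1, c(4, 4, 2, 3))
  d <- default_directions(3)
  expect_error(multib_stack(s, c(0, 1, 2), d, array(1, c(4, 4, 2))),
               "positive")
  expect_error(multib_stack(-s, c(1, 2, 3), d, array(1, c(4, 4, 2))),
               "non-negative")
  expect_warning(multib_stack(s, c(1, 2, 3), 2 * d, array(1, c(4, 4, 2))),
                 "renormalised")
})
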