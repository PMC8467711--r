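# Orchestration, file interchange and the command line ------------------------

#' Write a multi-b stack as NIfTI + bval/bvec files
#'
#' The unweighted volume is stored as the first volume of the 4-D stack
#' with b = 0 in the b-value table (the common interchange convention).
#'
#' @param stack A [multib_stack()].
#' @param prefix Output path prefix; writes `<prefix>.nii`,
#'   `<prefix>.bval`, `<prefix>.bvec` and `<prefix>_mask.nii`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_dwi <- function(stack, prefix) {
  stopifnot(inherits(stack, "multib_stack"))
  d <- c(stack$grid, length(stack$b_values) + 1L)
  vols <- array(0, d)
  vols[, , , 1L] <- stack$s0
  vols[, , , -1L] <- stack$signals
  paths <- c(nii = paste0(prefix, ".nii"), bval = paste0(prefix, ".bval"),
             bvec = paste0(prefix, ".bvec"), mask = paste0(prefix, "_mask.nii"))
  write_nifti(vols, paths["nii"])
  write_bvals_bvecs(c(0, stack$b_values),
                    rbind(c(0, 0, 0), stack$directions),
                    paths["bval"], paths["bvec"])
  write_nifti(stack$mask + 0, paths["mask"])
  invisible(paths)
}

#' Read a multi-b stack from NIfTI + bval/bvec files
#'
#' Volumes with b = 0 are averaged into the unweighted image `s0`
#' (several b = 0 volumes are allowed); the rest become the weighted stack.
#'
#' @param nii_path 4-D NIfTI file.
#' @param bval_path,bvec_path Matching b-value/direction text files.
#' @param mask Optional logical array or NIfTI path of the voxel mask.
#' @return A [multib_stack()].
#' @export
read_dwi <- function(nii_path, bval_path, bvec_path, mask = NULL) {
  vols <- read_nifti(nii_path)
  if (length(dim(vols)) != 4L) stop("expected a 4-D NIfTI stack")
  tab <- read_bvals_bvecs(bval_path, bvec_path)
  if (length(tab$b_values) != dim(vols)[4])
    stop(sprintf("b table length (%d) does not match volume count (%d)",
                 length(tab$b_values), dim(vols)[4]))
  b0 <- tab$b_values == 0
  if (!any(b0)) stop("no b = 0 volume found")
  s0 <- apply(vols[, , , b0, drop = FALSE], 1:3, mean)
  attr(s0, "voxel_size_mm") <- attr(vols, "voxel_size_mm")[1:3]
  if (is.character(mask)) mask <- read_nifti(mask) > 0
  multib_stack(vols[, , , !b0, drop = FALSE], tab$b_values[!b0],
               tab$directions[!b0, , drop = FALSE], s0, mask = mask)
}

#' Write a tensor field as NIfTI with a sidecar header
#'
#' Six components in the documented order as a 4-D volume, plus a JSON
#' sidecar recording quantity, units and component order.
#'
#' @param field A [tensor_field()].
#' @param prefix Output path prefix (writes `<prefix>.nii`,
#'   `<prefix>.json`, `<prefix>_mask.nii`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_tensor_field <- function(field, prefix) {
  stopifnot(inherits(field, "tensor_field"))
  paths <- c(nii = paste0(prefix, ".nii"), json = paste0(prefix, ".json"),
             mask = paste0(prefix, "_mask.nii"))
  write_nifti(field$values, paths["nii"], voxel_size_mm = field$voxel_size_mm)
  jsonlite::write_json(list(quantity = field$quantity,
                            component_order = tensor_component_order(),
                            voxel_size_mm = field$voxel_size_mm),
                       paths["json"], auto_unbox = TRUE, digits = NA)
  write_nifti(field$mask + 0, paths["mask"])
  invisible(paths)
}

#' Read a tensor field written by [write_tensor_field()]
#' @param prefix Path prefix used at write time.
#' @return A [tensor_field()].
#' @export
read_tensor_field <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  vals <- read_nifti(paste0(prefix, ".nii"))
  mask <- read_nifti(paste0(prefix, "_mask.nii")) > 0
  tensor_field(vals, quantity = meta$quantity, mask = mask,
               voxel_size_mm = meta$voxel_size_mm)
}

#' Run the full synthetic comparison pipeline
#'
#' simulate -> fit -> reconstruct (all applicable models) -> evaluate, for
#' one preset, writing every artifact plus a manifest (inputs, constants,
#' seed, file hashes) to `out_dir`.  Deterministic under fixed seed and
#' configuration.
#'
#' Phantom presets run LEM (matched to two electrolyte references), FEM,
#' VCM (calibrated to the reference conductivities) and CTI, and emit a
#' per-compartment relative-error table.  The brain preset also runs VFM
#' and emits ROI summaries, pooled regressions and relative-difference
#' summaries against CTI.
#'
#' @param preset `"phantom1"`, `"phantom2"` or `"brain"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed controlling all randomness.
#' @param snr Signal-to-noise ratio for Rician noise; `Inf` (default) for
#'   noiseless data.
#' @param grid Grid dimensions.
#' @param consts [literature_constants()].
#' @param erode_width ROI erosion width in voxels (default 2).
#' @return List with the evaluation tables and the manifest, invisibly
#'   written as JSON/TSV files.
#' @export
run_pipeline <- function(preset = c("phantom1", "phantom2", "brain"),
                         out_dir, seed = 1L, snr = Inf,
                         grid = if (preset == "brain") c(48, 48, 12) else c(48, 48, 12),
                         consts = literature_constants(),
                         erode_width = 2L) {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  is_brain <- preset == "brain"
  truth <- if (is_brain) {
    make_brain(grid = grid, consts = consts, seed = seed)
  } else {
    make_phantom(phantom_presets(preset), grid = grid, beta = consts$beta,
                 seed = seed)
  }
  stack <- simulate_dwi(truth)
  if (is.finite(snr)) stack <- add_rician_noise(stack, snr, seed = seed)
  sigmaH <- simulate_sigma_h(truth)
  masks <- truth_masks(truth)
  emasks <- lapply(masks, roi_erode, width = erode_width)

  fit <- assemble_fast_slow(stack, mode = "tensor6plus")
  D <- fit_dti(stack, b_used = 700)

  refs <- if (is_brain) {
    c(WM = consts$sigma_wm, GM = consts$sigma_gm, CSF = consts$sigma_csf)
  } else {
    stats::setNames(truth$spec_sheet$sigma_ref_S_per_m, truth$spec_sheet$name)
  }
  el <- if (is_brain) c("WM", "GM") else truth$spec_sheet$name[
    truth$spec_sheet$extracellular_volume_fraction == 1][1:2]
  recon <- list(
    LEM = reconstruct_lem(D, mode = "matched", masks = emasks[el],
                          consts = consts, sigma_refs = refs[el]),
    FEM = reconstruct_fem(fit$Df, consts = consts),
    VCM = reconstruct_vcm(D, refs, masks = masks),
    CTI = reconstruct_cti(sigmaH, fit, beta = consts$beta))
  if (is_brain)
    recon$VFM <- reconstruct_vfm(D, masks, consts = consts)

  err <- do.call(rbind, lapply(names(recon), function(m) {
    cbind(model = m, relative_error(recon[[m]], refs, emasks))
  }))
  utils::write.table(err, file.path(out_dir, "relative_errors.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  report <- list(preset = preset, seed = seed, snr = snr,
                 relative_errors = err)
  if (is_brain) {
    report$r2 <- lapply(recon, function(cf) {
      dref <- if (identical(attr(cf, "model"), "FEM")) fit$Df else D
      regression_r2(cf, dref, emasks)
    })
    report$rd <- lapply(recon[setdiff(names(recon), "CTI")], function(cf)
      rd_summary(relative_difference_map(cf, recon$CTI), emasks))
    report$roi <- lapply(recon, function(cf)
      do.call(rbind, list(cbind(stat = "sigma_L",
                                roi_stats(mean_scalar(cf), emasks)))))
    ar <- lapply(recon, function(cf)
      roi_stats(anisotropy_ratio(cf), emasks["WM"]))
    report$ar <- rbind(
      do.call(rbind, Map(cbind, model = names(ar), ar)),
      cbind(model = "D", roi_stats(anisotropy_ratio(D), emasks["WM"])))
  }

  for (m in names(recon))
    write_tensor_field(recon[[m]], file.path(out_dir, paste0("C_", m)))
  write_dwi(stack, file.path(out_dir, "dwi"))
  write_nifti(ifelse(is.na(sigmaH), 0, sigmaH), file.path(out_dir, "sigmaH.nii"))
  write_tensor_field(truth$C_true, file.path(out_dir, "C_true"))
  jsonlite::write_json(truth$spec_sheet, file.path(out_dir, "spec_sheet.json"),
                       digits = NA)

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("condtensor")),
    preset = preset, seed = seed, snr = snr, grid = grid,
    constants = unclass(consts),
    hashes = as.list(tools::md5sum(files[!grepl("manifest", files)])))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# --- command line ------------------------------------------------------------

.cli_parse <- function(argv) {
  if (!length(argv)) stop("usage: condtensor <simulate|fit|reconstruct|evaluate|run> --key value ...")
  cmd <- argv[[1L]]
  args <- list()
  i <- 2L
  while (i <= length(argv)) {
    key <- argv[[i]]
    if (!startsWith(key, "--")) stop("expected --key, got ", key)
    if (i + 1L > length(argv)) stop("missing value for ", key)
    args[[substring(key, 3L)]] <- argv[[i + 1L]]
    i <- i + 2L
  }
  list(cmd = cmd, args = args)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic dataset), `fit`
#' (bi-exponential + tensor fits of a stack), `reconstruct` (one model on a
#' fitted dataset), `evaluate` and `run` (end-to-end via
#' [run_pipeline()]).  Invoked by the `inst/cli/condtensor` script; exposed
#' as a function so it can be tested without spawning a process.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status 0 invisibly on success.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  p <- .cli_parse(argv)
  a <- p$args
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  switch(
    p$cmd,
    simulate = {
      preset <- a$preset %||% "phantom1"
      out <- a$out %||% stop("--out required")
      snr <- num(a$snr, Inf)
      seed <- num(a$seed, 1)
      grid <- if (is.null(a$grid)) NULL else
        as.integer(strsplit(a$grid, ",")[[1L]])
      truth <- if (preset == "brain") {
        make_brain(grid = grid %||% c(48, 48, 12), seed = seed)
      } else {
        make_phantom(phantom_presets(preset), grid = grid %||% c(64, 64, 16),
                     seed = seed)
      }
      stack <- simulate_dwi(truth)
      if (is.finite(snr)) stack <- add_rician_noise(stack, snr, seed = seed)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_dwi(stack, file.path(out, "dwi"))
      sh <- simulate_sigma_h(truth)
      write_nifti(ifelse(is.na(sh), 0, sh), file.path(out, "sigmaH.nii"))
      write_nifti(truth$labels, file.path(out, "labels.nii"))
      write_tensor_field(truth$C_true, file.path(out, "C_true"))
      jsonlite::write_json(truth$spec_sheet, file.path(out, "spec_sheet.json"),
                           digits = NA)
      message("simulated ", preset, " -> ", out)
    },
    fit = {
      stack <- read_dwi(a$`in` %||% stop("--in required"),
                        a$bvals %||% stop("--bvals required"),
                        a$bvecs %||% stop("--bvecs required"),
                        mask = a$mask)
      fit <- assemble_fast_slow(stack, mode = a$mode %||% "tensor6plus")
      out <- a$out %||% stop("--out required")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_tensor_field(fit$Df, file.path(out, "Df"))
      write_tensor_field(fit$Ds, file.path(out, "Ds"))
      write_tensor_field(fit_dti(stack, 700), file.path(out, "D"))
      for (nm in c("alpha", "dew", "diw", "fit_quality"))
        write_nifti(ifelse(is.na(fit[[nm]]), 0, fit[[nm]]),
                    file.path(out, paste0(nm, ".nii")))
      message("fit -> ", out)
    },
    reconstruct = {
      model <- tolower(a$model %||% stop("--model required"))
      ind <- a$`in` %||% stop("--in required (a `fit` output directory)")
      out <- a$out %||% stop("--out required")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      consts <- literature_constants()
      cf <- switch(
        model,
        lem = reconstruct_lem(read_tensor_field(file.path(ind, "D")),
                              consts = consts),
        fem = reconstruct_fem(read_tensor_field(file.path(ind, "Df")),
                              consts = consts),
        vcm = reconstruct_vcm(read_tensor_field(file.path(ind, "D")),
                              num(a$sigma_iso, consts$sigma_gm)),
        vfm = {
          lab <- read_nifti(file.path(ind, "labels.nii"))
          reconstruct_vfm(read_tensor_field(file.path(ind, "D")),
                          list(WM = lab == 1, GM = lab == 2, CSF = lab == 3),
                          consts = consts)
        },
        cti = {
          fitd <- list(Df = read_tensor_field(file.path(ind, "Df")),
                       alpha = read_nifti(file.path(ind, "alpha.nii")),
                       dew = read_nifti(file.path(ind, "dew.nii")),
                       diw = read_nifti(file.path(ind, "diw.nii")))
          fitd$grid <- fitd$Df$grid
          class(fitd) <- "biexp_fit"
          reconstruct_cti(read_nifti(file.path(ind, "sigmaH.nii")), fitd,
                          beta = consts$beta)
        },
        stop("unknown model: ", model))
      write_tensor_field(cf, file.path(out, paste0("C_", toupper(model))))
      message("reconstructed ", toupper(model), " -> ", out)
    },
    evaluate = {
      recon <- read_tensor_field(a$recon %||% stop("--recon required"))
      truth <- read_tensor_field(a$truth %||% stop("--truth required"))
      out <- a$out %||% stop("--out required")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      rd <- relative_difference_map(recon, truth)
      msk <- list(all = recon$mask & truth$mask)
      tab <- rd_summary(rd, msk)
      utils::write.table(tab, file.path(out, "rd_summary.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      r2 <- roi_stats(mean_scalar(recon), msk)
      utils::write.table(r2, file.path(out, "roi_stats.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      message("evaluation -> ", out)
    },
    run = {
      rep <- run_pipeline(a$preset %||% "phantom1",
                          out_dir = a$out %||% stop("--out required"),
                          seed = as.integer(num(a$seed, 1)),
                          snr = num(a$snr, Inf))
      message("pipeline complete -> ", a$out)
    },
    stop("unknown subcommand: ", p$cmd,
         " (use simulate|fit|reconstruct|evaluate|run)"))
  invisible(0L)
}
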