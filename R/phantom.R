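#' Parameters for a three-phase CT phantom
#'
#' Describes a digital phantom emulating a pancreatic-protocol CT study:
#' a parenchyma background with an anterior fat slab, a spherical tumor,
#' class-conditional tumor enhancement gains, and additive Gaussian CT
#' noise. Defaults place the parenchyma at 40 HU pre-contrast with gains of
#' +60 HU (AR) and +50 HU (PV), fat at -100 HU (non-enhancing), and a
#' hypo-enhancing conspicuous ("high" delta) tumor; "low" delta tumors
#' enhance nearly like parenchyma.
#'
#' @param grid_shape voxels per axis (all >= 16).
#' @param voxel_spacing_mm isotropic voxel spacing (> 0).
#' @param parenchyma_hu_nc baseline parenchyma HU.
#' @param parenchyma_gain_ar,parenchyma_gain_pv mean parenchyma enhancement
#'   added in the AR / PV phase (HU).
#' @param fat_hu_nc baseline fat HU (negative; fat does not enhance).
#' @param tumor_radius_mm tumor sphere radius in mm.
#' @param tumor_gain_ar_mean,tumor_gain_pv_mean mean tumor enhancement per
#'   phase (HU). `NULL` selects class defaults: "high" delta 25/20 (markedly
#'   hypo-enhancing, conspicuous border), "low" delta 55/46 (near
#'   iso-enhancing, inconspicuous border).
#' @param tumor_gain_sd voxel-wise SD of tumor enhancement (HU).
#' @param noise_sd_hu additive Gaussian CT noise SD (HU, >= 0).
#' @param class_label `"high"` or `"low"` delta.
#' @param seed integer seed.
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(64, 64, 64),
                           voxel_spacing_mm = 1,
                           parenchyma_hu_nc = 40,
                           parenchyma_gain_ar = 60,
                           parenchyma_gain_pv = 50,
                           fat_hu_nc = -100,
                           tumor_radius_mm = 10,
                           tumor_gain_ar_mean = NULL,
                           tumor_gain_pv_mean = NULL,
                           tumor_gain_sd = 10,
                           noise_sd_hu = 8,
                           class_label = c("high", "low"),
                           seed = 1L) {
  class_label <- match.arg(class_label)
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(grid_shape) != 3L || any(grid_shape < 16)) {
    stop("`grid_shape` must be 3 values, all >= 16", call. = FALSE)
  }
  if (voxel_spacing_mm <= 0) stop("`voxel_spacing_mm` must be > 0",
                                  call. = FALSE)
  if (noise_sd_hu < 0) stop("`noise_sd_hu` must be >= 0", call. = FALSE)
  if (tumor_gain_sd < 0) stop("`tumor_gain_sd` must be >= 0", call. = FALSE)
  if (tumor_radius_mm <= 0) stop("`tumor_radius_mm` must be > 0",
                                 call. = FALSE)
  if (is.null(tumor_gain_ar_mean)) {
    tumor_gain_ar_mean <- if (class_label == "high") 25 else 55
  }
  if (is.null(tumor_gain_pv_mean)) {
    tumor_gain_pv_mean <- if (class_label == "high") 20 else 46
  }
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = voxel_spacing_mm,
    parenchyma_hu_nc = parenchyma_hu_nc,
    parenchyma_gain_ar = parenchyma_gain_ar,
    parenchyma_gain_pv = parenchyma_gain_pv,
    fat_hu_nc = fat_hu_nc,
    tumor_radius_mm = tumor_radius_mm,
    tumor_gain_ar_mean = tumor_gain_ar_mean,
    tumor_gain_pv_mean = tumor_gain_pv_mean,
    tumor_gain_sd = tumor_gain_sd,
    noise_sd_hu = noise_sd_hu,
    class_label = class_label,
    seed = as.integer(seed)
  ), class = "phantom_params")
}

# Integer box dimensions approximating a target voxel count, with the first
# axis capped at `max_x`. Errors if the box cannot come within 20% of the
# 1 cm^3 reference-region volume.
.roi_box_dims <- function(target_vox, max_x, max_y, max_z) {
  dx <- max(1L, min(max_x, round(target_vox^(1 / 3))))
  dy <- max(1L, min(max_y, ceiling(sqrt(target_vox / dx))))
  dz <- max(1L, min(max_z, round(target_vox / (dx * dy))))
  dims <- c(dx, dy, dz)
  if (abs(prod(dims) - target_vox) / target_vox > 0.2) {
    stop("cannot place a ~1 cm^3 reference region on this grid ",
         "(geometry error)", call. = FALSE)
  }
  dims
}

#' Simulate a seeded three-phase CT phantom with masks and ground truth
#'
#' Builds NC/AR/PV volumes on one grid: an anterior fat slab (first ~20% of
#' the first axis), parenchyma elsewhere, and a spherical tumor whose
#' voxel-wise enhancement is drawn from the class-conditional gain
#' distribution. Reference-region masks are ~1 cm^3 boxes (within 20%):
#' NPP in parenchyma away from the tumor, AAF inside the fat slab. The same
#' seed reproduces the phantom bit for bit.
#'
#' @param params a [phantom_params()].
#' @return list with elements `study` ([registered_study()]),
#'   `masks` ([mask_set()]) and `truth` (class label, per-phase mean tumor
#'   gains, tumor voxel count).
#' @export
simulate_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) {
    stop("`params` must come from phantom_params()", call. = FALSE)
  }
  dm <- params$grid_shape
  sp <- params$voxel_spacing_mm
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]

  fat_end <- max(3L, floor(0.2 * nx))
  vox_vol <- sp^3
  target <- max(2L, round(1000 / vox_vol))

  # tumor sphere centered in the parenchyma region
  cx <- fat_end + ceiling((nx - fat_end) / 2)
  cy <- ceiling(ny / 2)
  cz <- ceiling(nz / 2)
  r_vox <- params$tumor_radius_mm / sp
  if (cx - r_vox <= fat_end + 1 || cx + r_vox >= nx ||
      cy - r_vox <= 1 || cy + r_vox >= ny ||
      cz - r_vox <= 1 || cz + r_vox >= nz) {
    stop("tumor does not fit inside the parenchyma region (geometry error)",
         call. = FALSE)
  }
  d2 <- outer(outer((seq_len(nx) - cx)^2, (seq_len(ny) - cy)^2, "+"),
              (seq_len(nz) - cz)^2, "+") * sp^2
  tumor <- array(d2 <= params$tumor_radius_mm^2, dm)
  if (sum(tumor) == 0) {
    stop("tumor sphere contains no voxels (geometry error)", call. = FALSE)
  }

  # AAF box inside the fat slab, centered in y/z
  aaf_dims <- .roi_box_dims(target, fat_end, ny - 2L, nz - 2L)
  aaf <- array(FALSE, dm)
  ay <- floor((ny - aaf_dims[2]) / 2)
  az <- floor((nz - aaf_dims[3]) / 2)
  aaf[seq_len(aaf_dims[1]), ay + seq_len(aaf_dims[2]),
      az + seq_len(aaf_dims[3])] <- TRUE

  # NPP box in the far parenchyma corner
  npp_dims <- .roi_box_dims(target, nx - fat_end - 2L, ny - 2L, nz - 2L)
  npp <- array(FALSE, dm)
  npp[(nx - npp_dims[1]):(nx - 1L), 1L + seq_len(npp_dims[2]),
      1L + seq_len(npp_dims[3])] <- TRUE
  if (any(npp & tumor) || any(aaf & tumor)) {
    stop("reference regions overlap the tumor (geometry error)",
         call. = FALSE)
  }

  fat <- array(FALSE, dm)
  fat[seq_len(fat_end), , ] <- TRUE

  base_nc <- array(params$parenchyma_hu_nc, dm)
  base_nc[fat] <- params$fat_hu_nc
  ar0 <- base_nc
  ar0[!fat] <- params$parenchyma_hu_nc + params$parenchyma_gain_ar
  pv0 <- base_nc
  pv0[!fat] <- params$parenchyma_hu_nc + params$parenchyma_gain_pv

  n_t <- sum(tumor)
  n_vox <- prod(dm)
  vols <- with_seed(params$seed, {
    gain_ar <- rnorm(n_t, params$tumor_gain_ar_mean, params$tumor_gain_sd)
    gain_pv <- rnorm(n_t, params$tumor_gain_pv_mean, params$tumor_gain_sd)
    ar <- ar0; ar[tumor] <- params$parenchyma_hu_nc + gain_ar
    pv <- pv0; pv[tumor] <- params$parenchyma_hu_nc + gain_pv
    nc <- base_nc
    if (params$noise_sd_hu > 0) {
      nc <- nc + array(rnorm(n_vox, 0, params$noise_sd_hu), dm)
      ar <- ar + array(rnorm(n_vox, 0, params$noise_sd_hu), dm)
      pv <- pv + array(rnorm(n_vox, 0, params$noise_sd_hu), dm)
    }
    list(nc = nc, ar = ar, pv = pv)
  })

  study <- registered_study(vols$nc, vols$ar, vols$pv, spacing_mm = sp)
  masks <- mask_set(tumor, npp, aaf, study = study)
  truth <- list(class_label = params$class_label,
                tumor_gain_ar_mean = params$tumor_gain_ar_mean,
                tumor_gain_pv_mean = params$tumor_gain_pv_mean,
                n_tumor_voxels = n_t,
                seed = params$seed)
  list(study = study, masks = masks, truth = truth)
}
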