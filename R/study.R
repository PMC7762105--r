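#' Bundle three co-registered CT phases into a study object
#'
#' A pancreatic-protocol CT study consists of a pre-contrast (NC), an arterial
#' (AR, ~40 s post-injection) and a portovenous (PV, ~65-70 s) acquisition.
#' All quantification assumes the three phases have been deformably registered
#' onto one voxel grid upstream; this constructor only checks that the grids
#' agree. Values are Hounsfield units.
#'
#' @param nc,ar,pv 3D numeric arrays of HU values sharing one grid.
#' @param spacing_mm per-axis voxel spacing in mm (length 1 or 3).
#' @return An object of class `registered_study`: a list with elements
#'   `nc`, `ar`, `pv` and `spacing_mm`.
#' @export
registered_study <- function(nc, ar, pv, spacing_mm = c(1, 1, 1)) {
  for (v in list(nc = nc, ar = ar, pv = pv)) {
    if (is.null(dim(v)) || length(dim(v)) != 3L) {
      stop("phase volumes must be 3D arrays", call. = FALSE)
    }
  }
  if (!identical(dim(nc), dim(ar)) || !identical(dim(nc), dim(pv))) {
    stop("phase volumes are not on a common grid (alignment error)",
         call. = FALSE)
  }
  if (!all(is.finite(nc)) || !all(is.finite(ar)) || !all(is.finite(pv))) {
    stop("HU values must be finite", call. = FALSE)
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0)) {
    stop("`spacing_mm` must be 3 positive values", call. = FALSE)
  }
  structure(list(nc = nc, ar = ar, pv = pv,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "registered_study")
}

#' Bundle tumor and reference-region masks aligned to a study grid
#'
#' @param tumor,npp,aaf binary 3D arrays: tumor contour, normal pancreatic
#'   parenchyma (NPP) reference region and anterior abdominal fat (AAF)
#'   reference region (each reference ~1 cm^3 in routine use).
#' @param study optional `registered_study` to check alignment against.
#' @return An object of class `mask_set` with logical arrays `tumor`,
#'   `npp`, `aaf`.
#' @export
mask_set <- function(tumor, npp, aaf, study = NULL) {
  tumor <- as_mask(tumor, "tumor")
  npp <- as_mask(npp, "npp")
  aaf <- as_mask(aaf, "aaf")
  if (!identical(dim(tumor), dim(npp)) || !identical(dim(tumor), dim(aaf))) {
    stop("masks are not on a common grid (alignment error)", call. = FALSE)
  }
  if (!is.null(study)) {
    if (!inherits(study, "registered_study")) {
      stop("`study` must be a registered_study", call. = FALSE)
    }
    if (!identical(dim(tumor), dim(study$nc))) {
      stop("masks do not match the study grid (alignment error)",
           call. = FALSE)
    }
  }
  if (sum(tumor) == 0 || sum(npp) == 0 || sum(aaf) == 0) {
    stop("all masks must be non-empty", call. = FALSE)
  }
  if (any(tumor & npp) || any(tumor & aaf)) {
    stop("tumor mask must be disjoint from the reference regions",
         call. = FALSE)
  }
  structure(list(tumor = tumor, npp = npp, aaf = aaf), class = "mask_set")
}

#' Read a co-registered three-phase study from NIfTI files
#'
#' @param nc_path,ar_path,pv_path paths to NIfTI volumes (.nii or .nii.gz).
#' @return A [registered_study()] with spacing taken from the NC header.
#' @export
read_study <- function(nc_path, ar_path, pv_path) {
  nc <- RNifti::readNifti(nc_path)
  ar <- RNifti::readNifti(ar_path)
  pv <- RNifti::readNifti(pv_path)
  spacing <- RNifti::pixdim(nc)[1:3]
  registered_study(array(as.numeric(nc), dim(nc)[1:3]),
                   array(as.numeric(ar), dim(ar)[1:3]),
                   array(as.numeric(pv), dim(pv)[1:3]),
                   spacing_mm = spacing)
}

#' Read a binary mask from a NIfTI file (any nonzero voxel = foreground)
#'
#' @param path path to a NIfTI volume.
#' @return logical 3D array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim(img)[1:3])
}

#' Write a volume or mask as NIfTI
#'
#' Masks are written as 0/1 integer volumes. Use a `.nii` suffix for
#' byte-reproducible output (gzip headers embed timestamps).
#'
#' @param x 3D numeric or logical array.
#' @param path output path (.nii or .nii.gz).
#' @param spacing_mm per-axis voxel spacing in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing_mm = c(1, 1, 1)) {
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  attr(x, "pixdim") <- as.numeric(spacing_mm)
  RNifti::writeNifti(x, path,
                     datatype = if (is.integer(x)) "int16" else "double")
  invisible(path)
}

#' @export
print.registered_study <- function(x, ...) {
  cat("Registered three-phase CT study\n")
  cat("  grid: ", paste(dim(x$nc), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing_mm, 3), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.mask_set <- function(x, ...) {
  cat("Mask set: tumor ", sum(x$tumor), " voxels, NPP ", sum(x$npp),
      " voxels, AAF ", sum(x$aaf), " voxels\n", sep = "")
  invisible(x)
}
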