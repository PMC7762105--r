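#' Perturb a contour the way a second rater would
#'
#' Emulates inter-/intrarater contouring variability by displacing the mask
#' boundary with a smooth random field. The signed distance to the boundary
#' is compared against a spatially smooth noise field scaled so its largest
#' excursion equals `magnitude_mm`; the perturbed mask is the sublevel set.
#' Boundary displacement is therefore bounded by `magnitude_mm` (up to grid
#' discretization), and for a fixed seed the symmetric difference grows
#' monotonically with the magnitude.
#'
#' @param mask logical 3D array, non-empty.
#' @param magnitude_mm maximum boundary displacement in mm; 0 returns the
#'   input unchanged.
#' @param seed integer seed controlling the displacement field.
#' @param spacing_mm per-axis voxel spacing (length 1 or 3).
#' @param smoothness_mm correlation length of the displacement field.
#' @return perturbed logical 3D array.
#' @export
perturb_contour <- function(mask, magnitude_mm, seed,
                            spacing_mm = c(1, 1, 1), smoothness_mm = 4) {
  mask <- as_mask(mask, "mask")
  if (sum(mask) == 0) stop("mask is empty", call. = FALSE)
  if (magnitude_mm < 0) stop("`magnitude_mm` must be >= 0", call. = FALSE)
  if (magnitude_mm == 0) return(mask)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)

  d_out <- distance_transform(mask, spacing_mm)
  d_in <- if (all(mask)) {
    array(sum(dim(mask) * spacing_mm), dim(mask))
  } else {
    distance_transform(!mask, spacing_mm)
  }
  # signed distance from the mask interface, which sits half a voxel beyond
  # the last foreground center: negative inside, positive outside
  half <- mean(spacing_mm) / 2
  sdist <- d_out - d_in
  sdist <- sdist - sign(sdist) * half

  field <- with_seed(seed, array(rnorm(length(mask)), dim(mask)))
  field <- gaussian_smooth(field, sigma_vox = smoothness_mm / spacing_mm)
  # normalize by the interior SD (edge replication inflates the amplitude
  # near the faces); typical displacement ~ magnitude/2, hard-clipped at
  # the magnitude so the boundary never moves farther than `magnitude_mm`
  margin <- pmin(ceiling(3 * smoothness_mm / spacing_mm),
                 pmax(dim(mask) %/% 4L, 0L))
  interior <- field[(1 + margin[1]):(dim(mask)[1] - margin[1]),
                    (1 + margin[2]):(dim(mask)[2] - margin[2]),
                    (1 + margin[3]):(dim(mask)[3] - margin[3])]
  field <- field / stats::sd(interior) * (magnitude_mm / 2)
  field <- pmin(pmax(field, -magnitude_mm), magnitude_mm)
  field <- array(field, dim(mask))

  out <- sdist <= field
  if (!any(out)) {
    stop("perturbation removed the entire mask; reduce `magnitude_mm`",
         call. = FALSE)
  }
  out
}
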