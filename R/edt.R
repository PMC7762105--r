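# Exact Euclidean distance transform for 3D binary grids, via the separable
# lower-envelope-of-parabolas algorithm applied along each axis in turn.
# Anisotropic spacing is supported by working in mm coordinates.

# 1D squared-distance transform. `f` holds squared distances (finite; use a
# large sentinel, not Inf), `x` the physical coordinates of the samples.
.dt1d <- function(f, x) {
  n <- length(f)
  if (n == 1L) return(f)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2L:n) {
    p <- v[k]
    s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
    while (s <= z[k]) {
      k <- k - 1L
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in 1L:n) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    d[q] <- (x[q] - x[v[j]])^2 + f[v[j]]
  }
  d
}

# Apply a line operator down the given axis of a 3D array.
.along_axis <- function(arr, axis, fun) {
  perm <- c(axis, setdiff(1:3, axis))
  g <- aperm(arr, perm)
  dg <- dim(g)
  gm <- matrix(g, nrow = dg[1L])
  gm <- fun(gm)
  aperm(array(gm, dg), order(perm))
}

#' Euclidean distance to the nearest foreground voxel
#'
#' Exact 3D Euclidean distance transform (separable parabolic-envelope
#' algorithm) in physical units. Voxels inside `mask` get distance 0.
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param spacing_mm per-axis voxel spacing (length 1 or 3).
#' @return numeric 3D array of distances in mm.
#' @export
distance_transform <- function(mask, spacing_mm = c(1, 1, 1)) {
  mask <- as_mask(mask, "mask")
  if (sum(mask) == 0) stop("mask is empty", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  dm <- dim(mask)
  big <- (sum(dm * spacing_mm))^2
  f <- array(0, dm)
  f[!mask] <- big
  for (ax in 1:3) {
    xcoord <- (seq_len(dm[ax])) * spacing_mm[ax]
    f <- .along_axis(f, ax, function(gm) {
      apply(gm, 2L, .dt1d, x = xcoord)
    })
  }
  sqrt(f)
}

# Separable Gaussian smoothing with edge replication; sigma in voxels,
# possibly per-axis.
gaussian_smooth <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1L) sigma_vox <- rep(sigma_vox, 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-r, r), sd = s)
    kern <- kern / sum(kern)
    arr <- .along_axis(arr, ax, function(gm) {
      n <- nrow(gm)
      padded <- rbind(gm[rep(1L, r), , drop = FALSE],
                      gm,
                      gm[rep(n, r), , drop = FALSE])
      sm <- stats::filter(padded, kern, sides = 2)
      matrix(sm[(r + 1L):(r + n), ], nrow = n)
    })
  }
  arr
}
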