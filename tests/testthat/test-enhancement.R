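test_that("enhancement map is voxelwise phase minus pre-contrast", {
  st <- tiny_study(1)
  expect_equal(enhancement_map(st, "ar"), st$ar - st$nc)

  # constant case: nc = 40, ar = 100 everywhere -> constant 60
  dm <- c(16, 16, 16)
  st2 <- registered_study(array(40, dm), array(100, dm), array(70, dm))
  expect_true(all(enhancement_map(st2, "ar") == 60))
  expect_true(all(enhancement_map(st2, "ar") - enhancement_map(st2, "ar") == 0))

  # identical phases -> all-zero map
  st3 <- registered_study(st$ar, st$ar, st$pv)
  expect_true(all(enhancement_map(st3, "ar") == 0))

  # random 4x4x4 equals an element-by-element loop subtraction
  set.seed(42)
  nc <- array(rnorm(64), c(4, 4, 4))
  ar <- array(rnorm(64), c(4, 4, 4))
  st4 <- registered_study(nc, ar, nc)
  em <- enhancement_map(st4, "ar")
  loop <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    loop[i, j, k] <- ar[i, j, k] - nc[i, j, k]
  }
  expect_identical(em, loop)
})

test_that("reference statistics are the ROI sample mean and SD", {
  dm <- c(8, 8, 8)
  emap <- array(0, dm)
  roi <- array(FALSE, dm)

  roi[1:3, 1, 1] <- TRUE
  emap[roi] <- 50
  rs <- reference_stats(emap, roi)
  expect_equal(rs$mu, 50)
  expect_equal(rs$sigma, 0)
  expect_equal(rs$n_voxels, 3L)

  # two-point closed form
  roi2 <- array(FALSE, dm); roi2[1:2, 2, 1] <- TRUE
  emap[1:2, 2, 1] <- c(40, 60)
  rs2 <- reference_stats(emap, roi2)
  expect_equal(rs2$mu, 50)
  expect_equal(rs2$sigma, sqrt(200), tolerance = 1e-12)  # 14.142...

  # random 200-voxel ROI matches the two-pass oracle
  set.seed(7)
  emap3 <- array(rnorm(512, 30, 12), dm)
  roi3 <- array(FALSE, dm)
  roi3[sample.int(512, 200)] <- TRUE
  rs3 <- reference_stats(emap3, roi3)
  o <- oracle_two_pass(emap3[roi3])
  expect_equal(rs3$mu, o$mu, tolerance = 1e-9)
  expect_equal(rs3$sigma, o$sigma, tolerance = 1e-9)

  # fewer than two voxels is an error
  roi4 <- array(FALSE, dm); roi4[1, 1, 1] <- TRUE
  expect_error(reference_stats(emap, roi4), "at least 2")
})

test_that("normalized enhancement counts tumor voxels strictly above mu + n*sigma", {
  dm <- c(6, 6, 6)
  emap <- array(0, dm)
  tumor <- array(FALSE, dm); tumor[2:4, 2:4, 2:4] <- TRUE
  ref <- structure(list(mu = 20, sigma = 5, n_voxels = 10L),
                   class = "reference_stats")

  emap[tumor] <- 20  # exactly at the reference mean
  expect_equal(normalized_enhancement(emap, tumor, ref), 0)

  emap[tumor] <- 30  # mu + 2 sigma
  expect_equal(normalized_enhancement(emap, tumor, ref), 100)

  # exactly at the threshold: strict comparison scores 0
  emap[tumor] <- 25
  expect_equal(normalized_enhancement(emap, tumor, ref), 0)

  # 13 of 27 voxels above threshold -> 48.148...
  vals <- c(rep(26, 13), rep(24, 14))
  emap[tumor] <- vals
  expect_equal(normalized_enhancement(emap, tumor, ref), 100 * 13 / 27,
               tolerance = 1e-12)

  # sigma = 0 degrades the threshold to mu, with a warning
  ref0 <- structure(list(mu = 20, sigma = 0, n_voxels = 10L),
                    class = "reference_stats")
  emap[tumor] <- 20
  expect_warning(ne0 <- normalized_enhancement(emap, tumor, ref0),
                 "reference SD is zero")
  expect_equal(ne0, 0)
})

test_that("NE equals the exhaustive voxel-count oracle on random phantoms", {
  for (seed in 1:25) {
    mp <- random_mini_phantom(seed)
    ref <- structure(list(mu = 40, sigma = 12, n_voxels = 50L),
                     class = "reference_stats")
    expect_equal(normalized_enhancement(mp$emap, mp$tumor, ref),
                 oracle_ne_count(mp$emap, mp$tumor, 40, 12))
  }
})

test_that("NE is invariant to joint positive affine recalibration", {
  for (seed in 1:10) {
    mp <- random_mini_phantom(seed)
    roi <- array(FALSE, dim(mp$emap)); roi[1:4, 1:4, 1] <- TRUE
    ne1 <- normalized_enhancement(mp$emap, mp$tumor,
                                  reference_stats(mp$emap, roi))
    recal <- 3 + 1.7 * mp$emap
    ne2 <- normalized_enhancement(recal, mp$tumor,
                                  reference_stats(recal, roi))
    expect_equal(ne1, ne2, tolerance = 1e-12)
  }
})

test_that("compute_ne_features composes map, reference stats and counting", {
  set.seed(11)
  dm <- c(12, 12, 12)
  st <- registered_study(array(rnorm(prod(dm), 40, 4), dm),
                         array(rnorm(prod(dm), 95, 10), dm),
                         array(rnorm(prod(dm), 85, 10), dm))
  tumor <- array(FALSE, dm); tumor[5:8, 5:8, 5:8] <- TRUE
  npp <- array(FALSE, dm); npp[1:3, 1:3, 1:3] <- TRUE
  aaf <- array(FALSE, dm); aaf[10:12, 10:12, 10:12] <- TRUE
  masks <- mask_set(tumor, npp, aaf, study = st)
  f <- compute_ne_features(st, masks)
  for (phase in c("ar", "pv")) {
    em <- st[[phase]] - st$nc
    for (refname in c("npp", "aaf")) {
      o <- oracle_two_pass(em[masks[[refname]]])
      expected <- oracle_ne_count(em, tumor, o$mu, o$sigma)
      expect_equal(f[[paste0("ne_", phase, "_", refname)]], expected)
    }
  }
  expect_true(all(unlist(as.data.frame(f)) >= 0 &
                    unlist(as.data.frame(f)) <= 100))
})

test_that("colormap bins tumor enhancement into 8 ordered levels", {
  dm <- c(6, 6, 6)
  emap <- array(0, dm)
  tumor <- array(FALSE, dm); tumor[2:5, 2:5, 2:5] <- TRUE

  # constant tumor -> all level 1, background 0
  emap[tumor] <- 7
  lab <- colormap_labels(emap, tumor)
  expect_true(all(lab[tumor] == 1L))
  expect_true(all(lab[!tumor] == 0L))

  # values spanning [0, 80): bin width 10, value 10 falls in bin 2
  vals <- seq(0, 79.9, length.out = sum(tumor))
  vals[3] <- 10
  emap[tumor] <- vals
  lab2 <- colormap_labels(emap, tumor)
  expect_equal(lab2[tumor][3], 2L)
  expect_lte(max(lab2), 8L)
  expect_gte(min(lab2[tumor]), 1L)

  # labels non-decreasing in the voxel value (sort-and-check)
  set.seed(3)
  emap[tumor] <- rnorm(sum(tumor), 50, 20)
  lab3 <- colormap_labels(emap, tumor)
  ord <- order(emap[tumor])
  expect_true(all(diff(lab3[tumor][ord]) >= 0))
  # every tumor voxel gets exactly one of the 8 levels
  expect_true(all(lab3[tumor] %in% 1:8))
})
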