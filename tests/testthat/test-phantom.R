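test_that("phantom geometry: sphere tumor, ~1 cm^3 references, disjoint masks", {
  ph <- simulate_phantom(phantom_params(seed = 2))
  vox_vol <- prod(ph$study$spacing_mm)
  npp_cc <- sum(ph$masks$npp) * vox_vol / 1000
  aaf_cc <- sum(ph$masks$aaf) * vox_vol / 1000
  expect_gte(npp_cc, 0.8); expect_lte(npp_cc, 1.2)
  expect_gte(aaf_cc, 0.8); expect_lte(aaf_cc, 1.2)
  expect_false(any(ph$masks$tumor & ph$masks$npp))
  expect_false(any(ph$masks$tumor & ph$masks$aaf))
  expect_false(any(ph$masks$npp & ph$masks$aaf))
  # tumor voxel count close to the sphere volume
  expect_equal(sum(ph$masks$tumor) * vox_vol, 4 / 3 * pi * 10^3,
               tolerance = 0.05)
  # AAF sits in fat (negative NC HU), NPP in parenchyma
  expect_lt(mean(ph$study$nc[ph$masks$aaf]), 0)
  expect_gt(mean(ph$study$nc[ph$masks$npp]), 0)
})

test_that("phantom generation is bit-identical under the same seed", {
  a <- simulate_phantom(phantom_params(seed = 7))
  b <- simulate_phantom(phantom_params(seed = 7))
  expect_identical(a$study$nc, b$study$nc)
  expect_identical(a$study$ar, b$study$ar)
  expect_identical(a$study$pv, b$study$pv)
  expect_identical(a$masks$tumor, b$masks$tumor)
  c <- simulate_phantom(phantom_params(seed = 8))
  expect_false(identical(a$study$ar, c$study$ar))
})

test_that("noiseless iso-enhancing tumor scores NE 0; +50 HU tumor scores 100", {
  pp0 <- phantom_params(noise_sd_hu = 0, tumor_gain_sd = 0,
                        tumor_gain_ar_mean = 60, tumor_gain_pv_mean = 50,
                        seed = 3)
  ph0 <- simulate_phantom(pp0)
  suppressWarnings(f0 <- compute_ne_features(ph0$study, ph0$masks))
  expect_equal(f0$ne_ar_npp, 0)
  expect_equal(f0$ne_pv_npp, 0)

  pp1 <- phantom_params(noise_sd_hu = 0, tumor_gain_sd = 0,
                        tumor_gain_ar_mean = 110, tumor_gain_pv_mean = 100,
                        seed = 3)
  ph1 <- simulate_phantom(pp1)
  suppressWarnings(f1 <- compute_ne_features(ph1$study, ph1$masks))
  expect_equal(f1$ne_ar_npp, 100)
  expect_equal(f1$ne_pv_npp, 100)
})

test_that("phantoms that cannot fit the tumor or references raise geometry errors", {
  expect_error(simulate_phantom(phantom_params(grid_shape = c(20, 20, 20),
                                               tumor_radius_mm = 12,
                                               seed = 1)),
               "geometry")
  expect_error(phantom_params(grid_shape = c(8, 8, 8)), ">= 16")
  expect_error(phantom_params(noise_sd_hu = -1), ">= 0")
})

test_that("class defaults separate NE in the documented direction", {
  f_high <- compute_ne_features(
    simulate_phantom(phantom_params(class_label = "high", seed = 5))$study,
    simulate_phantom(phantom_params(class_label = "high", seed = 5))$masks)
  ph_low <- simulate_phantom(phantom_params(class_label = "low", seed = 5))
  f_low <- compute_ne_features(ph_low$study, ph_low$masks)
  # low delta (inconspicuous, parenchyma-like) has the higher NE
  expect_gt(f_low$ne_ar_npp, f_high$ne_ar_npp)
  expect_gt(f_low$ne_pv_npp, f_high$ne_pv_npp)
})

test_that("distance transform matches exhaustive pairwise distances", {
  set.seed(14)
  dm <- c(10, 9, 8)
  mask <- array(runif(prod(dm)) < 0.1, dm)
  mask[5, 5, 4] <- TRUE
  sp <- c(1, 1.5, 2)
  d <- distance_transform(mask, sp)
  idx_all <- which(array(TRUE, dm), arr.ind = TRUE)
  seeds <- which(mask, arr.ind = TRUE)
  for (r in sample.int(nrow(idx_all), 40)) {
    p <- idx_all[r, ]
    d2 <- ((seeds[, 1] - p[1]) * sp[1])^2 + ((seeds[, 2] - p[2]) * sp[2])^2 +
      ((seeds[, 3] - p[3]) * sp[3])^2
    expect_equal(d[p[1], p[2], p[3]], sqrt(min(d2)), tolerance = 1e-10)
  }
})
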