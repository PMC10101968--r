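# 44-feature extraction: RI statistics, morphology, GLCM Haralick.

test_that("RI statistics of a homogeneous sphere follow the conventions", {
  ph <- sphere_phantom()
  st <- ri_statistics(ph$tomogram, ph$support)
  expect_equal(st[["stats_mean"]], 1.354, tolerance = 1e-12)
  expect_equal(st[["stats_median"]], 1.354, tolerance = 1e-12)
  expect_equal(st[["stats_max"]], 1.354, tolerance = 1e-12)
  expect_equal(st[["stats_sd"]], 0)
  expect_equal(st[["stats_skewness"]], 0)
  expect_equal(st[["stats_kurtosis"]], 0)
  expect_equal(st[["stats_entropy"]], 0)
  expect_equal(st[["stats_q25"]], 1.354, tolerance = 1e-12)
  # dry mass: 0.02 * (4/3) pi 4.5^3 um^3 / 0.19 mL/g ~ 40.2 pg
  expect_lt(abs(st[["stats_dry_mass_pg"]] - 40.2) / 40.2, 0.02)
})

test_that("a two-level volume yields the histogram statistics directly", {
  vol <- array(1.34, c(20, 20, 20))
  vol[1:10, , ] <- 1.36
  tom <- ri_tomogram(vol, 0.3, n0 = 1.334)
  sup <- cell_support(array(TRUE, c(20, 20, 20)), 0.3)
  st <- ri_statistics(tom, sup)
  expect_true(st[["stats_median"]] >= 1.34 && st[["stats_median"]] <= 1.36)
  expect_equal(st[["stats_entropy"]], 1, tolerance = 1e-12)
  expect_equal(st[["stats_q25"]], 1.34, tolerance = 1e-9)
  expect_equal(st[["stats_q75"]], 1.36, tolerance = 1e-9)
})

test_that("sphere morphology matches the analytic solid", {
  ph <- sphere_phantom()
  mo <- morphology_3d(ph$support, ph$tomogram)
  expect_lt(abs(mo[["morph_sphericity"]] - 1), 0.03)
  expect_lt(abs(mo[["morph_solidity"]] - 1), 0.02)
  for (ax in c("morph_axis_major", "morph_axis_mid", "morph_axis_minor"))
    expect_lt(abs(mo[[ax]] - 9) / 9, 0.03)
  expect_lt(mo[["morph_centroid_offset"]], 0.01)
  # extent carries a (2R/(2R+1))^3 voxelization bias, so it is checked
  # at the native pitch where the sphere spans 80 voxels
  phf <- generate_phantom(sphere_params(), c(91, 91, 91), 0.1125)
  mof <- morphology_3d(phf$support, phf$tomogram)
  expect_lt(abs(mof[["morph_extent"]] - pi / 6) / (pi / 6), 0.05)
  expect_lt(abs(mof[["morph_sphericity"]] - 1), 0.03)
})

test_that("ellipsoid axis lengths recover the 2:1:1 ratio", {
  p <- sphere_params()
  p$equiv_radius <- 3.5
  p$axis_ratios <- c(2, 1, 1) / 2^(1 / 3)
  ph <- generate_phantom(p, test_dim, test_pitch)
  mo <- morphology_3d(ph$support, ph$tomogram)
  expect_lt(abs(mo[["morph_axis_major"]] / mo[["morph_axis_minor"]] - 2), 0.06)
})

test_that("morphology rejects empty or fragmented supports", {
  ph <- sphere_phantom()
  frag <- ph$support$mask
  frag[1:3, 1:3, 1:3] <- TRUE  # disconnected corner blob
  expect_error(morphology_3d(cell_support(frag, test_pitch), ph$tomogram),
               "connected")
})

test_that("quantization bins uniformly and ignores the background", {
  vol <- array(0, c(12, 12, 12))
  sup <- array(TRUE, c(12, 12, 12))
  lev <- quantize(vol, sup, 32)
  expect_equal(unique(as.integer(lev)), 1L)
  ramp <- array(seq(0, 1, length.out = 12^3), c(12, 12, 12))
  lev_r <- quantize(ramp, sup, 32)
  counts <- tabulate(lev_r, 32)
  expect_true(all(abs(counts - mean(counts)) / mean(counts) < 0.1))
  # invariance to positive affine maps
  lev_a <- quantize(3.2 * ramp + 0.7, sup, 32)
  expect_identical(lev_r, lev_a)
  # off-support voxels flagged 0
  sup2 <- sup; sup2[1, 1, 1] <- FALSE
  expect_equal(quantize(ramp, sup2, 32)[1, 1, 1], 0L)
})

test_that("GLCM of a constant region is a single certain entry", {
  lev <- array(1L, c(10, 10, 10))
  g <- glcm(lev, c(0, 1, 0), 0.5, test_pitch, n_levels = 8)
  expect_equal(sum(g), 1)
  expect_equal(g[1, 1], 1)
  h <- haralick(g)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["max_probability"]], 1)
  expect_equal(h[["homogeneity"]], 1)
})

test_that("a strict checkerboard pairs only across levels", {
  d <- c(8, 8, 8)
  idx <- array(seq_len(prod(d)), d)
  j <- (slice.index(idx, 2) + slice.index(idx, 1) + slice.index(idx, 3))
  lev <- array(ifelse(j %% 2 == 0, 1L, 2L), d)
  # distance of exactly 1 voxel along y
  g <- glcm(lev, c(0, 1, 0), test_pitch, test_pitch, n_levels = 2)
  expect_equal(g[1, 2], 0.5)
  expect_equal(g[2, 1], 0.5)
  expect_equal(g[1, 1], 0)
  expect_equal(g[2, 2], 0)
  h <- haralick(g)
  expect_equal(h[["energy"]], 0.5)
  expect_equal(h[["entropy"]], 1)
  expect_equal(h[["contrast"]], 1)
  expect_equal(h[["max_probability"]], 0.5)
  expect_equal(g, t(unclass(g)), ignore_attr = TRUE)  # symmetric
  expect_error(glcm(lev, c(0, 1, 0), 100, test_pitch, 2), "exceeds")
})

test_that("Haralick values match the brute-force oracle to 1e-12", {
  set.seed(7)
  for (r in 1:25) {
    raw <- matrix(stats::rexp(64), 8, 8)
    p <- (raw + t(raw)) / (2 * sum(raw))
    got <- haralick(p)
    want <- haralick_brute(p)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
  # closed forms on the uniform GLCM
  P <- 16
  u <- matrix(1 / P^2, P, P)
  hu <- haralick(u)
  expect_equal(hu[["energy"]], 1 / P^2, tolerance = 1e-12)
  expect_equal(hu[["entropy"]], 2 * log2(P), tolerance = 1e-12)
  expect_error(haralick(2 * u), "normalized")
})

test_that("3D GLCM matches exhaustive pair enumeration", {
  set.seed(11)
  P <- 5
  lev <- array(sample(0:P, 16^3, replace = TRUE), c(16, 16, 16))
  dirs <- glcm_directions_3d()
  for (dist_vox in c(1L, 2L)) {
    for (r in seq_len(nrow(dirs))) {
      off <- dirs[r, ] * dist_vox
      got <- glcm(lev, dirs[r, ], dist_vox * test_pitch, test_pitch,
                  n_levels = P)
      want <- glcm_brute(lev, off, P)
      expect_equal(unclass(got), want, tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("glcm_features_3d averages 24 values with degenerate closed forms", {
  ph <- sphere_phantom()
  v <- glcm_features_3d(ph$tomogram, ph$support)
  expect_length(v, 24)
  expect_equal(v[["glcm_d05_energy"]], 1)
  expect_equal(v[["glcm_d05_entropy"]], 0)
  expect_equal(v[["glcm_d10_contrast"]], 0)
  expect_equal(v[["glcm_d10_max_probability"]], 1)
})

test_that("per-direction energies agree on isotropic texture", {
  set.seed(3)
  d <- c(24, 24, 24)
  vol <- array(cytotomo:::cpp_smooth3(rnorm(prod(d)), d, 1.2), d)
  sup <- array(TRUE, d)
  lev <- quantize(vol, sup, 16)
  dirs <- glcm_directions_3d()
  en <- vapply(seq_len(nrow(dirs)), function(r)
    haralick(glcm(lev, dirs[r, ], test_pitch, test_pitch, 16))[["energy"]], 0)
  expect_true(all(abs(en - mean(en)) < 3 * stats::sd(en) + 1e-12))
})

test_that("features_3d yields 44 stable, finite, linearly-behaved values", {
  ph <- textured_phantom("NB", 31)
  f <- features_3d(ph$tomogram, ph$support)
  expect_length(f, 44)
  expect_identical(names(f), feature_names("3D"))
  expect_true(all(is.finite(f)))
  # repeatability
  expect_identical(f, features_3d(ph$tomogram, ph$support))
  # mean-RI feature responds linearly to intensity scaling
  a <- 1.08
  fs <- features_3d(intensity_scale(ph$tomogram, a), ph$support)
  expect_equal(fs[["stats_mean"]] - 1.334, a * (f[["stats_mean"]] - 1.334),
               tolerance = 1e-9)
})

test_that("generated class populations separate on the mean-RI feature", {
  mri <- sapply(c("NB", "OC"), function(cls) {
    mean(vapply(1:25, function(i) {
      ph <- generate_phantom(sample_class_params(cls, 3000 + i),
                             test_dim, test_pitch)
      ri_statistics(ph$tomogram, ph$support)[["stats_mean"]]
    }, 0))
  })
  expect_gt(mri[["OC"]], mri[["NB"]])
})

test_that("QPM segmentation recovers the projected support", {
  ph <- sphere_phantom()
  q <- project_qpm(ph$tomogram, 0)
  sup <- segment_qpm(q)
  a_analytic <- pi * 4.5^2
  expect_lt(abs(sum(sup$mask) * test_pitch^2 - a_analytic) / a_analytic, 0.03)
  proj_true <- apply(ph$support$mask, c(1, 2), any)
  inter <- sum(sup$mask & proj_true)
  dice <- 2 * inter / (sum(sup$mask) + sum(proj_true))
  expect_gte(dice, 0.95)
  expect_error(segment_qpm(qpm(matrix(0, 21, 21), 0.3)), "no pixel above")
})

test_that("2D shape features hit their closed forms", {
  # rasterized disk via the sphere QPM
  ph <- sphere_phantom()
  f <- features_2d(project_qpm(ph$tomogram, 0))
  expect_length(f, 44)
  expect_identical(names(f), feature_names("2D"))
  expect_lt(abs(f[["morph_circularity"]] - 1), 0.03)
  expect_lt(f[["morph_eccentricity"]], 0.25)
  expect_lt(abs(f[["morph_feret_max"]] - 9), sqrt(2) * test_pitch + 0.15)
  expect_lt(abs(f[["morph_axis_major"]] - 9) / 9, 0.03)
  # square mask: circularity pi/4 (corner bias of the smoothed-contour
  # perimeter is a fixed ~1.7 px, so test at an 80 px side)
  m <- matrix(FALSE, 101, 101); m[11:90, 11:90] <- TRUE
  q <- qpm(ifelse(m, 1, 0), test_pitch)
  fsq <- features_2d(q, support = cell_support(m, test_pitch))
  expect_lt(abs(fsq[["morph_circularity"]] - pi / 4) / (pi / 4), 0.03)
})

test_that("dry mass agrees between a tomogram and its 0-degree QPM", {
  for (cls in c("MC", "NB", "OC")) {
    ph <- textured_phantom(cls, 37)
    f3 <- ri_statistics(ph$tomogram, ph$support)[["stats_dry_mass_pg"]]
    q <- project_qpm(ph$tomogram, 0)
    f2 <- features_2d(q)[["stats_dry_mass_pg"]]
    expect_lt(abs(f3 - f2) / f3, 0.01)
  }
})
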