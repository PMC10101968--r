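# 3D augmentation: intensity scaling, intensity shifting, morphological
# alteration and their composition.

test_that("intensity scaling rescales the contrast only on the support", {
  ph <- sphere_phantom()
  tom <- ph$tomogram
  expect_equal(intensity_scale(tom, 1)$values, tom$values, tolerance = 1e-15)
  s <- intensity_scale(tom, 0.9)
  # a support voxel at RI 1.354 (dn 0.02) lands on 1.352 (dn 0.018)
  expect_equal(unique(round(s$values[ph$support$mask], 9)), 1.3520)
  expect_true(all(s$values[!ph$support$mask] == 1.334))
  expect_error(intensity_scale(tom, -1), "positive")
})

test_that("dry mass scales linearly under intensity scaling", {
  ph <- textured_phantom("NB", 13)
  sup <- ph$support
  m0 <- ri_statistics(ph$tomogram, sup)[["stats_dry_mass_pg"]]
  m2 <- ri_statistics(intensity_scale(ph$tomogram, 1.07), sup)[["stats_dry_mass_pg"]]
  expect_equal(m2, 1.07 * m0, tolerance = 1e-9)
})

test_that("intensity shifting respects the half-minimum bound", {
  ph <- sphere_phantom()
  tom9 <- intensity_scale(ph$tomogram, 0.9)  # dn = 0.018 everywhere on the support
  expect_equal(intensity_shift(tom9, 0)$values, tom9$values, tolerance = 1e-15)
  sh <- intensity_shift(tom9, 0.005)
  expect_equal(unique(round(sh$values[ph$support$mask], 9)), 1.3570)
  dn <- sh$values - sh$n0
  expect_gt(min(dn[ph$support$mask]), 0)
  expect_error(intensity_shift(tom9, 0.01), "bound")
})

test_that("morphological alteration changes extents as requested", {
  ph <- textured_phantom("NB", 17, dim = c(81, 81, 81))
  tom <- ph$tomogram
  same <- morph_alter(tom, 0, 0, 0)
  expect_equal(dim(same$values), c(81, 81, 81))
  expect_lt(max(abs(same$values - tom$values)), 5e-3)
  alt <- morph_alter(tom, 20, 0, -20)
  expect_equal(dim(alt$values), c(101, 81, 61))
  ext_len <- function(m, axis) {
    w <- which(m > 1.334, arr.ind = TRUE)
    max(w[, axis]) - min(w[, axis]) + 1
  }
  expect_gt(ext_len(alt$values, 1), ext_len(tom$values, 1))
  expect_lt(ext_len(alt$values, 3), ext_len(tom$values, 3))
  expect_error(morph_alter(tom, -60, 0, 0), "degenerate")
})

test_that("isotropic stretch preserves sphericity", {
  ph <- sphere_phantom()
  alt <- morph_alter(ph$tomogram, 20, 20, 20)
  sup <- cell_support(alt$values > alt$n0, alt$voxel_pitch)
  mo <- morphology_3d(sup, alt)
  expect_lt(abs(mo[["morph_sphericity"]] - 1), 0.02)
})

test_that("augment is seeded, bounded and positive on the new support", {
  ph <- textured_phantom("OC", 23)
  a1 <- augment(ph$tomogram, 99)
  a2 <- augment(ph$tomogram, 99)
  expect_identical(a1$tomogram$values, a2$tomogram$values)
  expect_identical(a1$params, a2$params)
  for (s in 1:20) {
    a <- augment(ph$tomogram, s)
    expect_gte(a$params$a, 0.9); expect_lte(a$params$a, 1.1)
    expect_true(all(abs(a$params$c) <= 20))
    dn <- a$tomogram$values - a$tomogram$n0
    expect_gte(min(dn[dn != 0]), 0)  # never below the medium
    expect_gt(max(dn), 0)
  }
})

test_that("augment equals the explicit scale-shift-morph composition", {
  ph <- textured_phantom("MC", 29)
  a <- augment(ph$tomogram, 41)
  manual <- morph_alter(intensity_shift(intensity_scale(ph$tomogram,
                                                        a$params$a),
                                        a$params$b),
                        a$params$c[1], a$params$c[2], a$params$c[3])
  expect_equal(a$tomogram$values, manual$values, tolerance = 1e-12)
})

test_that("scale and shift commute with the adjusted shift", {
  ph <- sphere_phantom()
  tom <- ph$tomogram
  a <- 1.05; b <- 0.004
  lhs <- intensity_scale(intensity_shift(tom, b), a)
  rhs <- intensity_shift(intensity_scale(tom, a), a * b)
  expect_equal(lhs$values, rhs$values, tolerance = 1e-12)
})

test_that("the drawn scale factors follow U(0.9, 1.1)", {
  ph <- sphere_phantom(dim = c(52, 52, 52), pitch = 0.45)
  draws <- vapply(1:2000, function(s) augment(ph$tomogram, s)$params$a, 0)
  expect_lt(abs(mean(draws) - 1), 0.005)
  expect_gte(min(draws), 0.9)
  expect_lte(max(draws), 1.1)
})

test_that("augment_dataset applies multiplicities to the train split only", {
  counts <- list(train = c(MC = 2L, NB = 1L, OC = 1L),
                 test = c(MC = 1L, NB = 1L, OC = 1L))
  d <- file.path(tempdir(), "bench_aug")
  m <- make_benchmark(counts, master_seed = 3L, out_dir = d,
                      dim = c(61, 61, 61), voxel_pitch = 0.36)
  out <- augment_dataset(m, c(MC = 2L, NB = 1L, OC = 0L), rng_seed = 5, dir = d)
  # 2 MC x (1+2) + 1 NB x (1+1) + 1 OC x (1+0) train records, 3 test
  expect_equal(sum(out$split == "train" & out$class_label == "MC"), 6)
  expect_equal(sum(out$split == "train" & out$class_label == "NB"), 2)
  expect_equal(sum(out$split == "train" & out$class_label == "OC"), 1)
  expect_equal(sum(out$split == "test"), 3)
  aug_rows <- out[!is.na(out$source_id), ]
  expect_true(all(aug_rows$split == "train"))
  expect_true(all(file.exists(file.path(d, out$path))))
  # provenance: class label inherited from the source record
  src_cls <- m$class_label[match(aug_rows$source_id, m$id)]
  expect_identical(aug_rows$class_label, src_cls)
  expect_error(augment_dataset(m[m$split == "test", ], rng_seed = 1, dir = d),
               "train split")
  unlink(d, recursive = TRUE)
})

test_that("the stated multiplicities reproduce the augmented-set sizes", {
  mult <- c(MC = 9, NB = 3, OC = 3)
  train <- c(MC = 200, NB = 250, OC = 250)
  expect_equal(unname(train * (mult + 1)), c(2000, 1000, 1000))
})
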