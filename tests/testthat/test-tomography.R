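# Angle estimation, filtered back projection, support segmentation.

test_that("the rotation period is recovered exactly from uniform rolls", {
  ph <- textured_phantom("NB", 3)
  qs <- project_sequence(ph$tomogram, (0:129) * 3)  # 120 frames/turn
  tr <- estimate_angles(qs)
  expect_equal(tr$estimated_period, 120)
  expect_lt(max(abs(tr$angles_deg - (0:129) * 3)), 1)
  qs2 <- project_sequence(ph$tomogram, (0:99) * 4)  # 90 frames/turn
  expect_equal(estimate_angles(qs2)$estimated_period, 90)
})

test_that("identical frames give no rotation period", {
  ph <- sphere_phantom()
  q0 <- project_qpm(ph$tomogram, 0)
  qs <- replicate(60, q0, simplify = FALSE)
  expect_error(estimate_angles(qs), "period not found")
})

test_that("period recovery is exact across random angular speeds", {
  hits <- 0
  for (s in 1:20) {
    ph <- generate_phantom(sample_class_params(c("MC", "NB", "OC")[(s %% 3) + 1],
                                               700 + s), test_dim, test_pitch)
    set.seed(s)
    Tt <- round(360 / runif(1, 2, 6))
    step <- 360 / Tt
    qs <- project_sequence(ph$tomogram, (seq_len(Tt + 10) - 1) * step)
    est <- tryCatch(estimate_angles(qs)$estimated_period, error = function(e) NA)
    hits <- hits + isTRUE(est == Tt)
  }
  expect_gte(hits, 18)
})

test_that("FBP recovers a homogeneous sphere's RI", {
  ph <- sphere_phantom()
  qs <- project_sequence(ph$tomogram, seq(0, 358, by = 2))  # 180 projections
  rec <- reconstruct_fbp(qs)
  d <- dim(ph$support$mask)
  er <- array(cytotomo:::cpp_binary_morph(as.logical(ph$support$mask), d, 0L), d)
  er <- array(cytotomo:::cpp_binary_morph(as.logical(er), d, 0L), d)
  expect_lt(abs(median(rec$values[er]) - 1.354), 5e-4)
  expect_lt(sqrt(mean((rec$values[er] - 1.354)^2)), 2e-3)
})

test_that("all-zero projections reconstruct the uniform medium", {
  qs <- lapply(c(0, 90), function(a) qpm(matrix(0, 41, 41), 0.3, angle_deg = a))
  rec <- reconstruct_fbp(qs)
  expect_true(all(rec$values == 1.334))
})

test_that("more projections reconstruct at least as accurately", {
  ph <- textured_phantom("OC", 21)
  tru <- ph$tomogram$values
  er <- ph$support$mask
  rmse <- function(n_proj) {
    qs <- project_sequence(ph$tomogram, seq(0, 360 - 360 / n_proj,
                                            length.out = n_proj))
    rec <- reconstruct_fbp(qs)
    sqrt(mean((rec$values[er] - tru[er])^2))
  }
  expect_lte(rmse(180), rmse(60))
})

test_that("FBP is linear in the projections", {
  ph <- sphere_phantom()
  qs <- project_sequence(ph$tomogram, seq(0, 350, by = 10))
  qs2 <- lapply(qs, function(q) qpm(2 * q$phase, q$pixel_pitch,
                                    q$wavelength, q$angle_deg))
  r1 <- reconstruct_fbp(qs)
  r2 <- reconstruct_fbp(qs2)
  expect_equal(r2$values - 1.334, 2 * (r1$values - 1.334), tolerance = 1e-6)
})

test_that("reconstruction input contracts are enforced", {
  q1 <- qpm(matrix(0.1, 31, 31), 0.3, angle_deg = 0)
  q2 <- qpm(matrix(0.1, 21, 21), 0.3, angle_deg = 10)
  expect_error(reconstruct_fbp(list(q1, q2)), "mismatched")
  expect_error(reconstruct_fbp(list(q1)), "at least 2")
  expect_error(reconstruct_fbp(list(q1, q1)), "distinct")
})

test_that("segmentation recovers true and reconstructed supports", {
  ph <- sphere_phantom()
  seg <- segment_support(ph$tomogram)
  v_analytic <- 4 / 3 * pi * 4.5^3
  expect_lt(abs(sum(seg$mask) * test_pitch^3 - v_analytic) / v_analytic, 0.02)
  # FBP blurs the edge by about one voxel, so the overlap check runs at
  # the native pitch where the shell is small relative to the radius
  phf <- generate_phantom(sphere_params(), c(91, 91, 91), 0.1125)
  qs <- project_sequence(phf$tomogram, seq(0, 358, by = 2))
  rec <- reconstruct_fbp(qs)
  seg_rec <- segment_support(rec)
  inter <- sum(seg_rec$mask & phf$support$mask)
  dice <- 2 * inter / (sum(seg_rec$mask) + sum(phf$support$mask))
  expect_gte(dice, 0.95)
})

test_that("a uniform volume cannot be segmented", {
  tom <- ri_tomogram(array(1.334, c(31, 31, 31)), 0.3)
  expect_error(segment_support(tom), "no voxels above")
})
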