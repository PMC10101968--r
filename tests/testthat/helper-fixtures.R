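# Shared fixtures: all geometry is generated in code at a reduced grid
# (81 voxels at ~0.279 um -- the same physical box as the full-scale
# 201 x 0.1125 um geometry) so the suite stays fast.

test_pitch <- 201 * 0.1125 / 81
test_dim <- c(81L, 81L, 81L)

# degenerate homogeneous sphere: dn = 0.02, R = 4.5 um
sphere_params <- function(seed = 1L) {
  p <- sample_class_params("MC", seed)
  p$axis_ratios <- c(1, 1, 1)
  p$equiv_radius <- 4.5
  p$mean_delta_n <- 0.02
  p$texture_amplitude <- 0
  p$n_inclusions <- 0L
  p$nucleus_delta_n_offset <- 0
  p
}

sphere_phantom <- function(seed = 1L, dim = test_dim, pitch = test_pitch) {
  generate_phantom(sphere_params(seed), dim, pitch)
}

textured_phantom <- function(class = "NB", seed = 3L, dim = test_dim,
                             pitch = test_pitch) {
  generate_phantom(sample_class_params(class, seed), dim, pitch)
}

# independent brute-force Haralick oracle: plain double loops over the
# co-occurrence matrix, no shared code with the implementation
haralick_brute <- function(p) {
  P <- nrow(p)
  mui <- 0; muj <- 0
  for (i in 1:P) for (j in 1:P) { mui <- mui + i * p[i, j]; muj <- muj + j * p[i, j] }
  vi <- 0; vj <- 0
  for (i in 1:P) for (j in 1:P) {
    vi <- vi + (i - mui)^2 * p[i, j]; vj <- vj + (j - muj)^2 * p[i, j]
  }
  out <- c(energy = 0, entropy = 0, correlation = 0, contrast = 0,
           variance = 0, sum_average = 0, inertia = 0, cluster_shade = 0,
           cluster_tendency = 0, homogeneity = 0, max_probability = 0,
           inverse_variance = 0)
  for (i in 1:P) for (j in 1:P) {
    v <- p[i, j]
    out["energy"] <- out["energy"] + v^2
    if (v > 0) out["entropy"] <- out["entropy"] - v * log2(v)
    if (vi > 0 && vj > 0)
      out["correlation"] <- out["correlation"] +
        (i - mui) * (j - muj) * v / sqrt(vi * vj)
    out["contrast"] <- out["contrast"] + (i - j)^2 * v
    out["variance"] <- out["variance"] + (i - mui)^2 * v
    out["sum_average"] <- out["sum_average"] + (i + j) * v
    out["cluster_shade"] <- out["cluster_shade"] + (i + j - mui - muj)^3 * v
    out["cluster_tendency"] <- out["cluster_tendency"] + (i + j - mui - muj)^2 * v
    out["homogeneity"] <- out["homogeneity"] + v / (1 + (i - j)^2)
    out["max_probability"] <- max(out["max_probability"], v)
    if (i != j) out["inverse_variance"] <- out["inverse_variance"] + v / (i - j)^2
  }
  out["inertia"] <- out["contrast"]
  out
}

# brute-force symmetric GLCM by exhaustive pair enumeration
glcm_brute <- function(lev, offset, P) {
  d <- dim(lev)
  counts <- matrix(0, P, P)
  for (k in 1:d[3]) for (j in 1:d[2]) for (i in 1:d[1]) {
    v <- lev[i, j, k]
    if (v == 0) next
    i2 <- i + offset[1]; j2 <- j + offset[2]; k2 <- k + offset[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
    w <- lev[i2, j2, k2]
    if (w == 0) next
    counts[v, w] <- counts[v, w] + 1
    counts[w, v] <- counts[w, v] + 1
  }
  counts / sum(counts)
}

# brute-force binary panel from the four cells
binary_panel_brute <- function(tp, fn, fp, tn) {
  c(acc = 100 * (tp + tn) / (tp + fn + fp + tn),
    tpr = 100 * tp / (tp + fn),
    tnr = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn),
    ba = 100 * ((tp / (tp + fn)) + (tn / (tn + fp))) / 2,
    f1 = 100 * 2 * tp / (2 * tp + fp + fn),
    mcc = 100 * (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)),
    fm = 100 * sqrt((tp / (tp + fp)) * (tp / (tp + fn))))
}
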