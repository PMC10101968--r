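# The 44-feature descriptors: 11 RI (or phase) statistics, 9 morphology
# values, 24 gray-level co-occurrence (GLCM) Haralick textures averaged
# over 13 3D (or 4 in-plane) directions at probing distances of 0.5 and
# 1 micrometre.

#' Canonical Haralick feature names (in order)
#' @return Character vector of length 12.
#' @export
haralick_names <- function() {
  c("energy", "entropy", "correlation", "contrast", "variance",
    "sum_average", "inertia", "cluster_shade", "cluster_tendency",
    "homogeneity", "max_probability", "inverse_variance")
}

#' The 13 3D GLCM probing directions
#' @return 13 x 3 integer matrix of unit steps (x, y, z).
#' @export
glcm_directions_3d <- function() {
  matrix(c(0, 1, 0,   -1, 1, 0,   -1, 0, 0,   -1, -1, 0,
           0, 1, -1,   0, 0, -1,   0, -1, -1,  -1, 0, -1,
           1, 0, -1,  -1, 1, -1,   1, -1, -1,  -1, -1, -1,
           1, 1, -1),
         ncol = 3, byrow = TRUE)
}

#' The 4 in-plane GLCM probing directions
#' @return 4 x 2 integer matrix of unit steps (x, y).
#' @export
glcm_directions_2d <- function() {
  matrix(c(0, 1,  -1, 1,  -1, 0,  -1, -1), ncol = 2, byrow = TRUE)
}

#' Canonical names of the 44-feature vector
#'
#' @param flavor \code{"3D"} (tomogram) or \code{"2D"} (QPM).
#' @return Character vector of length 44.
#' @export
feature_names <- function(flavor = c("3D", "2D")) {
  flavor <- match.arg(flavor)
  stats <- paste0("stats_", c("mean", "median", "mode", "max", "sd",
                              "skewness", "entropy", "kurtosis",
                              "q25", "q75", "dry_mass_pg"))
  morph <- if (flavor == "3D") {
    paste0("morph_", c("volume", "convex_volume", "sphericity", "extent",
                       "solidity", "axis_major", "axis_mid", "axis_minor",
                       "centroid_offset"))
  } else {
    paste0("morph_", c("area", "extent", "solidity", "circularity",
                       "eccentricity", "feret_max", "feret_min",
                       "axis_major", "centroid_offset"))
  }
  glcm <- c(paste0("glcm_d05_", haralick_names()),
            paste0("glcm_d10_", haralick_names()))
  c(stats, morph, glcm)
}

# moments with degenerate-case conventions: sd 0, skew 0, excess kurt 0
moments_stats <- function(v) {
  m <- mean(v)
  d <- v - m
  m2 <- mean(d^2)
  if (m2 <= 0) return(c(sd = 0, skewness = 0, kurtosis = 0))
  c(sd = stats::sd(v),
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2 - 3)
}

hist_mode_entropy <- function(v, n_levels = 32L) {
  rng <- range(v)
  if (diff(rng) <= 0) return(c(mode = v[1], entropy = 0))
  br <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  cnt <- tabulate(pmin(findInterval(v, br, rightmost.closed = TRUE), n_levels),
                  nbins = n_levels)
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  mid <- (br[-1] + br[-length(br)]) / 2
  c(mode = mid[which.max(cnt)], entropy = -sum(p * log2(p)))
}

#' RI statistics over the cell support (11 features)
#'
#' Average, median, mode, maximum, standard deviation, skewness,
#' entropy, kurtosis (excess), 0.25/0.75 quantiles of the support RI
#' values, plus the dry mass in picograms:
#' \code{dry_mass = sum(dn) * pitch^3 / alpha_ri} with \code{alpha_ri}
#' the specific refraction increment (mL/g).
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param support A \code{\link{cell_support}} (3D).
#' @param alpha_ri Specific refraction increment, default 0.19 mL/g.
#' @param n_levels Histogram bins for mode/entropy (default 32).
#' @return Named numeric vector of length 11.
#' @export
ri_statistics <- function(tomogram, support, alpha_ri = 0.19, n_levels = 32L) {
  stopifnot(inherits(tomogram, "ri_tomogram"), inherits(support, "cell_support"))
  m <- support$mask
  if (!any(m)) stop("empty support")
  v <- tomogram$values[m]
  dn <- v - tomogram$n0
  me <- hist_mode_entropy(v, n_levels)
  mo <- moments_stats(v)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  out <- c(mean(v), q[2], me[["mode"]], max(v), mo[["sd"]], mo[["skewness"]],
           me[["entropy"]], mo[["kurtosis"]], q[1], q[3],
           sum(dn) * tomogram$voxel_pitch^3 / alpha_ri)
  names(out) <- paste0("stats_", c("mean", "median", "mode", "max", "sd",
                                   "skewness", "entropy", "kurtosis",
                                   "q25", "q75", "dry_mass_pg"))
  out
}

# surface area of a binary mask via the coarea formula on the smoothed
# indicator; mask is a (cropped, padded) logical array, pitch in um
coarea_surface <- function(mask, pitch, sigma = 1.0) {
  cpp_coarea(as.logical(mask), dim(mask), sigma) * pitch^2
}

# boundary voxel centers (lattice index coordinates) of a mask
boundary_voxels <- function(mask) {
  d <- dim(mask)
  inner <- array(cpp_binary_morph(as.logical(mask), d, 0L), d)
  bnd <- mask & !inner
  if (!any(bnd)) bnd <- mask
  which(bnd, arr.ind = TRUE)
}

# convex volume measured the same way as the voxel-count volume: hull of
# the boundary voxel centers, then lattice points inside the hull. The
# boundary cloud is deterministically thinned: omitted voxels sit within
# half a voxel of the hull, so the volume error is far below the
# feature's discretization noise.
convex_volume_voxels <- function(mask, max_points = 4000L) {
  pts <- boundary_voxels(mask)
  if (nrow(pts) > max_points) {
    pts <- pts[round(seq(1, nrow(pts), length.out = max_points)), ,
               drop = FALSE]
  }
  hull <- cpp_convex_hull(pts * 1.0)
  if (hull$volume <= 0) return(sum(mask))
  cpp_hull_voxel_count(hull$planes, dim(mask))
}

#' 3D morphology features (9 values)
#'
#' Volume, convex volume, sphericity, extent, solidity, the three
#' principal-axis lengths (moment-equivalent solid ellipsoid,
#' \code{2 * sqrt(5 * eigenvalue)}) and the normalized distance between
#' the centroid and the RI-weighted centroid.
#'
#' @param support A \code{\link{cell_support}} (3D), non-empty and
#'   connected.
#' @param tomogram The matching \code{\link{ri_tomogram}} (for the
#'   weighted centroid).
#' @return Named numeric vector of length 9. Volumes in um^3, axis
#'   lengths in um; sphericity, extent, solidity and centroid offset
#'   dimensionless.
#' @export
morphology_3d <- function(support, tomogram) {
  stopifnot(inherits(support, "cell_support"), inherits(tomogram, "ri_tomogram"))
  m <- support$mask
  if (!any(m)) stop("empty support")
  pitch <- support$pitch
  d <- dim(m)
  w <- which(m, arr.ind = TRUE)
  cr <- col_range(w)
  lo <- pmax(cr["lo", ] - 5L, 1L)
  hi <- pmin(cr["hi", ] + 5L, d)
  sub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  lab <- cpp_largest_component(as.logical(sub), dim(sub))
  if (sum(lab) != sum(sub)) stop("support is not a single connected component")

  n_vox <- nrow(w)
  vol <- n_vox * pitch^3
  area <- coarea_surface(sub, pitch)
  sphericity <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  bbox <- prod(cr["hi", ] - cr["lo", ] + 1) * pitch^3
  convex_vol <- convex_volume_voxels(sub) * pitch^3

  xyz <- sweep(w, 2, c(0, 0, 0)) * pitch
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  cov <- crossprod(cc) / n_vox + diag(pitch^2 / 12, 3)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  axes <- 2 * sqrt(5 * pmax(ev, 0))

  dn <- tomogram$values[m] - tomogram$n0
  wctr <- colSums(xyz * dn) / sum(dn)
  r_eq <- (3 * vol / (4 * pi))^(1 / 3)
  offset <- sqrt(sum((ctr - wctr)^2)) / r_eq

  out <- c(vol, convex_vol, sphericity, vol / bbox,
           vol / convex_vol, axes, offset)
  names(out) <- paste0("morph_", c("volume", "convex_volume", "sphericity",
                                   "extent", "solidity", "axis_major",
                                   "axis_mid", "axis_minor",
                                   "centroid_offset"))
  out
}

#' Quantize support values to gray levels
#'
#' Uniform binning between the support minimum and maximum into
#' \code{n_levels} levels (1..P); off-support voxels are set to 0 and
#' ignored downstream. Invariant under positive affine maps of the
#' values; a constant input occupies a single level.
#'
#' @param values Numeric array (or matrix).
#' @param support Logical array of the same shape.
#' @param n_levels Number of gray levels (default 32).
#' @return Integer array of levels, 0 off support.
#' @export
quantize <- function(values, support, n_levels = 32L) {
  if (n_levels < 2) stop("`n_levels` must be >= 2")
  if (!any(support)) stop("empty support")
  v <- values[support]
  rng <- range(v)
  lev <- array(0L, dim(values))
  if (diff(rng) <= 0) {
    lev[support] <- 1L
  } else {
    lev[support] <- pmin(as.integer(floor((values[support] - rng[1]) /
                                            diff(rng) * n_levels)) + 1L,
                         as.integer(n_levels))
  }
  lev
}

#' Gray-level co-occurrence matrix at one direction and distance
#'
#' Counts (symmetrically) pairs of on-support gray levels separated by
#' \code{round(distance_um / pitch)} voxels along the given unit step,
#' then normalizes to probabilities.
#'
#' @param volume_levels Integer array from \code{\link{quantize}} (0 =
#'   off support). A matrix is treated as a single-slice volume.
#' @param direction Integer unit step, length 3 (or 2 for matrices).
#' @param distance_um Probing distance in micrometres.
#' @param pitch Voxel/pixel pitch in micrometres.
#' @param n_levels Number of gray levels P.
#' @return P x P probability matrix of class \code{glcm} with attributes
#'   \code{direction}, \code{distance_um}, \code{distance_vox},
#'   \code{symmetric}.
#' @export
glcm <- function(volume_levels, direction, distance_um, pitch,
                 n_levels = 32L) {
  stopif_not_scalar_pos(distance_um, "distance_um")
  if (is.matrix(volume_levels)) {
    volume_levels <- array(volume_levels, c(dim(volume_levels), 1L))
    if (length(direction) == 2) direction <- c(direction, 0L)
  }
  d <- dim(volume_levels)
  if (length(direction) != 3 || !all(direction %in% -1:1) ||
      all(direction == 0))
    stop("`direction` must be a nonzero unit step of -1/0/1 entries")
  dv <- max(1L, as.integer(round(distance_um / pitch)))
  off <- as.integer(direction) * dv
  if (any(abs(off) >= d)) stop("offset exceeds the volume extent")
  counts <- cpp_glcm(as.integer(volume_levels), d, as.integer(n_levels),
                     off[1], off[2], off[3])
  tot <- sum(counts)
  if (tot == 0) stop("no co-occurring support pairs at this offset")
  structure(counts / tot, class = c("glcm", "matrix"),
            direction = as.integer(direction), distance_um = distance_um,
            distance_vox = dv, symmetric = TRUE)
}

#' The 12 Haralick features of a normalized GLCM
#'
#' Energy, entropy, correlation, contrast, variance, sum average,
#' inertia, cluster shade, cluster tendency, homogeneity, maximum
#' probability and inverse variance. Contrast and inertia share the
#' standard formula \code{sum((i-j)^2 p)}; both columns are kept so the
#' feature vector has its canonical length and names. Correlation of a
#' zero-variance matrix is reported as 0 by convention.
#'
#' @param glcm Normalized co-occurrence matrix (entries sum to 1).
#' @return Named numeric vector of length 12.
#' @export
haralick <- function(glcm) {
  p <- unclass(glcm)
  if (!is.matrix(p) || nrow(p) != ncol(p)) stop("`glcm` must be square")
  if (abs(sum(p) - 1) > 1e-8) stop("`glcm` must be normalized (sum 1)")
  P <- nrow(p)
  i <- matrix(seq_len(P), P, P)
  j <- t(i)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mui <- sum(seq_len(P) * pi_); muj <- sum(seq_len(P) * pj_)
  sdi <- sqrt(sum((seq_len(P) - mui)^2 * pi_))
  sdj <- sqrt(sum((seq_len(P) - muj)^2 * pj_))
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sdi * sdj > 0)
    sum((i - mui) * (j - muj) * p) / (sdi * sdj) else 0
  offdiag <- i != j
  out <- c(
    energy = sum(p^2),
    entropy = entropy,
    correlation = correlation,
    contrast = contrast,
    variance = sum((i - mui)^2 * p),
    # sum over k of k * p_{x+y}(k) collapses to sum((i + j) p)
    sum_average = sum((i + j) * p),
    inertia = contrast,
    cluster_shade = sum((i + j - mui - muj)^3 * p),
    cluster_tendency = sum((i + j - mui - muj)^2 * p),
    homogeneity = sum(p / (1 + (i - j)^2)),
    max_probability = max(p),
    inverse_variance = sum(p[offdiag] / (i[offdiag] - j[offdiag])^2)
  )
  out
}

#' 24 GLCM features of a tomogram (3D)
#'
#' Quantizes the support RI values to \code{n_levels} gray levels, then
#' for each probing distance (0.5 and 1 um) computes the 12 Haralick
#' features for each of the 13 3D directions and averages over
#' directions.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param support A \code{\link{cell_support}}.
#' @param n_levels Gray levels (default 32).
#' @param distances_um Probing distances (default \code{c(0.5, 1)}).
#' @return Named numeric vector of length 24.
#' @export
glcm_features_3d <- function(tomogram, support, n_levels = 32L,
                             distances_um = c(0.5, 1)) {
  lev <- quantize(tomogram$values, support$mask, n_levels)
  dirs <- glcm_directions_3d()
  glcm_block(lev, dirs, distances_um, tomogram$voxel_pitch, n_levels)
}

# shared 3D/2D GLCM block: average haralick over directions per distance
glcm_block <- function(lev, dirs, distances_um, pitch, n_levels) {
  out <- numeric(0)
  for (dist in distances_um) {
    acc <- matrix(0, nrow(dirs), 12)
    for (r in seq_len(nrow(dirs))) {
      g <- glcm(lev, dirs[r, ], dist, pitch, n_levels)
      acc[r, ] <- haralick(g)
    }
    v <- colMeans(acc)
    names(v) <- paste0("glcm_d", sub("\\.", "", sprintf("%02d", round(dist * 10))),
                       "_", haralick_names())
    out <- c(out, v)
  }
  out
}

#' Full 44-feature 3D descriptor of a tomogram
#'
#' Segments the support (unless one is supplied) and concatenates the 11
#' RI statistics, 9 morphology features and 24 GLCM features, in the
#' canonical order of \code{\link{feature_names}}.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param support Optional precomputed \code{\link{cell_support}}.
#' @param alpha_ri Specific refraction increment (mL/g).
#' @param n_levels GLCM gray levels.
#' @param alpha Segmentation threshold fraction (see
#'   \code{\link{segment_support}}).
#' @return Named numeric vector of length 44 with attribute
#'   \code{flavor = "3D"}.
#' @export
features_3d <- function(tomogram, support = NULL, alpha_ri = 0.19,
                        n_levels = 32L, alpha = 0.1) {
  if (is.null(support)) support <- segment_support(tomogram, alpha)
  # crop to the padded support bounding box: every feature only looks there
  d <- dim(tomogram$values)
  w <- which(support$mask, arr.ind = TRUE)
  cr <- col_range(w)
  lo <- pmax(cr["lo", ] - 4L, 1L)
  hi <- pmin(cr["hi", ] + 4L, d)
  vol <- tomogram$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- support$mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  tom_c <- ri_tomogram(vol, tomogram$voxel_pitch, tomogram$n0)
  sup_c <- cell_support(msk, tomogram$voxel_pitch)
  out <- c(ri_statistics(tom_c, sup_c, alpha_ri, n_levels),
           morphology_3d(sup_c, tom_c),
           glcm_features_3d(tom_c, sup_c, n_levels))
  stopifnot(identical(names(out), feature_names("3D")))
  structure(out, flavor = "3D")
}

#' Segment the cell support from a QPM
#'
#' 2D analogue of \code{\link{segment_support}}: threshold at
#' \code{alpha * max(phase)}, keep the largest component, fill holes,
#' one closing pass.
#'
#' @param qpm A \code{\link{qpm}}.
#' @param alpha Threshold fraction (default 0.1).
#' @return A \code{\link{cell_support}} with a 2D mask.
#' @export
segment_qpm <- function(qpm, alpha = 0.1) {
  stopifnot(inherits(qpm, "qpm"))
  mx <- max(qpm$phase)
  if (mx <= 0) stop("QPM contains no pixel above zero phase")
  mask <- qpm$phase > alpha * mx
  d3 <- c(dim(mask), 1L)
  m <- cpp_largest_component(as.logical(mask), d3)
  m <- cpp_fill_holes(m, d3)
  m <- cpp_binary_morph(m, d3, 1L)
  m <- cpp_binary_morph(m, d3, 0L)
  if (!any(m)) stop("QPM segmentation produced an empty mask")
  cell_support(matrix(m, d3[1], d3[2]), qpm$pixel_pitch)
}

# 2D convex hull helpers -------------------------------------------------

# boundary pixel centers (lattice index coordinates) of a 2D mask
boundary_pixels_2d <- function(mask) {
  d3 <- c(dim(mask), 1L)
  inner <- matrix(cpp_binary_morph(as.logical(mask), d3, 0L), dim(mask)[1])
  bnd <- mask & !inner
  if (!any(bnd)) bnd <- mask
  which(bnd, arr.ind = TRUE)
}

# convex area measured like the pixel-count area: lattice points inside
# the convex polygon of the boundary pixel centers
convex_area_pixels <- function(mask) {
  pts <- boundary_pixels_2d(mask)
  hv <- pts[chull(pts), , drop = FALSE]
  n <- nrow(hv)
  if (n < 3) return(sum(mask))
  d <- dim(mask)
  gx <- matrix(seq_len(d[1]), d[1], d[2])
  gy <- matrix(rep(seq_len(d[2]), each = d[1]), d[1], d[2])
  i2 <- c(2:n, 1)
  sgn <- sign(sum(hv[, 1] * hv[i2, 2] - hv[i2, 1] * hv[, 2]))  # orientation
  if (sgn == 0) sgn <- 1
  inside <- matrix(TRUE, d[1], d[2])
  for (a in seq_len(n)) {
    b <- i2[a]
    ex <- hv[b, 1] - hv[a, 1]; ey <- hv[b, 2] - hv[a, 2]
    cr <- ex * (gy - hv[a, 2]) - ey * (gx - hv[a, 1])
    inside <- inside & (sgn * cr >= -1e-7)
  }
  cnt <- sum(inside)
  if (cnt == 0) sum(mask) else cnt
}

# rotating-calipers Feret diameters from hull vertices
feret_diameters <- function(hull_xy) {
  n <- nrow(hull_xy)
  if (n < 2) return(c(max = 0, min = 0))
  dmax <- 0
  for (a in seq_len(n - 1)) {
    dd <- sqrt((hull_xy[(a + 1):n, 1] - hull_xy[a, 1])^2 +
                 (hull_xy[(a + 1):n, 2] - hull_xy[a, 2])^2)
    dmax <- max(dmax, dd)
  }
  if (n == 2) return(c(max = dmax, min = 0))
  wmin <- Inf
  for (a in seq_len(n)) {
    b <- if (a == n) 1L else a + 1L
    e <- hull_xy[b, ] - hull_xy[a, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    nrm <- c(-e[2], e[1]) / len
    dist <- abs((hull_xy[, 1] - hull_xy[a, 1]) * nrm[1] +
                  (hull_xy[, 2] - hull_xy[a, 2]) * nrm[2])
    wmin <- min(wmin, max(dist))
  }
  c(max = dmax, min = wmin)
}

# 2D perimeter via the coarea formula on the smoothed indicator
coarea_perimeter <- function(mask, pitch, sigma = 1.0) {
  cpp_coarea(as.logical(mask), c(dim(mask), 1L), sigma) * pitch
}

#' Full 44-feature 2D descriptor of a QPM
#'
#' Mirrors the 3D descriptor on a single phase map: 11 phase statistics
#' (2D dry mass \code{= lambda / (2 pi alpha_ri) * sum(phase) * pitch^2}),
#' 9 2D morphology features (area, extent, solidity, circularity,
#' eccentricity, max/min Feret diameters, major axis length, normalized
#' centroid offset) and 24 GLCM features averaged over the 4 in-plane
#' directions at 0.5 and 1 um.
#'
#' @param qpm A \code{\link{qpm}}.
#' @param support Optional precomputed 2D \code{\link{cell_support}}.
#' @param alpha_ri Specific refraction increment (mL/g).
#' @param n_levels GLCM gray levels.
#' @param alpha Segmentation threshold fraction.
#' @return Named numeric vector of length 44 with attribute
#'   \code{flavor = "2D"}.
#' @export
features_2d <- function(qpm, support = NULL, alpha_ri = 0.19,
                        n_levels = 32L, alpha = 0.1) {
  if (is.null(support)) support <- segment_qpm(qpm, alpha)
  m <- support$mask
  pitch <- qpm$pixel_pitch
  phi <- qpm$phase[m]

  me <- hist_mode_entropy(phi, n_levels)
  mo <- moments_stats(phi)
  q <- stats::quantile(phi, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  dry <- qpm$wavelength / (2 * pi * alpha_ri) * sum(phi) * pitch^2
  stats_v <- c(mean(phi), q[2], me[["mode"]], max(phi), mo[["sd"]],
               mo[["skewness"]], me[["entropy"]], mo[["kurtosis"]],
               q[1], q[3], dry)
  names(stats_v) <- paste0("stats_", c("mean", "median", "mode", "max", "sd",
                                       "skewness", "entropy", "kurtosis",
                                       "q25", "q75", "dry_mass_pg"))

  w <- which(m, arr.ind = TRUE)
  n_pix <- nrow(w)
  area <- n_pix * pitch^2
  cr2 <- col_range(w)
  bbox <- prod(cr2["hi", ] - cr2["lo", ] + 1) * pitch^2
  conv_area <- convex_area_pixels(m) * pitch^2
  bpts <- boundary_pixels_2d(m)
  hull <- bpts[chull(bpts), , drop = FALSE] * pitch
  perim <- coarea_perimeter(m, pitch)
  feret <- feret_diameters(hull)

  xy <- w * pitch
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  cov <- crossprod(cc) / n_pix + diag(pitch^2 / 12, 2)
  ev <- sort(eigen(cov, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- 4 * sqrt(pmax(ev[1], 0))
  ecc <- if (ev[1] > 0) sqrt(max(0, 1 - ev[2] / ev[1])) else 0
  wctr <- colSums(xy * phi) / sum(phi)
  r_eq <- sqrt(area / pi)
  offset <- sqrt(sum((ctr - wctr)^2)) / r_eq

  morph_v <- c(area, area / bbox, area / conv_area,
               4 * area * pi / perim^2, ecc, feret[["max"]], feret[["min"]],
               major, offset)
  names(morph_v) <- paste0("morph_", c("area", "extent", "solidity",
                                       "circularity", "eccentricity",
                                       "feret_max", "feret_min",
                                       "axis_major", "centroid_offset"))

  lev <- quantize(qpm$phase, m, n_levels)
  glcm_v <- glcm_block(lev, glcm_directions_2d(), c(0.5, 1), pitch, n_levels)

  out <- c(stats_v, morph_v, glcm_v)
  stopifnot(identical(names(out), feature_names("2D")))
  structure(out, flavor = "2D")
}
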