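# Tomographic inversion: rolling-angle estimation under the
# quasi-uniform rotation assumption, slice-wise filtered back projection
# (Ram-Lak), and support segmentation.

#' Estimate rolling angles from a QPM rotation sequence
#'
#' Assumes quasi-uniform rotation: the rotation period T is located as
#' the earliest lag (k >= \code{t_min}) attaining the strong maximum of
#' the Pearson similarity between frame 1 and frame k, and angles are
#' then assigned uniformly as \code{360 * k / T}. This is a deliberate
#' simplification of full holographic-tracking angle recovery.
#'
#' @param qpm_sequence List of \code{\link{qpm}} objects covering at
#'   least one full rotation.
#' @param t_min Smallest admissible period in frames (default 20).
#' @param threshold Similarity a candidate maximum must exceed
#'   (default 0.9).
#' @return A list of class \code{angle_track} with \code{angles_deg},
#'   \code{frame}, \code{estimated_period} and the \code{similarity}
#'   profile.
#' @export
estimate_angles <- function(qpm_sequence, t_min = 20L, threshold = 0.9) {
  n <- length(qpm_sequence)
  if (n < 3) stop("need at least 3 frames")
  f0 <- as.numeric(qpm_sequence[[1]]$phase)
  if (stats::sd(f0) == 0) stop("period not found: reference frame is constant")
  sim <- vapply(seq_len(n - 1), function(k) {
    fk <- as.numeric(qpm_sequence[[k + 1]]$phase)
    if (stats::sd(fk) == 0) return(NA_real_)
    stats::cor(f0, fk)
  }, 0)
  if (anyNA(sim)) stop("period not found: constant frame in sequence")
  if (max(sim) - min(sim) < 1e-5) {
    cnd <- structure(class = c("cytotomo_period_error", "error", "condition"),
                     list(message = "period not found: similarity profile is flat (symmetric cell?)",
                          call = sys.call(), similarity = sim))
    stop(cnd)
  }
  t_min <- max(2L, as.integer(t_min))
  # earliest lag attaining the global similarity maximum (ties broken
  # towards the smallest lag, so multi-turn sequences report one turn)
  cand <- seq(t_min, n - 1)
  vmax <- max(sim[cand])
  period <- if (vmax > threshold)
    cand[which(sim[cand] >= vmax - 1e-6)[1]] else NA_integer_
  if (is.na(period)) {
    cnd <- structure(class = c("cytotomo_period_error", "error", "condition"),
                     list(message = sprintf(
                       "period not found: no similarity maximum above %.2f at lag >= %d",
                       threshold, t_min),
                       call = sys.call(), similarity = sim))
    stop(cnd)
  }
  structure(list(angles_deg = 360 * (seq_len(n) - 1) / period,
                 frame = seq_len(n),
                 estimated_period = period,
                 similarity = sim),
            class = "angle_track")
}

#' @export
print.angle_track <- function(x, ...) {
  cat("<angle_track> ", length(x$frame), " frames, period ",
      x$estimated_period, " frames/turn (",
      format(360 / x$estimated_period, digits = 4), " deg/frame)\n", sep = "")
  invisible(x)
}

# Ram-Lak filtering of the projection stack along the detector (y) axis.
# sino: (Lx, Ly, A) array of line integrals (RI contrast * length, um).
# Returns the filtered stack, same shape, divided by the detector pitch.
ramp_filter <- function(sino, pitch) {
  d <- dim(sino)
  Ly <- d[2]
  M <- 2^ceiling(log2(2 * Ly))
  # discrete ramp kernel: h(0) = 1/4, h(odd n) = -1 / (pi^2 n^2)
  h <- numeric(M)
  h[1] <- 0.25
  n_odd <- seq(1, M / 2, by = 2)
  h[1 + n_odd] <- -1 / (pi^2 * n_odd^2)
  h[M + 1 - n_odd] <- -1 / (pi^2 * n_odd^2)
  H <- Re(stats::fft(h))
  out <- array(0, d)
  for (a in seq_len(d[3])) {
    # rows = detector axis; columns = x slices
    P <- matrix(0, M, d[1])
    P[seq_len(Ly), ] <- t(sino[, , a])
    Q <- stats::mvfft(stats::mvfft(P) * H, inverse = TRUE) / M
    out[, , a] <- t(Re(Q[seq_len(Ly), , drop = FALSE]))
  }
  out / pitch
}

#' Reconstruct an RI tomogram by filtered back projection
#'
#' Per x-slice, the 1D projections \code{p(y) = phase * lambda / (2 pi)}
#' form a sinogram over the rolling angles; Ram-Lak filtering followed by
#' linear-interpolation back projection recovers the RI contrast, which
#' is clipped at zero from below and returned on top of the medium RI.
#' Angles beyond 360 degrees are wrapped and duplicate angles are
#' averaged in the sinogram.
#'
#' @param qpm_sequence List of \code{\link{qpm}} objects sharing shape
#'   and pitch.
#' @param angle_track Optional \code{angle_track} (from
#'   \code{\link{estimate_angles}}); by default the angles carried by the
#'   QPMs are used.
#' @param n0 Medium refractive index of the output tomogram.
#' @param wavelength Wavelength in micrometres; defaults to the QPMs'.
#' @param Lz Output extent along z (defaults to the detector extent, so
#'   the default geometry gives a cubic volume).
#' @return An \code{\link{ri_tomogram}}.
#' @export
reconstruct_fbp <- function(qpm_sequence, angle_track = NULL, n0 = 1.334,
                            wavelength = NULL, Lz = NULL) {
  n <- length(qpm_sequence)
  if (n < 2) stop("need at least 2 projections")
  shapes <- vapply(qpm_sequence, function(q) dim(q$phase), integer(2))
  if (any(shapes != shapes[, 1])) stop("mismatched QPM shapes")
  pitches <- vapply(qpm_sequence, function(q) q$pixel_pitch, 0)
  if (diff(range(pitches)) > 1e-12) stop("mismatched QPM pixel pitches")
  if (is.null(wavelength)) wavelength <- qpm_sequence[[1]]$wavelength
  angles <- if (is.null(angle_track)) {
    vapply(qpm_sequence, function(q) q$angle_deg, 0)
  } else {
    angle_track$angles_deg
  }
  if (length(angles) < n) stop("angle track shorter than the sequence")
  angles <- angles[seq_len(n)]  # a longer track covers a truncated sequence
  angles <- angles %% 360
  if (length(unique(round(angles, 6))) < 2) stop("need at least 2 distinct angles")

  Lx <- shapes[1, 1]; Ly <- shapes[2, 1]
  if (is.null(Lz)) Lz <- Ly
  pitch <- pitches[1]
  # line integrals in um of RI contrast
  sino <- array(0, c(Lx, Ly, n))
  for (a in seq_len(n)) {
    sino[, , a] <- qpm_sequence[[a]]$phase * wavelength / (2 * pi)
  }
  # average duplicate (wrapped) angles
  key <- round(angles, 6)
  if (anyDuplicated(key)) {
    uk <- unique(key)
    merged <- array(0, c(Lx, Ly, length(uk)))
    for (u in seq_along(uk)) {
      sel <- which(key == uk[u])
      merged[, , u] <- apply(sino[, , sel, drop = FALSE], c(1, 2), mean)
    }
    sino <- merged
    angles <- uk
  }
  filt <- ramp_filter(sino, pitch)
  f <- cpp_backproject_x(as.numeric(filt), c(Lx, Ly, Lz), as.numeric(angles))
  dn <- pmax(array(f, c(Lx, Ly, Lz)), 0)
  ri_tomogram(dn + n0, pitch, n0)
}

#' Segment the cell support from a tomogram
#'
#' Thresholds the RI contrast at \code{alpha * max(dn)}, keeps the
#' largest 6-connected component, fills interior holes and applies one
#' binary closing pass. Deterministic.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param alpha Threshold fraction of the maximum RI contrast
#'   (default 0.1).
#' @return A \code{\link{cell_support}}.
#' @export
segment_support <- function(tomogram, alpha = 0.1) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  dn <- tomogram$values - tomogram$n0
  mx <- max(dn)
  if (mx <= 0) stop("tomogram contains no voxels above the medium RI")
  mask <- dn > alpha * mx
  d <- dim(mask)
  # crop to the padded bounding box before the morphological passes
  w <- which(mask, arr.ind = TRUE)
  cr <- col_range(w)
  lo <- pmax(cr["lo", ] - 2L, 1L)
  hi <- pmin(cr["hi", ] + 2L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sd3 <- dim(sub)
  m <- cpp_largest_component(as.logical(sub), sd3)
  m <- cpp_fill_holes(m, sd3)
  m <- cpp_binary_morph(m, sd3, 1L)  # closing: dilate ...
  m <- cpp_binary_morph(m, sd3, 0L)  # ... then erode
  if (!any(m)) stop("support segmentation produced an empty mask")
  out <- array(FALSE, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- array(m, sd3)
  cell_support(out, tomogram$voxel_pitch)
}
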