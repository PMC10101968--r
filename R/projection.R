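# Straight-ray forward model: RI tomogram -> quantitative phase maps.
#
# The phase accumulated along the optical z-axis is
#   phi(x, y) = (2*pi / lambda) * sum_z dn(x, y, z) * voxel_pitch,
# evaluated on the volume rotated to the requested rolling angle about x.
# Diffraction is deliberately ignored: the 2D baseline comparison and the
# filtered-back-projection inversion both assume the straight-ray model.

#' Rotate a tomogram about the x-axis
#'
#' Rotates the volume through its exact centre with bilinear
#' interpolation in the (y, z) plane; voxels sampled from outside the
#' volume are filled with the medium RI.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param angle_deg Rotation angle in degrees.
#' @return A rotated \code{\link{ri_tomogram}}.
#' @export
rotate_volume <- function(tomogram, angle_deg) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  if (!is.finite(angle_deg)) stop("`angle_deg` must be finite")
  d <- dim(tomogram$values)
  out <- cpp_rotate_x(tomogram$values, d, angle_deg, tomogram$n0)
  # interpolation can undershoot n0 by rounding error only
  out <- pmax(out, tomogram$n0)
  ri_tomogram(array(out, d), tomogram$voxel_pitch, tomogram$n0)
}

#' Project a tomogram to a QPM at a rolling angle
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param angle_deg Rolling angle (degrees about the x-axis).
#' @param wavelength Illumination wavelength in micrometres
#'   (default 0.532).
#' @return A \code{\link{qpm}}.
#' @export
project_qpm <- function(tomogram, angle_deg = 0, wavelength = 0.532) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  stopif_not_scalar_pos(wavelength, "wavelength")
  if (!is.finite(angle_deg)) stop("`angle_deg` must be finite")
  d <- dim(tomogram$values)
  dn <- tomogram$values - tomogram$n0
  s <- cpp_radon_x(dn, d, angle_deg)
  phase <- matrix(s, d[1], d[2]) * (2 * pi / wavelength) * tomogram$voxel_pitch
  qpm(phase, tomogram$voxel_pitch, wavelength, angle_deg)
}

#' Project a tomogram at a sequence of rolling angles
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param angles Numeric vector of rolling angles (degrees), non-empty.
#' @param wavelength Illumination wavelength in micrometres.
#' @return List of \code{\link{qpm}} objects, one per angle, in order.
#' @export
project_sequence <- function(tomogram, angles, wavelength = 0.532) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  if (length(angles) == 0) stop("`angles` must be non-empty")
  if (!all(is.finite(angles))) stop("`angles` must be finite")
  stopif_not_scalar_pos(wavelength, "wavelength")
  d <- dim(tomogram$values)
  dn <- tomogram$values - tomogram$n0
  s <- cpp_radon_x(dn, d, as.numeric(angles))
  k <- (2 * pi / wavelength) * tomogram$voxel_pitch
  lapply(seq_along(angles), function(a) {
    phase <- matrix(s[((a - 1) * d[1] * d[2] + 1):(a * d[1] * d[2])],
                    d[1], d[2]) * k
    qpm(phase, tomogram$voxel_pitch, wavelength, angles[a])
  })
}
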