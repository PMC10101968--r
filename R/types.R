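# Core S3 containers: RI tomograms, quantitative phase maps, supports.

#' Construct an RI tomogram
#'
#' A volumetric refractive-index (RI) map. The array is indexed
#' \code{[x, y, z]} with x the rotation axis, y the flow axis and z the
#' optical axis. Background voxels hold the medium RI \code{n0}; the cell
#' occupies the voxels where \code{values > n0}.
#'
#' @param values 3D numeric array of refractive indices.
#' @param voxel_pitch Isotropic voxel pitch in micrometres.
#' @param n0 Medium refractive index (default 1.334).
#' @return An object of class \code{ri_tomogram}.
#' @export
ri_tomogram <- function(values, voxel_pitch, n0 = 1.334) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  stopif_not_scalar_pos(voxel_pitch, "voxel_pitch")
  stopif_not_scalar_pos(n0, "n0")
  if (!all(is.finite(values))) stop("tomogram values must be finite")
  if (min(values) < n0 - 1e-12)
    stop("tomogram values must be >= n0 everywhere (min RI contrast < 0)")
  structure(list(values = values, voxel_pitch = voxel_pitch, n0 = n0),
            class = "ri_tomogram")
}

# internal constructor for trusted hot paths (skips the O(n) validation)
new_ri_tomogram <- function(values, voxel_pitch, n0) {
  structure(list(values = values, voxel_pitch = voxel_pitch, n0 = n0),
            class = "ri_tomogram")
}

#' @export
print.ri_tomogram <- function(x, ...) {
  d <- dim(x$values)
  dn <- x$values - x$n0
  cat("<ri_tomogram> ", paste(d, collapse = " x "),
      " voxels @ ", format(x$voxel_pitch), " um, n0 = ", format(x$n0), "\n",
      "  RI contrast: max ", format(max(dn), digits = 4),
      ", support ", sum(dn > 0), " voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.ri_tomogram <- function(x) dim(x$values)

#' Construct a quantitative phase map (QPM)
#'
#' A 2D map of optical phase delay (radians) through the cell at a given
#' rolling angle; axes \code{[x, y]}.
#'
#' @param phase 2D numeric matrix of phase values in radians.
#' @param pixel_pitch Pixel pitch in micrometres.
#' @param wavelength Illumination wavelength in micrometres.
#' @param angle_deg Rolling angle (degrees about the x-axis).
#' @return An object of class \code{qpm}.
#' @export
qpm <- function(phase, pixel_pitch, wavelength = 0.532, angle_deg = 0) {
  if (!is.matrix(phase)) stop("`phase` must be a matrix")
  if (!all(is.finite(phase))) stop("phase values must be finite")
  stopif_not_scalar_pos(pixel_pitch, "pixel_pitch")
  stopif_not_scalar_pos(wavelength, "wavelength")
  if (!is.finite(angle_deg)) stop("`angle_deg` must be finite")
  structure(list(phase = phase, pixel_pitch = pixel_pitch,
                 wavelength = wavelength, angle_deg = angle_deg),
            class = "qpm")
}

#' @export
print.qpm <- function(x, ...) {
  cat("<qpm> ", paste(dim(x$phase), collapse = " x "),
      " px @ ", format(x$pixel_pitch), " um, lambda = ", format(x$wavelength),
      " um, angle = ", format(x$angle_deg), " deg\n",
      "  phase range [", format(min(x$phase), digits = 4), ", ",
      format(max(x$phase), digits = 4), "] rad\n", sep = "")
  invisible(x)
}

#' Construct a cell support mask
#'
#' Boolean mask of the voxels (or pixels) occupied by the cell.
#'
#' @param mask Logical array (3D) or matrix (2D).
#' @param pitch Voxel/pixel pitch in micrometres.
#' @return An object of class \code{cell_support}.
#' @export
cell_support <- function(mask, pitch) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("`mask` must be a logical array or matrix")
  stopif_not_scalar_pos(pitch, "pitch")
  structure(list(mask = mask, pitch = pitch), class = "cell_support")
}

#' @export
print.cell_support <- function(x, ...) {
  cat("<cell_support> ", paste(dim(x$mask), collapse = " x "),
      ", ", sum(x$mask), " on, pitch ", format(x$pitch), " um\n", sep = "")
  invisible(x)
}
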