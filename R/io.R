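# On-disk formats: 32-bit TIFF stacks with JSON sidecars, JSON manifests.
# RI tomograms are stored as RI-contrast (values - n0) pages so every
# stored sample sits in [0, 1); phase stacks store phase / phase_scale.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an RI tomogram as a multi-page 32-bit TIFF
#'
#' One z-page per slice; RI contrast is stored and the medium RI and
#' voxel pitch go to a JSON sidecar next to the TIFF.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tomogram <- function(tomogram, path) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  d <- dim(tomogram$values)
  dn <- tomogram$values - tomogram$n0
  pages <- lapply(seq_len(d[3]), function(k) dn[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(kind = "ri_tomogram", dim = d,
                            voxel_pitch = tomogram$voxel_pitch,
                            n0 = tomogram$n0),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RI tomogram written by \code{\link{write_tomogram}}
#'
#' @param path TIFF file path (sidecar expected alongside).
#' @return An \code{\link{ri_tomogram}}.
#' @export
read_tomogram <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  vol <- array(0, d)
  for (k in seq_len(d[3])) vol[, , k] <- pages[[k]]
  ri_tomogram(vol + meta$n0, meta$voxel_pitch, meta$n0)
}

#' Write a QPM sequence as a multi-page 32-bit TIFF
#'
#' One page per rolling angle; phase values are stored divided by a
#' common scale recorded in the JSON sidecar together with the angle
#' list, wavelength and pixel pitch.
#'
#' @param qpms List of \code{\link{qpm}} objects.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_qpm_stack <- function(qpms, path) {
  stopifnot(length(qpms) > 0, all(vapply(qpms, inherits, TRUE, "qpm")))
  mx <- max(vapply(qpms, function(q) max(abs(q$phase)), 0), 1e-12)
  scale <- max(1, mx * 1.0000001)
  pages <- lapply(qpms, function(q) q$phase / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(kind = "qpm_stack",
         angles_deg = vapply(qpms, function(q) q$angle_deg, 0),
         pixel_pitch = qpms[[1]]$pixel_pitch,
         wavelength = qpms[[1]]$wavelength,
         phase_scale = scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a QPM sequence written by \code{\link{write_qpm_stack}}
#'
#' @param path TIFF file path (sidecar expected alongside).
#' @return List of \code{\link{qpm}} objects.
#' @export
read_qpm_stack <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(seq_along(pages), function(i) {
    qpm(pages[[i]] * meta$phase_scale, meta$pixel_pitch,
        meta$wavelength, meta$angles_deg[i])
  })
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
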