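# Minimal digital-holography layer: angular-spectrum propagation,
# Tamura-coefficient autofocusing, off-axis hologram synthesis and
# demodulation. Exercised on synthetic fields; the tomographic pipeline
# itself enters at the QPM level.

#' Construct a complex optical field
#'
#' @param values Complex (or numeric) N x N matrix of the field.
#' @param pixel_pitch Pixel pitch in micrometres.
#' @param wavelength Wavelength in micrometres.
#' @return An object of class \code{complex_field}.
#' @export
complex_field <- function(values, pixel_pitch, wavelength = 0.532) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 16 || ncol(values) != nrow(values))
    stop("field must be square, N >= 16")
  values <- matrix(as.complex(values), nrow(values))
  if (any(!is.finite(Re(values)) | !is.finite(Im(values))))
    stop("field values must be finite")
  stopif_not_scalar_pos(pixel_pitch, "pixel_pitch")
  stopif_not_scalar_pos(wavelength, "wavelength")
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 wavelength = wavelength),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat("<complex_field> ", nrow(x$values), " x ", ncol(x$values),
      " px @ ", format(x$pixel_pitch), " um, lambda ",
      format(x$wavelength), " um\n", sep = "")
  invisible(x)
}

fft_freqs <- function(N, pitch) {
  f <- c(seq(0, floor((N - 1) / 2)), seq(-floor(N / 2), -1)) / (N * pitch)
  f
}

#' Angular-spectrum propagation
#'
#' Exact transfer-function propagation over \code{distance_um} along the
#' optical axis; evanescent components are suppressed. Unitary over
#' propagating frequencies, so energy is conserved for band-limited
#' fields and \code{propagate(a)} then \code{propagate(-a)} is the
#' identity.
#'
#' @param field A \code{\link{complex_field}}.
#' @param distance_um Signed propagation distance in micrometres.
#' @return The propagated \code{\link{complex_field}}.
#' @export
propagate_angular_spectrum <- function(field, distance_um) {
  stopifnot(inherits(field, "complex_field"))
  if (!is.finite(distance_um)) stop("`distance_um` must be finite")
  N <- nrow(field$values)
  f <- fft_freqs(N, field$pixel_pitch)
  fx <- matrix(f, N, N)
  fy <- t(fx)
  arg <- 1 / field$wavelength^2 - fx^2 - fy^2
  prop <- arg > 0
  H <- matrix(0 + 0i, N, N)
  H[prop] <- exp(2i * pi * distance_um * sqrt(arg[prop]))
  F <- stats::fft(field$values)
  out <- stats::fft(F * H, inverse = TRUE) / length(F)
  complex_field(out, field$pixel_pitch, field$wavelength)
}

#' Tamura coefficient of an amplitude image
#'
#' \code{TC = sqrt(sd(A) / mean(A))}: a dimensionless contrast measure,
#' minimized at best focus for phase objects. Invariant to positive
#' scaling of the image.
#'
#' @param amplitude_image Non-negative numeric matrix.
#' @return Scalar TC >= 0.
#' @export
tamura_coefficient <- function(amplitude_image) {
  a <- as.numeric(amplitude_image)
  if (any(a < 0)) stop("amplitude must be non-negative")
  m <- mean(a)
  if (m <= 0) stop("all-zero amplitude image: TC undefined")
  sqrt(stats::sd(a) / m)
}

#' Autofocus by Tamura-coefficient minimization
#'
#' Coarse grid search of TC(amplitude(propagate(field, z))) over
#' \code{[z_min, z_max]} followed by a 3-point parabolic refinement
#' about the grid minimum.
#'
#' @param field A \code{\link{complex_field}}.
#' @param z_min,z_max Search interval in micrometres.
#' @param n_steps Number of grid points (>= 3).
#' @return List with \code{z_focus} (um), \code{field} (refocused),
#'   \code{z_grid} and \code{tc} (the TC profile).
#' @export
autofocus <- function(field, z_min, z_max, n_steps = 21L) {
  stopifnot(inherits(field, "complex_field"))
  if (!(z_min < z_max)) stop("need z_min < z_max")
  if (n_steps < 3) stop("need n_steps >= 3")
  zs <- seq(z_min, z_max, length.out = n_steps)
  tc <- vapply(zs, function(z) {
    v <- tamura_coefficient(Mod(propagate_angular_spectrum(field, z)$values))
    if (!is.finite(v)) stop("non-finite TC at z = ", format(z))
    v
  }, 0)
  if (max(tc) - min(tc) < 1e-9)
    stop("flat TC profile: no focus minimum (constant field?)")
  i <- which.min(tc)
  z_hat <- zs[i]
  if (i > 1 && i < length(zs)) {
    # parabolic refinement through the three points around the minimum
    denom <- tc[i - 1] - 2 * tc[i] + tc[i + 1]
    if (denom > 0) {
      z_hat <- zs[i] + 0.5 * (zs[2] - zs[1]) * (tc[i - 1] - tc[i + 1]) / denom
    }
  }
  list(z_focus = z_hat,
       field = propagate_angular_spectrum(field, z_hat),
       z_grid = zs, tc = tc)
}

#' Synthesize an off-axis hologram
#'
#' Interferes the object field with a unit-amplitude tilted plane
#' reference: \code{I = |O + R|^2},
#' \code{R = exp(2 pi i (fx x + fy y))} with the carrier in
#' cycles/pixel.
#'
#' @param object_field A \code{\link{complex_field}}.
#' @param reference_carrier Length-2 carrier frequency (cycles/pixel);
#'   magnitude must be below Nyquist (0.5).
#' @return An object of class \code{hologram}.
#' @export
synthesize_offaxis_hologram <- function(object_field,
                                        reference_carrier = c(0.25, 0)) {
  stopifnot(inherits(object_field, "complex_field"))
  fc <- as.numeric(reference_carrier)
  if (length(fc) != 2 || !all(is.finite(fc))) stop("bad carrier")
  if (sqrt(sum(fc^2)) >= 0.5)
    stop("super-Nyquist carrier: |f| = ", format(sqrt(sum(fc^2))),
         " cycles/px >= 0.5")
  N <- nrow(object_field$values)
  x <- matrix(0:(N - 1), N, N)
  y <- t(x)
  R <- exp(2i * pi * (fc[1] * x + fc[2] * y))
  I <- Mod(object_field$values + R)^2
  structure(list(intensity = I, carrier = fc,
                 pixel_pitch = object_field$pixel_pitch,
                 wavelength = object_field$wavelength),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat("<hologram> ", nrow(x$intensity), " x ", ncol(x$intensity),
      " px, carrier (", paste(format(x$carrier, digits = 3), collapse = ", "),
      ") cycles/px\n", sep = "")
  invisible(x)
}

#' Demodulate an off-axis hologram
#'
#' Selects the +1 diffraction order: the spectrum is shifted so the
#' carrier sits at baseband, a hard circular low-pass of
#' \code{bandpass_radius} (cycles/pixel) is applied, and the filtered
#' spectrum is transformed back. The carrier is taken from the hologram
#' metadata when present, otherwise detected as the off-centre spectral
#' maximum.
#'
#' @param hologram A \code{hologram} (or plain intensity matrix).
#' @param bandpass_radius Low-pass radius in cycles/pixel; must be
#'   smaller than the carrier separation.
#' @param pixel_pitch,wavelength Used when a bare matrix is given.
#' @return A \code{\link{complex_field}} estimate of the object field.
#' @export
demodulate <- function(hologram, bandpass_radius = 0.1,
                       pixel_pitch = NULL, wavelength = 0.532) {
  if (inherits(hologram, "hologram")) {
    I <- hologram$intensity
    fc <- hologram$carrier
    pixel_pitch <- hologram$pixel_pitch
    wavelength <- hologram$wavelength
  } else {
    I <- as.matrix(hologram)
    fc <- NULL
    if (is.null(pixel_pitch)) stop("`pixel_pitch` required for bare matrices")
  }
  if (any(I < 0)) stop("hologram intensity must be non-negative")
  N <- nrow(I)
  if (is.null(fc)) {
    S <- stats::fft(I)
    f <- fft_freqs(N, 1)  # cycles/px
    fx <- matrix(f, N, N)
    fy <- t(fx)
    mag <- Mod(S)
    mag[sqrt(fx^2 + fy^2) <= bandpass_radius] <- 0  # suppress the DC order
    pk <- which.max(mag)
    fc <- c(fx[pk], fy[pk])
    # keep the +1 order (conjugate symmetry gives a twin at -fc)
    if (fc[1] < 0 || (fc[1] == 0 && fc[2] < 0)) fc <- -fc
  }
  if (sqrt(sum(fc^2)) <= bandpass_radius)
    stop("orders overlap: carrier separation ", format(sqrt(sum(fc^2))),
         " <= bandpass radius ", format(bandpass_radius))
  x <- matrix(0:(N - 1), N, N)
  y <- t(x)
  # with R = exp(+2 pi i fc . x), the object term O * Conj(R) sits at
  # -fc; shifting by +fc brings it to baseband
  base <- I * exp(2i * pi * (fc[1] * x + fc[2] * y))
  S <- stats::fft(base)
  f <- fft_freqs(N, 1)
  fx <- matrix(f, N, N)
  fy <- t(fx)
  S[sqrt(fx^2 + fy^2) > bandpass_radius] <- 0
  out <- stats::fft(S, inverse = TRUE) / length(S)
  complex_field(out, pixel_pitch, wavelength)
}
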