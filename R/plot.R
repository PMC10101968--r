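# Quick-look plot methods.

#' Plot a QPM as a phase image
#'
#' @param x A \code{\link{qpm}}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.qpm <- function(x, ...) {
  d <- dim(x$phase)
  graphics::image(seq_len(d[1]) * x$pixel_pitch,
                  seq_len(d[2]) * x$pixel_pitch,
                  x$phase, asp = 1, xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("QPM @ %.1f deg (rad)", x$angle_deg),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Plot the central slices of an RI tomogram
#'
#' Shows the three orthogonal mid-plane slices of the RI contrast.
#'
#' @param x An \code{\link{ri_tomogram}}.
#' @param ... Passed to \code{\link[graphics]{image}}.
#' @export
plot.ri_tomogram <- function(x, ...) {
  d <- dim(x$values)
  mid <- (d + 1) %/% 2
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  dn <- x$values - x$n0
  planes <- list(xy = dn[, , mid[3]], xz = dn[, mid[2], ], yz = dn[mid[1], , ])
  for (nm in names(planes)) {
    graphics::image(planes[[nm]], asp = 1, axes = FALSE,
                    main = paste("dn, mid", nm), useRaster = TRUE, ...)
  }
  invisible(x)
}

#' Plot the frame-similarity profile of an angle track
#'
#' @param x An \code{angle_track} from \code{\link{estimate_angles}}.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.angle_track <- function(x, ...) {
  graphics::plot(seq_along(x$similarity), x$similarity, type = "l",
                 xlab = "lag (frames)", ylab = "similarity to frame 1", ...)
  graphics::abline(v = x$estimated_period, lty = 2)
  invisible(x)
}
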