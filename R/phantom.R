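# Class-conditional 3D refractive-index cell phantoms.
#
# Three populations are emulated: monocyte-like cells (MC), neuroblastoma
# (NB) and ovarian-cancer (OC) cells. The class parameter distributions
# encode the qualitative separations of the real populations: tumor cells
# are less spherical than monocytes, OC cells carry a higher average RI
# contrast than NB cells, and the intracellular texture statistics differ
# in amplitude and grain.

#' Default class-conditional phantom parameter distributions
#'
#' Returns the documented sampling configuration for the three cell
#' classes. Each entry gives the ranges/moments used by
#' \code{\link{sample_class_params}}: equivalent radius (um), ellipsoid
#' elongation, mean RI contrast, nucleus geometry, inclusion counts and
#' the band-limited texture model. Values are package defaults chosen to
#' reproduce the qualitative class orderings (sphericity: MC highest;
#' average RI: OC above NB), not any real population's absolute
#' distribution.
#'
#' @return Named list with one configuration per class label.
#' @export
phantom_class_config <- function() {
  list(
    MC = list(
      equiv_radius = c(4.2, 5.0),        # um, uniform
      elong_major = c(1.00, 1.12),       # near-spherical
      elong_minor = c(0.92, 1.00),
      mean_delta_n = c(0.022, 0.0015),   # RIU, normal(mean, sd)
      nucleus_fraction = c(0.50, 0.60),
      nucleus_offset = c(0.003, 0.005),  # RIU
      n_inclusions = c(2L, 4L),
      inclusion_radius = c(0.40, 0.60),  # um
      texture_amplitude = c(0.003, 0.005),
      texture_corr_length = c(0.70, 0.90)
    ),
    NB = list(
      equiv_radius = c(4.5, 5.6),
      elong_major = c(1.25, 1.60),       # clearly elongated
      elong_minor = c(0.80, 1.00),
      mean_delta_n = c(0.020, 0.0015),   # lowest average RI contrast
      nucleus_fraction = c(0.55, 0.65),
      nucleus_offset = c(0.004, 0.006),
      n_inclusions = c(5L, 7L),
      inclusion_radius = c(0.35, 0.50),
      texture_amplitude = c(0.005, 0.007),
      texture_corr_length = c(0.45, 0.60)  # finer grain -> higher GLCM contrast
    ),
    OC = list(
      equiv_radius = c(5.0, 6.2),
      elong_major = c(1.20, 1.50),
      elong_minor = c(0.80, 1.00),
      mean_delta_n = c(0.026, 0.0015),   # right-shifted vs NB
      nucleus_fraction = c(0.55, 0.65),
      nucleus_offset = c(0.004, 0.006),
      n_inclusions = c(7L, 9L),
      inclusion_radius = c(0.40, 0.55),
      texture_amplitude = c(0.006, 0.008),
      texture_corr_length = c(0.55, 0.70)
    )
  )
}

#' Draw phantom parameters for one cell of a given class
#'
#' Deterministic for a fixed seed: the same \code{(class_label, rng_seed)}
#' pair always yields the same parameter set.
#'
#' @param class_label One of \code{"MC"}, \code{"NB"}, \code{"OC"}.
#' @param rng_seed Integer seed for this draw.
#' @param config Class configuration, as from
#'   \code{\link{phantom_class_config}}.
#' @return A list of class \code{phantom_params}.
#' @export
sample_class_params <- function(class_label, rng_seed,
                                config = phantom_class_config()) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !class_label %in% names(config)) {
    stop("unknown class label: ", deparse(class_label),
         " (expected one of ", paste(names(config), collapse = ", "), ")")
  }
  cfg <- config[[class_label]]
  with_seed(rng_seed, {
    e_maj <- runif(1, cfg$elong_major[1], cfg$elong_major[2])
    e_min <- runif(1, cfg$elong_minor[1], cfg$elong_minor[2])
    ratios <- c(e_maj, 1, e_min)
    mdn <- rnorm(1, cfg$mean_delta_n[1], cfg$mean_delta_n[2])
    mdn <- max(mdn, 0.5 * cfg$mean_delta_n[1])  # keep strictly positive
    p <- list(
      class_label = class_label,
      equiv_radius = runif(1, cfg$equiv_radius[1], cfg$equiv_radius[2]),
      axis_ratios = ratios / prod(ratios)^(1 / 3),
      mean_delta_n = mdn,
      nucleus_fraction = runif(1, cfg$nucleus_fraction[1], cfg$nucleus_fraction[2]),
      nucleus_delta_n_offset = runif(1, cfg$nucleus_offset[1], cfg$nucleus_offset[2]),
      n_inclusions = sample(seq(cfg$n_inclusions[1], cfg$n_inclusions[2]), 1),
      inclusion_radius = runif(1, cfg$inclusion_radius[1], cfg$inclusion_radius[2]),
      texture_amplitude = runif(1, cfg$texture_amplitude[1], cfg$texture_amplitude[2]),
      texture_correlation_length = runif(1, cfg$texture_corr_length[1],
                                         cfg$texture_corr_length[2]),
      seed = as.integer(rng_seed)
    )
    class(p) <- "phantom_params"
    p
  })
}

#' @export
print.phantom_params <- function(x, ...) {
  cat("<phantom_params> class ", x$class_label,
      ", r_eq ", format(x$equiv_radius, digits = 3), " um",
      ", mean dn ", format(x$mean_delta_n, digits = 3),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# random rotation matrix (uniform over SO(3)) from the current RNG stream
random_rotation3 <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a 3D RI phantom from a parameter set
#'
#' Builds an ellipsoidal cell body (randomly oriented) carrying a
#' concentric scaled-ellipsoid nucleus, small spherical inclusions, and a
#' band-limited Gaussian random texture. The RI contrast is clipped to
#' stay strictly positive on the support and zero outside it, and capped
#' at a physiological maximum of 0.12 RIU.
#'
#' @param params A \code{phantom_params} object (see
#'   \code{\link{sample_class_params}}).
#' @param dim Volume extents in voxels (default \code{c(201, 201, 201)}).
#' @param voxel_pitch Voxel pitch in micrometres (default 0.1125, the
#'   camera pixel pitch divided by the objective magnification).
#' @param n0 Medium refractive index.
#' @return A list with elements \code{tomogram} (an
#'   \code{\link{ri_tomogram}}) and \code{support} (a
#'   \code{\link{cell_support}}).
#' @export
generate_phantom <- function(params, dim = c(201L, 201L, 201L),
                             voxel_pitch = 0.1125, n0 = 1.334) {
  stopifnot(inherits(params, "phantom_params") || is.list(params))
  stopif_not_scalar_pos(voxel_pitch, "voxel_pitch")
  dim <- as.integer(dim)
  semi <- params$equiv_radius * params$axis_ratios /
    prod(params$axis_ratios)^(1 / 3)
  max_semi_vox <- max(semi) / voxel_pitch
  margin <- (min(dim) - 1) / 2 - max_semi_vox
  if (margin < 5) {
    stop("cell does not fit: largest semi-axis ", format(max(semi), digits = 4),
         " um leaves a margin of ", format(margin, digits = 3),
         " voxels (>= 5 required)")
  }

  with_seed(derive_seed(params$seed, 7L), {
    rot <- random_rotation3()
    # cell centre = rotation centre: 0-based (L-1)/2, i.e. 1-based (L+1)/2
    ctr <- (dim + 1) / 2

    # work on a cropped cube around the cell, then embed
    hw <- ceiling(max_semi_vox) + 3L
    idx <- lapply(ctr, function(c0) seq.int(floor(c0) - hw, floor(c0) + hw))
    bb <- vapply(idx, length, 1L)
    gx <- (idx[[1]] - ctr[1]) * voxel_pitch
    gy <- (idx[[2]] - ctr[2]) * voxel_pitch
    gz <- (idx[[3]] - ctr[3]) * voxel_pitch

    # spherical inclusion centres drawn in the body frame (within 0.85 x
    # body so they stay interior); brighter than the nucleus
    n_inc <- params$n_inclusions
    inc <- matrix(0, 0, 4)
    if (n_inc > 0) {
      inc <- t(vapply(seq_len(n_inc), function(ii) {
        repeat {
          pu <- runif(3, -0.85, 0.85) * semi
          if (sum((pu / (0.85 * semi))^2) <= 1) break
        }
        c(pu, params$inclusion_radius)
      }, numeric(4)))
    }
    ns <- params$nucleus_fraction^(1 / 3)  # nucleus = volume-fraction scaled body
    fill <- cpp_phantom_fill(gx, gy, gz, rot, semi, params$mean_delta_n,
                             ns, params$nucleus_delta_n_offset, inc,
                             1.5 * params$nucleus_delta_n_offset)
    dn <- array(fill$dn, bb)
    body <- array(fill$body, bb)

    # band-limited Gaussian random field texture
    if (params$texture_amplitude > 0) {
      noise <- array(rnorm(prod(bb)), bb)
      sig <- params$texture_correlation_length / voxel_pitch
      sm <- array(cpp_smooth3(as.numeric(noise), bb, sig), bb)
      s <- stats::sd(sm[body])
      if (is.finite(s) && s > 0) {
        dn[body] <- dn[body] + params$texture_amplitude * sm[body] / s
      }
    }

    # positivity clip on the support, physiological cap
    floor_dn <- 0.05 * params$mean_delta_n
    dn[body] <- pmin(pmax(dn[body], floor_dn), 0.12)

    vol <- array(0, dim)
    sup <- array(FALSE, dim)
    vol[idx[[1]], idx[[2]], idx[[3]]] <- dn
    sup[idx[[1]], idx[[2]], idx[[3]]] <- body
    list(tomogram = new_ri_tomogram(vol + n0, voxel_pitch, n0),
         support = cell_support(sup, voxel_pitch))
  })
}

#' Generate a benchmark dataset of phantoms on disk
#'
#' Writes one tomogram per cell (32-bit TIFF z-stack plus JSON sidecar)
#' and a JSON manifest with per-cell id, class, split, seed and file path.
#' Fully reproducible from \code{master_seed}.
#'
#' @param counts Named list with \code{train} and \code{test} integer
#'   vectors named by class. Defaults to the benchmark split: train
#'   200/250/250 and test 47/122/60 for MC/NB/OC.
#' @param master_seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param dim,voxel_pitch,n0 Passed to \code{\link{generate_phantom}}.
#' @param config Class configuration for the parameter draws.
#' @return The manifest as a data frame (invisibly written to
#'   \code{manifest.json}).
#' @export
make_benchmark <- function(counts = benchmark_counts(), master_seed = 1L,
                           out_dir, dim = c(201L, 201L, 201L),
                           voxel_pitch = 0.1125, n0 = 1.334,
                           config = phantom_class_config()) {
  if (missing(out_dir)) stop("`out_dir` is required")
  if (any(unlist(counts) < 0)) stop("counts must be non-negative")
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0)
    stop("cannot write to output directory: ", out_dir)

  rows <- list()
  n_cell <- 0L
  for (split in names(counts)) {
    for (cls in names(counts[[split]])) {
      m <- counts[[split]][[cls]]
      if (m == 0) next
      for (i in seq_len(m)) {
        n_cell <- n_cell + 1L
        seed_i <- derive_seed(master_seed, n_cell)
        id <- sprintf("%s_%s_%04d", split, cls, i)
        params <- sample_class_params(cls, seed_i, config)
        ph <- generate_phantom(params, dim, voxel_pitch, n0)
        path <- file.path(out_dir, paste0(id, ".tif"))
        write_tomogram(ph$tomogram, path)
        rows[[n_cell]] <- data.frame(id = id, class_label = cls,
                                     seed = seed_i, path = basename(path),
                                     split = split,
                                     stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), class_label = character(),
               seed = integer(), path = character(), split = character(),
               stringsAsFactors = FALSE)
  if (anyDuplicated(manifest$id)) stop("internal error: duplicate cell ids")
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

#' Default benchmark split sizes
#'
#' Train 200/250/250 and test 47/122/60 cells for MC/NB/OC.
#'
#' @return Named list of named integer vectors.
#' @export
benchmark_counts <- function() {
  list(train = c(MC = 200L, NB = 250L, OC = 250L),
       test = c(MC = 47L, NB = 122L, OC = 60L))
}
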