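# Volumetric data augmentation: intensity scaling, intensity shifting,
# morphological alteration — applied in that order, with the shift bound
# taken on the post-scaling minimum RI contrast so positivity on the
# support is preserved by construction.

#' Scale the RI contrast of a tomogram
#'
#' \code{dn -> a * dn} on the support; background untouched; the support
#' itself is unchanged.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param a Positive scale factor (drawn from U(0.9, 1.1) by
#'   \code{\link{augment}}).
#' @return An \code{\link{ri_tomogram}}.
#' @export
intensity_scale <- function(tomogram, a) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number")
  dn <- tomogram$values - tomogram$n0
  ri_tomogram(a * dn + tomogram$n0, tomogram$voxel_pitch, tomogram$n0)
}

#' Shift the RI contrast of a tomogram on its support
#'
#' \code{dn -> dn + b} on the support only. The admissible range is
#' \code{|b| <= min(dn on support) / 2}, which keeps the contrast
#' strictly positive.
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param b Shift in RIU.
#' @return An \code{\link{ri_tomogram}}.
#' @export
intensity_shift <- function(tomogram, b) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("`b` must be a single finite number")
  dn <- tomogram$values - tomogram$n0
  sup <- dn > 0
  if (!any(sup)) stop("tomogram has an empty support")
  bound <- min(dn[sup]) / 2
  if (abs(b) > bound + 1e-15)
    stop(sprintf("|b| = %.6g exceeds the admissible bound min(dn)/2 = %.6g",
                 abs(b), bound))
  dn[sup] <- dn[sup] + b
  ri_tomogram(dn + tomogram$n0, tomogram$voxel_pitch, tomogram$n0)
}

#' Morphological alteration: anisotropic volume resize
#'
#' Resizes the \code{Lx x Ly x Lz} volume to
#' \code{(Lx+cx) x (Ly+cy) x (Lz+cz)} by trilinear interpolation of the
#' RI contrast; positive extents stretch, negative compress. The
#' background is re-clamped to \code{n0} after interpolation and the new
#' support follows the geometry (voxels with positive contrast).
#'
#' @param tomogram An \code{\link{ri_tomogram}}.
#' @param cx,cy,cz Integer extent changes (drawn from U(-20, 20) by
#'   \code{\link{augment}}).
#' @return An \code{\link{ri_tomogram}} with the new extents.
#' @export
morph_alter <- function(tomogram, cx, cy, cz) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  d <- dim(tomogram$values)
  nd <- d + c(as.integer(round(cx)), as.integer(round(cy)), as.integer(round(cz)))
  if (any(nd < 32)) {
    stop("degenerate target extents ", paste(nd, collapse = " x "),
         " (all must be >= 32)")
  }
  dn <- as.numeric(tomogram$values) - tomogram$n0
  out <- cpp_resize3(dn, d, nd)
  out <- pmax(out, 0)  # kill interpolation undershoot below the medium
  ri_tomogram(array(out, nd) + tomogram$n0, tomogram$voxel_pitch, tomogram$n0)
}

#' Apply one random augmentation draw to a tomogram
#'
#' Draws \code{a ~ U(0.9, 1.1)}, \code{b ~ U(-m/2, m/2)} with \code{m}
#' the post-scaling minimum support contrast, and
#' \code{cx, cy, cz ~ U(-20, 20)} (rounded to integers), then applies
#' scale, shift and morphological alteration in that order.
#'
#' @param tomogram An \code{\link{ri_tomogram}} with non-empty support.
#' @param rng_seed Integer seed; the draw is a pure function of it.
#' @return List with \code{tomogram} (augmented) and \code{params}
#'   (list \code{a}, \code{b}, \code{c}, \code{seed}).
#' @export
augment <- function(tomogram, rng_seed) {
  stopifnot(inherits(tomogram, "ri_tomogram"))
  with_seed(rng_seed, {
    # same arithmetic as intensity_scale / intensity_shift / morph_alter
    # composed, on one shared contrast array (the composition is
    # asserted equivalent in the test suite)
    d <- dim(tomogram$values)
    dn <- tomogram$values - tomogram$n0
    a <- runif(1, 0.9, 1.1)
    dn <- a * dn
    sup <- dn > 0
    if (!any(sup)) stop("tomogram has an empty support")
    m <- min(dn[sup])
    b <- runif(1, -m / 2, m / 2)
    dn[sup] <- dn[sup] + b
    cc <- round(runif(3, -20, 20))
    nd <- d + as.integer(cc)
    if (any(nd < 32))
      stop("degenerate target extents ", paste(nd, collapse = " x "))
    dn <- pmax(cpp_resize3(dn, d, nd), 0)
    list(tomogram = new_ri_tomogram(array(dn, nd) + tomogram$n0,
                                    tomogram$voxel_pitch, tomogram$n0),
         params = list(a = a, b = b, c = as.integer(cc),
                       seed = as.integer(rng_seed)))
  })
}

#' Augment the training split of a benchmark dataset on disk
#'
#' For each training cell the original is kept and \code{multiplicity}
#' augmented copies are added (so multiplicity 9 turns 200 originals into
#' 2000 records). The test split is never augmented. Augmented records
#' carry provenance (source id and drawn parameters).
#'
#' @param manifest Manifest data frame from \code{\link{make_benchmark}}.
#' @param multiplicity_per_class Named integer vector of augmented copies
#'   per training cell (default \code{c(MC = 9, NB = 3, OC = 3)}).
#' @param rng_seed Master seed for the augmentation draws.
#' @param dir Dataset directory holding the tomogram files.
#' @return The extended manifest data frame (also written to
#'   \code{manifest_augmented.json} in \code{dir}).
#' @export
augment_dataset <- function(manifest,
                            multiplicity_per_class = c(MC = 9L, NB = 3L, OC = 3L),
                            rng_seed = 1L, dir) {
  if (any(multiplicity_per_class < 0)) stop("multiplicities must be >= 0")
  if (!any(manifest$split == "train")) stop("manifest lacks a train split")
  rows <- list(manifest)
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  n_new <- 0L
  for (r in seq_len(nrow(tr))) {
    mult <- multiplicity_per_class[[tr$class_label[r]]]
    if (is.null(mult) || mult == 0) next
    tom <- read_tomogram(file.path(dir, tr$path[r]))
    for (m in seq_len(mult)) {
      n_new <- n_new + 1L
      sd <- derive_seed(rng_seed, n_new)
      aug <- augment(tom, sd)
      id <- sprintf("%s_aug%02d", tr$id[r], m)
      path <- paste0(id, ".tif")
      write_tomogram(aug$tomogram, file.path(dir, path))
      rows[[length(rows) + 1L]] <-
        data.frame(id = id, class_label = tr$class_label[r],
                   seed = sd, path = path, split = "train",
                   source_id = tr$id[r],
                   aug_a = aug$params$a, aug_b = aug$params$b,
                   aug_cx = aug$params$c[1], aug_cy = aug$params$c[2],
                   aug_cz = aug$params$c[3],
                   stringsAsFactors = FALSE)
    }
  }
  base <- rows[[1]]
  base$source_id <- NA_character_
  base$aug_a <- NA_real_; base$aug_b <- NA_real_
  base$aug_cx <- NA_integer_; base$aug_cy <- NA_integer_; base$aug_cz <- NA_integer_
  rows[[1]] <- base
  out <- do.call(rbind, rows)
  write_manifest(out, file.path(dir, "manifest_augmented.json"))
  out
}
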