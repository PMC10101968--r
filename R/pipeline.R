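# End-to-end synthetic experiment: generate class-conditional phantoms,
# (optionally) project and reconstruct them, augment the training split,
# extract the 44-feature 3D and 2D descriptors, train the hierarchical
# classifiers and evaluate the full metric panel. Cells are streamed:
# only feature rows are retained in memory.

#' Experiment configuration
#'
#' @param grid_dim Volume extent in voxels (cubic).
#' @param voxel_pitch Voxel pitch in micrometres. The default full-scale
#'   geometry is 201 voxels at 0.1125 um; the desk-scale benchmark used
#'   by the examples runs 71 voxels at ~0.319 um (same physical box).
#' @param n0 Medium refractive index.
#' @param wavelength Wavelength (um).
#' @param counts Train/test split sizes per class (see
#'   \code{\link{benchmark_counts}}).
#' @param multiplicity Augmented copies per training cell, by class.
#' @param tomogram_mode \code{"ideal"} uses the generated ground-truth
#'   tomograms; \code{"recon"} projects each cell over a rolling
#'   sequence, estimates the angles and reconstructs by FBP before
#'   feature extraction.
#' @param angle_step_deg,n_frames Rolling plan for \code{"recon"} mode
#'   (default 3 deg/frame over 130 frames, just past one full turn).
#' @param n_levels,alpha_ri,alpha Feature-extraction settings.
#' @param flavors Which feature pipelines to run: \code{"3D"}, \code{"2D"}
#'   or both (default).
#' @param seed Master seed; every random draw derives from it.
#' @return List of class \code{experiment_config}.
#' @export
experiment_config <- function(grid_dim = 201L, voxel_pitch = 0.1125,
                              n0 = 1.334, wavelength = 0.532,
                              counts = benchmark_counts(),
                              multiplicity = c(MC = 9L, NB = 3L, OC = 3L),
                              tomogram_mode = c("ideal", "recon"),
                              angle_step_deg = 3, n_frames = 130L,
                              n_levels = 32L, alpha_ri = 0.19, alpha = 0.1,
                              flavors = c("3D", "2D"), seed = 1L) {
  structure(list(grid_dim = as.integer(grid_dim), voxel_pitch = voxel_pitch,
                 n0 = n0, wavelength = wavelength, counts = counts,
                 multiplicity = multiplicity,
                 tomogram_mode = match.arg(tomogram_mode),
                 angle_step_deg = angle_step_deg,
                 n_frames = as.integer(n_frames),
                 n_levels = as.integer(n_levels), alpha_ri = alpha_ri,
                 alpha = alpha, flavors = match.arg(flavors, several.ok = TRUE),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' A reduced-geometry configuration for desk-scale runs
#'
#' Identical study conditions (split sizes, augmentation multiplicities,
#' class separations, physical cell sizes and box extent) on a coarser
#' grid: 71 voxels at ~0.319 um instead of 201 at 0.1125 um (the same
#' 22.6 um physical box), with ground-truth tomograms. Used by the
#' worked examples and the acceptance script.
#'
#' @param seed Master seed.
#' @param ... Overrides passed to \code{\link{experiment_config}}.
#' @return An \code{experiment_config}.
#' @export
desk_config <- function(seed = 1L, ...) {
  experiment_config(grid_dim = 71L, voxel_pitch = 201 * 0.1125 / 71,
                    tomogram_mode = "ideal", seed = seed, ...)
}

# tomogram (+ support when exactly known) for one cell under the
# configured mode. In "ideal" mode the generated ground-truth support is
# used directly; in "recon" mode the support is re-segmented from the
# FBP volume downstream.
cell_tomogram <- function(params, config) {
  ph <- generate_phantom(params, rep(config$grid_dim, 3),
                         config$voxel_pitch, config$n0)
  if (config$tomogram_mode == "ideal")
    return(list(tomogram = ph$tomogram, support = ph$support))
  angles <- (seq_len(config$n_frames) - 1) * config$angle_step_deg
  seq_q <- project_sequence(ph$tomogram, angles, config$wavelength)
  track <- estimate_angles(seq_q)
  keep <- seq_len(min(track$estimated_period, length(seq_q)))
  rec <- reconstruct_fbp(seq_q[keep],
                         structure(list(angles_deg = track$angles_deg[keep]),
                                   class = "angle_track"),
                         n0 = config$n0, wavelength = config$wavelength)
  list(tomogram = rec, support = NULL)
}

cell_features <- function(tom, config, support = NULL) {
  f3 <- NULL; f2 <- NULL
  if ("3D" %in% config$flavors) {
    if (is.null(support)) support <- segment_support(tom, config$alpha)
    f3 <- features_3d(tom, support, config$alpha_ri, config$n_levels)
  }
  if ("2D" %in% config$flavors) {
    q0 <- project_qpm(tom, 0, config$wavelength)
    f2 <- features_2d(q0, NULL, config$alpha_ri, config$n_levels, config$alpha)
  }
  list(f3 = f3, f2 = f2)
}

#' Run the full synthetic experiment
#'
#' Generates the benchmark, augments the training split with the
#' configured multiplicities (the test split is never augmented),
#' extracts 3D tomogram features and 2D phase-map features from the 0
#' degree projection of every (augmented) tomogram, trains the 3D
#' hierarchical classifier (shallow networks) and the 2D baseline
#' (logistic + LDA) and evaluates both on the same test cells.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param verbose Print stage progress.
#' @return List of class \code{tpifc_experiment} with the metric
#'   reports (\code{$reports}), fitted models (\code{$models}), feature
#'   tables (\code{$features}) and the 3D-vs-2D accuracy gap.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(...)
  rows3 <- list(); rows2 <- list(); meta <- list()
  idx <- 0L
  for (split in names(config$counts)) {
    for (cls in names(config$counts[[split]])) {
      n_cells <- config$counts[[split]][[cls]]
      if (n_cells == 0) next
      say(sprintf("[%s/%s] %d cells", split, cls, n_cells))
      for (i in seq_len(n_cells)) {
        idx <- idx + 1L
        id <- sprintf("%s_%s_%04d", split, cls, i)
        params <- sample_class_params(cls, derive_seed(config$seed, idx))
        ct <- tryCatch(cell_tomogram(params, config), error = function(e) {
          stop("stage tomogram failed for cell ", id, ": ",
               conditionMessage(e))
        })
        tom <- ct$tomogram
        fe <- tryCatch(cell_features(tom, config, ct$support),
                       error = function(e) {
          stop("stage features failed for cell ", id, ": ",
               conditionMessage(e))
        })
        rows3[[length(rows3) + 1L]] <- fe$f3
        rows2[[length(rows2) + 1L]] <- fe$f2
        meta[[length(meta) + 1L]] <- c(id = id, class_label = cls,
                                       split = split)
        if (split == "train") {
          mult <- config$multiplicity[[cls]] %||% 0L
          for (m in seq_len(mult)) {
            aug <- augment(tom, derive_seed(config$seed, idx * 32L + m))
            # augmentation preserves strict positivity on the support,
            # so the support is recoverable exactly as dn > 0
            asup <- cell_support(aug$tomogram$values > aug$tomogram$n0,
                                 aug$tomogram$voxel_pitch)
            fa <- tryCatch(cell_features(aug$tomogram, config, asup),
                           error = function(e) {
              stop("stage augment-features failed for cell ", id, ": ",
                   conditionMessage(e))
            })
            rows3[[length(rows3) + 1L]] <- fa$f3
            rows2[[length(rows2) + 1L]] <- fa$f2
            meta[[length(meta) + 1L]] <- c(id = sprintf("%s_aug%02d", id, m),
                                           class_label = cls, split = "train")
          }
        }
      }
    }
  }
  info <- as.data.frame(do.call(rbind, meta), stringsAsFactors = FALSE)
  tr <- info$split == "train"; te <- info$split == "test"

  say("training hierarchical classifiers")
  feats <- list(); models <- list(); reports <- list()
  for (fl in config$flavors) {
    X <- do.call(rbind, if (fl == "3D") rows3 else rows2)
    feats[[fl]] <- X
    models[[fl]] <- fit_hierarchical(X[tr, ], info$class_label[tr],
                                     hierarchical_config(fl),
                                     seed = derive_seed(config$seed,
                                                        if (fl == "3D") 900001L
                                                        else 900002L))
    reports[[fl]] <- evaluate_hierarchical(models[[fl]],
                                           X[te, , drop = FALSE],
                                           info$class_label[te])
  }
  gap <- if (all(c("3D", "2D") %in% config$flavors))
    reports$`3D`$hierarchical$raw$accuracy -
      reports$`2D`$hierarchical$raw$accuracy else NA_real_
  feats$info <- info
  structure(list(config = config, reports = reports, accuracy_gap = gap,
                 models = models, features = feats),
            class = "tpifc_experiment")
}

#' Evaluate a hierarchical model on a labelled test set
#'
#' Produces the stage-A panel (MC vs tumor, all test cells), the
#' stage-B panel (NB vs OC, evaluated standalone on the true tumor
#' cells) and the three-class hierarchical panel with its routed error
#' propagation. The routing identity — hierarchical MC recall equals
#' stage-A MC recall — is asserted on every run.
#'
#' @param model A \code{hier_model}.
#' @param test_features Feature matrix of the test cells.
#' @param test_labels True labels in \{MC, NB, OC\}.
#' @return List with \code{stage_A}, \code{stage_B} and
#'   \code{hierarchical} \code{metric_report}s.
#' @export
evaluate_hierarchical <- function(model, test_features, test_labels) {
  test_labels <- as.character(test_labels)
  pa <- predict_stage(model$stage_A, test_features)
  true_A <- ifelse(test_labels == "MC", "MC", "tumor")
  cm_A <- confusion_matrix(true_A, pa$labels, c("MC", "tumor"))

  tum <- test_labels %in% c("NB", "OC")
  pb <- predict_stage(model$stage_B,
                      as.matrix(test_features)[tum, , drop = FALSE])
  cm_B <- confusion_matrix(test_labels[tum], pb$labels, c("NB", "OC"))

  ph <- predict(model, test_features)
  cm_H <- confusion_matrix(test_labels, ph, c("MC", "NB", "OC"))

  rep_A <- binary_metrics(cm_A)
  rep_H <- multiclass_metrics(cm_H)
  # routing identity: an item exits as MC iff stage A says MC
  stopifnot(isTRUE(all.equal(rep_H$raw$per_class$MC[["tpr"]],
                             rep_A$raw$per_class$MC[["tpr"]])))
  list(stage_A = rep_A, stage_B = binary_metrics(cm_B),
       hierarchical = rep_H)
}

#' @export
print.tpifc_experiment <- function(x, ...) {
  cat("<tpifc_experiment> grid ", x$config$grid_dim, "^3 @ ",
      x$config$voxel_pitch, " um, mode ", x$config$tomogram_mode,
      ", seed ", x$config$seed, "\n", sep = "")
  for (fl in names(x$reports)) {
    r <- x$reports[[fl]]
    cat(sprintf("  %s: stage A acc %.1f%%, stage B acc %.1f%%, hierarchical acc %.1f%%\n",
                fl, r$stage_A$rounded$accuracy, r$stage_B$rounded$accuracy,
                r$hierarchical$rounded$accuracy))
  }
  if (is.finite(x$accuracy_gap))
    cat(sprintf("  3D - 2D hierarchical accuracy gap: %.1f points\n",
                round_half_up(x$accuracy_gap)))
  invisible(x)
}

#' Write the feature tables and metric reports of an experiment
#'
#' Features as CSV (44 canonical columns plus id, class, split, flavor)
#' and the metric panels as JSON.
#'
#' @param experiment A \code{tpifc_experiment}.
#' @param out_dir Output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_experiment <- function(experiment, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (fl in setdiff(names(experiment$features), "info")) {
    tab <- cbind(experiment$features$info,
                 flavor = fl,
                 as.data.frame(experiment$features[[fl]]))
    utils::write.csv(tab, file.path(out_dir, paste0("features_", fl, ".csv")),
                     row.names = FALSE)
  }
  rep_json <- lapply(experiment$reports, function(r) {
    lapply(r, function(m) list(confusion = unclass(m$confusion),
                               accuracy = m$rounded$accuracy,
                               per_class = m$rounded$per_class))
  })
  jsonlite::write_json(rep_json, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
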