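# Sparse-label random-forest voxel classification: the Labkit-style
# lightly-supervised regime where scribbles inside ~20 nuclei plus background
# strokes are enough to train a usable segmenter.

ann_linear_index <- function(ann, d) {
  co <- ann$coords
  if (any(co$z >= d[1] | co$y >= d[2] | co$x >= d[3]))
    stopf("annotation coordinates fall outside the %s grid", paste(d, collapse = "x"))
  co$z + 1L + d[1] * co$y + d[1] * d[2] * co$x
}

#' Train the random-forest voxel classifier
#'
#' Fits a binary classification forest (Gini splits, bootstrap resampling,
#' `floor(sqrt(p))` features per split, unlimited depth) on the annotated
#' voxels only. The model records the feature-configuration fingerprint
#' (feature names, scales, voxel spacing); prediction refuses feature stacks
#' with a different configuration.
#'
#' @param features a [compute_features()] stack.
#' @param annotations a [sparse_annotations()] object; both classes required.
#' @param n_trees number of trees (default 100; small training sets need the
#'   variance reduction).
#' @param seed integer seed; same inputs + seed give identical predictions.
#' @return object of class `rf_model`.
#' @export
train_classifier <- function(features, annotations, n_trees = 100, seed = 1L) {
  stopifnot(inherits(features, "feature_stack"),
            inherits(annotations, "sparse_annotations"))
  if (annotations$n_neuron == 0L || annotations$n_background == 0L)
    stopf("training needs annotations of both classes (neuron = 1 and background = 0)")
  idx <- ann_linear_index(annotations, features$dim)
  X <- features$X[idx, , drop = FALSE]
  y <- as.integer(annotations$coords$class)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  forest <- with_seed(seed, rf_fit_cpp(X, y, as.integer(n_trees), mtry))
  train_prob <- rf_predict_cpp(forest, X)
  structure(list(
    forest = forest,
    fingerprint = feature_fingerprint(features),
    metadata = list(n_neuron = annotations$n_neuron,
                    n_background = annotations$n_background,
                    seed = as.integer(seed), n_trees = as.integer(n_trees),
                    mtry = mtry,
                    training_accuracy = mean((train_prob >= 0.5) == (y == 1L))),
    threshold = 0.5
  ), class = "rf_model")
}

#' @export
print.rf_model <- function(x, ...) {
  cat(sprintf("<rf_model> %d trees, trained on %d neuron + %d background voxels (seed %d)\n",
              x$metadata$n_trees, x$metadata$n_neuron, x$metadata$n_background,
              x$metadata$seed))
  cat(sprintf("  features: %d @ scales %s um, spacing %s um; training accuracy %.3f\n",
              length(x$fingerprint$feature_names),
              paste(x$fingerprint$scales_um, collapse = ", "),
              paste(x$fingerprint$spacing, collapse = " x "),
              x$metadata$training_accuracy))
  invisible(x)
}

#' Predict per-voxel neuron probability
#'
#' @param object a trained `rf_model`.
#' @param features a [compute_features()] stack whose configuration matches
#'   the model fingerprint (same feature set, scales, and voxel spacing).
#' @param threshold binarization threshold on the neuron-class probability
#'   (default: the model's stored threshold, 0.5).
#' @param ... unused.
#' @return object of class `probability_map`: `prob` (3D array in `[0, 1]`),
#'   `mask` (`prob >= threshold`), `threshold`, `spacing`.
#' @export
predict.rf_model <- function(object, features, threshold = NULL, ...) {
  stopifnot(inherits(features, "feature_stack"))
  if (!fingerprints_match(object$fingerprint, feature_fingerprint(features)))
    stopf(paste0("feature configuration does not match the model fingerprint ",
                 "(trained: scales %s um, spacing %s; got: scales %s um, spacing %s)"),
          paste(object$fingerprint$scales_um, collapse = ","),
          paste(object$fingerprint$spacing, collapse = "x"),
          paste(features$scales_um, collapse = ","),
          paste(features$spacing, collapse = "x"))
  threshold <- threshold %||% object$threshold %||% 0.5
  p <- rf_predict_cpp(object$forest, features$X)
  prob <- array(p, features$dim)
  structure(list(prob = prob, mask = prob >= threshold, threshold = threshold,
                 spacing = features$spacing),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> %s voxels, threshold %.2f, %.1f%% foreground\n",
              paste(dim(x$prob), collapse = " x "), x$threshold,
              100 * mean(x$mask)))
  invisible(x)
}
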