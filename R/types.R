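# Core containers. Everything in this package uses (z, y, x) axis order with
# 0-based voxel indexing; the physical position of voxel (z, y, x) is
# (z*dz, y*dy, x*dx) um (voxel centers on the grid origin).

#' Construct a 3D intensity volume with physical voxel spacing
#'
#' The unit every pipeline stage operates on: a 3D numeric array in
#' `(z, y, x)` axis order plus the voxel spacing `(dz, dy, dx)` in micrometers.
#'
#' @param data 3D numeric array, axis order `(z, y, x)`.
#' @param spacing numeric length-3, voxel size `(dz, dy, dx)` in um; all > 0.
#' @return an object of class `volume_image` with elements `data` and
#'   `spacing`.
#' @export
#' @examples
#' v <- volume_image(array(0, c(3, 4, 4)), spacing = c(4, 1.8, 1.8))
#' dim(v$data)
volume_image <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3D array in (z, y, x) order")
  if (any(dim(data) < 1L)) stopf("all three extents must be >= 1")
  if (!is.numeric(data)) stopf("`data` must be numeric")
  if (any(!is.finite(data))) stopf("intensities must be finite")
  structure(list(data = data, spacing = check_spacing(spacing)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_image> %d x %d x %d voxels (z,y,x), spacing %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], physical extent %.1f x %.1f x %.1f um\n",
              min(x$data), max(x$data), d[1] * x$spacing[1], d[2] * x$spacing[2],
              d[3] * x$spacing[3]))
  invisible(x)
}

#' Construct an integer region label map
#'
#' A 3D grid of non-negative integer region IDs aligned to a paired
#' [volume_image()]; 0 is reserved for outside-brain / unlabeled voxels.
#'
#' @param labels 3D array of non-negative integers, `(z, y, x)` order.
#' @param name_table optional data.frame with columns `id`, `name` naming each
#'   nonzero ID; auto-populated with stringified IDs when omitted.
#' @param spacing optional voxel spacing `(dz, dy, dx)` in um.
#' @return object of class `region_labelmap`.
#' @export
region_labelmap <- function(labels, name_table = NULL, spacing = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("`labels` must be a 3D array in (z, y, x) order")
  if (any(!is.finite(labels)) || any(labels != round(labels)))
    stopf("label values must be non-negative integers")
  if (any(labels < 0)) stopf("label values must be non-negative integers")
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(name_table)) {
    name_table <- data.frame(id = ids, name = as.character(ids),
                             stringsAsFactors = FALSE)
  } else {
    if (!all(c("id", "name") %in% names(name_table)))
      stopf("`name_table` needs columns `id` and `name`")
    missing <- setdiff(ids, name_table$id)
    if (length(missing))
      stopf("labels contain IDs absent from name_table: %s",
            paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, name_table = name_table,
                 spacing = if (is.null(spacing)) NULL else check_spacing(spacing)),
            class = "region_labelmap")
}

#' @export
print.region_labelmap <- function(x, ...) {
  d <- dim(x$labels)
  ids <- sort(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<region_labelmap> %d x %d x %d voxels, %d region(s): %s\n",
              d[1], d[2], d[3], length(ids),
              paste(head(ids, 8), collapse = ", ")))
  invisible(x)
}

#' Construct sparse voxel annotations for classifier training
#'
#' @param df data.frame with integer columns `z`, `y`, `x` (0-based voxel
#'   indices) and `class` (1 = neuron, 0 = background).
#' @param dim optional grid extents used to validate coordinates.
#' @return object of class `sparse_annotations`.
#' @export
sparse_annotations <- function(df, dim = NULL) {
  need <- c("z", "y", "x", "class")
  if (!all(need %in% names(df))) stopf("annotations need columns z, y, x, class")
  df <- df[need]
  if (any(!df$class %in% c(0L, 1L))) stopf("class must be 0 (background) or 1 (neuron)")
  if (any(df$z != round(df$z) | df$y != round(df$y) | df$x != round(df$x)))
    stopf("voxel coordinates must be integers")
  if (any(df$z < 0 | df$y < 0 | df$x < 0)) stopf("voxel coordinates must be >= 0")
  if (!is.null(dim)) {
    if (any(df$z >= dim[1] | df$y >= dim[2] | df$x >= dim[3]))
      stopf("annotation coordinates fall outside the %s grid",
            paste(dim, collapse = "x"))
  }
  for (cc in need) df[[cc]] <- as.integer(df[[cc]])
  structure(list(coords = df,
                 n_neuron = sum(df$class == 1L),
                 n_background = sum(df$class == 0L)),
            class = "sparse_annotations")
}

#' @export
print.sparse_annotations <- function(x, ...) {
  cat(sprintf("<sparse_annotations> %d neuron voxel(s), %d background voxel(s)\n",
              x$n_neuron, x$n_background))
  invisible(x)
}

#' Construct an instance label grid
#'
#' 3D grid of non-negative integers: 0 = background, k > 0 = the k-th detected
#' object. IDs are relabeled to consecutive `1..K` in first-appearance order;
#' per-instance voxel counts and physical volumes are attached.
#'
#' @param labels 3D integer array (any non-negative IDs; relabeled).
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @return object of class `instance_labels` with elements `labels`,
#'   `spacing`, `n`, `voxel_counts`, `volumes_um3`.
#' @export
instance_labels <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("`labels` must be a 3D array")
  if (any(labels < 0) || any(labels != round(labels)))
    stopf("instance labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  spacing <- check_spacing(spacing)
  ids <- unique(labels[labels > 0L])
  if (length(ids) && !identical(sort(ids), seq_along(ids))) {
    # relabel to consecutive 1..K, order of first appearance
    map <- integer(max(ids))
    map[ids] <- seq_along(ids)
    pos <- labels > 0L
    labels[pos] <- map[labels[pos]]
  }
  K <- length(ids)
  counts <- if (K) tabulate(labels[labels > 0L], nbins = K) else integer(0)
  structure(list(labels = labels, spacing = spacing, n = K,
                 voxel_counts = counts,
                 volumes_um3 = counts * voxel_volume_um3(spacing)),
            class = "instance_labels")
}

#' @export
print.instance_labels <- function(x, ...) {
  cat(sprintf("<instance_labels> %d instance(s) in %s grid\n", x$n,
              paste(dim(x$labels), collapse = " x ")))
  if (x$n)
    cat(sprintf("  volumes: median %.0f um^3, range [%.0f, %.0f]\n",
                median(x$volumes_um3), min(x$volumes_um3), max(x$volumes_um3)))
  invisible(x)
}

#' Physical centroids of labeled instances
#'
#' @param inst an `instance_labels` object.
#' @return numeric matrix `n x 3` of centroids in um, `(z, y, x)` order.
#' @export
instance_centroids <- function(inst) {
  stopifnot(inherits(inst, "instance_labels"))
  if (inst$n == 0L) return(matrix(numeric(0), 0, 3,
                                  dimnames = list(NULL, c("z", "y", "x"))))
  d <- dim(inst$labels)
  idx <- which(inst$labels > 0L)
  lab <- inst$labels[idx]
  idx0 <- idx - 1L
  z <- idx0 %% d[1]
  y <- (idx0 %/% d[1]) %% d[2]
  x <- idx0 %/% (d[1] * d[2])
  cz <- tapply(z, lab, mean) * inst$spacing[1]
  cy <- tapply(y, lab, mean) * inst$spacing[2]
  cx <- tapply(x, lab, mean) * inst$spacing[3]
  out <- cbind(z = as.numeric(cz), y = as.numeric(cy), x = as.numeric(cx))
  out[order(as.integer(names(cz))), , drop = FALSE]
}
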