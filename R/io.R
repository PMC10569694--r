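# On-disk formats the pipeline touches. Axis order is (z, y, x) everywhere;
# spacing is mandatory metadata -- there is deliberately no "assume 1 um
# isotropic" fallback because the volume filter and the watershed both work
# in physical units.

is_nifti_path <- function(path) grepl("\\.nii$", path, ignore.case = TRUE)

#' Read a 3D volume from disk
#'
#' @param path multi-page TIFF (`.tif`/`.tiff`) or NIfTI-1 (`.nii`) file.
#' @param spacing_override optional `(dz, dy, dx)` um; required when the file
#'   carries no voxel-size metadata, and takes precedence when it does.
#' @return a [volume_image()].
#' @export
read_volume <- function(path, spacing_override = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  r <- if (is_nifti_path(path)) read_nifti(path) else read_tiff(path)
  if (length(dim(r$data)) != 3L || any(dim(r$data) == 1L) && length(dim(r$data)) < 3L)
    stopf("%s is not a 3D image", path)
  spacing <- spacing_override %||% r$spacing
  if (is.null(spacing) || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf(paste0("no voxel spacing in %s metadata; pass spacing_override = ",
                 "c(dz, dy, dx) in um (there is no implicit default)"), path)
  volume_image(r$data, spacing)
}

#' Write a volume to disk (TIFF or NIfTI by extension)
#'
#' @param volume a [volume_image()].
#' @param path output path; `.nii` selects NIfTI-1, anything else multi-page
#'   TIFF.
#' @param ... passed to [write_tiff()] / [write_nifti()] (e.g. `bits`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, ...) {
  stopifnot(inherits(volume, "volume_image"))
  if (is_nifti_path(path)) write_nifti(volume$data, path, volume$spacing, ...)
  else write_tiff(volume$data, path, volume$spacing, ...)
  invisible(path)
}

#' Read an integer region label map
#'
#' @param path NIfTI-1 or TIFF file of integer region IDs.
#' @param name_table optional path to a sidecar CSV with columns `id,name`;
#'   when absent, names default to stringified IDs.
#' @param companion optional [volume_image()] whose grid the labels must match.
#' @param spacing_override optional `(dz, dy, dx)` um.
#' @return a [region_labelmap()].
#' @export
read_labelmap <- function(path, name_table = NULL, companion = NULL,
                          spacing_override = NULL) {
  r <- if (is_nifti_path(path)) read_nifti(path) else read_tiff(path)
  if (any(r$data != round(r$data)))
    stopf("label map %s contains non-integer voxel values", path)
  if (!is.null(companion)) {
    stopifnot(inherits(companion, "volume_image"))
    if (!identical(dim(r$data), dim(companion$data)))
      stopf("label map shape (%s) does not match companion volume (%s)",
            paste(dim(r$data), collapse = "x"),
            paste(dim(companion$data), collapse = "x"))
  }
  nt <- NULL
  if (!is.null(name_table)) {
    nt <- read.csv(name_table, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("id", "name") %in% names(nt)))
      stopf("sidecar %s needs columns id,name", name_table)
  }
  spacing <- spacing_override %||% r$spacing
  if (!is.null(spacing) && (any(!is.finite(spacing)) || any(spacing <= 0)))
    spacing <- NULL
  region_labelmap(r$data, name_table = nt, spacing = spacing)
}

#' Write a region label map (plus optional name-table sidecar)
#'
#' @param labelmap a [region_labelmap()].
#' @param path output `.nii` or `.tif` path.
#' @param name_table_path optional path for the `id,name` sidecar CSV.
#' @param spacing `(dz, dy, dx)` um; defaults to the labelmap's own spacing.
#' @return `path`, invisibly.
#' @export
write_labelmap <- function(labelmap, path, name_table_path = NULL,
                           spacing = NULL) {
  stopifnot(inherits(labelmap, "region_labelmap"))
  spacing <- spacing %||% labelmap$spacing
  if (is.null(spacing)) stopf("labelmap has no spacing; pass `spacing`")
  if (is_nifti_path(path)) write_nifti(labelmap$labels, path, spacing, "int32")
  else write_tiff(labelmap$labels, path, spacing,
                  bits = if (max(labelmap$labels) <= 65535) 16L else "float")
  if (!is.null(name_table_path))
    write.csv(labelmap$name_table, name_table_path, row.names = FALSE)
  invisible(path)
}

#' Read / write sparse annotations as CSV
#'
#' CSV columns `z,y,x,class` with 0-based voxel indices, class 1 = neuron,
#' 0 = background.
#'
#' @param path CSV file.
#' @param dim optional grid extents for validation.
#' @return [sparse_annotations()].
#' @export
read_annotations <- function(path, dim = NULL) {
  df <- read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  sparse_annotations(df, dim = dim)
}

#' @rdname read_annotations
#' @param ann a [sparse_annotations()] object.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "sparse_annotations"))
  write.csv(ann$coords, path, row.names = FALSE)
  invisible(path)
}

fingerprint_json <- function(fp) {
  jsonlite::toJSON(fp, auto_unbox = TRUE, digits = NA)
}

fingerprint_md5 <- function(fp) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(as.character(fingerprint_json(fp)), tf, eos = NULL)
  unname(tools::md5sum(tf))
}

#' Save / load a trained classifier
#'
#' The model is stored as a single JSON file: the forest (plain numeric node
#' tables, full double precision), the feature-configuration fingerprint
#' (feature names, scales, voxel spacing), its md5 checksum, and training
#' metadata. `load_model()` refuses files whose fingerprint fails the
#' checksum, and `predict()` refuses feature stacks whose configuration
#' differs from training.
#'
#' @param model an `rf_model` from [train_classifier()].
#' @param path model file (JSON).
#' @return `save_model()`: `path` invisibly; `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rf_model"))
  obj <- list(
    format = "lsmcount-rf-1",
    fingerprint = model$fingerprint,
    fingerprint_md5 = fingerprint_md5(model$fingerprint),
    metadata = model$metadata,
    threshold = model$threshold,
    trees = model$forest
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  # parse without simplification: jsonlite would otherwise collapse a forest
  # of equally-sized trees into a 3D array
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "lsmcount-rf-1"))
    stopf("%s is not an lsmcount model file", path)
  fp <- list(feature_names = vapply(obj$fingerprint$feature_names,
                                    as.character, character(1), USE.NAMES = FALSE),
             scales_um = vapply(obj$fingerprint$scales_um, as.numeric, numeric(1),
                                USE.NAMES = FALSE),
             spacing = vapply(obj$fingerprint$spacing, as.numeric, numeric(1),
                              USE.NAMES = FALSE))
  if (!identical(unname(fingerprint_md5(fp)), obj$fingerprint_md5))
    stopf("model fingerprint integrity check failed for %s (file tampered or corrupted)",
          path)
  trees <- lapply(obj$trees, function(t) {
    m <- do.call(rbind, lapply(t, function(row) vapply(row, as.numeric, numeric(1))))
    if (ncol(m) != 5L) stopf("malformed tree table in %s", path)
    dimnames(m) <- NULL
    m
  })
  structure(list(forest = trees, fingerprint = fp,
                 metadata = lapply(obj$metadata, function(x) x),
                 threshold = as.numeric(obj$threshold)),
            class = "rf_model")
}

#' Write per-region density summaries to CSV
#'
#' @param summaries a list of `density_summary` objects (or a single one).
#' @param path output CSV.
#' @return `path`, invisibly. Warns and writes a header-only file when
#'   `summaries` is empty.
#' @export
write_report <- function(summaries, path) {
  if (inherits(summaries, "density_summary")) summaries <- list(summaries)
  cols <- c("specimen_id", "region_id", "region_name", "n_subvolumes",
            "subvolume_edge_um", "mean_density_per_mm3", "sd_density_per_mm3",
            "region_volume_mm3", "estimated_total", "seed")
  if (!length(summaries)) {
    warnf("no summaries to report; writing header-only CSV")
    df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "density_summary"))
    data.frame(specimen_id = s$specimen_id, region_id = s$region_id,
               region_name = s$region_name %||% as.character(s$region_id),
               n_subvolumes = s$n_subvolumes,
               subvolume_edge_um = s$subvolume_edge_um %||% NA_real_,
               mean_density_per_mm3 = s$mean_density_per_mm3,
               sd_density_per_mm3 = s$sd_density_per_mm3,
               region_volume_mm3 = s$region_volume_mm3,
               estimated_total = s$estimated_total,
               seed = s$seed %||% NA_integer_,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
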