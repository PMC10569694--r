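# One-command orchestration: region mask -> sampling plan -> per-subvolume
# segmentation -> volume-filter counting -> region summary -> report.

#' Segment a volume into neuron instances with a trained classifier
#'
#' Convenience chain: feature stack (at the model's scales) -> probability
#' prediction -> binarization -> erosion-seeded watershed -> connected
#' components.
#'
#' @param volume a [volume_image()].
#' @param model a trained `rf_model`.
#' @param threshold probability threshold (default: the model's).
#' @param connectivity 26 or 6.
#' @return an [instance_labels()] object.
#' @export
segment_instances <- function(volume, model, threshold = NULL, connectivity = 26) {
  stopifnot(inherits(volume, "volume_image"), inherits(model, "rf_model"))
  if (!isTRUE(all.equal(as.numeric(model$fingerprint$spacing), volume$spacing,
                        tolerance = 1e-9)))
    stopf("volume spacing (%s) differs from the spacing the model was trained at (%s)",
          paste(volume$spacing, collapse = "x"),
          paste(model$fingerprint$spacing, collapse = "x"))
  fs <- compute_features(volume, model$fingerprint$scales_um)
  pm <- predict(model, fs, threshold = threshold)
  ws <- watershed_split(pm$mask, volume$spacing, connectivity)
  # dams are background, so components of the dam-free binary are the basins
  connected_components(ws$labels > 0L, connectivity, volume$spacing)
}

#' Run configuration for an end-to-end region count
#'
#' @param volume path or [volume_image()].
#' @param labelmap path or [region_labelmap()].
#' @param model path or `rf_model`.
#' @param regions integer region IDs to analyze.
#' @param n_subvolumes,edge_um,inclusion_threshold sampling parameters.
#' @param filter_params a [volume_filter_params()], or `NULL` to derive them
#'   from the pooled empirical instance-volume distribution of the run.
#' @param pad_um halo added around each subvolume crop before segmentation so
#'   boundary-touching nuclei are segmented whole (default 10 um, about two
#'   nucleus radii).
#' @param seed master seed; region r uses `seed + r - 1` for its plan.
#' @param specimen_id identifier recorded in the report.
#' @param spacing_override passed to [read_volume()] for path input.
#' @param out_dir optional output directory (report CSV, subvolume detail
#'   CSV, manifest JSON).
#' @return object of class `run_config`.
#' @export
run_config <- function(volume, labelmap, model, regions,
                       n_subvolumes = 15, edge_um = 100,
                       inclusion_threshold = 1.0, filter_params = NULL,
                       pad_um = 10, seed = 1L, specimen_id = "specimen",
                       spacing_override = NULL, out_dir = NULL) {
  for (p in c(volume, labelmap, model))
    if (is.character(p) && !file.exists(p)) stopf("file not found: %s", p)
  structure(list(volume = volume, labelmap = labelmap, model = model,
                 regions = regions, n_subvolumes = n_subvolumes,
                 edge_um = edge_um, inclusion_threshold = inclusion_threshold,
                 filter_params = filter_params, pad_um = pad_um,
                 seed = as.integer(seed), specimen_id = specimen_id,
                 spacing_override = spacing_override, out_dir = out_dir),
            class = "run_config")
}

crop_volume <- function(volume, lo, hi) {
  volume_image(volume$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                           (lo[3] + 1):hi[3], drop = FALSE], volume$spacing)
}

#' Count neurons in labeled regions, end to end
#'
#' For each region: build the region mask, place the sampling plan, and for
#' each accepted subvolume segment a padded crop with the classifier,
#' watershed and label it, then count instances whose centroid falls in the
#' counting window through the volume filter. Densities are summarized per
#' region and written to the report. Fully deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return list of `density_summary`, one per region, invisibly also written
#'   to `out_dir` when configured.
#' @export
run_region_count <- function(config) {
  stopifnot(inherits(config, "run_config"))
  vol <- if (is.character(config$volume))
    read_volume(config$volume, config$spacing_override) else config$volume
  lm <- if (is.character(config$labelmap))
    read_labelmap(config$labelmap, companion = vol) else config$labelmap
  model <- if (is.character(config$model)) load_model(config$model) else config$model
  stopifnot(inherits(vol, "volume_image"), inherits(lm, "region_labelmap"),
            inherits(model, "rf_model"))
  if (!identical(dim(vol$data), dim(lm$labels)))
    stopf("volume and label map shapes differ")
  sp <- vol$spacing
  d <- dim(vol$data)
  pad <- pmax(0L, as.integer(ceiling(config$pad_um / sp)))

  summaries <- list()
  detail <- list()
  for (ri in seq_along(config$regions)) {
    rid <- config$regions[ri]
    stage <- function(what) sprintf("region %s: %s", rid, what)
    mask <- tryCatch(region_mask(lm, rid), error = function(e)
      stopf("%s: %s", stage("region_mask"), conditionMessage(e)))
    plan <- tryCatch(
      sample_subvolumes(mask, sp, n = config$n_subvolumes,
                        edge_um = config$edge_um,
                        inclusion_threshold = config$inclusion_threshold,
                        seed = config$seed + ri - 1L, region_id = rid),
      error = function(e) stopf("%s: %s", stage("sample_subvolumes"),
                                conditionMessage(e)))
    segs <- vector("list", length(plan$subvolumes))
    for (si in seq_along(plan$subvolumes)) {
      sv <- plan$subvolumes[[si]]
      lo <- pmax(sv$origin - pad, 0L)
      hi <- pmin(sv$origin + sv$extent + pad, d)
      segs[[si]] <- tryCatch({
        crop <- crop_volume(vol, lo, hi)
        inst <- segment_instances(crop, model)
        list(inst = inst, core = subvolume(sv$origin - lo, sv$extent, sp, rid))
      }, error = function(e)
        stopf("%s subvolume %d: %s", stage("segment"), si, conditionMessage(e)))
    }
    params <- config$filter_params %||%
      auto_filter_params(unlist(lapply(segs, function(s) s$inst$volumes_um3)))
    counts <- lapply(segs, function(s)
      volume_filter_count(s$inst, params, window = s$core))
    summaries[[ri]] <- summarize_region(
      counts, region_volume(mask, sp), specimen_id = config$specimen_id,
      region_id = rid,
      region_name = lm$name_table$name[match(rid, lm$name_table$id)],
      edge_um = config$edge_um, seed = config$seed)
    detail[[ri]] <- data.frame(
      region_id = rid,
      subvolume = seq_along(counts),
      origin_z = vapply(plan$subvolumes, function(s) s$origin[1], integer(1)),
      origin_y = vapply(plan$subvolumes, function(s) s$origin[2], integer(1)),
      origin_x = vapply(plan$subvolumes, function(s) s$origin[3], integer(1)),
      raw_count = vapply(counts, `[[`, numeric(1), "raw_count"),
      filtered_count = vapply(counts, `[[`, numeric(1), "filtered_count"),
      volume_mm3 = vapply(counts, `[[`, numeric(1), "volume_mm3"),
      density_per_mm3 = vapply(counts, `[[`, numeric(1), "density_per_mm3"))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(summaries, file.path(config$out_dir, "region_summary.csv"))
    write.csv(do.call(rbind, detail),
              file.path(config$out_dir, "subvolume_detail.csv"),
              row.names = FALSE)
    manifest <- list(
      package = "lsmcount",
      version = as.character(utils::packageVersion("lsmcount")),
      seed = config$seed, regions = config$regions,
      n_subvolumes = config$n_subvolumes, edge_um = config$edge_um,
      inclusion_threshold = config$inclusion_threshold,
      pad_um = config$pad_um, specimen_id = config$specimen_id,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  summaries
}
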