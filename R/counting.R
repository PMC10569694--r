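# The quantitative heart of the workflow: volume filtering, per-subvolume
# counting, density and total-number estimation, and variability statistics.

#' Volume-filter parameters
#'
#' `v_min` discards sub-threshold debris, objects between `v_min` and `v_max`
#' count once, and objects above `v_max` are treated as fused clusters whose
#' count is recovered by partitioning their volume by the mean single-neuron
#' volume `v_ref`.
#'
#' @param v_min,v_ref,v_max volumes in um^3 with `0 < v_min <= v_ref <= v_max`.
#' @return object of class `volume_filter_params`.
#' @export
volume_filter_params <- function(v_min, v_ref, v_max) {
  if (!(v_min > 0 && v_min <= v_ref && v_ref <= v_max))
    stopf("need 0 < v_min <= v_ref <= v_max (got %g, %g, %g)", v_min, v_ref, v_max)
  structure(list(v_min = v_min, v_ref = v_ref, v_max = v_max),
            class = "volume_filter_params")
}

#' Derive volume-filter parameters from an empirical volume distribution
#'
#' `v_ref` is the median of the mid-range (20th-80th percentile) instance
#' volumes, `v_min = 0.25 v_ref`, `v_max = 2 v_ref` -- the data-driven
#' counterpart of eyeballing the typical neuron size.
#'
#' @param volumes_um3 observed instance volumes.
#' @return a [volume_filter_params()] object.
#' @export
auto_filter_params <- function(volumes_um3) {
  v <- volumes_um3[is.finite(volumes_um3) & volumes_um3 > 0]
  if (!length(v)) stopf("no positive volumes to derive filter parameters from")
  q <- quantile(v, c(0.2, 0.8), names = FALSE)
  mid <- v[v >= q[1] & v <= q[2]]
  v_ref <- median(if (length(mid)) mid else v)
  volume_filter_params(0.25 * v_ref, v_ref, 2 * v_ref)
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-instance count contribution under the volume filter
#'
#' @param volumes_um3 instance volumes.
#' @param params a [volume_filter_params()].
#' @return integer vector: 0 for debris (`V < v_min`), 1 for
#'   `v_min <= V <= v_max`, and `max(2, round(V / v_ref))` for oversized
#'   (fused) objects.
#' @export
volume_filter_contribution <- function(volumes_um3, params) {
  stopifnot(inherits(params, "volume_filter_params"))
  out <- integer(length(volumes_um3))
  single <- volumes_um3 >= params$v_min & volumes_um3 <= params$v_max
  fused <- volumes_um3 > params$v_max
  out[single] <- 1L
  out[fused] <- pmax(2L, as.integer(round_half_up(volumes_um3[fused] / params$v_ref)))
  out
}

#' Count instances in a (sub)volume through the volume filter
#'
#' Sums the per-instance contributions of [volume_filter_contribution()].
#' When `window` is given, only instances whose centroid falls inside the
#' window's half-open physical box contribute (the associated-point counting
#' rule), and the density denominator is the window's realized volume; this
#' keeps the density estimator free of the edge bias that counting clipped
#' fragments would introduce. Without a window the whole grid is the counting
#' volume.
#'
#' @param instances an [instance_labels()] object (volumes in physical um^3).
#' @param params a [volume_filter_params()].
#' @param window optional [subvolume()] whose `origin` is expressed in the
#'   coordinate frame of `instances`.
#' @return object of class `subvolume_count`: `raw_count`, `filtered_count`,
#'   `volumes_um3` (contributing instances), `volume_mm3`,
#'   `density_per_mm3`, `window`.
#' @export
volume_filter_count <- function(instances, params, window = NULL) {
  stopifnot(inherits(instances, "instance_labels"),
            inherits(params, "volume_filter_params"))
  vols <- instances$volumes_um3
  keep <- rep(TRUE, instances$n)
  if (!is.null(window)) {
    stopifnot(inherits(window, "subvolume"))
    cen <- instance_centroids(instances)
    lo <- window$origin * instances$spacing
    hi <- (window$origin + window$extent) * instances$spacing
    keep <- cen[, 1] >= lo[1] & cen[, 1] < hi[1] &
            cen[, 2] >= lo[2] & cen[, 2] < hi[2] &
            cen[, 3] >= lo[3] & cen[, 3] < hi[3]
    vol_mm3 <- window$volume_mm3
  } else {
    vol_mm3 <- prod(dim(instances$labels) * instances$spacing) / UM3_PER_MM3
  }
  vols <- vols[keep]
  contrib <- volume_filter_contribution(vols, params)
  filtered <- sum(contrib)
  structure(list(raw_count = sum(keep), filtered_count = filtered,
                 volumes_um3 = vols[contrib > 0L], volume_mm3 = vol_mm3,
                 density_per_mm3 = filtered / vol_mm3, window = window,
                 params = params),
            class = "subvolume_count")
}

#' @export
print.subvolume_count <- function(x, ...) {
  cat(sprintf("<subvolume_count> %d raw -> %d filtered in %.4g mm^3 = %.0f /mm^3\n",
              x$raw_count, x$filtered_count, x$volume_mm3, x$density_per_mm3))
  invisible(x)
}

#' Neuron density of a subvolume count
#'
#' @param count a `subvolume_count`.
#' @return filtered count / realized physical volume, neurons per mm^3.
#' @export
density <- function(count) {
  stopifnot(inherits(count, "subvolume_count"))
  if (count$volume_mm3 <= 0) stopf("subvolume physical volume must be > 0")
  count$filtered_count / count$volume_mm3
}

#' Summarize subvolume counts into a per-region density estimate
#'
#' Mean and sample SD (n-1 denominator) of the subvolume densities; the
#' total-number estimate is mean density x region volume, rounded to the
#' nearest integer.
#'
#' @param counts list of `subvolume_count` (>= 2 for an SD); all from one
#'   region.
#' @param region_volume_mm3 label-map volume of the region.
#' @param specimen_id identifier recorded in reports.
#' @param region_id,region_name,edge_um,seed provenance recorded in reports.
#' @return object of class `density_summary`.
#' @export
summarize_region <- function(counts, region_volume_mm3, specimen_id = "specimen",
                             region_id = NA_integer_, region_name = NULL,
                             edge_um = NA_real_, seed = NA_integer_) {
  if (inherits(counts, "subvolume_count")) counts <- list(counts)
  if (length(counts) < 2L) stopf("need >= 2 subvolumes for a density SD")
  rid <- unique(c(region_id, vapply(counts, function(x)
    if (!is.null(x$window)) x$window$region_id else NA_integer_, numeric(1))))
  rid <- rid[!is.na(rid)]
  if (length(rid) > 1L)
    stopf("subvolume counts come from multiple regions: %s", paste(rid, collapse = ", "))
  if (length(rid)) region_id <- rid
  dens <- vapply(counts, density, numeric(1))
  m <- mean(dens)
  s <- sd(dens)
  structure(list(region_id = region_id,
                 region_name = region_name %||% as.character(region_id),
                 specimen_id = specimen_id,
                 n_subvolumes = length(counts),
                 subvolume_edge_um = edge_um,
                 mean_density_per_mm3 = m, sd_density_per_mm3 = s,
                 region_volume_mm3 = region_volume_mm3,
                 estimated_total = round_half_up(m * region_volume_mm3),
                 densities = dens, seed = seed),
            class = "density_summary")
}

#' @export
print.density_summary <- function(x, ...) {
  cat(sprintf("<density_summary> %s region %s: %.0f +/- %.0f /mm^3 over %d subvolumes\n",
              x$specimen_id, x$region_name, x$mean_density_per_mm3,
              x$sd_density_per_mm3, x$n_subvolumes))
  cat(sprintf("  region volume %.4g mm^3 -> estimated total %d\n",
              x$region_volume_mm3, as.integer(x$estimated_total)))
  invisible(x)
}

#' Coefficient of variation
#'
#' Sample SD divided by the mean; used across specimens per region.
#'
#' @param values >= 2 numeric values with nonzero mean.
#' @return SD / mean.
#' @export
cv <- function(values) {
  if (length(values) < 2L) stopf("need >= 2 values for a CV")
  m <- mean(values)
  if (m == 0) stopf("CV undefined for zero mean")
  sd(values) / m
}

#' Percent difference between raw and corrected density
#'
#' `|raw - corrected| / corrected x 100`, the morphology-distortion metric:
#' how far a density measured in uncorrected (deformed) space deviates from
#' the density in corrected space.
#'
#' @param raw_density density measured in deformed/uncorrected space.
#' @param corrected_density density in corrected space (> 0).
#' @return percent difference.
#' @export
percent_difference <- function(raw_density, corrected_density) {
  if (any(corrected_density <= 0)) stopf("corrected density must be > 0")
  abs(raw_density - corrected_density) / corrected_density * 100
}
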