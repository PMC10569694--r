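# Design-based random subvolume sampling inside a labeled region: the
# "digital optical fractionator". Counting cubes are placed uniformly at
# random over all grid positions where they fit, and accepted only if the
# required fraction of their voxels carries the target region label (strict
# screening, threshold 1.0, by default -- the only rule that guarantees
# counts are attributed to a single region). Accepted cubes may overlap:
# placements are independent, which keeps the density estimator unbiased.

#' Axis-aligned cubic counting window
#'
#' @param origin `(z, y, x)` voxel origin, 0-based.
#' @param extent `(z, y, x)` extents in voxels.
#' @param spacing voxel spacing um.
#' @param region_id region the window samples.
#' @return object of class `subvolume` with physical `edges_um` and
#'   `volume_mm3` (the realized volume, `prod(extent * spacing)`, which is the
#'   density denominator -- not the nominal cube volume).
#' @export
subvolume <- function(origin, extent, spacing, region_id = NA_integer_) {
  spacing <- check_spacing(spacing)
  origin <- as.integer(origin); extent <- as.integer(extent)
  if (any(origin < 0) || any(extent < 1)) stopf("bad subvolume geometry")
  edges <- extent * spacing
  structure(list(origin = origin, extent = extent, spacing = spacing,
                 edges_um = edges, volume_mm3 = prod(edges) / UM3_PER_MM3,
                 region_id = region_id),
            class = "subvolume")
}

#' @export
print.subvolume <- function(x, ...) {
  cat(sprintf("<subvolume> origin (%s), extent (%s) vox = %.1f x %.1f x %.1f um (%.3g mm^3)\n",
              paste(x$origin, collapse = ","), paste(x$extent, collapse = ","),
              x$edges_um[1], x$edges_um[2], x$edges_um[3], x$volume_mm3))
  invisible(x)
}

#' Binary mask of one region
#'
#' @param labelmap a [region_labelmap()].
#' @param region_id region ID; must be present in the map.
#' @return logical 3D array, `TRUE` exactly where `labels == region_id`.
#' @export
region_mask <- function(labelmap, region_id) {
  stopifnot(inherits(labelmap, "region_labelmap"))
  m <- labelmap$labels == region_id
  if (!any(m)) {
    ids <- sort(unique(labelmap$labels[labelmap$labels > 0L]))
    stopf("region %s not present in label map; available IDs: %s",
          region_id, paste(ids, collapse = ", "))
  }
  m
}

#' Physical volume of a region mask in mm^3
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @return voxel count x voxel volume, in mm^3.
#' @export
region_volume <- function(mask, spacing) {
  mask <- check_mask(mask)
  if (!any(mask)) stopf("region mask is empty")
  sum(mask) * voxel_volume_um3(spacing) / UM3_PER_MM3
}

# 3D summed-area table with a zero border, for O(1) window sums
integral_image <- function(mask) {
  s <- array(0, dim(mask) + 1L)
  s[-1, -1, -1] <- mask * 1
  for (a in 1:3) {
    perm <- c(a, setdiff(1:3, a))
    s <- aperm(s, perm)
    d <- dim(s)
    s <- array(apply(s, c(2, 3), cumsum), d)
    s <- aperm(s, order(perm))
  }
  s
}

window_sum <- function(S, o, e) {
  # o: 0-based origins (matrix n x 3), e: extent
  z0 <- o[, 1] + 1L; y0 <- o[, 2] + 1L; x0 <- o[, 3] + 1L
  z1 <- z0 + e[1]; y1 <- y0 + e[2]; x1 <- x0 + e[3]
  d <- dim(S)
  at <- function(z, y, x) S[cbind(z, y, x)]
  at(z1, y1, x1) - at(z0, y1, x1) - at(z1, y0, x1) - at(z1, y1, x0) +
    at(z0, y0, x1) + at(z0, y1, x0) + at(z1, y0, x0) - at(z0, y0, x0)
}

#' Place random counting subvolumes inside a region
#'
#' Cube extents are `round(edge_um / spacing)` per axis (minimum 1 voxel).
#' Origins are drawn uniformly at random over all positions where the cube
#' fits in the grid; a placement is accepted iff the fraction of its voxels
#' inside the mask is at least `inclusion_threshold`. Draws repeat until `n`
#' cubes are accepted or the retry cap is hit.
#'
#' @param mask logical 3D region mask.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param n number of subvolumes (default 15, the per-region sampling depth
#'   the workflow standardizes on).
#' @param edge_um nominal cube edge (default 100 um).
#' @param inclusion_threshold required in-region voxel fraction, in `(0, 1]`;
#'   default 1 (strict screening).
#' @param seed integer seed; identical inputs + seed give an identical plan.
#' @param region_id recorded on each subvolume.
#' @param max_tries retry cap (default `10000 * n`).
#' @return object of class `sampling_plan`: accepted `subvolumes`, `rejections`,
#'   `tries`, and the sampling parameters.
#' @export
sample_subvolumes <- function(mask, spacing, n = 15, edge_um = 100,
                              inclusion_threshold = 1.0, seed = 1L,
                              region_id = NA_integer_, max_tries = NULL) {
  mask <- check_mask(mask)
  spacing <- check_spacing(spacing)
  if (inclusion_threshold <= 0 || inclusion_threshold > 1)
    stopf("inclusion_threshold must be in (0, 1]")
  max_tries <- max_tries %||% (10000 * n)
  d <- dim(mask)
  extent <- pmax(1L, as.integer(round(edge_um / spacing)))
  nfree <- d - extent + 1L
  if (any(nfree < 1L))
    stopf("a %g um cube (%s voxels) does not fit in the %s grid",
          edge_um, paste(extent, collapse = "x"), paste(d, collapse = "x"))
  S <- integral_image(mask)
  cube_vox <- prod(extent)

  accepted <- list()
  rejections <- 0L
  tries <- 0L
  with_seed(seed, {
    while (length(accepted) < n && tries < max_tries) {
      chunk <- min(max(2L * n, 64L), max_tries - tries)
      o <- cbind(sample.int(nfree[1], chunk, replace = TRUE) - 1L,
                 sample.int(nfree[2], chunk, replace = TRUE) - 1L,
                 sample.int(nfree[3], chunk, replace = TRUE) - 1L)
      frac <- window_sum(S, o, extent) / cube_vox
      for (i in seq_len(chunk)) {
        tries <- tries + 1L
        if (frac[i] >= inclusion_threshold - 1e-12) {
          accepted[[length(accepted) + 1L]] <-
            subvolume(o[i, ], extent, spacing, region_id)
          if (length(accepted) == n) break
        } else rejections <- rejections + 1L
      }
    }
  })
  if (length(accepted) < n)
    stopf("retry cap %d exhausted with %d/%d accepted (acceptance rate %.4f); region too small or thin for a %g um cube at threshold %g",
          max_tries, length(accepted), n,
          length(accepted) / max(tries, 1L), edge_um, inclusion_threshold)
  structure(list(region_id = region_id, n_subvolumes = n, edge_um = edge_um,
                 inclusion_threshold = inclusion_threshold, seed = as.integer(seed),
                 extent = extent, spacing = spacing,
                 subvolumes = accepted, rejections = rejections, tries = tries),
            class = "sampling_plan")
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("<sampling_plan> region %s: %d cube(s) of %g um (extent %s vox), %d rejection(s), seed %d\n",
              x$region_id, x$n_subvolumes, x$edge_um,
              paste(x$extent, collapse = "x"), x$rejections, x$seed))
  invisible(x)
}

#' Serialize / restore a sampling plan as JSON
#'
#' @param plan a `sampling_plan`.
#' @param path JSON file.
#' @return `write_plan()`: `path` invisibly; `read_plan()`: the plan.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "sampling_plan"))
  obj <- list(region_id = plan$region_id, n_subvolumes = plan$n_subvolumes,
              edge_um = plan$edge_um,
              inclusion_threshold = plan$inclusion_threshold,
              seed = plan$seed, extent = plan$extent, spacing = plan$spacing,
              rejections = plan$rejections, tries = plan$tries,
              origins = do.call(rbind, lapply(plan$subvolumes, `[[`, "origin")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spacing <- as.numeric(obj$spacing)
  extent <- as.integer(obj$extent)
  origins <- matrix(as.integer(obj$origins), ncol = 3)
  subs <- lapply(seq_len(nrow(origins)), function(i)
    subvolume(origins[i, ], extent, spacing, obj$region_id))
  structure(list(region_id = obj$region_id, n_subvolumes = obj$n_subvolumes,
                 edge_um = obj$edge_um,
                 inclusion_threshold = obj$inclusion_threshold,
                 seed = as.integer(obj$seed), extent = extent, spacing = spacing,
                 subvolumes = subs, rejections = obj$rejections,
                 tries = obj$tries),
            class = "sampling_plan")
}
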