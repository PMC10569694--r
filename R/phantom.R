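# Synthetic LSM-like phantoms with ground truth. The generator emulates a
# NeuN channel: bright ellipsoidal nuclei on a textured background, rendered
# in physical units on an anisotropic grid, blurred by an isotropic Gaussian
# PSF stand-in and corrupted by Gaussian (optionally Poisson) noise. A stated
# fraction of nuclei is placed as near-contact pairs (center distance = 0.9 x
# the sum of their radii) so watershed tests have known merge topology.

#' Phantom specification
#'
#' Defaults describe the package's reference phantom: ~0.005 mm^3 at
#' 30,000 nuclei/mm^3 (about 150 nuclei) on a (4, 1.8, 1.8) um grid -- the
#' voxelization at which a 100 um counting cube spans 25 x 56 x 56 voxels.
#' Nucleus radii are ~4.5 um (9 um diameter NeuN-like somata).
#'
#' @param extent grid extents `(nz, ny, nx)` voxels.
#' @param spacing voxel size `(dz, dy, dx)` um.
#' @param target_density expected nuclei per mm^3 (> 0).
#' @param radius_mean_um,radius_sd_um base nucleus radius distribution (um);
#'   per-axis semi-axes get +/-15% jitter around the base radius.
#' @param fg_mean,fg_sd per-nucleus foreground intensity distribution.
#' @param bg_mean,bg_sd background level and amplitude of the smoothed
#'   background texture (low-amplitude so that a global threshold is not
#'   sufficient for segmentation).
#' @param blur_sigma_um isotropic PSF stand-in (um).
#' @param noise_sd additive Gaussian read-noise SD.
#' @param poisson logical; also apply Poisson resampling of intensities.
#' @param touching_fraction fraction of nuclei placed as near-contact pairs,
#'   in `[0, 1]`.
#' @param seed integer seed; identical spec + seed gives bit-identical output.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent = c(31L, 112L, 112L),
                         spacing = c(4, 1.8, 1.8),
                         target_density = 30000,
                         radius_mean_um = 4.5, radius_sd_um = 0.5,
                         fg_mean = 180, fg_sd = 20,
                         bg_mean = 30, bg_sd = 10,
                         blur_sigma_um = 1.5,
                         noise_sd = 8, poisson = FALSE,
                         touching_fraction = 0.15,
                         seed = 1L) {
  if (target_density <= 0) stopf("target_density must be > 0")
  if (radius_mean_um <= 0 || radius_sd_um < 0) stopf("radii must be positive")
  if (touching_fraction < 0 || touching_fraction > 1)
    stopf("touching_fraction must be in [0, 1]")
  structure(list(extent = as.integer(extent), spacing = check_spacing(spacing),
                 target_density = target_density,
                 radius_mean_um = radius_mean_um, radius_sd_um = radius_sd_um,
                 fg_mean = fg_mean, fg_sd = fg_sd,
                 bg_mean = bg_mean, bg_sd = bg_sd,
                 blur_sigma_um = blur_sigma_um,
                 noise_sd = noise_sd, poisson = isTRUE(poisson),
                 touching_fraction = touching_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

draw_radius <- function(spec, n) pmax(1, rnorm(n, spec$radius_mean_um, spec$radius_sd_um))

# Place nuclei (centers in um, per-axis semi-axes) inside the physical box
# [lo, hi), avoiding accidental contact with already-placed nuclei and
# realizing `touching_fraction` as explicit near-contact pairs.
place_nuclei <- function(spec, lo, hi, lambda, centers = NULL, radii = NULL) {
  n_new <- rpois(1, lambda)
  centers <- centers %||% matrix(numeric(0), 0, 3)
  radii <- radii %||% numeric(0)
  if (n_new == 0L)
    return(list(centers = centers, radii = radii, n_new = 0L))
  n_paired <- 2L * (round(spec$touching_fraction * n_new) %/% 2L)
  n_single <- n_new - n_paired

  sep_ok <- function(ctr, r) {
    if (!nrow(centers)) return(TRUE)
    d <- sqrt(colSums((t(centers) - ctr)^2))
    all(d > 1.02 * (radii + r))
  }
  draw_center <- function() lo + runif(3) * (hi - lo)
  add <- function(ctr, r) {
    centers <<- rbind(centers, ctr)
    radii <<- c(radii, r)
  }

  for (i in seq_len(n_single)) {
    r <- draw_radius(spec, 1)
    placed <- FALSE
    for (try in 1:1000) {
      ctr <- draw_center()
      if (sep_ok(ctr, r)) { add(ctr, r); placed <- TRUE; break }
    }
    if (!placed)
      stopf("could not place nucleus without contact after 1000 tries; density too high for touching_fraction = %g",
            spec$touching_fraction)
  }
  for (i in seq_len(n_paired %/% 2L)) {
    r1 <- draw_radius(spec, 1); r2 <- draw_radius(spec, 1)
    placed <- FALSE
    for (try in 1:1000) {
      c1 <- draw_center()
      if (!sep_ok(c1, r1)) next
      # partner at 0.9 x (r1 + r2) in a uniform random direction
      ok <- FALSE
      for (dtry in 1:50) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        c2 <- c1 + 0.9 * (r1 + r2) * u
        if (all(c2 >= lo) && all(c2 < hi) && sep_ok(c2, r2)) { ok <- TRUE; break }
      }
      if (ok) { add(c1, r1); add(c2, r2); placed <- TRUE; break }
    }
    if (!placed) stopf("could not place touching pair after 1000 tries")
  }
  list(centers = centers, radii = radii, n_new = n_new)
}

# Rasterize ellipsoids: instance grid by nearest-normalized-distance, plus the
# noiseless intensity image.
render_nuclei <- function(spec, centers, radii) {
  d <- spec$extent
  sp <- spec$spacing
  n <- prod(d)
  inst <- array(0L, d)
  qmin <- array(Inf, d)
  intens <- array(0, d)
  K <- nrow(centers)
  axes <- matrix(0, K, 3)
  fg <- rnorm(K, spec$fg_mean, spec$fg_sd)
  for (k in seq_len(K)) {
    ax <- radii[k] * runif(3, 0.85, 1.15)
    axes[k, ] <- ax
    ctr <- centers[k, ]
    rng <- lapply(1:3, function(a) {
      i0 <- max(0L, ceiling((ctr[a] - ax[a]) / sp[a]))
      i1 <- min(d[a] - 1L, floor((ctr[a] + ax[a]) / sp[a]))
      if (i0 > i1) integer(0) else i0:i1
    })
    if (!all(lengths(rng) > 0L)) next
    qz <- ((rng[[1]] * sp[1] - ctr[1]) / ax[1])^2
    qy <- ((rng[[2]] * sp[2] - ctr[2]) / ax[2])^2
    qx <- ((rng[[3]] * sp[3] - ctr[3]) / ax[3])^2
    q <- outer(outer(qz, qy, `+`), qx, `+`)
    sel <- q <= 1
    if (!any(sel)) next
    sub <- as.matrix(expand.grid(z = rng[[1]] + 1L, y = rng[[2]] + 1L,
                                 x = rng[[3]] + 1L))
    lin <- sub[, 1] + d[1] * (sub[, 2] - 1L) + d[1] * d[2] * (sub[, 3] - 1L)
    cond <- as.vector(sel) & as.vector(q) < qmin[lin]
    win <- lin[cond]
    qwin <- as.vector(q)[cond]
    inst[win] <- k
    qmin[win] <- qwin
    intens[win] <- fg[k]
  }
  list(instances = inst, intensity = intens)
}

#' Generate an LSM-like phantom with ground truth
#'
#' Draws the nucleus count as Poisson(target_density x physical volume),
#' places centers uniformly (with `touching_fraction` realized as explicit
#' near-contact pairs and accidental contacts between the remaining nuclei
#' rejected), rasterizes ellipsoids in physical units, blurs, and adds noise.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [volume_image()]) and `truth`
#'   (class `ground_truth`: `instances` ([instance_labels()] grid of the
#'   noiseless geometry), `centroids` (n x 3 um), `radii_um`, `volumes_um3`,
#'   `count`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$extent
  sp <- spec$spacing
  vol_mm3 <- prod(d * sp) / UM3_PER_MM3
  lambda <- spec$target_density * vol_mm3
  if (lambda < 1)
    stopf("expected nucleus count %.2f < 1; enlarge the extent or raise target_density",
          lambda)
  with_seed(spec$seed, {
    pl <- place_nuclei(spec, lo = c(0, 0, 0), hi = d * sp, lambda = lambda)
    rn <- render_nuclei(spec, pl$centers, pl$radii)
    finish_phantom(spec, rn, pl$centers, pl$radii)
  })
}

finish_phantom <- function(spec, rn, centers, radii) {
  d <- spec$extent
  sp <- spec$spacing
  n <- prod(d)
  tex <- array(rnorm(n), d)
  tex <- gaussian_smooth(tex, 8, sp)
  tex <- tex / max(sd(tex), 1e-12) * spec$bg_sd
  img <- spec$bg_mean + tex
  fgm <- rn$instances > 0L
  img[fgm] <- rn$intensity[fgm]
  img <- gaussian_smooth(img, spec$blur_sigma_um, sp)
  if (spec$poisson) img <- rpois(n, pmax(img, 0))
  img <- img + rnorm(n, 0, spec$noise_sd)
  dim(img) <- d

  # keep only nuclei that rasterized to >= 1 voxel; relabel in placement order
  K <- nrow(centers)
  counts <- tabulate(rn$instances[rn$instances > 0L], nbins = K)
  keep <- which(counts > 0L)
  map <- integer(K)
  map[keep] <- seq_along(keep)
  inst <- rn$instances
  pos <- inst > 0L
  inst[pos] <- map[inst[pos]]
  truth <- structure(list(
    instances = instance_labels(inst, sp),
    centroids = `colnames<-`(centers[keep, , drop = FALSE], c("z", "y", "x")),
    radii_um = radii[keep],
    volumes_um3 = counts[keep] * voxel_volume_um3(sp),
    count = length(keep)
  ), class = "ground_truth")
  list(volume = volume_image(img, sp), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d nuclei, mean radius %.2f um, mean volume %.0f um^3\n",
              x$count, mean(x$radii_um), mean(x$volumes_um3)))
  invisible(x)
}

#' Generate a phantom partitioned into labeled regions
#'
#' The grid is split into `n_regions` rectangular regions (slabs along x)
#' surrounded by a zero-label margin; nuclei are placed only inside regions,
#' with per-region densities `target_density * density_factors`.
#'
#' @param n_regions number of regions (>= 1).
#' @param spec a [phantom_spec()].
#' @param density_factors numeric, one multiplier per region.
#' @param margin_um width of the empty label-0 margin.
#' @return list with `volume`, `labelmap` (a [region_labelmap()]), `truth`,
#'   and `meta` (placement warnings, e.g. regions smaller than a counting
#'   cube).
#' @export
generate_region_phantom <- function(n_regions, spec,
                                    density_factors = rep(1, n_regions),
                                    margin_um = 20) {
  stopifnot(inherits(spec, "phantom_spec"), n_regions >= 1)
  if (length(density_factors) != n_regions)
    stopf("need one density factor per region")
  d <- spec$extent
  sp <- spec$spacing
  m <- pmax(1L, round(margin_um / sp))           # margin in voxels per axis
  if (any(2L * m >= d)) stopf("margin leaves no interior; enlarge the extent")
  inner_x <- d[3] - 2L * m[3]
  if (inner_x < n_regions) stopf("extent too small for %d regions", n_regions)
  # slab r occupies x voxels bx[r] .. bx[r+1]-1 (0-based)
  bx <- m[3] + round(seq(0, inner_x, length.out = n_regions + 1L))

  labels <- array(0L, d)
  meta <- list(warnings = character(0))
  with_seed(spec$seed, {
    centers <- NULL; radii <- NULL
    for (r in seq_len(n_regions)) {
      zr <- c(m[1], d[1] - m[1]); yr <- c(m[2], d[2] - m[2])
      xr <- c(bx[r], bx[r + 1])
      labels[(zr[1] + 1):zr[2], (yr[1] + 1):yr[2], (xr[1] + 1):xr[2]] <- r
      lo <- c(zr[1], yr[1], xr[1]) * sp
      hi <- c(zr[2], yr[2], xr[2]) * sp
      if (any(hi - lo < 100))
        meta$warnings <- c(meta$warnings,
          sprintf("region %d extent (%s um) smaller than a 100 um counting cube",
                  r, paste(round(hi - lo), collapse = " x ")))
      vol_mm3 <- prod(hi - lo) / UM3_PER_MM3
      lam <- spec$target_density * density_factors[r] * vol_mm3
      pl <- place_nuclei(spec, lo, hi, lam, centers, radii)
      centers <- pl$centers; radii <- pl$radii
    }
    rn <- render_nuclei(spec, centers, radii)
    ph <- finish_phantom(spec, rn, centers, radii)
    list(volume = ph$volume,
         labelmap = region_labelmap(labels, spacing = sp),
         truth = ph$truth, meta = meta)
  })
}

as_field_array <- function(field, d) {
  if (is.list(field)) {
    stopifnot(length(field) == 3L)
    fa <- array(0, c(d, 3L))
    for (a in 1:3) fa[, , , a] <- field[[a]]
    field <- fa
  }
  if (!is.array(field) || length(dim(field)) != 4L || dim(field)[4] != 3L ||
      !identical(dim(field)[1:3], as.integer(d)))
    stopf("field must be a (nz, ny, nx, 3) array of um displacements matching the input grid")
  if (any(!is.finite(field))) stopf("displacement field contains non-finite values")
  field
}

#' Resample a grid through a dense displacement field
#'
#' Output voxel `v` takes the value of the input at `v + field(v)` (field in
#' um, converted to voxels by the grid spacing): a zero field is the identity.
#' Intensity mode uses trilinear interpolation; label mode uses
#' nearest-neighbour and therefore never invents IDs.
#'
#' @param x a [volume_image()], [region_labelmap()], [instance_labels()], or a
#'   plain 3D array (then `spacing` is required).
#' @param field `(nz, ny, nx, 3)` array of `(dz, dy, dx)` displacements in um,
#'   or a list of three 3D arrays.
#' @param mode `"intensity"` (trilinear) or `"labels"` (nearest); chosen
#'   automatically from the class of `x` when omitted.
#' @param spacing spacing for plain-array input.
#' @return the deformed object, same class as `x`.
#' @export
apply_deformation <- function(x, field, mode = NULL, spacing = NULL) {
  if (inherits(x, "volume_image")) {
    arr <- x$data; spacing <- x$spacing; mode <- mode %||% "intensity"
  } else if (inherits(x, "region_labelmap")) {
    arr <- x$labels
    spacing <- x$spacing %||% spacing
    mode <- mode %||% "labels"
  } else if (inherits(x, "instance_labels")) {
    arr <- x$labels; spacing <- x$spacing; mode <- mode %||% "labels"
  } else {
    arr <- x
    if (is.null(spacing)) stopf("plain-array input needs `spacing`")
    if (is.null(mode)) stopf("plain-array input needs `mode`")
  }
  mode <- match.arg(mode, c("intensity", "labels"))
  spacing <- check_spacing(spacing)
  d <- dim(arr)
  fa <- as_field_array(field, d)

  idx0 <- seq_len(prod(d)) - 1L
  z <- idx0 %% d[1]
  y <- (idx0 %/% d[1]) %% d[2]
  xv <- idx0 %/% (d[1] * d[2])
  coords <- cbind(z + as.vector(fa[, , , 1]) / spacing[1],
                  y + as.vector(fa[, , , 2]) / spacing[2],
                  xv + as.vector(fa[, , , 3]) / spacing[3])
  v <- interp3d(as.numeric(arr), as.integer(d), coords,
                nearest = (mode == "labels"), fill = 0)
  out <- array(v, d)
  if (inherits(x, "volume_image")) volume_image(out, spacing)
  else if (inherits(x, "region_labelmap"))
    region_labelmap(out, name_table = x$name_table, spacing = spacing)
  else if (inherits(x, "instance_labels")) instance_labels(out, spacing)
  else out
}

#' Dense displacement field for a uniform isotropic scaling about the center
#'
#' With scale factor `s < 1` the imaged content shrinks by `s` per axis, so a
#' region's measured volume scales by `s^3` and a naive density computed in
#' deformed space is inflated by `1/s^3` -- the morphology-distortion regime
#' the deformation experiments emulate.
#'
#' @param dim grid extents `(nz, ny, nx)`.
#' @param spacing voxel size um.
#' @param s scale factor (> 0).
#' @return `(nz, ny, nx, 3)` displacement array in um.
#' @export
scaling_field <- function(dim, spacing, s) {
  stopifnot(s > 0)
  spacing <- check_spacing(spacing)
  ctr <- (dim - 1) / 2 * spacing
  fa <- array(0, c(dim, 3L))
  for (a in 1:3) {
    pos <- (seq_len(dim[a]) - 1) * spacing[a]
    dsp <- (pos - ctr[a]) * (1 / s - 1)
    fa[, , , a] <- switch(a,
      array(rep(dsp, times = dim[2] * dim[3]), dim),
      aperm(array(rep(dsp, times = dim[1] * dim[3]), dim[c(2, 1, 3)]), c(2, 1, 3)),
      aperm(array(rep(dsp, times = dim[1] * dim[2]), dim[c(3, 1, 2)]), c(2, 3, 1)))
  }
  fa
}

#' Derive sparse training annotations from phantom ground truth
#'
#' Emulates the sparse-labeling workflow: point/scribble annotations inside
#' `n_nuclei` distinct ground-truth instances plus a comparable number of
#' background voxels (sampled at least `min_bg_dist_um` away from any
#' nucleus).
#'
#' @param truth a `ground_truth` object.
#' @param n_nuclei number of distinct nuclei to annotate (default 20, the
#'   sparse-training regime the workflow is designed for).
#' @param vox_per_nucleus annotated voxels per nucleus (centroid-nearest voxel
#'   plus random interior voxels).
#' @param n_background background voxels (default `n_nuclei * vox_per_nucleus`).
#' @param min_bg_dist_um minimum distance of background samples from any
#'   nucleus surface.
#' @param seed integer seed.
#' @return a [sparse_annotations()] object.
#' @export
annotations_from_truth <- function(truth, n_nuclei = 20, vox_per_nucleus = 5,
                                   n_background = NULL, min_bg_dist_um = 2,
                                   seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  n_background <- n_background %||% (n_nuclei * vox_per_nucleus)
  inst <- truth$instances
  d <- dim(inst$labels)
  if (truth$count < n_nuclei)
    stopf("phantom has only %d nuclei; cannot annotate %d", truth$count, n_nuclei)
  with_seed(seed, {
    ids <- sort(sample.int(truth$count, n_nuclei))
    rows <- list()
    for (k in ids) {
      lin <- which(inst$labels == k)
      lin0 <- lin - 1L
      zyx <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2], lin0 %/% (d[1] * d[2]))
      pos <- sweep(zyx, 2, inst$spacing, `*`)
      dc <- sqrt(colSums((t(pos) - truth$centroids[k, ])^2))
      take <- order(dc)[1]                         # centroid-nearest voxel
      extra <- setdiff(seq_along(lin), take)
      if (length(extra) && vox_per_nucleus > 1)
        take <- c(take, sample(extra, min(vox_per_nucleus - 1L, length(extra))))
      rows[[length(rows) + 1L]] <-
        data.frame(z = zyx[take, 1], y = zyx[take, 2], x = zyx[take, 3], class = 1L)
    }
    bgdist <- edt3d(as.vector(inst$labels == 0L), as.integer(d), inst$spacing)
    cand <- which(as.vector(inst$labels == 0L) & bgdist >= min_bg_dist_um)
    bg <- sample(cand, min(n_background, length(cand)))
    bg0 <- bg - 1L
    rows[[length(rows) + 1L]] <-
      data.frame(z = bg0 %% d[1], y = (bg0 %/% d[1]) %% d[2],
                 x = bg0 %/% (d[1] * d[2]), class = 0L)
    sparse_annotations(do.call(rbind, rows), dim = d)
  })
}
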