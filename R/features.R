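# Multi-scale voxel features in the ilastik/Labkit family. Scales are given
# in physical units (um) and converted per-axis to voxel sigmas, so features
# respect anisotropic voxels. Per scale sigma: Gaussian-smoothed intensity,
# gradient magnitude, Laplacian of Gaussian, difference of Gaussians
# (sigma, 2 sigma), and the three sorted Hessian eigenvalues; plus the raw
# intensity.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox < 1e-8) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

#' Gaussian smoothing in physical units
#'
#' Separable Gaussian filter with per-axis voxel sigma `sigma_um / spacing`,
#' symmetric boundary.
#'
#' @param arr 3D array `(z, y, x)`.
#' @param sigma_um isotropic physical scale, um.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @return smoothed 3D array.
#' @export
gaussian_smooth <- function(arr, sigma_um, spacing) {
  d <- dim(arr)
  v <- as.numeric(arr)
  for (a in 1:3) {
    k <- gaussian_kernel_1d(sigma_um / spacing[a])
    if (length(k) > 1L) v <- conv_axis3d(v, as.integer(d), k, a - 1L)
  }
  array(v, d)
}

# central difference along axis (replicate boundary), physical units
ax_shift <- function(arr, axis, by) {
  d <- dim(arr)
  n <- d[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}
ax_d1 <- function(arr, axis, h) (ax_shift(arr, axis, 1L) - ax_shift(arr, axis, -1L)) / (2 * h)
ax_d2 <- function(arr, axis, h) {
  (ax_shift(arr, axis, 1L) - 2 * arr + ax_shift(arr, axis, -1L)) / h^2
}

#' Compute the multi-scale feature stack for a volume
#'
#' @param volume a [volume_image()].
#' @param scales_um positive physical scales (um); default `c(1.6, 3.2, 6.4)`.
#' @return object of class `feature_stack`: matrix `X` (one row per voxel in
#'   array order, one column per feature), `feature_names`, `scales_um`,
#'   `spacing`, `dim`.
#' @export
compute_features <- function(volume, scales_um = c(1.6, 3.2, 6.4)) {
  stopifnot(inherits(volume, "volume_image"))
  if (any(scales_um <= 0)) stopf("scales must be positive")
  sp <- volume$spacing
  if (any(scales_um < max(sp) / 2))
    warnf("scale(s) %s um are below half the coarsest voxel dimension (%g um); the feature is degenerate on that axis",
          paste(scales_um[scales_um < max(sp) / 2], collapse = ", "), max(sp))
  arr <- volume$data
  d <- dim(arr)
  n <- prod(d)

  smooth_cache <- new.env(parent = emptyenv())
  get_smooth <- function(sigma) {
    key <- sprintf("%.9g", sigma)
    if (is.null(smooth_cache[[key]]))
      smooth_cache[[key]] <- gaussian_smooth(arr, sigma, sp)
    smooth_cache[[key]]
  }

  feats <- list(raw = as.numeric(arr))
  for (s in scales_um) {
    g <- get_smooth(s)
    d1 <- lapply(1:3, function(a) ax_d1(g, a, sp[a]))
    feats[[sprintf("gauss_%g", s)]] <- as.numeric(g)
    feats[[sprintf("gradmag_%g", s)]] <-
      sqrt(as.numeric(d1[[1]])^2 + as.numeric(d1[[2]])^2 + as.numeric(d1[[3]])^2)
    hzz <- ax_d2(g, 1, sp[1]); hyy <- ax_d2(g, 2, sp[2]); hxx <- ax_d2(g, 3, sp[3])
    hzy <- ax_d1(d1[[1]], 2, sp[2])
    hzx <- ax_d1(d1[[1]], 3, sp[3])
    hyx <- ax_d1(d1[[2]], 3, sp[3])
    feats[[sprintf("log_%g", s)]] <- as.numeric(hzz) + as.numeric(hyy) + as.numeric(hxx)
    feats[[sprintf("dog_%g", s)]] <- as.numeric(g) - as.numeric(get_smooth(2 * s))
    ev <- sym3_eigenvalues(as.numeric(hzz), as.numeric(hyy), as.numeric(hxx),
                           as.numeric(hzy), as.numeric(hzx), as.numeric(hyx))
    feats[[sprintf("hess1_%g", s)]] <- ev[, 1]
    feats[[sprintf("hess2_%g", s)]] <- ev[, 2]
    feats[[sprintf("hess3_%g", s)]] <- ev[, 3]
  }
  X <- do.call(cbind, feats)
  structure(list(X = X, feature_names = colnames(X),
                 scales_um = as.numeric(scales_um), spacing = sp, dim = d),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d voxels x %d features, scales %s um\n",
              nrow(x$X), ncol(x$X), paste(x$scales_um, collapse = ", ")))
  invisible(x)
}

feature_fingerprint <- function(features) {
  list(feature_names = as.character(features$feature_names),
       scales_um = as.numeric(features$scales_um),
       spacing = as.numeric(features$spacing))
}

fingerprints_match <- function(a, b) {
  identical(a$feature_names, b$feature_names) &&
    isTRUE(all.equal(a$scales_um, b$scales_um, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-9))
}
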