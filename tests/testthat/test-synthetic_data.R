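# synthetic_data: phantom generator, ground truth consistency, deformation.

test_that("nucleus count is Poisson(target_density x volume) across seeds", {
  # coarser lateral spacing keeps 50 phantoms cheap at the same lambda ~ 300
  spec0 <- phantom_spec(extent = c(28L, 100L, 100L), spacing = c(4, 3, 3),
                        target_density = 30000, touching_fraction = 0)
  lambda <- spec0$target_density * prod(spec0$extent * spec0$spacing) / 1e9
  expect_gt(lambda, 290); expect_lt(lambda, 320)
  counts <- vapply(1:50, function(s) {
    sp <- phantom_spec(extent = spec0$extent, spacing = spec0$spacing,
                       target_density = 30000, touching_fraction = 0, seed = s)
    generate_phantom(sp)$truth$count
  }, numeric(1))
  se <- sqrt(lambda / 50)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # and the variance is Poisson-like, not degenerate
  expect_gt(var(counts), lambda / 4)
})

test_that("ground truth is internally consistent", {
  ph <- small_phantom()
  tr <- ph$truth
  expect_identical(tr$count, tr$instances$n)
  expect_identical(tr$count, nrow(tr$centroids))
  expect_identical(tr$count, length(tr$radii_um))
  expect_identical(sort(unique(as.integer(tr$instances$labels[tr$instances$labels > 0]))),
                   seq_len(tr$count))
  expect_equal(tr$volumes_um3, tr$instances$volumes_um3)
  # centroids inside the physical volume
  ext <- dim(ph$volume$data) * ph$volume$spacing
  expect_true(all(tr$centroids >= 0 & tr$centroids <= rep(ext, each = tr$count)))
})

test_that("touching_fraction = 0 phantoms have no touching nuclei", {
  ph <- fixture("nontouch_phantom", function()
    generate_phantom(phantom_spec(extent = c(24L, 80L, 80L),
                                  touching_fraction = 0, seed = 31L)))
  tr <- ph$truth
  cen <- tr$centroids
  d <- as.matrix(dist(cen))
  rsum <- outer(tr$radii_um, tr$radii_um, `+`)
  diag(d) <- Inf
  expect_true(all(d > rsum))
})

test_that("same seed gives bit-identical phantoms; RNG state is untouched", {
  spec <- phantom_spec(extent = c(12L, 40L, 40L), seed = 5L)
  set.seed(999); before <- runif(3)
  set.seed(999)
  a <- generate_phantom(spec)
  after <- runif(3)
  b <- generate_phantom(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$instances$labels, b$truth$instances$labels)
  expect_identical(a$truth$centroids, b$truth$centroids)
  expect_identical(before, after) # with_seed restored the caller's stream
})

test_that("too-small volumes are rejected with advice", {
  expect_error(generate_phantom(phantom_spec(extent = c(3L, 4L, 4L),
                                             target_density = 100)),
               "enlarge")
})

test_that("rendered nucleus volumes approach the analytic ellipsoid volume", {
  # fine isotropic sampling so discretization error is small
  spec <- phantom_spec(extent = c(60L, 60L, 60L), spacing = c(1, 1, 1),
                       target_density = 30000, touching_fraction = 0, seed = 8L)
  ph <- generate_phantom(spec)
  # semi-axes jitter is +/-15% around the base radius, so compare to the
  # sphere volume of the base radius with a generous band
  expected <- 4 / 3 * pi * ph$truth$radii_um^3
  interior <- ph$truth$centroids[, 1] > 8 & ph$truth$centroids[, 1] < 52 &
    ph$truth$centroids[, 2] > 8 & ph$truth$centroids[, 2] < 52 &
    ph$truth$centroids[, 3] > 8 & ph$truth$centroids[, 3] < 52
  rel <- ph$truth$volumes_um3[interior] / expected[interior]
  expect_gt(length(rel), 3)
  expect_true(all(rel > 0.6 & rel < 1.6))   # per-nucleus (jittered axes)
  expect_lt(abs(mean(rel) - 1), 0.12)       # unbiased on average
})

test_that("region phantoms honor per-region densities, margins and IDs", {
  spec <- phantom_spec(extent = c(28L, 96L, 96L), seed = 13L)
  one <- generate_region_phantom(1, spec)
  expect_identical(sort(unique(as.integer(one$labelmap$labels))), c(0L, 1L))

  two <- fixture("two_region_phantom", function()
    generate_region_phantom(2, phantom_spec(extent = c(36L, 140L, 140L), seed = 41L),
                            density_factors = c(1, 2)))
  lm <- two$labelmap$labels
  # margin voxels all carry 0
  expect_true(all(lm[1, , ] == 0L) && all(lm[, 1, ] == 0L) && all(lm[, , 1] == 0L))
  expect_true(all(lm[dim(lm)[1], , ] == 0L))
  # per-region truth counts ~ 1 : 2 within Poisson error
  cen_vox <- floor(sweep(two$truth$centroids, 2, two$volume$spacing, `/`)) + 1L
  reg <- lm[cen_vox]
  n1 <- sum(reg == 1L); n2 <- sum(reg == 2L)
  expect_lt(abs(n2 - 2 * n1) / sqrt(n2 + 4 * n1), 3.5)

  w <- generate_region_phantom(3, phantom_spec(extent = c(20L, 60L, 60L), seed = 3L))
  expect_gt(length(w$meta$warnings), 0) # slabs thinner than a counting cube
})

test_that("zero displacement field is the identity in both modes", {
  ph <- small_phantom()
  d <- dim(ph$volume$data)
  zero <- array(0, c(d, 3))
  expect_equal(apply_deformation(ph$volume, zero)$data, ph$volume$data)
  expect_identical(apply_deformation(ph$truth$instances, zero)$labels,
                   ph$truth$instances$labels)
  bad <- zero; bad[1] <- NaN
  expect_error(apply_deformation(ph$volume, bad), "finite")
})

test_that("a uniform shrink scales measured volumes by s^3 and labels stay a subset", {
  two <- fixture("two_region_phantom", function()
    generate_region_phantom(2, phantom_spec(extent = c(36L, 140L, 140L), seed = 41L),
                            density_factors = c(1, 2)))
  s <- 0.85
  fld <- scaling_field(dim(two$volume$data), two$volume$spacing, s)
  dlm <- apply_deformation(two$labelmap, fld, spacing = two$volume$spacing)
  expect_true(all(unique(as.integer(dlm$labels)) %in%
                  c(0L, unique(as.integer(two$labelmap$labels)))))
  for (rid in 1:2) {
    v0 <- region_volume(region_mask(two$labelmap, rid), two$volume$spacing)
    v1 <- region_volume(region_mask(dlm, rid), two$volume$spacing)
    expect_lt(abs(v1 / v0 - s^3), 0.05) # one-voxel discretization shell
  }
})
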