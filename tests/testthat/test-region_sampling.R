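# region_sampling: masks, volumes, and the random counting-cube placement.

test_that("region_mask agrees with a brute-force voxel scan", {
  set.seed(42)
  lab <- array(sample(c(0L, 3L, 7L, 12L), 4 * 5 * 6, replace = TRUE), c(4, 5, 6))
  lm <- region_labelmap(lab)
  m <- region_mask(lm, 7L)
  brute <- array(FALSE, dim(lab))
  for (z in 1:4) for (y in 1:5) for (x in 1:6)
    brute[z, y, x] <- lab[z, y, x] == 7L
  expect_identical(m, brute)
  expect_identical(sum(m), sum(lab == 7L))
  expect_error(region_mask(lm, 999L), "available IDs")
})

test_that("region_volume is voxel count x voxel volume with correct units", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  expect_equal(region_volume(m, c(4, 1.8, 1.8)), 1000 * 12.96 / 1e9)
  m2 <- array(c(TRUE, FALSE), c(6, 6, 6))
  v1 <- region_volume(m2, c(1, 2, 3))
  expect_equal(region_volume(m2, 2 * c(1, 2, 3)), 8 * v1)
  # analytic volume of a rectangular phantom region
  lab <- array(0L, c(20, 20, 20)); lab[3:12, 5:14, 2:16] <- 1L
  expect_equal(region_volume(region_mask(region_labelmap(lab), 1L), c(4, 1.8, 1.8)),
               10 * 10 * 15 * 12.96 / 1e9)
  expect_error(region_volume(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("cube extents realize the documented voxelization", {
  m <- array(TRUE, c(30, 70, 70))
  plan <- sample_subvolumes(m, c(4, 1.8, 1.8), n = 2, edge_um = 100, seed = 1L)
  expect_identical(plan$extent, c(25L, 56L, 56L))       # 100 um at (4,1.8,1.8)
  sv <- plan$subvolumes[[1]]
  expect_equal(sv$edges_um, c(100, 100.8, 100.8))
  expect_equal(sv$volume_mm3, 100 * 100.8 * 100.8 / 1e9) # realized, not nominal
})

test_that("strict inclusion accepts only fully in-region cubes (exhaustive check)", {
  lab <- array(0L, c(40, 80, 80))
  lab[6:38, 11:75, 11:75] <- 5L                         # ~ 500 um cuboid region
  lm <- region_labelmap(lab)
  m <- region_mask(lm, 5L)
  plan <- sample_subvolumes(m, c(4, 1.8, 1.8), n = 15, edge_um = 100,
                            inclusion_threshold = 1.0, seed = 3L, region_id = 5L)
  expect_length(plan$subvolumes, 15L)
  for (sv in plan$subvolumes) {
    cube <- lab[(sv$origin[1] + 1):(sv$origin[1] + sv$extent[1]),
                (sv$origin[2] + 1):(sv$origin[2] + sv$extent[2]),
                (sv$origin[3] + 1):(sv$origin[3] + sv$extent[3])]
    expect_true(all(cube == 5L))                        # zero foreign voxels
  }
})

test_that("impossible geometries error with the acceptance rate", {
  thin <- array(FALSE, c(40, 80, 80)); thin[10:20, , ] <- TRUE # 44 um slab < cube
  expect_error(
    sample_subvolumes(thin, c(4, 1.8, 1.8), n = 5, edge_um = 100,
                      inclusion_threshold = 1.0, seed = 1L, max_tries = 2000),
    "acceptance rate")
  tiny <- array(TRUE, c(10, 10, 10))
  expect_error(sample_subvolumes(tiny, c(4, 1.8, 1.8), n = 1, edge_um = 100),
               "does not fit")
})

test_that("plans are deterministic in the seed and serialize losslessly", {
  m <- array(TRUE, c(30, 70, 70))
  p1 <- sample_subvolumes(m, c(4, 1.8, 1.8), n = 10, seed = 17L)
  p2 <- sample_subvolumes(m, c(4, 1.8, 1.8), n = 10, seed = 17L)
  expect_identical(p1, p2)
  p3 <- sample_subvolumes(m, c(4, 1.8, 1.8), n = 10, seed = 18L)
  expect_false(identical(lapply(p1$subvolumes, `[[`, "origin"),
                         lapply(p3$subvolumes, `[[`, "origin")))
  tf <- withr::local_tempfile(fileext = ".json")
  write_plan(p1, tf)
  b <- read_plan(tf)
  expect_equal(lapply(b$subvolumes, `[[`, "origin"),
               lapply(p1$subvolumes, `[[`, "origin"))
  expect_equal(b$seed, p1$seed)
  expect_equal(b$rejections, p1$rejections)
})

test_that("accepted origins are spatially uniform and the acceptance rate is analytic", {
  m <- array(FALSE, c(41, 96, 96))
  m[2:41, 5:96, 5:96] <- TRUE                            # rectangular region
  sp <- c(4, 1.8, 1.8)
  plan <- sample_subvolumes(m, sp, n = 2000, edge_um = 72, seed = 23L)
  o <- do.call(rbind, lapply(plan$subvolumes, `[[`, "origin"))
  ext <- plan$extent
  # chi-square uniformity over the 8 octants of the feasible origin box
  feas_lo <- c(1, 4, 4); feas_hi <- dim(m) - ext        # 0-based feasible range
  octant <- 1 +
    (o[, 1] > (feas_lo[1] + feas_hi[1]) / 2) +
    (o[, 2] > (feas_lo[2] + feas_hi[2]) / 2) * 2 +
    (o[, 3] > (feas_lo[3] + feas_hi[3]) / 2) * 4
  counts <- tabulate(octant, nbins = 8)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  # acceptance probability matches the analytic placement ratio
  n_all <- prod(dim(m) - ext + 1L)
  n_ok <- prod(feas_hi - feas_lo + 1L)
  rate_hat <- plan$n_subvolumes / plan$tries
  expect_lt(abs(rate_hat - n_ok / n_all), 3.5 * sqrt(n_ok / n_all / plan$tries) + 0.01)
})
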