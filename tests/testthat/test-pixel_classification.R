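# pixel_classification: multi-scale features, sparse-label training,
# probability prediction.

test_that("derivative features vanish on constant volumes", {
  v <- volume_image(array(7.5, c(12, 16, 16)), c(4, 1.8, 1.8))
  fs <- suppressWarnings(compute_features(v, scales_um = c(3.2, 6.4)))
  nm <- colnames(fs$X)
  for (f in nm[grepl("gradmag|log|dog|hess", nm)])
    expect_equal(unname(range(fs$X[, f])), c(0, 0), tolerance = 1e-10)
  for (f in nm[grepl("gauss|raw", nm)])
    expect_equal(unname(range(fs$X[, f])), c(7.5, 7.5), tolerance = 1e-10)
})

test_that("Gaussian response at an impulse decays with scale; blobs give negative Hessian", {
  arr <- array(0, c(21, 21, 21)); arr[11, 11, 11] <- 100
  v <- volume_image(arr, c(2, 2, 2))
  fs <- compute_features(v, scales_um = c(2, 4, 8))
  center <- 11 + 21 * 10 + 21 * 21 * 10
  g <- fs$X[center, c("gauss_2", "gauss_4", "gauss_8")]
  expect_true(all(diff(g) < 0))

  # rendered sphere: all Hessian eigenvalues negative at the center
  m <- sphere_mask(c(21, 21, 21), c(2, 2, 2), matrix(c(20, 20, 20), 1), 8)
  vs <- volume_image(array(100 * m, dim(m)), c(2, 2, 2))
  fss <- compute_features(vs, scales_um = c(4, 8))
  expect_lt(fss$X[center, "hess1_8"], 0)
  expect_lt(fss$X[center, "hess3_8"], 0)
})

test_that("features respect anisotropy: coarse-z sampling of a smooth field matches isotropic", {
  # a smooth analytic blob sampled at (4,2,2) and at (2,2,2); the gaussian
  # feature at shared physical positions must agree up to discretization
  blob <- function(dim, sp) {
    ctr <- (dim - 1) / 2 * sp
    z <- (seq_len(dim[1]) - 1) * sp[1]
    y <- (seq_len(dim[2]) - 1) * sp[2]
    x <- (seq_len(dim[3]) - 1) * sp[3]
    qz <- exp(-((z - ctr[1]) / 18)^2)
    qy <- exp(-((y - ctr[2]) / 18)^2)
    qx <- exp(-((x - ctr[3]) / 18)^2)
    array(100 * outer(outer(qz, qy), qx), dim)
  }
  va <- volume_image(blob(c(21, 41, 41), c(4, 2, 2)), c(4, 2, 2))
  vi <- volume_image(blob(c(41, 41, 41), c(2, 2, 2)), c(2, 2, 2))
  ga <- gaussian_smooth(va$data, 6.4, va$spacing)
  gi <- gaussian_smooth(vi$data, 6.4, vi$spacing)
  shared <- gi[seq(1, 41, by = 2), , ]      # iso z-planes at the aniso positions
  expect_equal(max(abs(ga - shared)) / max(ga), 0, tolerance = 0.02)
})

test_that("training records annotation counts and refuses single-class input", {
  ph <- small_phantom()
  ann <- annotations_from_truth(ph$truth, n_nuclei = 15, vox_per_nucleus = 2,
                                n_background = 40, seed = 2L)
  expect_identical(ann$n_neuron, 30L)
  expect_identical(ann$n_background, 40L)
  fs <- small_features()
  m <- train_classifier(fs, ann, n_trees = 20, seed = 1L)
  expect_identical(m$metadata$n_neuron, 30L)
  expect_identical(m$metadata$n_background, 40L)

  only_pos <- sparse_annotations(ann$coords[ann$coords$class == 1L, ])
  expect_error(train_classifier(fs, only_pos, seed = 1L), "both classes")
})

test_that("a perfectly separable two-intensity volume is learned exactly", {
  arr <- array(10, c(16, 24, 24))
  arr[6:11, 8:16, 8:16] <- 200
  truth_fg <- arr > 100
  v <- volume_image(arr, c(2, 2, 2))
  fs <- compute_features(v, scales_um = c(2, 4))
  set.seed(3)
  fg <- sample(which(truth_fg & array(TRUE, dim(arr))), 30)
  bg <- sample(which(!truth_fg), 60)
  d <- dim(arr)
  tov <- function(lin) {
    i0 <- lin - 1L
    data.frame(z = i0 %% d[1], y = (i0 %/% d[1]) %% d[2], x = i0 %/% (d[1] * d[2]))
  }
  ann <- sparse_annotations(rbind(cbind(tov(fg), class = 1L),
                                  cbind(tov(bg), class = 0L)), dim = d)
  m <- train_classifier(fs, ann, n_trees = 50, seed = 7L)
  expect_equal(m$metadata$training_accuracy, 1.0)
  pm <- predict(m, fs)
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  tp <- sum(pm$mask & truth_fg); fp <- sum(pm$mask & !truth_fg)
  fn <- sum(!pm$mask & truth_fg)
  f1 <- 2 * tp / (2 * tp + fp + fn)
  expect_gte(f1, 0.95)
})

test_that("prediction is deterministic and respects the threshold contract", {
  fs <- small_features()
  m <- small_model()
  p1 <- predict(m, fs)
  p2 <- predict(m, fs)
  expect_identical(p1$prob, p2$prob)
  expect_identical(p1$mask, p1$prob >= p1$threshold)
  p3 <- predict(m, fs, threshold = 0.8)
  expect_identical(p3$mask, p3$prob >= 0.8)
  expect_true(all(sum(p3$mask) <= sum(p1$mask)))
})

test_that("degenerate scales warn; bad annotation coordinates error", {
  ph <- small_phantom()
  expect_warning(compute_features(ph$volume, scales_um = c(1.6, 3.2, 6.4)),
                 "half the coarsest")
  ann <- sparse_annotations(data.frame(z = 999, y = 0, x = 0, class = 1))
  expect_error(ann_ok <- sparse_annotations(data.frame(z = 999, y = 0, x = 0,
                                                       class = 1),
                                            dim = c(20, 64, 64)), "outside")
})
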