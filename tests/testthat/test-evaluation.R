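# evaluation: instance matching and detection scores.

test_that("identical predictions score perfectly; empty ones score all-FN", {
  ph <- small_phantom()
  tr <- ph$truth
  m <- match_instances(tr$instances, tr)
  expect_identical(m$TP, tr$count)
  expect_identical(m$FP, 0L)
  expect_identical(m$FN, 0L)
  expect_equal(unname(f1_score(m)), c(1, 1, 1))

  empty <- instance_labels(array(0L, dim(tr$instances$labels)),
                           tr$instances$spacing)
  m0 <- match_instances(empty, tr)
  expect_identical(m0$TP, 0L)
  expect_identical(m0$FN, tr$count)

  shaped <- instance_labels(array(0L, c(2, 2, 2)), tr$instances$spacing)
  expect_error(match_instances(shaped, tr), "grids differ")
})

test_that("greedy centroid matching equals optimal assignment on separated scenes", {
  set.seed(77)
  sp <- c(2, 2, 2)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    # well-separated truth points, jittered predictions, some FP/FN
    tc <- matrix(runif(3 * n, 10, 70), n, 3)
    while (min(dist(tc)) < 16) tc <- matrix(runif(3 * n, 10, 70), n, 3)
    keep <- runif(n) < 0.8
    pc <- tc[keep, , drop = FALSE] + matrix(runif(3 * sum(keep), -2, 2),
                                            ncol = 3)
    if (runif(1) < 0.5) pc <- rbind(pc, runif(3, 10, 70))
    lab_t <- array(0L, c(40, 40, 40)); lab_p <- array(0L, c(40, 40, 40))
    vox <- function(p) pmin(pmax(round(p / 2), 0), 39) + 1
    for (i in seq_len(nrow(tc))) lab_t[matrix(vox(tc[i, ]), 1)] <- i
    for (i in seq_len(nrow(pc))) lab_p[matrix(vox(pc[i, ]), 1)] <- i
    pred <- instance_labels(lab_p, sp)
    truth <- instance_labels(lab_t, sp)
    m <- match_instances(pred, truth, criterion = "centroid", tol = 5)
    opt <- optimal_match_count(instance_centroids(pred),
                               instance_centroids(truth), tol = 5)
    expect_identical(m$TP, opt, info = sprintf("scene %d", rep))
  }
})

test_that("overlap matching uses one-to-one IoU", {
  sp <- c(1, 1, 1)
  t_lab <- array(0L, c(10, 10, 10)); t_lab[2:5, 2:5, 2:5] <- 1L
  p_lab <- array(0L, c(10, 10, 10)); p_lab[3:6, 2:5, 2:5] <- 1L # IoU 3/5... per z overlap
  pred <- instance_labels(p_lab, sp)
  truth <- instance_labels(t_lab, sp)
  m <- match_instances(pred, truth, criterion = "overlap", tol = 0.3)
  expect_identical(m$TP, 1L)
  m2 <- match_instances(pred, truth, criterion = "overlap", tol = 0.9)
  expect_identical(m2$TP, 0L)
})

test_that("f1 matches the harmonic-mean formula on random confusion triples", {
  expect_equal(unname(f1_score(list(TP = 18L, FP = 2L, FN = 2L))),
               c(0.9, 0.9, 0.9))
  expect_equal(f1_score(list(TP = 5L, FP = 0L, FN = 0L))[["f1"]], 1)
  expect_warning(z <- f1_score(list(TP = 0L, FP = 0L, FN = 0L)), "0")
  expect_equal(unname(z), c(0, 0, 0))
  set.seed(12)
  for (i in 1:50) {
    tp <- sample(0:30, 1); fp <- sample(0:10, 1); fn <- sample(0:10, 1)
    if (tp + fp + fn == 0) next
    got <- f1_score(list(TP = tp, FP = fp, FN = fn))
    P <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
    R <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
    expect_equal(got[["precision"]], P)
    expect_equal(got[["recall"]], R)
    expect_equal(got[["f1"]], ifelse(P + R > 0, 2 * P * R / (P + R), 0))
  }
})

test_that("scores are invariant to instance relabeling; fixing an FP helps", {
  ph <- small_phantom()
  inst <- ph$truth$instances
  set.seed(21)
  perm <- sample(inst$n)
  lab <- inst$labels
  lab[lab > 0L] <- perm[lab[lab > 0L]]
  m1 <- match_instances(inst, ph$truth)
  m2 <- match_instances(instance_labels(lab, inst$spacing), ph$truth)
  expect_identical(f1_score(m1), f1_score(m2))

  f_before <- f1_score(list(TP = 10L, FP = 5L, FN = 3L))[["f1"]]
  f_after <- f1_score(list(TP = 11L, FP = 4L, FN = 3L))[["f1"]]
  expect_gt(f_after, f_before)
})
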