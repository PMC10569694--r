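# counting_stats: volume filter, densities, summaries, CV, percent difference.

mk_count <- function(filtered, volume_mm3 = 1e-3) {
  structure(list(raw_count = filtered, filtered_count = filtered,
                 volumes_um3 = numeric(0), volume_mm3 = volume_mm3,
                 density_per_mm3 = filtered / volume_mm3, window = NULL),
            class = "subvolume_count")
}

test_that("volume-filter contributions follow the partition rule", {
  p <- volume_filter_params(200, 500, 1000)
  expect_identical(volume_filter_contribution(c(50, 600, 700), p), c(0L, 1L, 1L))
  expect_identical(volume_filter_contribution(1950, p), 4L)   # round(3.9)
  expect_identical(volume_filter_contribution(1100, p), 2L)   # floor of 2
  # boundaries are inclusive on both sides of the singleton band
  expect_identical(volume_filter_contribution(c(200, 1000), p), c(1L, 1L))
  expect_error(volume_filter_params(600, 500, 1000), "v_min <= v_ref")
})

test_that("the contribution rule holds on an exhaustive parameter grid", {
  vmins <- c(50, 100, 200)
  vrefs <- c(200, 400, 500)
  vmaxs <- c(500, 800, 1500)
  Vs <- c(1, 49, 50, 150, 199, 200, 201, 499, 500, 501, 799, 800, 801,
          1500, 1501, 2200, 5000)
  for (a in vmins) for (b in vrefs) for (cc in vmaxs) {
    if (!(a <= b && b <= cc)) next
    p <- volume_filter_params(a, b, cc)
    got <- volume_filter_contribution(Vs, p)
    want <- vapply(Vs, function(V) {
      if (V < a) 0L
      else if (V <= cc) 1L
      else max(2L, as.integer(floor(V / b + 0.5)))
    }, integer(1))
    expect_identical(got, want, info = sprintf("params %g/%g/%g", a, b, cc))
  }
})

test_that("density uses the realized subvolume volume", {
  expect_equal(density(mk_count(30, 1e-3)), 30000)
  expect_equal(density(mk_count(0)), 0)
  realized <- (25 * 4) * (56 * 1.8) * (56 * 1.8) / 1e9
  expect_equal(density(mk_count(30, realized)), 30 / realized)
  expect_false(isTRUE(all.equal(density(mk_count(30, realized)), 30000)))
})

test_that("volume_filter_count applies the centroid window rule", {
  sp <- c(2, 2, 2)
  lab <- array(0L, c(20, 20, 20))
  lab[2:4, 2:4, 2:4] <- 1L        # centroid ~ (4, 4, 4) um
  lab[10:12, 10:12, 10:12] <- 2L  # centroid ~ (20, 20, 20) um
  inst <- instance_labels(lab, sp)
  p <- volume_filter_params(10, 216, 500)
  all_in <- volume_filter_count(inst, p)
  expect_identical(all_in$raw_count, 2L)
  expect_identical(all_in$filtered_count, 2L)
  win <- subvolume(origin = c(0, 0, 0), extent = c(8, 8, 8), spacing = sp)
  one <- volume_filter_count(inst, p, window = win)
  expect_identical(one$filtered_count, 1L)
  expect_equal(one$volume_mm3, (16^3) / 1e9)
  # monotonicity: adding an instance never decreases the filtered count
  lab2 <- lab; lab2[16:18, 3:5, 3:5] <- 3L
  inst2 <- instance_labels(lab2, sp)
  expect_gte(volume_filter_count(inst2, p)$filtered_count,
             volume_filter_count(inst, p)$filtered_count)
  # v_max = Inf degeneracy: count = number of instances >= v_min
  pinf <- volume_filter_params(100, 216, Inf)
  expect_identical(volume_filter_count(inst2, pinf)$filtered_count,
                   sum(inst2$volumes_um3 >= 100))
})

test_that("a fused clump that watershed cannot split is rescued by the filter", {
  sp <- c(2, 2, 2)
  # three heavily overlapping spheres -> one connected object ~3x single volume
  ctr <- rbind(c(20, 20, 16), c(20, 20, 24), c(20, 24, 20))
  m <- sphere_mask(c(21, 21, 21) * 2 %/% 1, sp, ctr, c(5.2, 5.2, 5.2))
  cc3 <- connected_components(m, spacing = sp)
  expect_identical(cc3$n, 1L)
  vsingle <- 4 / 3 * pi * 5.2^3
  p <- volume_filter_params(0.25 * vsingle, vsingle, 1.6 * vsingle)
  cnt <- volume_filter_count(cc3, p)
  expect_identical(cnt$filtered_count, 3L)
})

test_that("summaries compute mean, sample SD and total estimates", {
  counts <- lapply(c(10, 20, 30), mk_count)                # 10k/20k/30k per mm3
  s <- summarize_region(counts, region_volume_mm3 = 0.37, specimen_id = "s1",
                        region_id = 3L)
  expect_equal(s$mean_density_per_mm3, 20000)
  expect_equal(s$sd_density_per_mm3, 10000)                # n-1 denominator
  expect_equal(s$estimated_total, round(20000 * 0.37))
  same <- summarize_region(lapply(c(5, 5, 5), mk_count), 1, "s")
  expect_equal(same$sd_density_per_mm3, 0)
  expect_error(summarize_region(list(mk_count(5)), 1), ">= 2 subvolumes")

  # mixed-region counts refuse to summarize
  sp <- c(2, 2, 2)
  w1 <- subvolume(c(0, 0, 0), c(4, 4, 4), sp, region_id = 1L)
  w2 <- subvolume(c(0, 0, 0), c(4, 4, 4), sp, region_id = 2L)
  c1 <- mk_count(3); c1$window <- w1
  c2 <- mk_count(4); c2$window <- w2
  expect_error(summarize_region(list(c1, c2), 1), "multiple regions")
})

test_that("cv follows its definition and guards its preconditions", {
  expect_equal(cv(c(1, 1, 1)), 0)
  expect_equal(cv(c(2, 4)), sqrt(2) / 3)
  expect_error(cv(5), ">= 2")
  expect_error(cv(c(-1, 1)), "zero mean")
})

test_that("percent difference matches its formula", {
  expect_equal(percent_difference(1.07, 1.00), 7)
  expect_equal(percent_difference(3, 3), 0)
  expect_equal(percent_difference(0.5, 1), 50)             # absolute difference
  expect_error(percent_difference(1, 0), "> 0")
})

test_that("densities are invariant under consistent unit rescaling", {
  ph <- small_phantom()
  inst_um <- ph$truth$instances
  params <- auto_filter_params(inst_um$volumes_um3)
  d_um <- volume_filter_count(inst_um, params)$density_per_mm3
  # same grid described in nm: spacing x1000, volumes x1e9
  inst_nm <- instance_labels(inst_um$labels, inst_um$spacing * 1000)
  params_nm <- volume_filter_params(params$v_min * 1e9, params$v_ref * 1e9,
                                    params$v_max * 1e9)
  d_nm <- volume_filter_count(inst_nm, params_nm)$density_per_mm3
  expect_equal(d_nm * 1e9, d_um, tolerance = 1e-9)         # per mm3 -> per m3
})

test_that("oracle-path density estimation is consistent with the generator", {
  # ground-truth instances -> filter -> sampling -> summary, one phantom
  ph <- fixture("nontouch_phantom", function()
    generate_phantom(phantom_spec(extent = c(24L, 80L, 80L),
                                  touching_fraction = 0, seed = 31L)))
  sp <- ph$volume$spacing
  mask <- array(TRUE, dim(ph$volume$data))
  plan <- sample_subvolumes(mask, sp, n = 12, edge_um = 80, seed = 9L)
  params <- auto_filter_params(ph$truth$instances$volumes_um3)
  counts <- lapply(plan$subvolumes, function(svl)
    volume_filter_count(ph$truth$instances, params, window = svl))
  s <- summarize_region(counts, region_volume(mask, sp), "oracle")
  lambda_tot <- 30000 * region_volume(mask, sp)
  expect_lt(abs(s$estimated_total - ph$truth$count), 3 * sqrt(lambda_tot))
})
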