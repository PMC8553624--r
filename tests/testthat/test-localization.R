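tube_scene <- function(seed = 1, shape = c(64L, 64L, 12L),
                       spacing = c(0.5, 0.5, 1)) {
  gen_scene(scene_spec(shape = shape, spacing = spacing, radius_um = 5,
                       sigma = 0), seed = seed)
}

test_that("classify_in_out counts and normalizes correctly", {
  m <- array(FALSE, c(10, 10, 10)); m[4:6, 4:6, 4:6] <- TRUE
  scene <- list(mask = m, spacing = c(1, 1, 1))
  inside_cell <- data.frame(cell_id = 1, x_um = 4, y_um = 4, z_um = 4)
  r1 <- classify_in_out(inside_cell, scene)
  expect_equal(r1$n_inside, 1L)
  expect_equal(r1$n_outside, 0L)
  expect_false(r1$ratio_defined)
  expect_true(is.na(r1$in_out_ratio))
  # 5 inside cells over a 1000 um^3 vessel -> density 0.005
  big <- array(FALSE, c(12, 12, 12)); big[1:10, 1:10, 1:10] <- TRUE
  cells5 <- data.frame(cell_id = 1:5, x_um = 1:5, y_um = 1:5, z_um = 1:5)
  r2 <- classify_in_out(cells5, list(mask = big, spacing = c(1, 1, 1)))
  expect_equal(r2$vessel_volume, 1000)
  expect_equal(r2$inside_density, 0.005)
  expect_error(classify_in_out(cells5,
                               list(mask = big & FALSE,
                                    spacing = c(1, 1, 1))), "empty")
  far <- data.frame(cell_id = "c99", x_um = 500, y_um = 1, z_um = 1)
  expect_error(classify_in_out(far, list(mask = big,
                                         spacing = c(1, 1, 1))), "c99")
})

test_that("classification reproduces generator ground truth exactly", {
  for (seed in 1:5) {
    g <- tube_scene(seed)
    gc <- gen_cells(g$scene, n_cells = 50, inside_fraction = 0.4,
                    seed = seed + 100)
    res <- classify_in_out(gc$cells, g$scene)
    expect_identical(res$inside, gc$truth$inside)
    expect_equal(res$n_inside + res$n_outside, nrow(gc$cells))
  }
})

test_that("classification is order- and translation-invariant", {
  g <- tube_scene(2)
  gc <- gen_cells(g$scene, n_cells = 40, seed = 7)
  res <- classify_in_out(gc$cells, g$scene)
  perm <- sample(nrow(gc$cells))
  res_p <- classify_in_out(gc$cells[perm, ], g$scene)
  expect_equal(res_p$n_inside, res$n_inside)
  # rigid translation by whole voxels applied jointly to cells and scene
  shift_vox <- c(3L, 2L, 0L) # (y, x, z)
  m <- g$scene$mask
  m2 <- array(FALSE, dim(m))
  m2[(1 + shift_vox[1]):dim(m)[1], (1 + shift_vox[2]):dim(m)[2], ] <-
    m[1:(dim(m)[1] - shift_vox[1]), 1:(dim(m)[2] - shift_vox[2]), ]
  cells2 <- gc$cells
  cells2$y_um <- cells2$y_um + shift_vox[1] * g$scene$spacing[1]
  cells2$x_um <- cells2$x_um + shift_vox[2] * g$scene$spacing[2]
  keep <- cells2$y_um < (dim(m)[1] - 1) * g$scene$spacing[1] - 0.5 &
    cells2$x_um < (dim(m)[2] - 1) * g$scene$spacing[2] - 0.5
  res2 <- classify_in_out(cells2[keep, ],
                          list(mask = m2, spacing = g$scene$spacing))
  expect_equal(res2$inside, res$inside[keep])
})

test_that("inside_density scales as one over voxel volume", {
  m <- array(FALSE, c(8, 8, 8)); m[3:6, 3:6, 3:6] <- TRUE
  cells <- data.frame(cell_id = 1:3, x_um = c(3, 4, 5), y_um = c(3, 4, 5),
                      z_um = c(3, 4, 5))
  r1 <- classify_in_out(cells, list(mask = m, spacing = c(1, 1, 1)))
  cells2 <- cells; cells2$z_um <- cells$z_um * 2
  r2 <- classify_in_out(cells2, list(mask = m, spacing = c(1, 1, 2)))
  expect_equal(r2$n_inside, r1$n_inside)
  expect_equal(r2$inside_density, r1$inside_density / 2)
})

test_that("distance_to_vessel looks up exact map values", {
  m <- matrix(FALSE, 1, 20); m[1, 1] <- TRUE
  dmap <- distance_transform(m, c(0.5, 0.5))
  cells <- data.frame(cell_id = 1:2, x_um = c(0, 5), y_um = c(0, 0))
  out <- distance_to_vessel(cells, dmap)
  expect_equal(out$distance_um, c(0, 5)) # 10 voxels at 0.5 um
  # random cells against brute-force nearest-foreground search
  set.seed(21)
  m2 <- random_mask(c(24L, 24L))
  sp <- c(0.5, 1)
  dmap2 <- distance_transform(m2, sp)
  bf <- brute_force_edt(m2, sp)
  cells2 <- data.frame(cell_id = 1:100,
                       x_um = (sample(0:23, 100, TRUE)) * sp[2],
                       y_um = (sample(0:23, 100, TRUE)) * sp[1])
  got <- distance_to_vessel(cells2, dmap2)$distance_um
  idx <- cbind(round(cells2$y_um / sp[1]) + 1, round(cells2$x_um / sp[2]) + 1)
  expect_equal(got, bf[idx])
  # surface-style distance subtracts a mean vessel radius, floored at 0
  surf <- distance_to_vessel(cells, dmap, mean_radius = 2)
  expect_equal(surf$surface_distance_um, c(0, 3))
})

test_that("zone distributions are fractions of a partition", {
  m <- matrix(FALSE, 1, 50); m[1, 1] <- TRUE
  zm <- make_zone_map(distance_transform(m, c(1, 1)), c(0, 10, 20))
  cells <- data.frame(cell_id = 1:4, x_um = c(2, 5, 12, 15), y_um = 0)
  zd <- zone_distribution(cells, zm, c(1, 1))
  expect_equal(zd$count[zd$zone == 1], 2L)
  expect_equal(zd$count[zd$zone == 2], 2L)
  expect_equal(zd$fraction[zd$zone %in% 1:2], c(0.5, 0.5))
  expect_equal(sum(zd$fraction), 1, tolerance = 1e-9)
  none <- zone_distribution(cells[0, ], zm, c(1, 1))
  expect_false(attr(none, "defined"))
  expect_true(all(is.na(none$fraction)))
})

test_that("zone-weighted placement matches the analytic expectation", {
  # densities (4, 2, 1) over bands [0,10), [10,20) and beyond: observed
  # pooled fractions must sit inside binomial 95% bounds of the
  # area-weighted expectation
  edges <- c(0, 10, 20)
  g <- gen_scene(scene_spec(shape = c(96L, 96L), spacing = c(0.5, 0.5),
                            radius_um = 5, sigma = 0), seed = 1)
  dmap <- g$truth$dmap
  zm <- make_zone_map(dmap, edges)
  bg_zones <- zm$labels[!g$truth$mask]
  area <- table(factor(bg_zones, levels = 1:3))
  w <- c(4, 2, 1)
  expected <- as.numeric(area) * w / sum(as.numeric(area) * w)
  counts <- numeric(3)
  n_per <- 100L
  for (seed in 1:20) {
    gc <- gen_cells(g$scene, n_cells = n_per, inside_fraction = 0,
                    zone_density = w, zone_edges = edges, seed = seed)
    counts <- counts + tabulate(gc$truth$zone, nbins = 3)
  }
  n_tot <- 20L * n_per
  obs <- counts / n_tot
  se <- sqrt(expected * (1 - expected) / n_tot)
  expect_true(all(abs(obs - expected) <= 1.96 * se + 1e-3))
})

test_that("golgi_ratio splits by quantile and recovers enrichment", {
  set.seed(31)
  mask <- matrix(runif(40 * 40) < 0.5, 40, 40)
  golph <- matrix(runif(40 * 40), 40, 40)
  # uniform chemokine -> ratio 1
  r <- golgi_ratio(matrix(7, 40, 40), mask, golph)
  expect_equal(r$ratio, 1)
  # perfect colocalization -> high exceeds low
  r2 <- golgi_ratio(golph, mask, golph)
  expect_gt(r2$mfi_high, r2$mfi_low)
  expect_gt(r2$ratio, 1)
  # 3x enrichment in golgi-high pixels recovered within 10%
  thr <- quantile(golph[mask], 0.75)
  ccl <- matrix(10, 40, 40)
  ccl[golph > thr] <- 30
  noisy <- ccl + matrix(rnorm(1600, 0, 1), 40, 40)
  r3 <- golgi_ratio(noisy, mask, golph)
  expect_lt(abs(r3$ratio - 3) / 3, 0.1)
  # empty region flagged undefined
  flat <- matrix(1, 40, 40)
  r4 <- golgi_ratio(ccl, mask, flat) # no pixel exceeds the quantile
  expect_false(r4$ratio_defined)
  expect_error(golgi_ratio(ccl, mask & FALSE, golph), "empty")
  expect_error(golgi_ratio(ccl, mask[1:10, ], golph), "share")
})
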