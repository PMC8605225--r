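test_that("volume_cc is voxel count times voxel volume", {
  g1 <- grid_spec(c(12, 12, 12), c(1, 1, 1))
  expect_equal(volume_cc(make_box_mask(g1, c(1, 1, 1), c(10, 10, 10))), 1.0)
  expect_equal(volume_cc(structure_mask(array(FALSE, g1$dims), g1)), 0.0)
  g2 <- grid_spec(c(5, 5, 5), c(2, 2, 2))
  expect_equal(volume_cc(make_box_mask(g2, c(1, 1, 1), c(3, 3, 3))), 0.216)
})

test_that("dice handles identity, disjointness, half overlap and errors", {
  g <- grid_spec(c(20, 20, 20), c(1, 1, 1))
  a <- make_box_mask(g, c(3, 3, 3), c(12, 12, 12))
  expect_identical(dice(a, a), 1)
  disjoint <- make_box_mask(g, c(14, 14, 14), c(18, 18, 18))
  expect_identical(dice(a, disjoint), 0)
  # two 10x10x10 boxes overlapping in a 5x10x10 slab
  b <- make_box_mask(g, c(8, 3, 3), c(17, 12, 12))
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(b, a), dice(a, b))
  empty <- structure_mask(array(FALSE, g$dims), g)
  expect_error(dice(empty, empty), "empty")
  other <- make_box_mask(grid_spec(c(20, 20, 20), c(1, 1, 2)),
                         c(3, 3, 3), c(12, 12, 12))
  expect_error(dice(a, other), "different grids")
})

test_that("surface extraction matches analytic counts and the neighbor-scan oracle", {
  g <- grid_spec(c(14, 14, 14), c(1, 1, 1), origin = c(2, 0, -1))
  single <- make_box_mask(g, c(5, 6, 7), c(5, 6, 7))
  sp <- surface_points(single)
  expect_identical(nrow(sp$points), 1L)
  expect_equal(as.numeric(sp$points), c(2 + 4, 5, -1 + 6))
  box4 <- make_box_mask(g, c(2, 2, 2), c(5, 5, 5))
  expect_identical(nrow(surface_points(box4)$points), 56L)
  box10 <- make_box_mask(g, c(2, 2, 2), c(11, 11, 11))
  pts <- surface_points(box10)$points
  oracle <- bf_surface_points(box10)
  expect_identical(nrow(pts), 488L)
  expect_equal(pts[order(pts[, 1], pts[, 2], pts[, 3]), ],
               oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ],
               ignore_attr = TRUE)
  # voxels on the grid border are boundary even without an empty neighbor
  full <- structure_mask(array(TRUE, c(3, 3, 3)), grid_spec(c(3, 3, 3), c(1, 1, 1)))
  expect_identical(nrow(surface_points(full)$points), 26L)
  expect_error(surface_points(structure_mask(array(FALSE, g$dims), g)), "empty")
})

test_that("surface distances reproduce analytic cases", {
  g <- grid_spec(c(20, 20, 20), c(1, 1, 1))
  a <- make_box_mask(g, c(3, 3, 3), c(12, 12, 12))
  expect_equal(avg_surface_distance(a, a), 0)
  expect_equal(hausdorff(a, a), 0)
  # two single voxels 5 mm apart
  p <- make_box_mask(g, c(3, 3, 3), c(3, 3, 3))
  q <- make_box_mask(g, c(8, 3, 3), c(8, 3, 3))
  expect_equal(avg_surface_distance(p, q), 5)
  expect_equal(hausdorff(p, q), 5)
  # large box translated on-grid by 3 mm
  b <- make_box_mask(g, c(6, 3, 3), c(15, 12, 12))
  expect_equal(hausdorff(a, b), 3)
  expect_equal(avg_surface_distance(a, b), bf_avg_surface_distance(a, b),
               tolerance = 1e-9)
  # concentric cubes of side 10 and 6
  inner <- make_box_mask(g, c(5, 5, 5), c(10, 10, 10))
  expect_equal(hausdorff(a, inner), bf_hausdorff(a, inner), tolerance = 1e-9)
  expect_equal(avg_surface_distance(a, inner),
               bf_avg_surface_distance(a, inner), tolerance = 1e-9)
})

test_that("pooled and mean-of-means symmetrizations differ as defined", {
  g <- grid_spec(c(20, 20, 20), c(1, 1, 1))
  a <- make_box_mask(g, c(3, 3, 3), c(14, 14, 14))
  b <- make_box_mask(g, c(5, 5, 5), c(9, 9, 9))  # asymmetric surface sizes
  expect_equal(avg_surface_distance(a, b, mode = "pooled"),
               bf_avg_surface_distance(a, b, "pooled"), tolerance = 1e-9)
  expect_equal(avg_surface_distance(a, b, mode = "mean_of_means"),
               bf_avg_surface_distance(a, b, "mean_of_means"),
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(avg_surface_distance(a, b, "pooled"),
                                avg_surface_distance(a, b, "mean_of_means"))))
})

test_that("distance metrics equal the all-pairs brute-force oracle on random masks", {
  grids <- list(grid_spec(c(12, 12, 12), c(1, 1, 1)),
                grid_spec(c(12, 12, 12), c(1, 1.3, 2), origin = c(-3, 1, 7)))
  set.seed(424242)
  for (i in 1:100) {
    g <- grids[[1 + i %% 2]]
    a <- random_blob_mask(g)
    b <- random_blob_mask(g)
    asd <- avg_surface_distance(a, b)
    hd <- hausdorff(a, b)
    expect_equal(asd, bf_avg_surface_distance(a, b), tolerance = 1e-9)
    expect_equal(hd, bf_hausdorff(a, b), tolerance = 1e-9)
    # symmetry is exact, bounds hold on every pair
    expect_identical(avg_surface_distance(b, a), asd)
    expect_identical(hausdorff(b, a), hd)
    expect_gte(hd, asd)
    dsc <- dice(a, b)
    expect_gte(dsc, 0); expect_lte(dsc, 1)
  }
})

test_that("dice degrades and hausdorff grows monotonically with translation", {
  g <- grid_spec(c(30, 30, 30), c(1, 1, 1))
  base <- make_sphere_mask(g, c(10, 14, 14), 6)
  dscs <- hds <- numeric(0)
  for (d in 0:5) {
    shifted <- make_sphere_mask(g, c(10 + d, 14, 14), 6)
    dscs <- c(dscs, dice(base, shifted))
    hds <- c(hds, hausdorff(base, shifted))
  }
  expect_true(all(diff(dscs) <= 0))
  expect_true(all(diff(hds) >= 0))
})

test_that("scaling the spacing scales distances and leaves dice unchanged", {
  d <- c(14, 14, 14)
  occ_a <- array(FALSE, d); occ_a[3:9, 4:10, 2:8] <- TRUE
  occ_b <- array(FALSE, d); occ_b[5:12, 2:7, 4:11] <- TRUE
  for (s in c(1, 2.5)) {
    g <- grid_spec(d, c(1, 1, 1) * s)
    a <- structure_mask(occ_a, g); b <- structure_mask(occ_b, g)
    if (s == 1) {
      asd1 <- avg_surface_distance(a, b); hd1 <- hausdorff(a, b)
      dsc1 <- dice(a, b)
    } else {
      expect_equal(avg_surface_distance(a, b), asd1 * s, tolerance = 1e-12)
      expect_equal(hausdorff(a, b), hd1 * s, tolerance = 1e-12)
      expect_identical(dice(a, b), dsc1)
    }
  }
})

test_that("pair_metrics bundles consistent values and a percentile option", {
  g <- grid_spec(c(20, 20, 20), c(1, 1, 1))
  a <- make_box_mask(g, c(3, 3, 3), c(12, 12, 12))
  b <- make_box_mask(g, c(6, 3, 3), c(15, 12, 12))
  pm <- pair_metrics(a, b)
  expect_equal(pm$dsc, dice(a, b))
  expect_equal(pm$avg_surface_distance_mm, avg_surface_distance(a, b))
  expect_equal(pm$hausdorff_mm, hausdorff(a, b))
  expect_equal(pm$volume_a_cc, volume_cc(a))
  expect_equal(pm$volume_b_cc, volume_cc(b))
  pm95 <- pair_metrics(a, b, hausdorff_percentile = 95)
  expect_lte(pm95$hausdorff_mm, pm$hausdorff_mm)
})
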