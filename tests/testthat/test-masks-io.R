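test_that("NIfTI write/read round trip is lossless for occupancy and grid", {
  cases <- list(
    list(spacing = c(1, 1, 2), lo = c(3, 4, 2), hi = c(12, 13, 11)),
    list(spacing = c(0.5, 0.5, 2.0), lo = c(2, 2, 2), hi = c(9, 9, 5))
  )
  for (cs in cases) {
    g <- grid_spec(c(16, 16, 12), cs$spacing, origin = c(-5, 2.25, 10))
    m <- make_box_mask(g, cs$lo, cs$hi, patient_id = "P01", rater_id = "R1",
                       structure = "prostate")
    f <- file.path(tempdir(), "rt.nii.gz")
    write_mask(m, f)
    back <- read_mask(f, patient_id = "P01", rater_id = "R1",
                      structure = "prostate")
    expect_identical(back$occupancy, m$occupancy)
    expect_identical(back$grid$dims, g$dims)
    expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-10)
    expect_equal(back$grid$origin, g$origin, tolerance = 1e-10)
  }
  # a 1000-voxel box at 1 x 1 x 2 mm keeps its count and spacing
  g <- grid_spec(c(16, 16, 12), c(1, 1, 2))
  m <- make_box_mask(g, c(1, 1, 1), c(10, 10, 10))
  f <- file.path(tempdir(), "box.nii.gz")
  write_mask(m, f)
  back <- read_mask(f)
  expect_identical(voxel_count(back), 1000L)
  expect_equal(back$grid$spacing, c(1, 1, 2))
})

test_that("empty masks survive the round trip", {
  g <- grid_spec(c(8, 8, 4), c(1, 1, 2))
  m <- structure_mask(array(FALSE, g$dims), g)
  f <- file.path(tempdir(), "empty.nii.gz")
  write_mask(m, f)
  expect_identical(voxel_count(read_mask(f)), 0L)
})

test_that("any nonzero voxel value binarizes to occupied", {
  g <- grid_spec(c(6, 6, 4), c(1, 1, 1))
  vals <- array(0, g$dims)
  vals[2:4, 2:4, 2:3] <- 7
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- g$spacing
  f <- file.path(tempdir(), "labels.nii.gz")
  RNifti::writeNifti(img, f)
  m <- read_mask(f)
  expect_identical(m$occupancy, vals != 0)
})

test_that("unsupported formats, missing spacing and grid mismatch raise distinct errors", {
  f <- file.path(tempdir(), "notavolume.txt")
  writeLines("hello", f)
  expect_error(read_mask(f), class = "concord_unsupported_format")

  # NRRD without any spacing field
  nrrd <- file.path(tempdir(), "nospacing.nrrd")
  con <- file(nrrd, "wb")
  writeLines(c("NRRD0004", "type: uchar", "dimension: 3", "sizes: 2 2 2",
               "encoding: raw", ""), con)
  writeBin(as.raw(rep(1, 8)), con)
  close(con)
  expect_error(read_mask(nrrd), class = "concord_missing_spacing")

  g <- grid_spec(c(8, 8, 4), c(1, 1, 2))
  m <- make_box_mask(g, c(2, 2, 2), c(5, 5, 3))
  f2 <- file.path(tempdir(), "gm.nii.gz")
  write_mask(m, f2)
  other <- grid_spec(c(8, 8, 4), c(1, 1, 2.5))
  expect_error(read_mask(f2, expected_grid = other),
               class = "concord_grid_mismatch")
  # within 1e-4 mm the grids are considered equal
  close_enough <- grid_spec(c(8, 8, 4), c(1, 1, 2 + 5e-5))
  expect_silent(read_mask(f2, expected_grid = close_enough))
})

test_that("NRRD volumes load with spacing, origin and binarization", {
  vals <- array(0L, c(3, 4, 2))
  vals[2, 2, 1] <- 3L
  vals[3, 4, 2] <- 1L
  hdr <- c("NRRD0004", "type: short", "dimension: 3", "sizes: 3 4 2",
           "endian: little", "spacings: 0.5 0.5 2",
           "space origin: (1.5, -2, 0)")
  for (enc in c("raw", "gzip")) {
    f <- file.path(tempdir(), paste0("vol_", enc, ".nrrd"))
    con <- file(f, "wb")
    writeLines(c(hdr, paste0("encoding: ", enc), ""), con)
    payload <- writeBin(as.integer(vals), raw(), size = 2, endian = "little")
    if (enc == "gzip") payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
    close(con)
    m <- read_mask(f)
    expect_identical(m$occupancy, vals != 0L)
    expect_equal(m$grid$spacing, c(0.5, 0.5, 2))
    expect_equal(m$grid$origin, c(1.5, -2, 0))
  }
  # spacing given as (diagonal) space directions instead of spacings
  f <- file.path(tempdir(), "vol_dirs.nrrd")
  con <- file(f, "wb")
  writeLines(c("NRRD0004", "type: uchar", "dimension: 3", "sizes: 3 4 2",
               "space directions: (0.5,0,0) (0,0.5,0) (0,0,2)",
               "encoding: raw", ""), con)
  writeBin(as.raw(as.integer(vals)), con)
  close(con)
  m <- read_mask(f)
  expect_identical(m$occupancy, vals != 0L)
  expect_equal(m$grid$spacing, c(0.5, 0.5, 2))
})

test_that("square polygon rasterizes to its analytic voxel count", {
  g <- grid_spec(c(20, 20, 5), c(1, 1, 2))
  sq <- data.frame(slice_z_mm = 4, vertex_index = 0:3,
                   x_mm = c(4.5, 14.5, 14.5, 4.5),
                   y_mm = c(4.5, 4.5, 14.5, 14.5))
  m <- rasterize_slice_polygons(sq, g)
  expect_identical(voxel_count(m), 100L)
  # all occupancy on the z = 4 mm slice (index 3, 1-based)
  expect_identical(sum(m$occupancy[, , 3]), 100L)
  expect_identical(sum(m$occupancy[, , -3]), 0L)
})

test_that("nested polygons cut holes by the even-odd rule", {
  g <- grid_spec(c(20, 20, 3), c(1, 1, 2))
  outer_sq <- data.frame(slice_z_mm = 2, vertex_index = 0:3,
                         x_mm = c(2.5, 16.5, 16.5, 2.5),
                         y_mm = c(2.5, 2.5, 16.5, 16.5))
  hole <- data.frame(slice_z_mm = 2, vertex_index = 0:3,
                     x_mm = c(6.5, 12.5, 12.5, 6.5),
                     y_mm = c(6.5, 6.5, 12.5, 12.5))
  m <- rasterize_slice_polygons(rbind(outer_sq, hole), g)
  expect_identical(voxel_count(m), 14L * 14L - 6L * 6L)
})

test_that("circle rasterization matches a brute-force point-in-polygon oracle", {
  g <- grid_spec(c(60, 60, 3), c(0.5, 0.5, 2))
  r <- 10
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- data.frame(slice_z_mm = 2, vertex_index = seq_along(th) - 1,
                     x_mm = 14.8 + r * cos(th), y_mm = 15.1 + r * sin(th))
  m <- rasterize_slice_polygons(circ, g)
  # area check: within 2% of pi r^2 / pixel area
  expect_equal(voxel_count(m), pi * r^2 / 0.25, tolerance = 0.02)
  # exact check against an independent even-odd crossing count per center
  inside_oracle <- function(px, py, xs, ys) {
    n <- length(xs); cnt <- 0L; j <- n
    for (i in seq_len(n)) {
      if ((ys[j] > py) != (ys[i] > py)) {
        xint <- xs[j] + (py - ys[j]) * (xs[i] - xs[j]) / (ys[i] - ys[j])
        if (px < xint) cnt <- cnt + 1L
      }
      j <- i
    }
    cnt %% 2L == 1L
  }
  centers <- expand.grid(x = (0:59) * 0.5, y = (0:59) * 0.5)
  oracle <- mapply(inside_oracle, centers$x, centers$y,
                   MoreArgs = list(xs = circ$x_mm, ys = circ$y_mm))
  expect_identical(as.vector(m$occupancy[, , 2]), as.vector(oracle))
})

test_that("rasterization is invariant to vertex rotation order and start", {
  g <- grid_spec(c(20, 20, 3), c(1, 1, 2))
  xs <- c(3.2, 15.8, 12.1, 5.5)
  ys <- c(4.1, 6.3, 15.2, 13.8)
  base <- rasterize_slice_polygons(
    data.frame(slice_z_mm = 2, vertex_index = 0:3, x_mm = xs, y_mm = ys), g)
  # reversed orientation
  rev_m <- rasterize_slice_polygons(
    data.frame(slice_z_mm = 2, vertex_index = 0:3,
               x_mm = rev(xs), y_mm = rev(ys)), g)
  expect_identical(rev_m$occupancy, base$occupancy)
  # rotated starting vertex
  for (s in 1:3) {
    rot <- c((s + 1):4, 1:s)
    rot_m <- rasterize_slice_polygons(
      data.frame(slice_z_mm = 2, vertex_index = 0:3,
                 x_mm = xs[rot], y_mm = ys[rot]), g)
    expect_identical(rot_m$occupancy, base$occupancy)
  }
})

test_that("abutting polygons never double-cover under the half-open rule", {
  g <- grid_spec(c(20, 20, 3), c(1, 1, 2))
  left <- data.frame(slice_z_mm = 2, vertex_index = 0:3,
                     x_mm = c(2, 10, 10, 2), y_mm = c(2, 2, 12, 12))
  right <- data.frame(slice_z_mm = 2, vertex_index = 0:3,
                      x_mm = c(10, 18, 18, 10), y_mm = c(2, 2, 12, 12))
  both <- rasterize_slice_polygons(rbind(left, right), g)
  ml <- rasterize_slice_polygons(left, g)
  mr <- rasterize_slice_polygons(right, g)
  expect_identical(voxel_count(both), voxel_count(ml) + voxel_count(mr))
  expect_false(any(ml$occupancy & mr$occupancy))
})

test_that("misaligned planes and self-intersecting polygons are rejected", {
  g <- grid_spec(c(10, 10, 3), c(1, 1, 2))  # slice centers at 0, 2, 4 mm
  sq <- data.frame(slice_z_mm = 5.2, vertex_index = 0:3,
                   x_mm = c(1, 5, 5, 1), y_mm = c(1, 1, 5, 5))
  expect_error(rasterize_slice_polygons(sq, g), "not aligned")
  bow <- data.frame(slice_z_mm = 2, vertex_index = 0:3,
                    x_mm = c(1, 5, 5, 1), y_mm = c(1, 5, 1, 5))
  expect_error(rasterize_slice_polygons(bow, g), "self-intersecting")
})

test_that("manifests reject duplicate triples and round trip via JSON and CSV", {
  df <- data.frame(patient_id = c("P01", "P01"), rater_id = c("R1", "R2"),
                   structure = "prostate", path = c("a.nii.gz", "b.nii.gz"))
  man <- cohort_manifest(df)
  expect_s3_class(man, "cohort_manifest")
  expect_error(cohort_manifest(rbind(df, df[1, ])), "duplicate")
  for (ext in c("json", "csv")) {
    f <- file.path(tempdir(), paste0("man.", ext))
    write_manifest(man, f)
    back <- read_manifest(f)
    expect_identical(back$patient_id, man$patient_id)
    expect_identical(back$rater_id, man$rater_id)
    expect_identical(basename(back$path), basename(man$path))
  }
})
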