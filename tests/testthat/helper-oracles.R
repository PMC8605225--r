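# Shape builders and independent brute-force oracles used across tests.
# The oracles deliberately avoid the package's distance-transform path:
# surfaces come from an explicit neighbor scan and distances from all-pairs
# Euclidean minimization.

make_box_mask <- function(grid, lo, hi, ...) {
  occ <- array(FALSE, grid$dims)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  structure_mask(occ, grid, ...)
}

make_sphere_mask <- function(grid, center_mm, r_mm, ...) {
  cc <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a]
  })
  d2 <- outer(outer((cc[[1]] - center_mm[1])^2,
                    (cc[[2]] - center_mm[2])^2, `+`),
              (cc[[3]] - center_mm[3])^2, `+`)
  structure_mask(d2 <= r_mm^2, grid, ...)
}

# boundary voxel centers by explicit 6-neighbor scan over occupied voxels
bf_surface_points <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  idx <- which(occ)
  sub <- arrayInd(idx, d)
  on_surface <- logical(nrow(sub))
  for (r in seq_len(nrow(sub))) {
    i <- sub[r, 1]; j <- sub[r, 2]; k <- sub[r, 3]
    nb <- c(
      if (i > 1) occ[i - 1, j, k] else FALSE,
      if (i < d[1]) occ[i + 1, j, k] else FALSE,
      if (j > 1) occ[i, j - 1, k] else FALSE,
      if (j < d[2]) occ[i, j + 1, k] else FALSE,
      if (k > 1) occ[i, j, k - 1] else FALSE,
      if (k < d[3]) occ[i, j, k + 1] else FALSE
    )
    on_surface[r] <- !all(nb)
  }
  pts <- sweep(sweep(sub[on_surface, , drop = FALSE] - 1, 2,
                     mask$grid$spacing, `*`),
               2, mask$grid$origin, `+`)
  pts
}

# directed nearest-point distances from each row of A to the set B
bf_directed_dists <- function(A, B) {
  tB <- t(B)
  vapply(seq_len(nrow(A)), function(r) {
    sqrt(min(colSums((tB - A[r, ])^2)))
  }, numeric(1))
}

bf_avg_surface_distance <- function(a, b, mode = "pooled") {
  sa <- bf_surface_points(a)
  sb <- bf_surface_points(b)
  dab <- bf_directed_dists(sa, sb)
  dba <- bf_directed_dists(sb, sa)
  if (mode == "pooled") mean(c(dab, dba)) else (mean(dab) + mean(dba)) / 2
}

bf_hausdorff <- function(a, b) {
  sa <- bf_surface_points(a)
  sb <- bf_surface_points(b)
  max(max(bf_directed_dists(sa, sb)), max(bf_directed_dists(sb, sa)))
}

# random non-empty blob on a small grid: union of a random box and 1-2
# random spheres (in voxel units scaled by spacing)
random_blob_mask <- function(grid) {
  occ <- array(FALSE, grid$dims)
  d <- grid$dims
  lo <- sapply(d, function(n) sample(n - 1, 1))
  hi <- pmin(lo + sample(0:4, 3, replace = TRUE), d)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  for (s in seq_len(sample(1:2, 1))) {
    ctr_vox <- sapply(d, function(n) sample(n, 1)) - 1
    ctr <- grid$origin + ctr_vox * grid$spacing
    r <- stats::runif(1, 1, 4) * min(grid$spacing)
    sp <- make_sphere_mask(grid, ctr, r)
    occ <- occ | sp$occupancy
  }
  structure_mask(occ, grid)
}

# morphological dilation with a Euclidean ball of radius r_mm
# (voxel-center distances), by explicit offset enumeration
bf_dilate_ball <- function(mask, r_mm) {
  occ <- mask$occupancy
  d <- dim(occ)
  sp <- mask$grid$spacing
  rng <- lapply(1:3, function(a) seq(-floor(r_mm / sp[a]), floor(r_mm / sp[a])))
  out <- array(FALSE, d)
  for (oi in rng[[1]]) for (oj in rng[[2]]) for (ok in rng[[3]]) {
    if (sum((c(oi, oj, ok) * sp)^2) > r_mm^2) next
    si <- intersect(seq_len(d[1]), seq_len(d[1]) - oi)
    sj <- intersect(seq_len(d[2]), seq_len(d[2]) - oj)
    sk <- intersect(seq_len(d[3]), seq_len(d[3]) - ok)
    out[si + oi, sj + oj, sk + ok] <-
      out[si + oi, sj + oj, sk + ok] | occ[si, sj, sk]
  }
  structure_mask(out, mask$grid, mask$patient_id, mask$rater_id,
                 mask$structure)
}

# manifest for masks already in memory: writes them to dir and returns the
# manifest data frame
write_cohort_masks <- function(masks_by_triple, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(masks_by_triple, function(entry) {
    m <- entry$mask
    path <- file.path(dir, sprintf("%s_%s_%s.nii.gz", entry$patient,
                                   entry$rater, entry$structure))
    write_mask(m, path)
    data.frame(patient_id = entry$patient, rater_id = entry$rater,
               structure = entry$structure, path = path,
               stringsAsFactors = FALSE)
  })
  cohort_manifest(do.call(rbind, rows))
}
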