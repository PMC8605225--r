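#' Structure volume in cubic centimetres
#'
#' Voxel count times the physical voxel volume, `dx * dy * dz / 1000`.
#'
#' @param mask A [structure_mask()].
#' @return Volume in cc (`>= 0`).
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  voxel_count(mask) * prod(mask$grid$spacing) / 1000
}

#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` by voxel counts. 0 means no spatial
#' overlap, 1 complete overlap. Symmetric in its arguments. Undefined (an
#' error) when both masks are empty.
#'
#' @param a,b [structure_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  .assert_same_grid(a, b)
  na <- voxel_count(a); nb <- voxel_count(b)
  if (na == 0L && nb == 0L) {
    stop("Dice coefficient is undefined for two empty masks")
  }
  2 * sum(a$occupancy & b$occupancy) / (na + nb)
}

# occupancy array shifted by `by` voxels along `axis`; out-of-grid is FALSE
.shift_occ <- function(occ, axis, by) {
  d <- dim(occ)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by > 0) 1:(n - by) else (1 - by):n
  dst <- if (by > 0) (1 + by):n else 1:(n + by)
  idx_src <- idx_dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), idx_dst,
                          list(value = do.call(`[`, c(list(occ), idx_src)))))
  out
}

# logical array marking boundary voxels: occupied with >= 1 of the 6
# face-neighbors unoccupied (outside the grid counts as unoccupied)
.surface_occ <- function(mask) {
  occ <- mask$occupancy
  interior <- occ
  for (axis in 1:3) {
    interior <- interior & .shift_occ(occ, axis, 1L) &
      .shift_occ(occ, axis, -1L)
  }
  occ & !interior
}

#' Boundary surface of a mask as physical points
#'
#' The surface is the set of occupied voxels having at least one of their 6
#' face-adjacent neighbors unoccupied (voxels on the grid border count as
#' boundary), reported as voxel-center coordinates in mm. This voxel-center
#' surface model underlies both distance metrics.
#'
#' @param mask A non-empty [structure_mask()].
#' @return An object of class `surface_point_set`: a list with `points`
#'   (n x 3 matrix, mm), `idx` (linear voxel indices) and `grid`.
#' @export
surface_points <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (voxel_count(mask) == 0L) stop("cannot extract the surface of an empty mask")
  surf <- .surface_occ(mask)
  idx <- which(surf)
  sub <- arrayInd(idx, dim(surf))
  pts <- sweep(sweep(sub - 1, 2, mask$grid$spacing, `*`),
               2, mask$grid$origin, `+`)
  colnames(pts) <- c("x_mm", "y_mm", "z_mm")
  structure(list(points = pts, idx = idx, grid = mask$grid),
            class = "surface_point_set")
}

#' @export
print.surface_point_set <- function(x, ...) {
  cat(sprintf("<surface_point_set> %d boundary voxel centers\n", nrow(x$points)))
  invisible(x)
}

# mm distance from every voxel center to the nearest surface point of `mask`
# (exact Euclidean distance transform of the boundary-voxel set)
.dist_to_surface <- function(mask) {
  surf <- .surface_occ(mask)
  d2 <- .edt_sq_cpp(as.logical(surf), mask$grid$dims, mask$grid$spacing)
  array(sqrt(d2), dim = mask$grid$dims)
}

# the two directed nearest-surface distance multisets between masks a and b;
# precomputed surfaces/EDTs may be supplied to amortize work across pairs
.directed_surface_distances <- function(a, b, cache_a = NULL, cache_b = NULL) {
  .assert_same_grid(a, b)
  if (voxel_count(a) == 0L || voxel_count(b) == 0L) {
    stop("surface distances require two non-empty masks")
  }
  ca <- if (is.null(cache_a)) .surface_cache(a) else cache_a
  cb <- if (is.null(cache_b)) .surface_cache(b) else cache_b
  list(a_to_b = cb$dist[ca$idx], b_to_a = ca$dist[cb$idx])
}

# surface voxel indices + full-grid distance map for one mask
.surface_cache <- function(mask) {
  surf <- .surface_occ(mask)
  idx <- which(surf)
  d2 <- .edt_sq_cpp(as.logical(surf), mask$grid$dims, mask$grid$spacing)
  list(idx = idx, dist = sqrt(d2))
}

#' Symmetric 3D average surface distance between two masks
#'
#' For each boundary point of either mask, the Euclidean mm distance to the
#' nearest boundary point of the other mask is computed; the two directed
#' distance multisets are combined symmetrically. The default (`"pooled"`)
#' averages over the pooled multiset, weighting each surface by its size;
#' `"mean_of_means"` averages the two directed means with equal weight.
#' 0 indicates perfectly coinciding surfaces.
#'
#' @param a,b Non-empty [structure_mask()] objects on the same grid.
#' @param mode `"pooled"` (default) or `"mean_of_means"`.
#' @return Average surface distance in mm (`>= 0`).
#' @export
avg_surface_distance <- function(a, b, mode = c("pooled", "mean_of_means")) {
  mode <- match.arg(mode)
  d <- .directed_surface_distances(a, b)
  .symmetric_mean(d, mode)
}

# combining the directed sums (not a concatenated vector) keeps the result
# bit-identical under argument swap
.symmetric_mean <- function(d, mode) {
  if (mode == "pooled") {
    (sum(d$a_to_b) + sum(d$b_to_a)) / (length(d$a_to_b) + length(d$b_to_a))
  } else {
    (mean(d$a_to_b) + mean(d$b_to_a)) / 2
  }
}

#' Hausdorff distance between two masks
#'
#' The maximum over both directed maximal nearest-surface distances: the
#' worst-case boundary discrepancy, in mm. Symmetric; always at least the
#' average surface distance of the same pair. An optional percentile
#' (e.g. 95) replaces the maximum of each directed distance distribution
#' with that percentile; the default 100 is the exact maximum.
#'
#' @param a,b Non-empty [structure_mask()] objects on the same grid.
#' @param percentile Percentile of the directed distance distributions
#'   (default 100, the exact maximum).
#' @return Hausdorff distance in mm (`>= 0`).
#' @export
hausdorff <- function(a, b, percentile = 100) {
  stopifnot(percentile > 0, percentile <= 100)
  d <- .directed_surface_distances(a, b)
  if (percentile == 100) {
    max(max(d$a_to_b), max(d$b_to_a))
  } else {
    max(stats::quantile(d$a_to_b, percentile / 100, names = FALSE),
        stats::quantile(d$b_to_a, percentile / 100, names = FALSE))
  }
}

#' All pairwise agreement metrics for one rater pair
#'
#' Computes the Dice coefficient, symmetric average surface distance,
#' Hausdorff distance and both volumes in one pass, sharing the surface
#' extraction and distance transforms.
#'
#' @inheritParams avg_surface_distance
#' @param hausdorff_percentile See [hausdorff()].
#' @param cache_a,cache_b Optional precomputed surface caches (internal use
#'   by the study pipeline).
#' @return A list with elements `dsc`, `avg_surface_distance_mm`,
#'   `hausdorff_mm`, `volume_a_cc`, `volume_b_cc`.
#' @export
pair_metrics <- function(a, b, mode = c("pooled", "mean_of_means"),
                         hausdorff_percentile = 100,
                         cache_a = NULL, cache_b = NULL) {
  mode <- match.arg(mode)
  d <- .directed_surface_distances(a, b, cache_a, cache_b)
  asd <- .symmetric_mean(d, mode)
  hd <- if (hausdorff_percentile == 100) {
    max(max(d$a_to_b), max(d$b_to_a))
  } else {
    max(stats::quantile(d$a_to_b, hausdorff_percentile / 100, names = FALSE),
        stats::quantile(d$b_to_a, hausdorff_percentile / 100, names = FALSE))
  }
  list(dsc = dice(a, b),
       avg_surface_distance_mm = asd,
       hausdorff_mm = hd,
       volume_a_cc = volume_cc(a),
       volume_b_cc = volume_cc(b))
}
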