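#' Cranio-caudal interval of slice centers
#'
#' An interval along the superior axis, in physical mm of slice centers
#' (`inf_mm <= sup_mm`). Used to harmonize raters' contours to a common
#' superior-inferior extent before comparison.
#'
#' @param inf_mm,sup_mm Physical coordinates (mm) of the inferior-most and
#'   superior-most slice centers.
#' @return An object of class `longitudinal_interval`.
#' @export
longitudinal_interval <- function(inf_mm, sup_mm) {
  stopifnot(is.finite(inf_mm), is.finite(sup_mm))
  if (sup_mm < inf_mm) stop("sup_mm must be >= inf_mm")
  structure(list(inf_mm = inf_mm, sup_mm = sup_mm),
            class = "longitudinal_interval")
}

#' @export
print.longitudinal_interval <- function(x, ...) {
  cat(sprintf("<longitudinal_interval> [%g, %g] mm (slice centers)\n",
              x$inf_mm, x$sup_mm))
  invisible(x)
}

#' Outer-border length of an interval
#'
#' The reported "distance between superior and inferior border" counts
#' whole slices: `(number of slices) * slice_spacing`, i.e. the distance
#' between the outer borders of the bounding slices, which exceeds
#' `sup_mm - inf_mm` (a center-to-center distance) by one slice spacing.
#'
#' @param interval A [longitudinal_interval()].
#' @param slice_spacing Slice spacing in mm.
#' @return Length in mm.
#' @export
interval_length_mm <- function(interval, slice_spacing) {
  stopifnot(inherits(interval, "longitudinal_interval"), slice_spacing > 0)
  interval$sup_mm - interval$inf_mm + slice_spacing
}

#' Superior-inferior extent of one mask
#'
#' The interval spanning the lowest and highest slice (by center coordinate)
#' containing at least one occupied voxel. Internal empty slices do not
#' shrink the extent.
#'
#' @param mask A non-empty [structure_mask()].
#' @return A [longitudinal_interval()].
#' @export
longitudinal_extent <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (voxel_count(mask) == 0L) stop("empty mask has no longitudinal extent")
  per_slice <- .slice_counts(mask)
  occ_slices <- which(per_slice > 0L)
  zc <- slice_centers(mask$grid)
  longitudinal_interval(zc[min(occ_slices)], zc[max(occ_slices)])
}

.slice_counts <- function(mask) {
  apply(mask$occupancy, mask$grid$superior_axis, sum)
}

#' Maximal common superior-inferior extent of several raters' masks
#'
#' The intersection of all raters' longitudinal extents: the maximal
#' interval contained in every rater's extent. Raised as an error (class
#' `concord_no_overlap`) when the intersection is empty.
#'
#' @param masks List of `>= 2` non-empty [structure_mask()] objects on the
#'   same grid.
#' @return A [longitudinal_interval()].
#' @export
common_extent <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 2L)
  for (m in masks[-1]) .assert_same_grid(masks[[1]], m)
  exts <- lapply(masks, longitudinal_extent)
  lo <- max(vapply(exts, `[[`, numeric(1), "inf_mm"))
  hi <- min(vapply(exts, `[[`, numeric(1), "sup_mm"))
  if (hi < lo) {
    .concord_error(
      "concord_no_overlap",
      sprintf("no longitudinal overlap for patient %s, structure %s",
              masks[[1]]$patient_id, masks[[1]]$structure))
  }
  longitudinal_interval(lo, hi)
}

#' Crop a mask to a cranio-caudal interval
#'
#' Occupancy is preserved on slices whose centers lie in
#' `[inf_mm, sup_mm]` and cleared elsewhere; in-plane occupancy is never
#' touched. An error is raised when the cropped mask would be empty (the
#' rater had no voxels inside the interval).
#'
#' @param mask A [structure_mask()].
#' @param interval A [longitudinal_interval()].
#' @return The cropped [structure_mask()].
#' @export
crop_to_interval <- function(mask, interval) {
  stopifnot(inherits(mask, "structure_mask"),
            inherits(interval, "longitudinal_interval"))
  zc <- slice_centers(mask$grid)
  keep <- zc >= interval$inf_mm - 1e-9 & zc <= interval$sup_mm + 1e-9
  if (!any(keep)) stop("interval does not intersect the mask's grid")
  occ <- mask$occupancy
  ax <- mask$grid$superior_axis
  for (k in which(!keep)) .set_slice(occ, ax, k) <- FALSE
  out <- structure_mask(occ, mask$grid, mask$patient_id, mask$rater_id,
                        mask$structure)
  if (voxel_count(out) == 0L) {
    stop(sprintf("mask of rater %s is empty after cropping to [%g, %g] mm",
                 mask$rater_id, interval$inf_mm, interval$sup_mm))
  }
  out
}

#' Exact inferior half of an interval
#'
#' The sub-interval of slices whose centers lie at or below the physical
#' midpoint `(inf_mm + sup_mm) / 2`. With an even slice count this is
#' exactly the lower half; with an odd count the middle slice is included,
#' erring toward the clinically critical apex-side region.
#'
#' @param interval A [longitudinal_interval()] spanning `>= 1` slice.
#' @param slice_spacing Slice spacing in mm.
#' @return A [longitudinal_interval()].
#' @export
inferior_half <- function(interval, slice_spacing) {
  stopifnot(inherits(interval, "longitudinal_interval"), slice_spacing > 0)
  mid <- (interval$inf_mm + interval$sup_mm) / 2
  n_below <- floor((mid - interval$inf_mm) / slice_spacing + 1e-9)
  longitudinal_interval(interval$inf_mm,
                        interval$inf_mm + n_below * slice_spacing)
}

#' Harmonize all raters' masks of one structure to a common extent
#'
#' Crops every rater's mask of one structure (one patient) to the maximal
#' common superior-inferior extent of all raters' contours, so that all
#' compared contours run from the same superior to the same inferior level.
#' Harmonization is per structure, per patient, never across patients.
#' Idempotent: harmonizing an already-harmonized set changes nothing.
#'
#' @param masks List of `>= 2` non-empty [structure_mask()] objects of the
#'   same structure and patient, one per rater, on the same grid.
#' @return An object of class `harmonized_set`: list with `masks` (cropped,
#'   named by rater where available), `interval`
#'   (the common [longitudinal_interval()]), `structure` and `patient_id`.
#' @export
harmonize <- function(masks) {
  interval <- common_extent(masks)
  cropped <- lapply(masks, crop_to_interval, interval = interval)
  rater_ids <- vapply(cropped, `[[`, character(1), "rater_id")
  if (!anyNA(rater_ids) && !anyDuplicated(rater_ids)) {
    names(cropped) <- rater_ids
  }
  structure(
    list(masks = cropped, interval = interval,
         structure = masks[[1]]$structure,
         patient_id = masks[[1]]$patient_id),
    class = "harmonized_set"
  )
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s / %s: %d raters, interval [%g, %g] mm\n",
              x$patient_id, x$structure, length(x$masks),
              x$interval$inf_mm, x$interval$sup_mm))
  invisible(x)
}

#' Derive the inferior-half subset of a harmonized set
#'
#' Crops every member of a [harmonize()]d set to the exact inferior half of
#' its common interval and relabels the structure with
#' [inf_half_label()]. Used for the neurovascular bundle, whose inferior
#' half (approximately prostate midgland to apex) lies closest to the
#' prostate.
#'
#' @param hset A `harmonized_set`.
#' @return A new `harmonized_set` over the inferior-half interval.
#' @export
inferior_half_set <- function(hset) {
  stopifnot(inherits(hset, "harmonized_set"))
  dz <- hset$masks[[1]]$grid$spacing[hset$masks[[1]]$grid$superior_axis]
  half <- inferior_half(hset$interval, dz)
  label <- inf_half_label(hset$structure)
  cropped <- lapply(hset$masks, function(m) {
    out <- crop_to_interval(m, half)
    out$structure <- label
    out
  })
  structure(
    list(masks = cropped, interval = half, structure = label,
         patient_id = hset$patient_id),
    class = "harmonized_set"
  )
}
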