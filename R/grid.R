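#' Regular 3D voxel grid with physical spacing
#'
#' A `grid_spec` fixes the voxel lattice on which masks live: integer
#' dimensions, positive physical spacing in mm, a physical origin, and which
#' array axis points in the superior (cranial) direction. The physical
#' coordinate of the center of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`.
#'
#' @param dims Integer vector of length 3, all `>= 1`.
#' @param spacing Numeric vector of length 3, voxel spacing in mm, all `> 0`.
#' @param origin Numeric vector of length 3, physical coordinate (mm) of the
#'   center of voxel `(0, 0, 0)`. Default `c(0, 0, 0)`.
#' @param superior_axis Which axis (1, 2 or 3) increases toward the superior
#'   (cranial) direction. Axial image stacks conventionally index feet to
#'   head along the third axis, so the default is 3.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(c(64, 64, 40), spacing = c(1, 1, 2))
#' @export
grid_spec <- function(dims, spacing, origin = c(0, 0, 0), superior_axis = 3L) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(dims) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(dims < 1L)) stop("all grid dimensions must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("all spacing components must be positive")
  }
  superior_axis <- as.integer(superior_axis)
  if (!superior_axis %in% 1:3) stop("superior_axis must be 1, 2 or 3")
  structure(
    list(dims = dims, spacing = spacing, origin = origin,
         superior_axis = superior_axis),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing (%g, %g, %g) mm,\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, superior axis %d\n",
              x$origin[1], x$origin[2], x$origin[3], x$superior_axis))
  invisible(x)
}

#' Test two grids for equality within a physical tolerance
#'
#' Dimensions and superior axis must match exactly; spacing and origin must
#' agree within `tol` mm per component.
#'
#' @param a,b `grid_spec` objects.
#' @param tol Tolerance in mm (default `1e-4`).
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "grid_spec"), inherits(b, "grid_spec"))
  identical(a$dims, b$dims) &&
    a$superior_axis == b$superior_axis &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' Physical slice-center coordinates along the superior axis
#'
#' @param grid A `grid_spec`.
#' @return Numeric vector of length `dims[superior_axis]`: the physical mm
#'   coordinate of each slice center, in index order (increasing = superior).
#' @export
slice_centers <- function(grid) {
  ax <- grid$superior_axis
  grid$origin[ax] + (seq_len(grid$dims[ax]) - 1) * grid$spacing[ax]
}

#' One rater's binary delineation of one structure
#'
#' Bundles a binary occupancy array with its grid and identifying metadata
#' (patient, rater, structure label). Any non-zero / `TRUE` voxel is occupied.
#'
#' @param occupancy Logical (or coercible) array with extent `grid$dims`.
#' @param grid A `grid_spec`.
#' @param patient_id,rater_id,structure Character identifiers (may be `NA`).
#' @return An object of class `structure_mask`.
#' @examples
#' g <- grid_spec(c(8, 8, 4), c(1, 1, 2))
#' occ <- array(FALSE, g$dims); occ[3:6, 3:6, 2:3] <- TRUE
#' m <- structure_mask(occ, g, structure = "prostate")
#' voxel_count(m)
#' @export
structure_mask <- function(occupancy, grid, patient_id = NA_character_,
                           rater_id = NA_character_,
                           structure = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"))
  occupancy <- array(as.logical(occupancy), dim = dim(occupancy))
  if (!identical(as.integer(dim(occupancy)), grid$dims)) {
    stop("occupancy extent ", paste(dim(occupancy), collapse = "x"),
         " does not match grid dims ", paste(grid$dims, collapse = "x"))
  }
  if (anyNA(occupancy)) stop("occupancy must not contain NA")
  structure(
    list(occupancy = occupancy, grid = grid,
         patient_id = as.character(patient_id),
         rater_id = as.character(rater_id),
         structure = as.character(structure)),
    class = "structure_mask"
  )
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s / %s / %s: %d occupied voxels (%.2f cc)\n",
              x$patient_id, x$rater_id, x$structure,
              voxel_count(x), volume_cc(x)))
  print(x$grid)
  invisible(x)
}

#' Number of occupied voxels in a mask
#'
#' @param mask A `structure_mask`.
#' @return Integer count.
#' @export
voxel_count <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$occupancy)
}

#' Base structure labels of the delineation study
#'
#' The five structures contoured per patient: the prostate, the left and
#' right neurovascular bundles (NVB), and the left and right internal
#' pudendal arteries (IPA). Derived inferior-half NVB subsets carry the
#' labels returned by [inf_half_label()].
#'
#' @return Character vector of length 5.
#' @export
base_structures <- function() {
  c("prostate", "NVB_left", "NVB_right", "IPA_left", "IPA_right")
}

#' Label of the derived inferior-half subset of a structure
#'
#' @param structure Base structure label, e.g. `"NVB_left"`.
#' @return Character label, e.g. `"NVB_left_inf_half"`.
#' @export
inf_half_label <- function(structure) paste0(structure, "_inf_half")

.assert_same_grid <- function(a, b) {
  if (!grids_equal(a$grid, b$grid)) {
    stop("masks are defined on different grids")
  }
}
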