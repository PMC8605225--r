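#' Parametric pelvic phantom specification
#'
#' Describes a simplified pelvic anatomy on a voxel grid: the prostate as an
#' ellipsoid; the left and right neurovascular bundles (NVB) as tubes whose
#' per-slice centers hug the prostate's dorsolateral surface and whose
#' radius widens toward the superior end (where the real NVB becomes more
#' divergent and diffuse); and the left and right internal pudendal arteries
#' (IPA) as lateral tubes whose centerline makes a posterior-to-ventral turn
#' going superior. The NVB slice range extends beyond the prostate's at both
#' ends, mirroring contouring from the seminal-vesicle base down to the
#' urogenital diaphragm.
#'
#' All lengths are in mm. Defaults give structure volumes in the range seen
#' for these organs (prostate tens of cc, NVB and IPA a few cc) on a
#' 96 x 96 x 40 grid at 1 x 1 x 2 mm spacing.
#'
#' @param grid A [grid_spec()]; the superior axis must be axis 3.
#' @param prostate_center Prostate ellipsoid center (mm, length 3).
#' @param prostate_semi_axes Ellipsoid semi-axes (mm, length 3).
#' @param nvb_theta_deg Dorsolateral direction of the NVB center relative to
#'   the lateral (+x) axis, in degrees toward posterior (+y).
#' @param nvb_radius_inf_mm,nvb_radius_sup_mm NVB tube radius at the
#'   inferior and superior end (linearly interpolated between).
#' @param nvb_margin_mm Gap between the prostate surface and the NVB tube.
#' @param nvb_extend_slices How many slices the NVB range extends beyond the
#'   prostate's occupied slice range at each end.
#' @param nvb_scale_floor Minimum in-plane prostate scale used to place the
#'   NVB center on slices beyond the prostate poles.
#' @param ipa_lateral_offset_mm Lateral distance of the IPA centerline from
#'   the prostate center.
#' @param ipa_radius_mm IPA tube radius.
#' @param ipa_y_posterior_mm,ipa_y_anterior_mm Posterior offset of the IPA
#'   centerline at its inferior end and (negative = anterior) at its
#'   superior end; the turn between them is quadratic in normalized height.
#' @param ipa_slice_range Integer slice range (0-based, inclusive) of the
#'   IPA.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = grid_spec(c(96, 96, 40), c(1, 1, 2)),
                         prostate_center = c(47.5, 45.5, 40),
                         prostate_semi_axes = c(22, 18.5, 20),
                         nvb_theta_deg = 40,
                         nvb_radius_inf_mm = 4.2,
                         nvb_radius_sup_mm = 5.8,
                         nvb_margin_mm = 1.5,
                         nvb_extend_slices = 3L,
                         nvb_scale_floor = 0.35,
                         ipa_lateral_offset_mm = 34,
                         ipa_radius_mm = 4,
                         ipa_y_posterior_mm = 12,
                         ipa_y_anterior_mm = -10,
                         ipa_slice_range = c(7L, 28L)) {
  stopifnot(inherits(grid, "grid_spec"), grid$superior_axis == 3L,
            all(prostate_semi_axes > 0),
            nvb_radius_inf_mm > 0, nvb_radius_sup_mm > 0, ipa_radius_mm > 0)
  structure(
    list(grid = grid,
         prostate = list(center = prostate_center,
                         semi_axes = prostate_semi_axes),
         nvb = list(theta_deg = nvb_theta_deg,
                    radius_inf_mm = nvb_radius_inf_mm,
                    radius_sup_mm = nvb_radius_sup_mm,
                    margin_mm = nvb_margin_mm,
                    extend_slices = as.integer(nvb_extend_slices),
                    scale_floor = nvb_scale_floor),
         ipa = list(lateral_offset_mm = ipa_lateral_offset_mm,
                    radius_mm = ipa_radius_mm,
                    y_posterior_mm = ipa_y_posterior_mm,
                    y_anterior_mm = ipa_y_anterior_mm,
                    slice_range = as.integer(ipa_slice_range))),
    class = "phantom_spec"
  )
}

# voxel-center coordinate vectors of a grid, per axis
.axis_coords <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$dims[a]) - 1) * grid$spacing[a]
  })
}

.voxelize_ellipsoid <- function(grid, center, semi) {
  cc <- .axis_coords(grid)
  x2 <- ((cc[[1]] - center[1]) / semi[1])^2
  y2 <- ((cc[[2]] - center[2]) / semi[2])^2
  z2 <- ((cc[[3]] - center[3]) / semi[3])^2
  r2 <- outer(outer(x2, y2, `+`), z2, `+`)
  r2 <= 1
}

# tube from per-slice centers (matrix k x 2) and radii over slice indices
.voxelize_tube <- function(grid, slice_idx, centers_xy, radii) {
  cc <- .axis_coords(grid)
  occ <- array(FALSE, grid$dims)
  for (i in seq_along(slice_idx)) {
    k <- slice_idx[i] + 1L  # 0-based slice to 1-based array index
    if (k < 1L || k > grid$dims[3]) next
    d2 <- outer((cc[[1]] - centers_xy[i, 1])^2,
                (cc[[2]] - centers_xy[i, 2])^2, `+`)
    occ[, , k] <- occ[, , k] | (d2 <= radii[i]^2)
  }
  occ
}

# in-plane radius of an ellipse with semi-axes (a, b) along direction theta
.ellipse_radius <- function(a, b, theta) {
  1 / sqrt((cos(theta) / a)^2 + (sin(theta) / b)^2)
}

#' Generate the phantom's ground-truth structure masks
#'
#' Deterministic in its specification: no randomness is involved. The five
#' structures are pairwise disjoint and fit inside the grid with at least a
#' 2-voxel margin (an error is raised otherwise). A voxel belongs to a
#' structure iff its center lies inside the analytic shape, so the
#' voxelized ellipsoid volume converges to `4/3 pi a b c` as spacing
#' shrinks.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id Patient identifier stamped on the masks.
#' @return Named list of [structure_mask()] objects, one per
#'   [base_structures()] label.
#' @export
generate_phantom <- function(spec, patient_id = NA_character_) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  pr <- spec$prostate
  occ_pros <- .voxelize_ellipsoid(g, pr$center, pr$semi_axes)
  pros_slices <- which(apply(occ_pros, 3, any)) - 1L  # 0-based
  if (length(pros_slices) == 0L) stop("prostate does not occupy any slice")

  nv <- spec$nvb
  theta <- nv$theta_deg * pi / 180
  nvb_lo <- min(pros_slices) - nv$extend_slices
  nvb_hi <- max(pros_slices) + nv$extend_slices
  nvb_slices <- nvb_lo:nvb_hi
  zc <- .axis_coords(g)[[3]]
  t_nvb <- (nvb_slices - nvb_lo) / max(1, nvb_hi - nvb_lo)
  radii_nvb <- nv$radius_inf_mm + t_nvb * (nv$radius_sup_mm - nv$radius_inf_mm)
  zq <- (zc[pmin(pmax(nvb_slices, 0L), g$dims[3] - 1L) + 1L] -
           pr$center[3]) / pr$semi_axes[3]
  scale <- sqrt(pmax(1 - zq^2, 0))
  scale <- pmax(scale, nv$scale_floor)
  r_e <- .ellipse_radius(pr$semi_axes[1] * scale, pr$semi_axes[2] * scale,
                         theta)
  dist_c <- r_e + radii_nvb + nv$margin_mm
  centers_left <- cbind(pr$center[1] - dist_c * cos(theta),
                        pr$center[2] + dist_c * sin(theta))
  centers_right <- cbind(pr$center[1] + dist_c * cos(theta),
                         pr$center[2] + dist_c * sin(theta))
  occ_nvb_l <- .voxelize_tube(g, nvb_slices, centers_left, radii_nvb)
  occ_nvb_r <- .voxelize_tube(g, nvb_slices, centers_right, radii_nvb)

  ip <- spec$ipa
  ipa_slices <- ip$slice_range[1]:ip$slice_range[2]
  t_ipa <- (ipa_slices - ip$slice_range[1]) /
    max(1, diff(ip$slice_range))
  y_off <- ip$y_posterior_mm +
    (ip$y_anterior_mm - ip$y_posterior_mm) * t_ipa^2
  centers_ipa_l <- cbind(rep(pr$center[1] - ip$lateral_offset_mm,
                             length(ipa_slices)),
                         pr$center[2] + y_off)
  centers_ipa_r <- cbind(rep(pr$center[1] + ip$lateral_offset_mm,
                             length(ipa_slices)),
                         pr$center[2] + y_off)
  radii_ipa <- rep(ip$radius_mm, length(ipa_slices))
  occ_ipa_l <- .voxelize_tube(g, ipa_slices, centers_ipa_l, radii_ipa)
  occ_ipa_r <- .voxelize_tube(g, ipa_slices, centers_ipa_r, radii_ipa)

  occs <- list(prostate = occ_pros,
               NVB_left = occ_nvb_l, NVB_right = occ_nvb_r,
               IPA_left = occ_ipa_l, IPA_right = occ_ipa_r)

  # pairwise disjointness and a 2-voxel grid margin are structural
  # guarantees the rater-noise model relies on
  total <- Reduce(`+`, lapply(occs, function(o) array(as.integer(o), dim(o))))
  if (any(total > 1L)) stop("phantom structures overlap; adjust the spec")
  for (nm in names(occs)) {
    sub <- arrayInd(which(occs[[nm]]), g$dims)
    if (nrow(sub) == 0L) stop("structure ", nm, " is empty")
    if (any(sub <= 2L) || any(sweep(sub, 2, g$dims - 2L) > 0L)) {
      stop("structure ", nm, " exceeds the grid margin")
    }
  }
  lapply(names(occs), function(nm) {
    structure_mask(occs[[nm]], g, patient_id = patient_id, structure = nm)
  }) |> stats::setNames(names(occs))
}
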