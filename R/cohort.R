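#' Default per-rater noise models
#'
#' Four raters with a common smooth surface displacement, individual
#' systematic margin biases (one neutral, one wide, one tight, one wider),
#' cranio-caudal extent jitter of up to 2 slices per end, and
#' superior-weighted extra displacement. These defaults are illustrative:
#' they are chosen to produce the degree of disagreement typical of small
#' tubular pelvic structures (pairwise Dice roughly in the 0.4-0.8 band),
#' not calibrated to any specific clinical cohort.
#'
#' @param n_raters Number of raters (default 4).
#' @param surface_sigma_mm,extent_jitter_slices,divergence_gain Shared
#'   parameters, see [rater_noise_model()].
#' @param margin_bias_mm Vector of per-rater biases, recycled to
#'   `n_raters`.
#' @return List of `n_raters` [rater_noise_model()] objects.
#' @export
default_rater_noise <- function(n_raters = 4L, surface_sigma_mm = 1.5,
                                margin_bias_mm = c(0, 0.5, -0.5, 1.0),
                                extent_jitter_slices = 2L,
                                divergence_gain = 1.0) {
  bias <- rep_len(margin_bias_mm, n_raters)
  lapply(seq_len(n_raters), function(r) {
    rater_noise_model(surface_sigma_mm = surface_sigma_mm,
                      margin_bias_mm = bias[r],
                      extent_jitter_slices = extent_jitter_slices,
                      divergence_gain = divergence_gain,
                      seed = r)
  })
}

# per-patient anatomical variation: jitter the phantom's free parameters
# by at most `frac` (relative) around the base spec; consumes RNG draws
.jitter_phantom_spec <- function(base, frac = 0.1) {
  u <- function(n = 1L) stats::runif(n, 1 - frac, 1 + frac)
  phantom_spec(
    grid = base$grid,
    prostate_center = base$prostate$center +
      c(stats::runif(2, -2, 2), stats::runif(1, -1, 1)),
    prostate_semi_axes = base$prostate$semi_axes * u(3),
    nvb_theta_deg = base$nvb$theta_deg * u(),
    nvb_radius_inf_mm = base$nvb$radius_inf_mm * u(),
    nvb_radius_sup_mm = base$nvb$radius_sup_mm * u(),
    nvb_margin_mm = base$nvb$margin_mm,
    nvb_extend_slices = base$nvb$extend_slices +
      sample(c(-1L, 0L, 1L), 1L),
    nvb_scale_floor = base$nvb$scale_floor,
    ipa_lateral_offset_mm = base$ipa$lateral_offset_mm * u(),
    ipa_radius_mm = base$ipa$radius_mm * u(),
    ipa_y_posterior_mm = base$ipa$y_posterior_mm * u(),
    ipa_y_anterior_mm = base$ipa$y_anterior_mm * u(),
    ipa_slice_range = base$ipa$slice_range + sample(c(-1L, 0L, 1L), 2L,
                                                    replace = TRUE)
  )
}

#' Generate a synthetic multi-rater cohort on disk
#'
#' Builds `n_patients` phantom anatomies (each a seeded anatomical
#' variation of `base_spec`), simulates every rater's contour of every
#' structure with that rater's noise model, writes all masks as NIfTI files
#' under `out_dir`, and writes a cohort manifest (`manifest.json`). The
#' noise models' seeds are overridden by seeds derived deterministically
#' from `master_seed`, one per (patient, rater, structure), so the whole
#' cohort is reproducible from `master_seed` alone and no two simulated
#' contours share a noise realization.
#'
#' @param n_patients Number of patients (`>= 1`).
#' @param n_raters Number of raters (`>= 2`).
#' @param per_rater_noise List of one [rater_noise_model()] per rater
#'   (default [default_rater_noise()]).
#' @param master_seed Integer master seed.
#' @param out_dir Output directory (created if needed).
#' @param base_spec Base [phantom_spec()] shared by the cohort.
#' @param structures Which base structures to generate (default all 5).
#' @param anatomy_jitter Relative magnitude of per-patient anatomical
#'   variation (default 0.1, i.e. up to 10%).
#' @return The [cohort_manifest()] (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
generate_cohort <- function(n_patients, n_raters = 4L,
                            per_rater_noise = default_rater_noise(n_raters),
                            master_seed = 1L, out_dir,
                            base_spec = phantom_spec(),
                            structures = base_structures(),
                            anatomy_jitter = 0.1) {
  stopifnot(n_patients >= 1L, n_raters >= 2L,
            length(per_rater_noise) == n_raters)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) .concord_error("concord_unwritable_path",
                            paste0("cannot create output directory: ", out_dir))
  }
  structures <- match.arg(structures, base_structures(), several.ok = TRUE)
  patients <- sprintf("P%02d", seq_len(n_patients))
  raters <- sprintf("R%d", seq_len(n_raters))

  rows <- list()
  .with_seed(master_seed, {
    noise_seeds <- array(
      sample.int(.Machine$integer.max - 1L,
                 n_patients * n_raters * length(structures)),
      dim = c(n_patients, n_raters, length(structures)))
    anatomy_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  })
  for (p in seq_len(n_patients)) {
    spec_p <- .with_seed(anatomy_seeds[p],
                         .jitter_phantom_spec(base_spec, anatomy_jitter))
    truth <- generate_phantom(spec_p, patient_id = patients[p])
    for (r in seq_len(n_raters)) {
      for (s in seq_along(structures)) {
        noise <- per_rater_noise[[r]]
        noise$seed <- noise_seeds[p, r, s]
        mask <- simulate_rater(truth[[structures[s]]], noise,
                               rater_id = raters[r])
        rel <- file.path(patients[p],
                         sprintf("%s_%s.nii.gz", raters[r], structures[s]))
        dir.create(file.path(out_dir, patients[p]), showWarnings = FALSE)
        write_mask(mask, file.path(out_dir, rel))
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = patients[p], rater_id = raters[r],
          structure = structures[s], path = rel,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  df$path <- file.path(out_dir, df$path)
  manifest <- cohort_manifest(df)
  rel_df <- df
  rel_df$path <- vapply(rows, function(x) x$path, character(1))
  write_manifest(cohort_manifest(rel_df), file.path(out_dir, "manifest.json"))
  manifest
}
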