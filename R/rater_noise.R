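#' Stochastic rater-noise model
#'
#' Parameterizes how a simulated rater's contour deviates from ground
#' truth, along the disagreement axes observed between human raters:
#'
#' * `surface_sigma_mm` — standard deviation of a smooth random radial
#'   boundary displacement (a low-order harmonic field, so simulated
#'   contours stay simply connected like human contours rather than
#'   speckled).
#' * `margin_bias_mm` — systematic dilation (`+`) or erosion (`-`) of the
#'   whole structure, emulating raters who habitually take a wider or
#'   tighter margin around a structure.
#' * `extent_jitter_slices` — random truncation or extension of the
#'   superior and inferior ends by whole slices, emulating disagreement on
#'   where a structure starts and stops cranio-caudally.
#' * `divergence_gain` — extra displacement amplitude applied toward the
#'   superior end (amplitude scales linearly from 1 at the inferior end to
#'   `1 + divergence_gain` at the superior end), emulating structures that
#'   become more diffuse and harder to distinguish toward the superior end.
#'
#' An all-zero model reproduces the ground truth exactly.
#'
#' @param surface_sigma_mm Non-negative displacement SD in mm.
#' @param margin_bias_mm Systematic margin in mm (may be negative).
#' @param extent_jitter_slices Non-negative integer; each end is moved by a
#'   uniform draw from `-j .. +j` slices.
#' @param divergence_gain Non-negative superior extra-noise gain.
#' @param seed Integer seed making the simulated contour reproducible.
#' @return An object of class `rater_noise_model`.
#' @export
rater_noise_model <- function(surface_sigma_mm = 0, margin_bias_mm = 0,
                              extent_jitter_slices = 0L,
                              divergence_gain = 0, seed = 1L) {
  stopifnot(surface_sigma_mm >= 0, extent_jitter_slices >= 0,
            divergence_gain >= 0)
  structure(
    list(surface_sigma_mm = surface_sigma_mm,
         margin_bias_mm = margin_bias_mm,
         extent_jitter_slices = as.integer(extent_jitter_slices),
         divergence_gain = divergence_gain,
         seed = as.integer(seed)),
    class = "rater_noise_model"
  )
}

#' @export
print.rater_noise_model <- function(x, ...) {
  cat(sprintf(
    "<rater_noise_model> sigma %g mm, bias %+g mm, extent jitter %d, divergence gain %g, seed %d\n",
    x$surface_sigma_mm, x$margin_bias_mm, x$extent_jitter_slices,
    x$divergence_gain, x$seed))
  invisible(x)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# smooth standardized random field over the grid: a sum of K low-frequency
# cosine harmonics, rescaled to unit sample SD (draws K*(3+2) RNG values)
.smooth_field <- function(dims, n_harmonics = 10L, max_freq = 2L) {
  K <- n_harmonics
  kvec <- matrix(sample(seq(-max_freq, max_freq), 3L * K, replace = TRUE),
                 ncol = 3L)
  zero <- rowSums(kvec != 0L) == 0L
  kvec[zero, 1L] <- 1L
  amp <- stats::rnorm(K)
  phase <- stats::runif(K, 0, 2 * pi)
  u <- lapply(1:3, function(a) 2 * pi * (seq_len(dims[a]) - 1) / dims[a])
  field <- array(0, dims)
  for (m in seq_len(K)) {
    ph <- outer(outer(kvec[m, 1] * u[[1]], kvec[m, 2] * u[[2]], `+`),
                kvec[m, 3] * u[[3]], `+`)
    field <- field + amp[m] * cos(ph + phase[m])
  }
  s <- stats::sd(field)
  if (s < 1e-12) array(0, dims) else field / s
}

# occupied slice range (1-based indices) along axis 3
.occupied_slice_range <- function(occ) {
  ks <- which(apply(occ, 3, any))
  c(min(ks), max(ks))
}

# truncate/extend the ends of a mask by whole slices; positive delta
# extends (added slices copy the nearest true end slice), negative truncates
.apply_extent_jitter <- function(occ, delta_inf, delta_sup) {
  nz <- dim(occ)[3]
  rng <- .occupied_slice_range(occ)
  lo <- rng[1] - delta_inf
  hi <- rng[2] + delta_sup
  # keep at least one occupied slice
  if (lo > hi) {
    mid <- (rng[1] + rng[2]) %/% 2
    lo <- hi <- mid
  }
  lo <- max(1L, lo)
  hi <- min(nz, hi)
  out <- occ
  for (k in seq_len(nz)) {
    if (k < lo || k > hi) {
      out[, , k] <- FALSE
    } else if (k < rng[1]) {
      out[, , k] <- occ[, , rng[1]]
    } else if (k > rng[2]) {
      out[, , k] <- occ[, , rng[2]]
    }
  }
  out
}

#' Simulate one rater's contour of a structure
#'
#' Perturbs a ground-truth mask according to a [rater_noise_model()]. The
#' jittered truth (after cranio-caudal extent jitter) is converted to a
#' signed Euclidean distance field (negative inside), and a voxel is
#' occupied in the output iff its signed distance is at most
#' `margin_bias_mm` plus a smooth random displacement field of SD
#' `surface_sigma_mm`, whose amplitude grows toward the superior end when
#' `divergence_gain > 0`. Thresholding the exact distance field makes a
#' pure margin bias an exact physical-distance dilation/erosion.
#'
#' Reproducible given the truth and the model's seed; an all-zero model
#' returns the truth exactly.
#'
#' @param truth A non-empty [structure_mask()].
#' @param noise A [rater_noise_model()].
#' @param rater_id Identifier stamped on the simulated mask.
#' @return A [structure_mask()] on the same grid.
#' @export
simulate_rater <- function(truth, noise, rater_id = NA_character_) {
  stopifnot(inherits(truth, "structure_mask"),
            inherits(noise, "rater_noise_model"))
  if (voxel_count(truth) == 0L) stop("cannot simulate a rater on an empty mask")
  g <- truth$grid
  if (noise$surface_sigma_mm == 0 && noise$margin_bias_mm == 0 &&
      noise$extent_jitter_slices == 0L) {
    out <- truth
    out$rater_id <- as.character(rater_id)
    return(out)
  }
  .with_seed(noise$seed, {
    occ <- truth$occupancy
    if (noise$extent_jitter_slices > 0L) {
      j <- noise$extent_jitter_slices
      deltas <- sample(seq(-j, j), 2L, replace = TRUE)
      occ <- .apply_extent_jitter(occ, deltas[1], deltas[2])
    }
    dt_out <- sqrt(.edt_sq_cpp(as.logical(occ), g$dims, g$spacing))
    dt_in <- sqrt(.edt_sq_cpp(as.logical(!occ), g$dims, g$spacing))
    sdist <- array(dt_out - dt_in, g$dims)
    thr <- noise$margin_bias_mm
    if (noise$surface_sigma_mm > 0) {
      f <- .smooth_field(g$dims) * noise$surface_sigma_mm
      if (noise$divergence_gain > 0) {
        rng <- .occupied_slice_range(occ)
        s <- rep(0, g$dims[3])
        if (rng[2] > rng[1]) {
          s[rng[1]:rng[2]] <- (rng[1]:rng[2] - rng[1]) / (rng[2] - rng[1])
          s[seq_len(g$dims[3]) > rng[2]] <- 1
        }
        amp <- 1 + noise$divergence_gain * s
        f <- sweep(f, 3, amp, `*`)
      }
      thr <- thr + f
    }
    new_occ <- sdist <= thr
    if (!any(new_occ)) {
      stop("rater noise so severe that the simulated contour is empty")
    }
    structure_mask(new_occ, g, patient_id = truth$patient_id,
                   rater_id = rater_id, structure = truth$structure)
  })
}
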