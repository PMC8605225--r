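#' All unordered rater pairs
#'
#' Every pair of distinct raters exactly once, in deterministic sorted
#' order; four raters yield six pairs, `n` raters `choose(n, 2)`.
#'
#' @param raters Character vector of `>= 2` distinct rater ids.
#' @return Data frame with columns `rater_a`, `rater_b`
#'   (`rater_a < rater_b` in sort order).
#' @export
enumerate_rater_pairs <- function(raters) {
  raters <- sort(unique(as.character(raters)))
  if (length(raters) < 2L) stop("need at least 2 distinct raters")
  idx <- utils::combn(length(raters), 2L)
  data.frame(rater_a = raters[idx[1, ]], rater_b = raters[idx[2, ]],
             stringsAsFactors = FALSE)
}

#' Study configuration
#'
#' @param asd_mode How the symmetric average surface distance combines the
#'   two directed distance sets: `"pooled"` (default) or
#'   `"mean_of_means"`; see [avg_surface_distance()].
#' @param hausdorff_percentile See [hausdorff()]; default 100 (exact
#'   maximum).
#' @param no_crop_structures Structures never harmonized (cropped); their
#'   border distance is reported as `NA` and volumes are taken as
#'   contoured. Default `"prostate"`.
#' @param inf_half_structures Structures for which a derived inferior-half
#'   subset is analyzed. Default the two NVBs.
#' @param volume_stage `"post_harmonization"` (default) or
#'   `"pre_harmonization"`: whether reported volumes of cropped structures
#'   are measured after or before cropping.
#' @param max_failures Error out when more than this many (patient,
#'   structure) analyses fail (default `Inf`: log and continue).
#' @return A list of class `study_config`.
#' @export
study_config <- function(asd_mode = c("pooled", "mean_of_means"),
                         hausdorff_percentile = 100,
                         no_crop_structures = "prostate",
                         inf_half_structures = c("NVB_left", "NVB_right"),
                         volume_stage = c("post_harmonization",
                                          "pre_harmonization"),
                         max_failures = Inf) {
  structure(
    list(asd_mode = match.arg(asd_mode),
         hausdorff_percentile = hausdorff_percentile,
         no_crop_structures = no_crop_structures,
         inf_half_structures = inf_half_structures,
         volume_stage = match.arg(volume_stage),
         max_failures = max_failures),
    class = "study_config"
  )
}

#' Run the full interrater agreement study
#'
#' For every patient and structure in the manifest: load all raters' masks,
#' harmonize them to their maximal common superior-inferior extent (except
#' structures in `config$no_crop_structures`), derive inferior-half subsets
#' for `config$inf_half_structures`, and compute Dice, symmetric average
#' surface distance and Hausdorff distance for every unordered rater pair.
#' Volumes are recorded per rater per structure per patient - as contoured
#' for uncropped structures and (by default) after harmonization for
#' cropped ones. Any failure (missing mask, no longitudinal overlap, empty
#' crop) is logged in the returned `failures` and the (patient, structure)
#' skipped, never silently dropped.
#'
#' The run is deterministic: no randomness is consumed, and two runs on the
#' same manifest and configuration yield identical results.
#'
#' @param manifest A [cohort_manifest()] or path to one.
#' @param config A [study_config()].
#' @return A list of class `agreement_study` with data frames:
#'   `records` (patient_id, structure, rater_a, rater_b, dsc,
#'   avg_surface_distance_mm, hausdorff_mm), `intervals` (patient_id,
#'   structure, border_distance_mm; `NA` for uncropped structures),
#'   `volumes` (patient_id, structure, rater_id, volume_cc) and `failures`
#'   (patient_id, structure, reason).
#' @export
run_agreement_study <- function(manifest, config = study_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"),
            inherits(config, "study_config"))
  patients <- sort(unique(manifest$patient_id))
  structures <- unique(manifest$structure)
  # stable presentation order: base structures first, in canonical order
  structures <- c(intersect(base_structures(), structures),
                  sort(setdiff(structures, base_structures())))

  records <- list(); intervals <- list(); volumes <- list(); failures <- list()
  add_fail <- function(pat, struct, reason) {
    failures[[length(failures) + 1L]] <<- data.frame(
      patient_id = pat, structure = struct, reason = reason,
      stringsAsFactors = FALSE)
    if (length(failures) > config$max_failures) {
      stop("aborting: more than ", config$max_failures,
           " (patient, structure) analyses failed")
    }
  }

  for (pat in patients) {
    for (struct in structures) {
      sel <- manifest[manifest$patient_id == pat &
                        manifest$structure == struct, , drop = FALSE]
      sel <- sel[order(sel$rater_id), , drop = FALSE]
      missing <- is.na(sel$path)
      if (any(missing)) {
        add_fail(pat, struct,
                 paste0("missing mask for rater(s) ",
                        paste(sel$rater_id[missing], collapse = ", ")))
        sel <- sel[!missing, , drop = FALSE]
      }
      if (nrow(sel) < 2L) {
        add_fail(pat, struct, "fewer than 2 raters with a mask")
        next
      }
      masks <- tryCatch({
        first <- read_mask(sel$path[1], patient_id = pat,
                           rater_id = sel$rater_id[1], structure = struct)
        rest <- lapply(seq_len(nrow(sel))[-1], function(i) {
          read_mask(sel$path[i], expected_grid = first$grid,
                    patient_id = pat, rater_id = sel$rater_id[i],
                    structure = struct)
        })
        c(list(first), rest)
      }, error = function(e) e)
      if (inherits(masks, "error")) {
        add_fail(pat, struct, conditionMessage(masks))
        next
      }
      pre_volumes <- vapply(masks, volume_cc, numeric(1))

      if (struct %in% config$no_crop_structures) {
        sets <- list(list(label = struct, masks = masks,
                          border_mm = NA_real_, volumes = pre_volumes))
      } else {
        hset <- tryCatch(harmonize(masks), error = function(e) e)
        if (inherits(hset, "error")) {
          add_fail(pat, struct, conditionMessage(hset))
          next
        }
        dz <- hset$masks[[1]]$grid$spacing[hset$masks[[1]]$grid$superior_axis]
        vols <- if (config$volume_stage == "post_harmonization") {
          vapply(hset$masks, volume_cc, numeric(1))
        } else pre_volumes
        sets <- list(list(label = struct, masks = unname(hset$masks),
                          border_mm = interval_length_mm(hset$interval, dz),
                          volumes = vols))
        if (struct %in% config$inf_half_structures) {
          half <- tryCatch(inferior_half_set(hset), error = function(e) e)
          if (inherits(half, "error")) {
            add_fail(pat, inf_half_label(struct), conditionMessage(half))
          } else {
            sets[[2]] <- list(
              label = half$structure, masks = unname(half$masks),
              border_mm = interval_length_mm(half$interval, dz),
              volumes = vapply(half$masks, volume_cc, numeric(1)))
          }
        }
      }

      # masks are in sorted rater order (sel was sorted above)
      rater_ids <- vapply(masks, `[[`, character(1), "rater_id")
      pairs <- enumerate_rater_pairs(rater_ids)
      for (set in sets) {
        caches <- lapply(set$masks, .surface_cache)
        for (q in seq_len(nrow(pairs))) {
          ia <- match(pairs$rater_a[q], rater_ids)
          ib <- match(pairs$rater_b[q], rater_ids)
          pm <- pair_metrics(set$masks[[ia]], set$masks[[ib]],
                             mode = config$asd_mode,
                             hausdorff_percentile = config$hausdorff_percentile,
                             cache_a = caches[[ia]], cache_b = caches[[ib]])
          records[[length(records) + 1L]] <- data.frame(
            patient_id = pat, structure = set$label,
            rater_a = pairs$rater_a[q], rater_b = pairs$rater_b[q],
            dsc = pm$dsc,
            avg_surface_distance_mm = pm$avg_surface_distance_mm,
            hausdorff_mm = pm$hausdorff_mm,
            stringsAsFactors = FALSE)
        }
        intervals[[length(intervals) + 1L]] <- data.frame(
          patient_id = pat, structure = set$label,
          border_distance_mm = set$border_mm, stringsAsFactors = FALSE)
        volumes[[length(volumes) + 1L]] <- data.frame(
          patient_id = pat, structure = set$label,
          rater_id = rater_ids, volume_cc = unname(set$volumes),
          stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  structure(
    list(
      records = bind(records, data.frame(
        patient_id = character(), structure = character(),
        rater_a = character(), rater_b = character(), dsc = numeric(),
        avg_surface_distance_mm = numeric(), hausdorff_mm = numeric())),
      intervals = bind(intervals, data.frame(
        patient_id = character(), structure = character(),
        border_distance_mm = numeric())),
      volumes = bind(volumes, data.frame(
        patient_id = character(), structure = character(),
        rater_id = character(), volume_cc = numeric())),
      failures = bind(failures, data.frame(
        patient_id = character(), structure = character(),
        reason = character())),
      config = config),
    class = "agreement_study"
  )
}

#' @export
print.agreement_study <- function(x, ...) {
  cat(sprintf("<agreement_study> %d pair records, %d structures, %d failures\n",
              nrow(x$records), length(unique(x$records$structure)),
              nrow(x$failures)))
  invisible(x)
}

#' Median and interquartile range of a sample
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7, the common default of mainstream
#' statistics software), so `c(1, 2, 3, 4)` gives median 2.5 and IQR
#' (1.75, 3.25).
#'
#' @param values Numeric vector with `>= 1` finite value.
#' @return A list with `n`, `median`, `q1`, `q3`.
#' @export
summarize_median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("cannot summarize an empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3])
}

.metric_rows <- c(volume_cc = "Overall volume (cc)",
                  border_distance_mm = "Overall distance between superior and inferior border (mm)",
                  dsc = "Overall Dice similarity coefficient",
                  avg_surface_distance_mm = "Overall average surface distance (mm)",
                  hausdorff_mm = "Overall Hausdorff distance (mm)")

#' Summarize a study as a report table
#'
#' One row per (structure, metric) with n, median and IQR, covering
#' per-rater volumes, per-patient harmonized border distances, and the
#' three pairwise agreement metrics. The border distance of never-cropped
#' structures (the prostate) is `NA`.
#'
#' @param study An `agreement_study` from [run_agreement_study()].
#' @return Data frame of class `agreement_report` with columns `structure`,
#'   `metric`, `n`, `median`, `q1`, `q3`, in stable presentation order.
#' @export
build_report <- function(study) {
  stopifnot(inherits(study, "agreement_study"))
  if (nrow(study$records) == 0L) stop("study contains no pair records")
  structs <- unique(c(study$volumes$structure, study$records$structure))
  canonical <- c("prostate", "IPA_left", "IPA_right", "NVB_left", "NVB_right",
                 inf_half_label("NVB_left"), inf_half_label("NVB_right"))
  structs <- c(intersect(canonical, structs),
               sort(setdiff(structs, canonical)))
  rows <- list()
  for (st in structs) {
    for (metric in names(.metric_rows)) {
      vals <- switch(metric,
        volume_cc = study$volumes$volume_cc[study$volumes$structure == st],
        border_distance_mm =
          study$intervals$border_distance_mm[study$intervals$structure == st],
        study$records[[metric]][study$records$structure == st])
      if (metric == "border_distance_mm" &&
          (length(vals) == 0L || all(is.na(vals)))) {
        rows[[length(rows) + 1L]] <- data.frame(
          structure = st, metric = metric, n = length(vals),
          median = NA_real_, q1 = NA_real_, q3 = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      if (length(vals) == 0L) next
      s <- summarize_median_iqr(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = st, metric = metric, n = s$n,
        median = s$median, q1 = s$q1, q3 = s$q3, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' Render a report as a human-readable table
#'
#' Structures as columns, metrics as rows, each cell
#' `median (q1 - q3)` rounded to 2 decimals; `NA` where a metric does not
#' apply (prostate border distance).
#'
#' @param report An `agreement_report` from [build_report()].
#' @return Character matrix (metrics x structures) with row and column
#'   names, printed by [print.agreement_report()].
#' @export
render_report <- function(report) {
  structs <- unique(report$structure)
  metrics <- names(.metric_rows)[names(.metric_rows) %in% report$metric]
  fmt <- function(m, q1, q3) {
    if (is.na(m)) "NA"
    else sprintf("%.2f (%.2f - %.2f)", m, q1, q3)
  }
  cells <- matrix("", nrow = length(metrics), ncol = length(structs),
                  dimnames = list(unname(.metric_rows[metrics]), structs))
  for (i in seq_along(metrics)) {
    for (j in seq_along(structs)) {
      r <- report[report$metric == metrics[i] &
                    report$structure == structs[j], , drop = FALSE]
      cells[i, j] <- if (nrow(r) == 0L) "" else {
        n <- r$n[1]
        paste0(fmt(r$median[1], r$q1[1], r$q3[1]),
               if (metrics[i] == "border_distance_mm" && is.na(r$median[1]))
                 "" else sprintf(" [n=%d]", n))
      }
    }
  }
  cells
}

#' @export
print.agreement_report <- function(x, ...) {
  print(render_report(x), quote = FALSE)
  invisible(x)
}

#' Write study outputs to a directory
#'
#' Emits `pair_metrics.csv` (one rater-pair record per row),
#' `summary_table.csv` and `summary_table.json` (the median/IQR report,
#' rounded to 2 decimals so the machine- and human-readable renderings
#' agree), and `config_used.json`. Output is deterministic: two runs on the
#' same manifest and configuration produce byte-identical files.
#'
#' @param study An `agreement_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_outputs <- function(study, dir) {
  stopifnot(inherits(study, "agreement_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- build_report(study)
  rounded <- report
  for (cn in c("median", "q1", "q3")) rounded[[cn]] <- round(rounded[[cn]], 2)
  utils::write.csv(study$records, file.path(dir, "pair_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(rounded, file.path(dir, "summary_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.data.frame(rounded), file.path(dir, "summary_table.json"),
                       dataframe = "rows", na = "null", pretty = TRUE,
                       digits = NA)
  cfg <- unclass(study$config)
  jsonlite::write_json(cfg, file.path(dir, "config_used.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (nrow(study$failures)) {
    utils::write.csv(study$failures, file.path(dir, "failures.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
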