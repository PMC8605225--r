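#' Cohort manifest: which mask file belongs to which triple
#'
#' A cohort manifest maps every (patient, rater, structure) triple to a mask
#' file location. A triple may be explicitly marked missing with an `NA`
#' path; a triple listed twice is an error, so every triple resolves to
#' exactly one mask or is explicitly missing.
#'
#' @param df Data frame with character columns `patient_id`, `rater_id`,
#'   `structure`, `path`.
#' @return The validated data frame with class `cohort_manifest`.
#' @export
cohort_manifest <- function(df) {
  req <- c("patient_id", "rater_id", "structure", "path")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  for (cn in req) df[[cn]] <- as.character(df[[cn]])
  key <- paste(df$patient_id, df$rater_id, df$structure, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate manifest entry for (%s, %s, %s)",
                 dup$patient_id, dup$rater_id, dup$structure))
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' @export
print.cohort_manifest <- function(x, ...) {
  cat(sprintf("<cohort_manifest> %d patients x %d raters x %d structures (%d entries, %d missing)\n",
              length(unique(x$patient_id)), length(unique(x$rater_id)),
              length(unique(x$structure)), nrow(x), sum(is.na(x$path))))
  invisible(x)
}

#' Read a cohort manifest from JSON or CSV
#'
#' @param path File ending in `.json` or `.csv`, with fields/columns
#'   `patient_id`, `rater_id`, `structure`, `path`. Relative mask paths are
#'   resolved against the manifest's directory.
#' @return A [cohort_manifest()].
#' @export
read_manifest <- function(path) {
  if (grepl("\\.json$", tolower(path))) {
    df <- jsonlite::fromJSON(path)
  } else if (grepl("\\.csv$", tolower(path))) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    stop("manifest must be .json or .csv: ", path)
  }
  df$path <- as.character(df$path)
  rel <- !is.na(df$path) & !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  cohort_manifest(df)
}

#' Write a cohort manifest
#'
#' @param manifest A [cohort_manifest()].
#' @param path Output file ending in `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  df <- as.data.frame(unclass(manifest), stringsAsFactors = FALSE)
  if (grepl("\\.json$", tolower(path))) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         pretty = TRUE)
  } else if (grepl("\\.csv$", tolower(path))) {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    stop("manifest must be .json or .csv: ", path)
  }
  invisible(path)
}
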